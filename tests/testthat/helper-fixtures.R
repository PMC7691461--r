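# Fixture builders shared across test files. All data are generated in code.

# genotype matrix from a haplotype 0/1 matrix (rows = haplotypes, consecutive
# pairs form diploids), with per-population sample naming
make_gm <- function(hap, pops_per_ind, pos = NULL, contig = "chr1") {
  n_ind <- nrow(hap) / 2
  stopifnot(n_ind == length(pops_per_ind))
  S <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(S)
  ids <- character(n_ind)
  cnt <- integer(0)
  for (i in seq_len(n_ind)) {
    p <- pops_per_ind[i]
    cnt[p] <- (if (is.na(cnt[p])) 0L else cnt[p]) + 1L
    ids[i] <- paste0(p, "_", cnt[p])
  }
  dos <- hap[seq(1, 2 * n_ind, 2), , drop = FALSE] +
    hap[seq(2, 2 * n_ind, 2), , drop = FALSE]
  genotype_matrix(ids, rep(contig, S), pos, rep("A", S), rep("T", S),
                  dos, haplotypes = hap)
}

pop_map_of <- function(gm, pops_per_ind) {
  tibble::tibble(sample = gm$sample_ids, population = pops_per_ind)
}

# random biallelic haplotype matrix (every site segregating)
random_hap <- function(n_hap, n_sites, seed = 1) {
  withr::with_seed(seed, {
    h <- matrix(rbinom(n_hap * n_sites, 1, runif(n_sites, 0.1, 0.9)),
                n_hap, n_sites, byrow = TRUE)
    for (s in seq_len(n_sites)) {
      if (all(h[, s] == h[1, s])) h[sample(n_hap, 1), s] <- 1L - h[1, s]
    }
    h
  })
}

single_pop_model <- function(ne = 10000, mu_per_year = 1e-8,
                             generation_years = 1) {
  demographic_model("A", c(A = ne), mu_per_year = mu_per_year,
                    generation_years = generation_years)
}

two_pop_model <- function(ne = c(A = 5000, B = 5000), t_split = 8000,
                          anc_ne = 6000, mig = NULL, mu_per_year = 1e-8,
                          generation_years = 1) {
  demographic_model(c("A", "B"), ne, mig,
                    splits = data.frame(time_gen = t_split, derived = "B",
                                        ancestral = "A",
                                        ancestral_ne = anc_ne),
                    mu_per_year = mu_per_year,
                    generation_years = generation_years)
}

# small three-population IM model; shallow A/B split, deeper C split
three_pop_model <- function(mu_per_year = 1e-8, generation_years = 1) {
  mig <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mig["A", "B"] <- 1e-4
  mig["B", "A"] <- 5e-5
  demographic_model(c("A", "B", "C"), c(A = 8000, B = 8000, C = 4000), mig,
                    splits = data.frame(time_gen = c(3000, 20000),
                                        derived = c("B", "C"),
                                        ancestral = c("A", "A"),
                                        ancestral_ne = c(NA, 9000)),
                    mu_per_year = mu_per_year,
                    generation_years = generation_years)
}
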