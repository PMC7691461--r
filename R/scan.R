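# Windowed genome scan: one row per window carrying every per-population,
# per-pair and branch statistic.

#' Convert one simulated window to a genotype matrix
#'
#' Pairs consecutive haplotypes into diploids and builds an in-memory
#' `genotype_matrix` (REF = ancestral allele) plus the matching population
#' map. Used to push simulated windows through exactly the same statistic
#' code paths as observed data.
#'
#' @param wins Result of [simulate_windows()].
#' @param k Window index.
#' @param contig Contig name to assign.
#' @return List with `gm` and `pop_map`.
#' @export
sim_window_genotypes <- function(wins, k, contig = "sim1") {
  w <- wins[[k]]
  pops <- attr(wins, "pops")
  nsam <- attr(wins, "nsam")
  pops_rep <- rep(pops, nsam)
  n_ind <- sum(nsam) / 2
  ind_pop <- pops_rep[seq(1, sum(nsam), by = 2)]
  ids <- character(n_ind)
  cnt <- setNames(integer(length(pops)), pops)
  for (i in seq_len(n_ind)) {
    cnt[ind_pop[i]] <- cnt[ind_pop[i]] + 1L
    ids[i] <- paste0(ind_pop[i], "_", cnt[ind_pop[i]])
  }
  S <- length(w$pos)
  hap <- w$geno
  dos <- hap[seq(1, 2 * n_ind, 2), , drop = FALSE] +
    hap[seq(2, 2 * n_ind, 2), , drop = FALSE]
  gm <- genotype_matrix(ids, rep(contig, S), w$pos + 1L,
                        rep("A", S), rep("T", S), dos, haplotypes = hap)
  list(gm = gm,
       pop_map = tibble::tibble(sample = ids, population = ind_pop))
}

#' Windowed statistics table
#'
#' Computes, for every window, the per-population diversity and neutrality
#' statistics, LD and recombination summaries, the pairwise FST (with its
#' ratio-of-sums components) and dxy, RND against the outgroup, polarized
#' site-class counts for the focal pair, and (for three populations) the
#' per-population PBS.
#'
#' @param gm A `genotype_matrix` covering the scanned region.
#' @param pop_map Population map; populations other than `outgroup` are
#'   scanned.
#' @param windows Window tibble from [make_windows()].
#' @param pol Optional `polarized_sites` (enables H, Fu & Li's D and site
#'   classes).
#' @param focal Character pair of focal populations for site classes and RND.
#' @param outgroup Outgroup population label in `pop_map` (or `NULL`).
#' @param estimator FST estimator (see [fst_window()]).
#' @param ld_min_dist,rho_min_snps,ld_bin_bp LD/rho settings.
#' @param compute_ld,compute_rho Toggle the quadratic-cost LD statistics.
#' @return Tibble with one row per window (`NA` for undefined statistics).
#' @export
scan_windows <- function(gm, pop_map, windows, pol = NULL,
                         focal = NULL, outgroup = NULL, estimator = "wc",
                         ld_min_dist = 1000, rho_min_snps = 10,
                         ld_bin_bp = 1000, compute_ld = TRUE,
                         compute_rho = TRUE) {
  pops <- setdiff(unique(pop_map$population), outgroup)
  if (is.null(focal)) focal <- pops[seq_len(min(2, length(pops)))]
  samp <- lapply(setNames(pops, pops),
                 function(p) pop_map$sample[pop_map$population == p])
  out_samp <- if (!is.null(outgroup))
    pop_map$sample[pop_map$population == outgroup] else NULL
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  rows <- vector("list", nrow(windows))
  for (k in seq_len(nrow(windows))) {
    win <- windows[k, ]
    idx <- window_sites(gm, win)
    wgm <- slice_sites(gm, idx)
    wpol <- if (!is.null(pol)) pol[idx, , drop = FALSE] else NULL
    callable <- win$end - win$start
    row <- list(contig = win$contig, start = win$start, end = win$end,
                callable_length = callable, n_snps = length(wgm$pos))
    for (p in pops) {
      dv <- diversity_stats(wgm, samp[[p]], callable)
      nt <- neutrality_stats(wgm, samp[[p]], wpol)
      row[[paste0("pi_", p)]] <- dv$pi
      row[[paste0("theta_w_", p)]] <- dv$theta_w
      row[[paste0("he_", p)]] <- dv$he
      row[[paste0("tajima_d_", p)]] <- nt$tajima_d
      row[[paste0("fay_wu_h_", p)]] <- nt$fay_wu_h
      row[[paste0("fu_li_d_", p)]] <- nt$fu_li_d
      if (compute_ld) {
        ld <- ld_stats(wgm, samp[[p]], min_pair_dist = ld_min_dist,
                       bin_bp = ld_bin_bp)
        row[[paste0("mean_r2_", p)]] <- ld$mean_r2
      }
      if (compute_rho) {
        rh <- estimate_rho(wgm, samp[[p]], min_snps = rho_min_snps,
                           callable_length = callable)
        row[[paste0("rho_", p)]] <- rh$rho
        row[[paste0("rho_over_theta_", p)]] <- rh$rho_over_theta
      }
    }
    fsts <- list()
    for (pr in pairs) {
      key <- paste0(pr[1], "_", pr[2])
      fs <- fst_window(wgm, samp[[pr[1]]], samp[[pr[2]]], estimator = estimator)
      fsts[[key]] <- fs$fst
      row[[paste0("fst_", key)]] <- fs$fst
      row[[paste0("fst_num_", key)]] <- fs$num
      row[[paste0("fst_den_", key)]] <- fs$den
      dx <- dxy_rnd_window(wgm, samp[[pr[1]]], samp[[pr[2]]],
                           if (setequal(pr, focal)) out_samp else NULL,
                           callable)
      row[[paste0("dxy_", key)]] <- dx$dxy
      if (setequal(pr, focal)) {
        row[["dxy_focal_out"]] <- dx$dxy_a_out
        row[["rnd"]] <- dx$rnd
      }
    }
    if (!is.null(wpol) && length(focal) == 2) {
      cl <- classify_sites(wgm, samp[[focal[1]]], samp[[focal[2]]], wpol)
      row[["fixed_diff"]] <- cl$fixed_difference
      row[["shared_poly"]] <- cl$shared_polymorphism
      row[[paste0("private_", focal[1])]] <- cl$private_A
      row[[paste0("private_", focal[2])]] <- cl$private_B
    }
    if (length(pops) == 3) {
      key <- function(a, b) {
        k1 <- paste0("fst_", a, "_", b); k2 <- paste0("fst_", b, "_", a)
        if (!is.null(row[[k1]])) row[[k1]] else row[[k2]]
      }
      for (i in seq_along(pops)) {
        a <- pops[i]; bc <- setdiff(pops, a)
        row[[paste0("pbs_", a)]] <-
          as.numeric(pbs(key(a, bc[1]), key(a, bc[2]), key(bc[1], bc[2])))
      }
    }
    rows[[k]] <- tibble::as_tibble(row)
  }
  do.call(rbind, rows)
}

#' Genome-wide FST as a ratio of sums
#'
#' Aggregates the per-window numerator and denominator columns of a scan
#' table (mean-of-window-ratios is biased when windows differ in information
#' content).
#'
#' @param scan Tibble from [scan_windows()].
#' @param pair Character pair, e.g. `c("N", "S")`.
#' @return Genome-wide FST.
#' @export
genomewide_fst <- function(scan, pair) {
  key <- paste0(pair[1], "_", pair[2])
  if (!paste0("fst_num_", key) %in% names(scan))
    key <- paste0(pair[2], "_", pair[1])
  num <- sum(scan[[paste0("fst_num_", key)]], na.rm = TRUE)
  den <- sum(scan[[paste0("fst_den_", key)]], na.rm = TRUE)
  num / den
}
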