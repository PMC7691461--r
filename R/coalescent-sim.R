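# Simulation front-ends over the C++ structured-coalescent engine.

# Flatten model + sampling config into the list the C++ engine expects.
# Adds the outgroup as an extra population merging into the ingroup root.
.sim_model <- function(model, config) {
  validate_model(model)
  stopifnot(inherits(config, "sample_config"))
  pops <- model$populations
  nsam <- setNames(integer(length(pops)), pops)
  hap <- config$haplotypes
  if (!all(names(hap) %in% pops)) stop("sample_config names unknown populations: ",
                                       paste(setdiff(names(hap), pops), collapse = ", "))
  nsam[names(hap)] <- as.integer(hap)
  ne <- as.numeric(model$ne)
  # events
  ev <- data.frame(time = numeric(), type = integer(), pop = integer(),
                   dest = integer(), size = numeric())
  root_pop <- model$populations
  if (nrow(model$splits) > 0) {
    for (i in seq_len(nrow(model$splits))) {
      di <- match(model$splits$derived[i], pops) - 1L
      ai <- match(model$splits$ancestral[i], pops) - 1L
      ev <- rbind(ev, data.frame(time = model$splits$time_gen[i], type = 0L,
                                 pop = di, dest = ai, size = 0))
      if (!is.na(model$splits$ancestral_ne[i]))
        ev <- rbind(ev, data.frame(time = model$splits$time_gen[i], type = 1L,
                                   pop = ai, dest = -1L,
                                   size = model$splits$ancestral_ne[i]))
      root_pop <- setdiff(root_pop, model$splits$derived[i])
    }
  }
  if (!is.null(model$size_changes) && nrow(model$size_changes) > 0) {
    for (i in seq_len(nrow(model$size_changes)))
      ev <- rbind(ev, data.frame(time = model$size_changes$time_gen[i], type = 1L,
                                 pop = match(model$size_changes$pop[i], pops) - 1L,
                                 dest = -1L, size = model$size_changes$ne[i]))
  }
  mig_b <- t(model$migration)  # backward[i, j] = forward[j, i]
  if (isTRUE(config$include_outgroup)) {
    tmax <- if (nrow(model$splits) > 0) max(model$splits$time_gen) else 0
    if (config$outgroup_split_gen <= tmax)
      stop("outgroup_split_gen must exceed the deepest ingroup split")
    out_ne <- config$outgroup_ne
    if (is.null(out_ne)) {
      anc <- model$splits$ancestral_ne[!is.na(model$splits$ancestral_ne)]
      out_ne <- if (length(anc) > 0) anc[length(anc)] else ne[match(root_pop, pops)]
    }
    pops <- c(pops, "OUT")
    nsam <- c(nsam, OUT = as.integer(config$outgroup_haplotypes))
    ne <- c(ne, out_ne)
    mig_b <- rbind(cbind(mig_b, 0), 0)
    ev <- rbind(ev, data.frame(time = config$outgroup_split_gen, type = 0L,
                               pop = length(pops) - 1L,
                               dest = match(root_pop, pops) - 1L, size = 0))
  }
  ev <- ev[order(ev$time, ev$type), , drop = FALSE]
  list(nsam = unname(nsam), ne = unname(ne), mig_backward = unname(mig_b),
       ev_time = as.numeric(ev$time), ev_type = as.integer(ev$type),
       ev_pop = as.integer(ev$pop), ev_dest = as.integer(ev$dest),
       ev_size = as.numeric(ev$size), pops = pops)
}

.mu_per_gen <- function(model) model$mu_per_year * model$generation_years

#' Simulate one genealogy under a demographic model
#'
#' Runs the structured coalescent backward in time (coalescence at rate
#' k(k-1)/(4 Ne) within a population of diploid size Ne, migration at the
#' model's backward rates, splits merging lineage pools, size changes applied
#' at their event times) until all sampled lineages find a common ancestor.
#'
#' @param model A `demographic_model`.
#' @param config A [sample_config()].
#' @param seed Integer seed; the same seed reproduces the genealogy exactly.
#' @return An [ape::ape-package] `phylo` tree with branch lengths in
#'   generations, tip labels `<pop>_<i>`, and attributes `tmrca`,
#'   `total_length` (generations) and `tip_pop`.
#' @export
simulate_genealogy <- function(model, config, seed) {
  sm <- .sim_model(model, config)
  res <- sim_tree_cpp(sm, as.double(seed))
  n <- sum(sm$nsam)
  if (n < 2) stop("need at least two sampled haplotypes")
  # engine ids: tips 0..n-1, internals n..2n-2 in coalescence order (root last)
  # ape ids: tips 1..n, root n+1, internals n+1..2n-1
  remap <- function(id) ifelse(id < n, id + 1L, n + 1L + (2L * n - 2L - id))
  edge <- cbind(remap(res$parent), remap(res$child))
  tip_pop <- sm$pops[rep(seq_along(sm$nsam), sm$nsam)]
  tip_label <- paste0(tip_pop, "_", unlist(lapply(sm$nsam, seq_len)))
  tr <- structure(list(edge = edge, edge.length = as.numeric(res$blen),
                       tip.label = tip_label, Nnode = n - 1L),
                  class = "phylo", order = "postorder")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tmrca") <- res$tmrca
  attr(tr, "total_length") <- res$total_length
  attr(tr, "tip_pop") <- tip_pop
  tr
}

#' Batch genealogy summaries
#'
#' Simulates `n_reps` independent genealogies and returns their TMRCA and
#' total branch length (generations), e.g. to check `E[TMRCA] = 2 Ne` for a
#' pair of lineages in a constant-size population.
#'
#' @inheritParams simulate_genealogy
#' @param n_reps Number of replicate genealogies.
#' @return A tibble with columns `tmrca` and `total_length`.
#' @export
simulate_genealogy_stats <- function(model, config, n_reps, seed) {
  sm <- .sim_model(model, config)
  res <- sim_sfs_branch_cpp(sm, as.integer(n_reps), as.double(seed))
  tibble::tibble(tmrca = res$tmrca, total_length = res$total_length)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places `Poisson(total_length * mu_per_gen * length_bp)` mutations on the
#' tree, each on a branch chosen proportionally to its length and at a
#' distinct position uniform on the window; the derived allele is carried by
#' the branch's descendants.
#'
#' @param genealogy A `phylo` tree from [simulate_genealogy()].
#' @param mu_per_gen Mutation rate per site per generation.
#' @param length_bp Window length in bp.
#' @param seed Integer seed.
#' @return A list with `pos` (0-based positions, sorted) and `geno`
#'   (haplotype-by-site 0/1 matrix, rows named by tip label).
#' @export
drop_mutations <- function(genealogy, mu_per_gen, length_bp, seed) {
  if (mu_per_gen < 0) stop("mutation rate must be >= 0")
  n <- length(genealogy$tip.label)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    tot <- sum(genealogy$edge.length)
    nmut <- stats::rpois(1, tot * mu_per_gen * length_bp)
    if (nmut > 0.9 * length_bp)
      stop("window diversity saturates the infinite-sites model")
    if (nmut == 0) {
      return(list(pos = integer(0),
                  geno = matrix(0L, n, 0, dimnames = list(genealogy$tip.label, NULL))))
    }
    eidx <- sample.int(nrow(genealogy$edge), nmut, replace = TRUE,
                       prob = genealogy$edge.length)
    pos <- sample.int(length_bp, nmut) - 1L
    o <- order(pos)
    pos <- pos[o]; eidx <- eidx[o]
    # descendant tips below each edge's child node
    desc <- .tip_descendants(genealogy)
    geno <- matrix(0L, n, nmut, dimnames = list(genealogy$tip.label, NULL))
    for (s in seq_len(nmut)) geno[desc[[genealogy$edge[eidx[s], 2]]], s] <- 1L
    list(pos = pos, geno = geno)
  })
}

# tip sets below every node of a phylo tree
.tip_descendants <- function(tr) {
  n <- length(tr$tip.label)
  nn <- n + tr$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  tr2 <- ape::reorder.phylo(tr, "postorder")
  for (e in seq_len(nrow(tr2$edge))) {
    p <- tr2$edge[e, 1]; ch <- tr2$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Monte-Carlo expected joint site-frequency spectrum
#'
#' For each replicate genealogy, every branch contributes its length to the
#' joint derived-count class of its descendant set; averaging over replicates
#' gives the expected (branch-length) joint SFS, optionally normalized to
#' proportions over the polymorphic classes. Per-replicate substreams are
#' derived by counter from `seed`, so the same seed gives common random
#' numbers across models (used to smooth likelihood surfaces).
#'
#' @inheritParams simulate_genealogy_stats
#' @param normalize Return proportions over polymorphic classes (`TRUE`) or
#'   raw expected branch lengths (`FALSE`, the storage used in likelihoods).
#' @return A `joint_sfs` array (one dimension per sampled population,
#'   dimension `p` indexing derived counts `0..n_p`).
#' @export
expected_joint_sfs <- function(model, config, n_reps, seed, normalize = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  sm <- .sim_model(model, config)
  res <- sim_sfs_branch_cpp(sm, as.integer(n_reps), as.double(seed))
  de <- .sfs_drop_empty(res$sfs / n_reps, sm$pops, sm$nsam)
  s <- joint_sfs(array(de$arr, dim = de$nsam + 1L), pops = de$pops,
                 type = "expected")
  attr(s, "n_reps") <- n_reps
  if (normalize) s <- normalize_sfs(s)
  s
}

#' Simulate independent sequence windows in memory
#'
#' Each window is a single non-recombining genealogy with infinite-sites
#' mutations (see [simulate_dataset()] for the file-producing variant, and
#' the note there on saturation). Window `k` uses an RNG substream derived by
#' counter, so it is reproducible in isolation.
#'
#' @inheritParams simulate_genealogy
#' @param n_windows Number of windows.
#' @param window_bp Window length in bp.
#' @return A list of windows, each with `pos` (0-based, sorted), `geno`
#'   (haplotype x site 0/1), `tmrca`, `total_length`; attribute `pops` and
#'   `nsam` describe the haplotype rows (populations in order, outgroup last).
#' @export
simulate_windows <- function(model, config, n_windows, window_bp = 10000, seed = 1) {
  sm <- .sim_model(model, config)
  res <- sim_windows_cpp(sm, as.integer(n_windows), as.double(window_bp),
                         .mu_per_gen(model), as.double(seed))
  attr(res, "pops") <- sm$pops
  attr(res, "nsam") <- sm$nsam
  attr(res, "window_bp") <- window_bp
  res
}

#' Simulate an observed joint-SFS dataset
#'
#' The SFS-level analogue of [simulate_dataset()]: for each window one
#' genealogy is drawn and the number of mutations on each branch is Poisson
#' with mean `branch_length * mu * window_bp`, tallied directly into joint
#' derived-count classes. This is exact under the infinite-sites model at the
#' count level and remains usable when per-site diversity is too high for
#' distinct positions to exist (deep ancestral sizes).
#'
#' @inheritParams simulate_windows
#' @return A `joint_sfs` count array with attributes `n_sites` and
#'   `n_windows`.
#' @export
simulate_sfs_dataset <- function(model, config, n_windows, window_bp = 10000,
                                 seed = 1) {
  sm <- .sim_model(model, config)
  res <- sim_sfs_count_cpp(sm, as.integer(n_windows), as.double(window_bp),
                           .mu_per_gen(model), as.double(seed))
  de <- .sfs_drop_empty(res$sfs, sm$pops, sm$nsam)
  s <- joint_sfs(array(de$arr, dim = de$nsam + 1L), pops = de$pops,
                 type = "counts")
  attr(s, "n_windows") <- n_windows
  s
}

#' Simulate a dataset to VCF with truth files
#'
#' Simulates `n_windows` independent windows laid head-to-tail on one contig,
#' forms diploids by pairing consecutive haplotypes, randomizes which allele
#' is written as REF (recording the truth), and writes a VCF, a population
#' map TSV, a BED of windows and a truth JSON (model, seed, per-window TMRCA
#' and total length, per-site ancestral allele). Identical seeds give
#' byte-identical output.
#'
#' Windows are non-recombining by default. `recombination = "smc"` simulates
#' intra-window recombination with a sequential-coalescent (SMC) model and is
#' available for single-population models only (its use here is LD/rho
#' validation). Models whose diversity would exceed ~0.9 segregating sites
#' per bp are rejected: the infinite-sites assumption has no room left (use
#' [simulate_sfs_dataset()] for SFS-level work at such parameter values).
#'
#' @inheritParams simulate_windows
#' @param out_dir Output directory (created if needed).
#' @param recombination `"none"` or `"smc"`.
#' @param rho_window Population-scaled recombination rate (4 Ne c) per window
#'   when `recombination = "smc"`.
#' @param contig Contig name used in the VCF/BED.
#' @return Invisibly, a list with paths `vcf`, `popmap`, `bed`, `truth` and
#'   the parsed truth list.
#' @export
simulate_dataset <- function(model, config, n_windows, window_bp = 10000,
                             recombination = c("none", "smc"), rho_window = 0,
                             seed = 1, out_dir = tempfile("simdata"),
                             contig = "sim1") {
  recombination <- match.arg(recombination)
  sm <- .sim_model(model, config)
  nsam <- sm$nsam
  if (any(nsam %% 2 != 0))
    stop("haplotype counts must be even to form diploids")
  if (recombination == "smc") {
    if (length(nsam[nsam > 0]) != 1 || isTRUE(config$include_outgroup))
      stop("SMC recombination is supported for single-population samples only")
    wins <- lapply(seq_len(n_windows) - 1L, function(k) {
      sim_smc_window_cpp(sum(nsam), sm$ne[which(nsam > 0)], rho_window,
                         as.double(window_bp), .mu_per_gen(model),
                         as.double(seed) + 1000003 * k)
    })
    attr(wins, "pops") <- sm$pops
    attr(wins, "nsam") <- nsam
  } else {
    wins <- simulate_windows(model, config, n_windows, window_bp, seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pops_rep <- rep(sm$pops, nsam)
  n_ind <- sum(nsam) / 2
  ind_pop <- pops_rep[seq(1, sum(nsam), by = 2)]
  sample_ids <- character(n_ind)
  cnt <- setNames(integer(length(sm$pops)), sm$pops)
  for (i in seq_len(n_ind)) {
    p <- ind_pop[i]
    cnt[p] <- cnt[p] + 1L
    sample_ids[i] <- paste0(p, "_", cnt[p])
  }

  vcf_path <- file.path(out_dir, "sim.vcf")
  truth_path <- file.path(out_dir, "truth.json")
  popmap_path <- file.path(out_dir, "popmap.tsv")
  bed_path <- file.path(out_dir, "windows.bed")

  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contig,
                     as.integer(n_windows * window_bp)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"))
  con <- file(vcf_path, "w")
  writeLines(lines, con)
  truth_windows <- vector("list", n_windows)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    for (k in seq_len(n_windows)) {
      w <- wins[[k]]
      S <- length(w$pos)
      ref_is_anc <- if (S > 0) runif(S) < 0.5 else logical(0)
      truth_windows[[k]] <- list(
        tmrca = if (!is.null(w$tmrca)) w$tmrca else NA,
        total_length = if (!is.null(w$total_length)) w$total_length else NA,
        pos = as.integer((k - 1) * window_bp + w$pos + 1L),  # VCF POS
        ref_is_ancestral = ref_is_anc)
      if (S == 0) next
      anc_base <- sample(bases, S, replace = TRUE)
      der_base <- vapply(anc_base, function(b) sample(setdiff(bases, b), 1), "")
      gt <- matrix("", n_ind, S)
      for (i in seq_len(n_ind)) {
        h1 <- w$geno[2 * i - 1, ]
        h2 <- w$geno[2 * i, ]
        a1 <- ifelse(ref_is_anc, h1, 1L - h1)
        a2 <- ifelse(ref_is_anc, h2, 1L - h2)
        gt[i, ] <- paste0(a1, "|", a2, ":99")
      }
      ref <- ifelse(ref_is_anc, anc_base, der_base)
      alt <- ifelse(ref_is_anc, der_base, anc_base)
      body <- paste(contig, truth_windows[[k]]$pos, ".", ref, alt, ".", "PASS",
                    ".", "GT:GQ", sep = "\t")
      for (i in seq_len(n_ind)) body <- paste(body, gt[i, ], sep = "\t")
      writeLines(body, con)
    }
  })
  close(con)

  write.table(data.frame(sample = sample_ids, population = ind_pop),
              popmap_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  wset <- make_windows(setNames(n_windows * window_bp, contig), window_bp)
  write_windows_bed(wset, bed_path)
  truth <- list(model = model_params(model),
                mu_per_year = model$mu_per_year,
                generation_years = model$generation_years,
                seed = seed, n_windows = n_windows, window_bp = window_bp,
                recombination = recombination, rho_window = rho_window,
                windows = truth_windows)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcf_path, popmap = popmap_path, bed = bed_path,
                 truth_path = truth_path, truth = truth))
}
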