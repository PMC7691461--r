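# Outlier-window detection, simulation-null significance with FDR, rank-sum
# contrasts, and HKA/PBS gene-level selection calls.

#' Flag high- and low-differentiation outlier windows
#'
#' `high_diff`: FST at or above the empirical top-`fst_top_fraction`
#' threshold (nearest-rank over non-missing FST windows; ties at the
#' boundary are all included) AND Tajima's D negative per `tajd_rule`
#' (`"either"` — negative in at least one focal population, `"both"`, or
#' `"focal"` — the first focal population only). `low_diff`: FST below
#' `low_fst_threshold`.
#'
#' @param scan Tibble from [scan_windows()] (or any table with the named
#'   columns).
#' @param fst_col FST column name.
#' @param tajd_cols Character vector of Tajima's D column names for the
#'   focal population(s).
#' @param fst_top_fraction Upper tail fraction defining high differentiation.
#' @param tajd_rule `"either"`, `"both"` or `"focal"`.
#' @param low_fst_threshold Low-differentiation cutoff.
#' @return The input with columns `fst_rank_pct`, `high_diff`, `low_diff`.
#' @export
flag_outlier_windows <- function(scan, fst_col, tajd_cols,
                                 fst_top_fraction = 0.01,
                                 tajd_rule = c("either", "both", "focal"),
                                 low_fst_threshold = 0.15) {
  tajd_rule <- match.arg(tajd_rule)
  if (nrow(scan) == 0) stop("empty window table")
  fst <- scan[[fst_col]]
  ok <- !is.na(fst)
  if (!any(ok)) stop("no windows with defined FST")
  m <- sum(ok)
  k <- max(1L, ceiling(fst_top_fraction * m))
  thr <- sort(fst[ok], decreasing = TRUE)[k]
  dmat <- as.matrix(scan[, tajd_cols, drop = FALSE])
  dneg <- switch(tajd_rule,
                 either = rowSums(dmat < 0, na.rm = TRUE) > 0,
                 both = rowSums(dmat < 0, na.rm = TRUE) == length(tajd_cols),
                 focal = !is.na(dmat[, 1]) & dmat[, 1] < 0)
  scan$fst_rank_pct <- NA_real_
  scan$fst_rank_pct[ok] <- rank(fst[ok]) / m * 100
  scan$high_diff <- ok & fst >= thr & dneg
  scan$low_diff <- ok & fst < low_fst_threshold
  scan
}

#' Simulation-null p-values for window FST
#'
#' Simulates `n_sims` windows under the demographic null, computes window
#' FST through the same code path as the observed values, and attaches
#' two-tailed Monte-Carlo p-values with the add-one rule
#' `p+ = (#{sim >= obs} + 1) / (n + 1)` (and the lower-tail analogue), each
#' tail Benjamini-Hochberg corrected separately. Candidate windows have
#' `q < fdr` in either tail.
#'
#' @param obs_fst Numeric vector of observed window FST (NA allowed).
#' @param model Null `demographic_model`.
#' @param config [sample_config()] matching the observed design.
#' @param n_sims Number of null windows (>= 100).
#' @param window_bp Window length.
#' @param pair Population pair to contrast in the simulated windows.
#' @param estimator FST estimator.
#' @param fdr FDR level for the candidate flag.
#' @param seed Seed.
#' @return Tibble: `fst`, `p_high`, `p_low`, `q_high`, `q_low`, `candidate`,
#'   `direction`; attribute `null_fst` carries the null draw.
#' @export
null_fst_pvalues <- function(obs_fst, model, config, n_sims, window_bp = 10000,
                             pair = NULL, estimator = "wc", fdr = 0.01,
                             seed = 1) {
  if (n_sims < 100) stop("n_sims must be >= 100")
  wins <- simulate_windows(model, config, n_sims, window_bp, seed)
  pops <- attr(wins, "pops")[attr(wins, "nsam") > 0]
  if (is.null(pair)) pair <- pops[1:2]
  null_fst <- vapply(seq_len(n_sims), function(k) {
    sw <- sim_window_genotypes(wins, k)
    sa <- sw$pop_map$sample[sw$pop_map$population == pair[1]]
    sb <- sw$pop_map$sample[sw$pop_map$population == pair[2]]
    fst_window(sw$gm, sa, sb, estimator = estimator)$fst
  }, 0)
  null_fst <- null_fst[!is.na(null_fst)]
  ns <- length(null_fst)
  if (ns == 0) stop("null simulation produced no polymorphic windows")
  sorted <- sort(null_fst)
  n_ge <- ns - findInterval(obs_fst, sorted, left.open = TRUE)  # sim >= obs
  n_le <- findInterval(obs_fst, sorted)                          # sim <= obs
  p_high <- (n_ge + 1) / (ns + 1)
  p_low <- (n_le + 1) / (ns + 1)
  p_high[is.na(obs_fst)] <- NA
  p_low[is.na(obs_fst)] <- NA
  q_high <- rep(NA_real_, length(obs_fst))
  q_low <- rep(NA_real_, length(obs_fst))
  ok <- !is.na(obs_fst)
  q_high[ok] <- p.adjust(p_high[ok], method = "BH")
  q_low[ok] <- p.adjust(p_low[ok], method = "BH")
  cand_hi <- !is.na(q_high) & q_high < fdr
  cand_lo <- !is.na(q_low) & q_low < fdr
  out <- tibble::tibble(fst = obs_fst, p_high = p_high, p_low = p_low,
                        q_high = q_high, q_low = q_low,
                        candidate = cand_hi | cand_lo,
                        direction = ifelse(cand_hi, "high",
                                           ifelse(cand_lo, "low", "none")))
  attr(out, "null_fst") <- null_fst
  out
}

#' Wilcoxon/Mann-Whitney rank-sum comparison
#'
#' Two-sided Mann-Whitney U with the normal approximation and tie
#' correction; exact enumeration when both groups have at most 8
#' observations and no ties straddle the groups. Degenerate input (all
#' values tied across both groups) returns `p = 1`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Group-size bound below which the exact distribution is
#'   used.
#' @return List with `U`, `p`, `direction` (`"x_high"`, `"y_high"` or
#'   `"none"`).
#' @export
rank_sum_compare <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1)
    return(list(U = U, p = 1, direction = "none"))
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = FALSE))
  mu <- length(x) * length(y) / 2
  dir <- if (U > mu) "x_high" else if (U < mu) "y_high" else "none"
  list(U = unname(wt$statistic), p = wt$p.value, direction = dir)
}

#' Per-gene polymorphism (A) and fixed-difference (B) counts for the HKA test
#'
#' For each gene interval: `A` — sites polymorphic in the focal population;
#' `B` — sites whose per-site FST between the focal population and the
#' pooled other populations exceeds `fst_threshold` (fixed differences).
#' Genome totals are the sums over the analyzed genes.
#'
#' @param gm A `genotype_matrix`.
#' @param pop_map Population map.
#' @param focal Focal population label.
#' @param others Labels of the populations contrasted with the focal one.
#' @param genes Tibble with `contig`, `start`, `end` (0-based half-open) and
#'   `gene`.
#' @param fst_threshold Per-site FST above which a site counts as fixed.
#' @return Tibble: `gene`, `A`, `B`, plus attributes `A_tot`, `B_tot`.
#' @export
hka_gene_counts <- function(gm, pop_map, focal, others, genes,
                            fst_threshold = 0.95) {
  fs <- pop_map$sample[pop_map$population == focal]
  os <- pop_map$sample[pop_map$population %in% others]
  sf <- .site_counts(gm, fs)
  so <- .site_counts(gm, os)
  poly_focal <- sf$alt > 0 & sf$alt < sf$n
  ok <- sf$n >= 2 & so$n >= 2
  p1 <- sf$alt / sf$n; p2 <- so$alt / so$n
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (sf$n - 1) - p2 * (1 - p2) / (so$n - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst_site <- ifelse(ok & den > 0, num / den, NA_real_)
  fixed <- !is.na(fst_site) & fst_site > fst_threshold
  A <- integer(nrow(genes)); B <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    in_gene <- gm$contig == genes$contig[i] &
      (gm$pos - 1L) >= genes$start[i] & (gm$pos - 1L) < genes$end[i]
    A[i] <- sum(poly_focal & in_gene)
    B[i] <- sum(fixed & in_gene)
  }
  out <- tibble::tibble(gene = genes$gene, A = A, B = B)
  attr(out, "A_tot") <- sum(A)
  attr(out, "B_tot") <- sum(B)
  out
}

#' HKA test against the genome-wide polymorphism/divergence ratio
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' `[[A_gene, B_gene], [A_tot - A_gene, B_tot - B_gene]]`, testing
#' `A(gene)/B(gene) = A(genome)/B(genome)`. Cells with expected count below
#' 5 are flagged.
#'
#' @param a_gene,b_gene Per-gene counts (vectors).
#' @param a_tot,b_tot Genome-wide totals (scalars).
#' @return Tibble: `chisq`, `p`, `low_expected`.
#' @export
hka_test <- function(a_gene, b_gene, a_tot, b_tot) {
  if (a_tot + b_tot <= 0) stop("genome-wide totals must be positive")
  if (any(a_gene > a_tot) || any(b_gene > b_tot))
    stop("gene counts exceed genome totals")
  chisq <- p <- lowexp <- rep(NA_real_, length(a_gene))
  for (i in seq_along(a_gene)) {
    tab <- rbind(c(a_gene[i], b_gene[i]),
                 c(a_tot - a_gene[i], b_tot - b_gene[i]))
    n <- sum(tab)
    if (n == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chisq[i] <- 0; p[i] <- 1; lowexp[i] <- TRUE
      next
    }
    E <- outer(rowSums(tab), colSums(tab)) / n
    chisq[i] <- sum((tab - E)^2 / E)
    p[i] <- pchisq(chisq[i], df = 1, lower.tail = FALSE)
    lowexp[i] <- min(E) < 5
  }
  tibble::tibble(chisq = chisq, p = p, low_expected = as.logical(lowexp))
}

#' Call positively selected genes from HKA and PBS
#'
#' A gene is positive when its HKA p-value is below `hka_alpha` AND its PBS
#' is at or above the nearest-rank `pbs_percentile` of all analyzed genes.
#'
#' @param genes Tibble with `gene`, `hka_p` and `pbs` columns.
#' @param hka_alpha Nominal HKA significance level.
#' @param pbs_percentile Percentile (0-100) of the PBS ranking.
#' @return The input with `pbs_rank_pct` and `positive_selection` columns;
#'   warns when fewer than 20 genes make the percentile unstable.
#' @export
call_positive_genes <- function(genes, hka_alpha = 0.01, pbs_percentile = 95) {
  m <- sum(!is.na(genes$pbs))
  if (m < 20) warning("fewer than 20 genes: PBS percentile is unstable")
  sorted <- sort(genes$pbs)
  thr <- sorted[max(1L, ceiling(pbs_percentile / 100 * m))]
  genes$pbs_rank_pct <- rank(genes$pbs, na.last = "keep") / m * 100
  genes$positive_selection <- !is.na(genes$hka_p) & genes$hka_p < hka_alpha &
    !is.na(genes$pbs) & genes$pbs >= thr
  genes
}

#' Read gene intervals from BED
#'
#' BED3+ (0-based half-open); column 4, when present, names the gene.
#'
#' @param path BED file path.
#' @return Tibble: `contig`, `start`, `end`, `gene`.
#' @export
read_gene_bed <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(tb)[1:3] <- c("contig", "start", "end")
  tb$gene <- if (ncol(tb) >= 4) as.character(tb[[4]]) else
    paste0("gene", seq_len(nrow(tb)))
  tibble::as_tibble(tb[, c("contig", "start", "end", "gene")])
}
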