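# Per-window population-genetic statistics. All estimators are
# frequency-based on called genotypes (haplotypes when phased); undefined
# statistics are NA, never 0.

# per-site ALT counts / available haplotypes for a set of samples,
# preferring phased haplotypes when present
.site_counts <- function(gm, sample_ids) {
  idx <- match(sample_ids, gm$sample_ids)
  if (anyNA(idx)) stop("samples absent from genotype matrix")
  if (!is.null(gm$haplotypes)) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    h <- gm$haplotypes[rows, , drop = FALSE]
    list(alt = colSums(h, na.rm = TRUE), n = colSums(!is.na(h)))
  } else {
    dos <- gm$dosage[idx, , drop = FALSE]
    list(alt = colSums(dos, na.rm = TRUE), n = 2L * colSums(!is.na(dos)))
  }
}

#' Within-population diversity: pi, Watterson's theta, expected heterozygosity
#'
#' `pi` is the mean pairwise difference per callable site
#' (`sum 2 d (n - d) / (n (n - 1)) / callable_length`); `thetaW` is the
#' per-site Watterson estimator `S / (a1(n) * callable_length)` with the
#' harmonic number evaluated at each site's available sample size; `HE` is
#' the mean over SNPs of `2 p (1 - p) * n / (n - 1)`.
#'
#' @param gm A `genotype_matrix` (typically one window).
#' @param samples Sample ids of the population.
#' @param callable_length Callable length of the window in bp (> 0).
#' @return A list with `pi`, `theta_w`, `he`, `n_snps`.
#' @export
diversity_stats <- function(gm, samples, callable_length) {
  if (callable_length <= 0) stop("callable_length must be positive")
  sc <- .site_counts(gm, samples)
  ok <- sc$n >= 2
  d <- sc$alt[ok]; n <- sc$n[ok]
  seg <- d > 0 & d < n
  pi_tot <- sum(2 * d * (n - d) / (n * (n - 1)))
  a1 <- vapply(n[seg], function(k) sum(1 / seq_len(k - 1)), 0)
  theta_tot <- sum(if (any(seg)) 1 / a1 else numeric(0))
  he <- if (any(seg)) {
    p <- d[seg] / n[seg]
    mean(2 * p * (1 - p) * n[seg] / (n[seg] - 1))
  } else 0
  list(pi = pi_tot / callable_length, theta_w = theta_tot / callable_length,
       he = he, n_snps = sum(seg))
}

# Tajima (1989) constants
.tajd_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Fu & Li (1993) D constants (with outgroup; external = derived singletons)
.fuli_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  cn <- if (n > 2) 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2)) else 1
  vd <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  ud <- a1 - 1 - vd
  list(a1 = a1, ud = ud, vd = vd)
}

#' Frequency-spectrum neutrality statistics
#'
#' Tajima's D (standard constants), Fay & Wu's H (`pi - thetaH` with
#' `thetaH = sum 2 xi_i i^2 / (n (n - 1))` over derived counts) and Fu &
#' Li's D (contrast of derived singletons with total polymorphism). H and
#' Fu & Li's D need polarized sites; all three are computed on sites with
#' complete data so a single sample size applies, and are `NA` (never 0)
#' when undefined (no segregating sites, or n below 4 for the D variances).
#'
#' @param gm A `genotype_matrix` (one window).
#' @param samples Sample ids of the population.
#' @param pol Optional `polarized_sites` tibble; required for H and Fu & Li's
#'   D.
#' @return List with `tajima_d`, `fay_wu_h`, `fu_li_d`, `S`.
#' @export
neutrality_stats <- function(gm, samples, pol = NULL) {
  sc <- .site_counts(gm, samples)
  if (length(sc$n) == 0 || max(sc$n) < 2) {
    return(list(tajima_d = NA_real_, fay_wu_h = NA_real_,
                fu_li_d = NA_real_, S = 0L))
  }
  n_full <- max(sc$n)
  complete <- sc$n == n_full
  d <- sc$alt[complete]
  n <- n_full
  seg <- d > 0 & d < n
  S <- sum(seg)
  tajima_d <- NA_real_
  if (n >= 4 && S > 0) {
    k <- .tajd_constants(n)
    pi_tot <- sum(2 * d[seg] * (n - d[seg]) / (n * (n - 1)))
    theta_w <- S / k$a1
    tajima_d <- (pi_tot - theta_w) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  fay_wu_h <- NA_real_
  fu_li_d <- NA_real_
  if (!is.null(pol)) {
    polz <- pol$polarizable[complete]
    flip <- pol$ancestral[complete] == "alt"
    der <- ifelse(flip, n - d, d)
    use <- polz & der > 0 & der < n
    Sp <- sum(use)
    if (Sp > 0) {
      xi <- tabulate(der[use], nbins = n - 1)
      i <- seq_len(n - 1)
      pi_tot <- sum(2 * xi * i * (n - i)) / (n * (n - 1))
      theta_h <- sum(2 * xi * i^2) / (n * (n - 1))
      fay_wu_h <- pi_tot - theta_h
      if (n >= 4) {
        fl <- .fuli_constants(n)
        eta_s <- xi[1]
        fu_li_d <- (Sp - fl$a1 * eta_s) / sqrt(fl$ud * Sp + fl$vd * Sp^2)
      }
    }
  }
  list(tajima_d = tajima_d, fay_wu_h = fay_wu_h, fu_li_d = fu_li_d, S = S)
}

# per-site Weir & Cockerham (1984) variance components for two populations
.wc_components <- function(gm, samplesA, samplesB) {
  ia <- match(samplesA, gm$sample_ids)
  ib <- match(samplesB, gm$sample_ids)
  da <- gm$dosage[ia, , drop = FALSE]
  db <- gm$dosage[ib, , drop = FALSE]
  n1 <- colSums(!is.na(da)); n2 <- colSums(!is.na(db))
  p1 <- colSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(da == 1, na.rm = TRUE) / n1
  h2 <- colSums(db == 1, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- n1 >= 2 & n2 >= 2 & is.finite(a)
  list(a = a, b = b, c = cc, ok = ok, p1 = p1, p2 = p2, n1 = n1, n2 = n2)
}

#' Window FST (Weir-Cockerham or Hudson)
#'
#' Per-site variance components are accumulated and the window value is the
#' ratio of sums (not the mean of per-site ratios, which is biased when few
#' sites segregate). `"wc"` is Weir & Cockerham (1984) on genotypes;
#' `"hudson"` is the Bhatia et al. (2013) form on haplotype frequencies.
#' Windows with no usable polymorphic site return `NA`. The numerator and
#' denominator sums are returned so genome-wide values can be formed as
#' ratios of sums across windows.
#'
#' @param gm A `genotype_matrix` (one window).
#' @param samplesA,samplesB Sample ids of the two populations.
#' @param estimator `"wc"` or `"hudson"`.
#' @return List with `fst`, `num`, `den`.
#' @export
fst_window <- function(gm, samplesA, samplesB, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (estimator == "wc") {
    w <- .wc_components(gm, samplesA, samplesB)
    num <- sum(w$a[w$ok])
    den <- sum((w$a + w$b + w$c)[w$ok])
  } else {
    sa <- .site_counts(gm, samplesA)
    sb <- .site_counts(gm, samplesB)
    ok <- sa$n >= 2 & sb$n >= 2
    p1 <- sa$alt[ok] / sa$n[ok]; p2 <- sb$alt[ok] / sb$n[ok]
    n1 <- sa$n[ok]; n2 <- sb$n[ok]
    num_s <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den_s <- p1 * (1 - p2) + p2 * (1 - p1)
    num <- sum(num_s)
    den <- sum(den_s)
  }
  list(fst = if (den > 0) num / den else NA_real_, num = num, den = den)
}

#' Between-population divergence dxy and relative node depth
#'
#' `dxy` is the mean per-site difference between haplotypes drawn one from
#' each population (`p_A (1 - p_B) + p_B (1 - p_A)` summed over sites),
#' normalized by the callable window length. RND divides `dxy(A, B)` by
#' `dxy(A, outgroup)` to control for mutation-rate variation; it is `NA`
#' when the denominator is zero.
#'
#' @param gm A `genotype_matrix` (one window).
#' @param samplesA,samplesB Population sample ids.
#' @param outgroup_samples Outgroup sample ids (may be `NULL`: no RND).
#' @param callable_length Callable length in bp (> 0).
#' @return List with `dxy`, `dxy_a_out`, `rnd`.
#' @export
dxy_rnd_window <- function(gm, samplesA, samplesB, outgroup_samples = NULL,
                           callable_length) {
  if (callable_length <= 0) stop("callable_length must be positive")
  sa <- .site_counts(gm, samplesA)
  sb <- .site_counts(gm, samplesB)
  ok <- sa$n >= 1 & sb$n >= 1
  pa <- sa$alt[ok] / sa$n[ok]; pb <- sb$alt[ok] / sb$n[ok]
  dxy <- sum(pa * (1 - pb) + pb * (1 - pa)) / callable_length
  dxy_a_out <- NA_real_
  rnd <- NA_real_
  if (!is.null(outgroup_samples)) {
    so <- .site_counts(gm, outgroup_samples)
    ok2 <- sa$n >= 1 & so$n >= 1
    pa2 <- sa$alt[ok2] / sa$n[ok2]; po <- so$alt[ok2] / so$n[ok2]
    dxy_a_out <- sum(pa2 * (1 - po) + po * (1 - pa2)) / callable_length
    if (is.finite(dxy_a_out) && dxy_a_out > 0) rnd <- dxy / dxy_a_out
  }
  list(dxy = dxy, dxy_a_out = dxy_a_out, rnd = rnd)
}

#' Classify polarized sites between two populations
#'
#' Using derived-allele frequencies: `fixed_difference` — derived fixed in
#' one population and absent in the other; `shared_polymorphism` —
#' segregating in both; `private_A` / `private_B` — segregating in exactly
#' one; `monomorphic` otherwise. Classes are mutually exclusive per site.
#'
#' @param gm A `genotype_matrix` (one window).
#' @param samplesA,samplesB Population sample ids.
#' @param pol `polarized_sites` tibble.
#' @return List with per-class counts and the per-site class factor
#'   (`NA` for non-polarizable sites).
#' @export
classify_sites <- function(gm, samplesA, samplesB, pol) {
  sa <- .site_counts(gm, samplesA)
  sb <- .site_counts(gm, samplesB)
  flip <- pol$ancestral == "alt"
  da <- ifelse(flip, sa$n - sa$alt, sa$alt)
  db <- ifelse(flip, sb$n - sb$alt, sb$alt)
  usable <- pol$polarizable & sa$n >= 1 & sb$n >= 1
  segA <- da > 0 & da < sa$n
  segB <- db > 0 & db < sb$n
  fixedA <- da == sa$n
  fixedB <- db == sb$n
  absentA <- da == 0
  absentB <- db == 0
  cls <- rep(NA_character_, length(da))
  cls[usable & ((fixedA & absentB) | (fixedB & absentA))] <- "fixed_difference"
  cls[usable & segA & segB] <- "shared_polymorphism"
  cls[usable & segA & !segB & !(fixedB & absentA)] <- "private_A"
  cls[usable & !segA & segB & !(fixedA & absentB)] <- "private_B"
  cls[usable & is.na(cls)] <- "monomorphic"
  lv <- c("fixed_difference", "shared_polymorphism", "private_A", "private_B",
          "monomorphic")
  f <- factor(cls, levels = lv)
  counts <- as.list(table(f))
  c(counts, list(site_class = f))
}

# r^2 matrix and distances for eligible site pairs
.ld_pairs <- function(gm, samples, min_pair_dist) {
  idx <- match(samples, gm$sample_ids)
  # rows = observations (haplotypes or samples), columns = sites
  if (!is.null(gm$haplotypes)) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    X <- gm$haplotypes[rows, , drop = FALSE]
  } else {
    X <- gm$dosage[idx, , drop = FALSE]
  }
  v <- apply(X, 2, var, na.rm = TRUE)
  sel <- which(is.finite(v) & v > 0)
  if (length(sel) < 2) return(NULL)
  r2 <- suppressWarnings(cor(X[, sel, drop = FALSE],
                             use = "pairwise.complete.obs"))^2
  dmat <- abs(outer(gm$pos[sel], gm$pos[sel], "-"))
  ut <- upper.tri(r2)
  keep <- ut & dmat > min_pair_dist & is.finite(r2)
  if (!any(keep)) return(NULL)
  list(r2 = r2[keep], dist = dmat[keep],
       n_hap = if (!is.null(gm$haplotypes)) 2L * length(idx) else length(idx))
}

#' Linkage-disequilibrium summaries
#'
#' Pairwise `r^2` between polymorphic sites separated by more than
#' `min_pair_dist` bp. Phased data use haplotype allele correlation
#' (equivalently `D^2 / (p_A q_A p_B q_B)`); unphased data fall back to the
#' squared genotype-dosage correlation. The decay profile bins pairs by
#' distance; the half-decay distance is the start of the smallest bin whose
#' mean `r^2` drops to half the maximum bin mean.
#'
#' @param gm A `genotype_matrix` (window or chromosome).
#' @param samples Population sample ids.
#' @param min_pair_dist Minimum pair separation in bp.
#' @param bin_bp Distance-bin width for the decay profile.
#' @return List with `mean_r2`, `n_pairs`, `profile` (tibble: bin_start,
#'   bin_end, mean_r2, n_pairs), `half_decay_bp`; all-`NA` record when no
#'   eligible pair exists.
#' @export
ld_stats <- function(gm, samples, min_pair_dist = 1000, bin_bp = 1000) {
  pr <- .ld_pairs(gm, samples, min_pair_dist)
  if (is.null(pr)) {
    return(list(mean_r2 = NA_real_, n_pairs = 0L,
                profile = tibble::tibble(bin_start = integer(),
                                         bin_end = integer(),
                                         mean_r2 = numeric(),
                                         n_pairs = integer()),
                half_decay_bp = NA_real_))
  }
  bins <- floor(pr$dist / bin_bp)
  prof <- tibble::tibble(
    bin_start = as.integer(sort(unique(bins)) * bin_bp),
    bin_end = as.integer((sort(unique(bins)) + 1) * bin_bp),
    mean_r2 = as.numeric(tapply(pr$r2, bins, mean)),
    n_pairs = as.integer(tapply(pr$r2, bins, length)))
  half <- max(prof$mean_r2) / 2
  below <- prof$bin_start[prof$mean_r2 <= half]
  list(mean_r2 = mean(pr$r2), n_pairs = length(pr$r2), profile = prof,
       half_decay_bp = if (length(below) > 0) min(below) else NA_real_)
}

# Hill & Weir (1988) expected r^2 with sample-size adjustment
.e_r2_hill_weir <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Moment estimate of the population recombination rate rho
#'
#' Least-squares fit of binned mean `r^2` against pair distance to the
#' sample-size-adjusted Hill-Weir expected decay `E[r^2](C = rho_bp * d)`,
#' solved for `rho_bp` and scaled to the window (`rho = 4 Ne c` per window
#' span). A moment fit of this kind recovers the ordering of recombination
#' rates; absolute calibration is not claimed. Also reports `rho` over
#' `theta_pi` (per-site), the size-controlled form used when comparing
#' recombination between differentiation classes.
#'
#' @param gm A `genotype_matrix` (one window).
#' @param samples Population sample ids.
#' @param min_snps Minimum SNPs required (else `NA` record).
#' @param bin_bp Distance-bin width used in the fit.
#' @param callable_length Window span used for scaling and theta_pi.
#' @return List with `rho` (per window), `rho_per_bp`, `rho_over_theta`.
#' @export
estimate_rho <- function(gm, samples, min_snps = 10, bin_bp = 500,
                         callable_length = NULL) {
  if (is.null(callable_length))
    callable_length <- max(gm$pos) - min(gm$pos) + 1
  pr <- .ld_pairs(gm, samples, min_pair_dist = 0)
  empty <- list(rho = NA_real_, rho_per_bp = NA_real_, rho_over_theta = NA_real_)
  if (is.null(pr)) return(empty)
  sc <- .site_counts(gm, samples)
  seg <- sum(sc$alt > 0 & sc$alt < sc$n)
  if (seg < min_snps) return(empty)
  bins <- floor(pr$dist / bin_bp)
  bd <- tapply(pr$dist, bins, mean)
  br <- tapply(pr$r2, bins, mean)
  bw <- tapply(pr$r2, bins, length)
  n <- pr$n_hap
  sse <- function(log_rho_bp) {
    C <- exp(log_rho_bp) * bd
    sum(bw * (br - .e_r2_hill_weir(C, n))^2)
  }
  opt <- optimize(sse, lower = log(1e-8), upper = log(1), tol = 1e-4)
  rho_bp <- exp(opt$minimum)
  # boundary handling: if the fit runs to the lower bound, call it 0
  if (opt$minimum <= log(1e-8) + 1e-3 ||
      sse(log(1e-8)) <= opt$objective + 1e-12) rho_bp <- 0
  ds <- diversity_stats(gm, samples, callable_length)
  list(rho = rho_bp * callable_length, rho_per_bp = rho_bp,
       rho_over_theta = if (ds$pi > 0) rho_bp / ds$pi else NA_real_)
}

#' Population branch statistic
#'
#' `PBS_A = (T_AB + T_AC - T_BC) / 2` with `T = -log(1 - FST)`; the length of
#' the allele-frequency branch leading to population A since its divergence.
#' FST values at or above 1 are clamped to `1 - 1e-9` (flagged via attribute
#' `clamped`); negative PBS is allowed.
#'
#' @param fst_ab,fst_ac,fst_bc Pairwise FST values (vectors recycle).
#' @return PBS for the branch leading to A.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  vals <- cbind(fst_ab, fst_ac, fst_bc)
  if (any(!is.finite(vals) & !is.na(vals))) stop("non-finite FST input")
  clamp <- function(x) pmin(x, 1 - 1e-9)
  clamped <- any(vals >= 1, na.rm = TRUE)
  tt <- -log(1 - clamp(vals))
  out <- (tt[, 1] + tt[, 2] - tt[, 3]) / 2
  attr(out, "clamped") <- clamped
  out
}

#' Principal component analysis of genotype dosages
#'
#' Centers (and optionally frequency-standardizes) the sample-by-site dosage
#' matrix, imputes missing calls at the site mean, drops monomorphic or
#' all-missing sites, and eigendecomposes. Variance-explained fractions sum
#' to 1 over all components.
#'
#' @param gm A `genotype_matrix`.
#' @param pop_map Optional population map; adds a `population` column to the
#'   scores.
#' @param standardize Divide sites by `sqrt(p (1 - p))`?
#' @return List with `scores` (tibble: sample, population, PC1..), and
#'   `var_explained`.
#' @export
genotype_pca <- function(gm, pop_map = NULL, standardize = FALSE) {
  X <- gm$dosage
  if (nrow(X) < 2 || ncol(X) < 1) stop("need >= 2 samples and >= 1 site")
  cm <- colMeans(X, na.rm = TRUE)
  keep <- is.finite(cm) & apply(X, 2, function(x) var(x, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  X <- X[, keep, drop = FALSE]
  cm <- cm[keep]
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- cm[j]
  Xc <- sweep(X, 2, cm)
  if (standardize) {
    p <- cm / 2
    Xc <- sweep(Xc, 2, sqrt(pmax(p * (1 - p), 1e-12)), "/")
  }
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x)
  scores <- cbind(tibble::tibble(sample = gm$sample_ids), scores)
  if (!is.null(pop_map))
    scores$population <- pop_map$population[match(scores$sample, pop_map$sample)]
  list(scores = tibble::as_tibble(scores), var_explained = ve)
}
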