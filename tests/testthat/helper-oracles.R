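# Brute-force reference implementations: direct loops over haplotypes and
# enumeration, kept deliberately independent of the package's vectorized code.

oracle_pi <- function(hap, callable) {
  n <- nrow(hap)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(hap[i, ] != hap[j, ])
    np <- np + 1
  }
  tot / np / callable
}

oracle_thetaw <- function(hap, callable) {
  n <- nrow(hap)
  seg <- 0
  for (s in seq_len(ncol(hap))) {
    if (length(unique(hap[, s])) > 1) seg <- seg + 1
  }
  seg / sum(1 / seq_len(n - 1)) / callable
}

oracle_he <- function(hap) {
  n <- nrow(hap)
  hes <- c()
  for (s in seq_len(ncol(hap))) {
    p <- mean(hap[, s])
    if (p > 0 && p < 1) hes <- c(hes, 2 * p * (1 - p) * n / (n - 1))
  }
  if (length(hes) == 0) 0 else mean(hes)
}

oracle_dxy <- function(hapA, hapB, callable) {
  tot <- 0
  np <- 0
  for (i in seq_len(nrow(hapA))) for (j in seq_len(nrow(hapB))) {
    tot <- tot + sum(hapA[i, ] != hapB[j, ])
    np <- np + 1
  }
  tot / np / callable
}

# Weir & Cockerham (1984) from diploid genotypes, per-site loop
oracle_fst_wc <- function(dosA, dosB) {
  num <- den <- 0
  for (s in seq_len(ncol(dosA))) {
    gA <- dosA[, s]; gB <- dosB[, s]
    n1 <- length(gA); n2 <- length(gB)
    p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
    h1 <- mean(gA == 1); h2 <- mean(gB == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

oracle_fst_hudson <- function(hapA, hapB) {
  num <- den <- 0
  n1 <- nrow(hapA); n2 <- nrow(hapB)
  for (s in seq_len(ncol(hapA))) {
    p1 <- mean(hapA[, s]); p2 <- mean(hapB[, s])
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# Fay & Wu's H from derived-allele haplotypes (ancestral coded 0)
oracle_fay_wu_h <- function(hap) {
  n <- nrow(hap)
  pi_tot <- theta_h <- 0
  for (s in seq_len(ncol(hap))) {
    i <- sum(hap[, s])
    if (i == 0 || i == n) next
    pi_tot <- pi_tot + 2 * i * (n - i) / (n * (n - 1))
    theta_h <- theta_h + 2 * i^2 / (n * (n - 1))
  }
  pi_tot - theta_h
}

oracle_fu_li_d <- function(hap) {
  n <- nrow(hap)
  S <- 0; eta_s <- 0
  for (s in seq_len(ncol(hap))) {
    i <- sum(hap[, s])
    if (i == 0 || i == n) next
    S <- S + 1
    if (i == 1) eta_s <- eta_s + 1
  }
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vd <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  ud <- a1 - 1 - vd
  (S - a1 * eta_s) / sqrt(ud * S + vd * S^2)
}

# haplotype r^2 by direct two-locus haplotype counting
oracle_r2 <- function(x, y) {
  pA <- mean(x); pB <- mean(y)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

oracle_pbs <- function(fab, fac, fbc) {
  (-log(1 - fab) - log(1 - fac) + log(1 - fbc)) / 2
}

# Benjamini-Hochberg step-up, textbook form
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  combs <- utils::combn(nx + ny, nx)
  u_obs <- sum(rank(vals)[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  cnt <- 0
  for (j in seq_len(ncol(combs))) {
    xi <- combs[, j]
    u <- sum(rank(vals)[xi]) - nx * (nx + 1) / 2
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(combs)
}

oracle_chisq_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
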