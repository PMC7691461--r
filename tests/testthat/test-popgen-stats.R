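test_that("hand-computed statistic values are reproduced", {
  # pi: 4 haplotypes, one SNP at derived count 2, callable 10 bp
  hap <- matrix(c(1, 1, 0, 0), ncol = 1)
  gm <- make_gm(hap, c("A", "A"))
  expect_equal(diversity_stats(gm, c("A_1", "A_2"), 10)$pi, (4 / 6) / 10,
               tolerance = 1e-12)
  # thetaW: S = 3, n = 4, callable 1
  hap3 <- matrix(c(1, 0, 0, 0,  0, 1, 0, 0,  1, 1, 0, 0), 4, 3)
  gm3 <- make_gm(hap3, c("A", "A"))
  expect_equal(diversity_stats(gm3, c("A_1", "A_2"), 1)$theta_w,
               3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-4)
  # monomorphic window
  gm0 <- make_gm(matrix(0L, 4, 2), c("A", "A"))
  dv0 <- diversity_stats(gm0, c("A_1", "A_2"), 100)
  expect_equal(c(dv0$pi, dv0$theta_w, dv0$he), c(0, 0, 0))
  # Hudson FST, one site: p1 = 0.5 (n1 = 4), p2 = 0 (n2 = 4) -> 1/3
  hapf <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0), ncol = 1)
  gmf <- make_gm(hapf, c("A", "A", "B", "B"))
  expect_equal(fst_window(gmf, c("A_1", "A_2"), c("B_1", "B_2"),
                          estimator = "hudson")$fst, 1 / 3, tolerance = 1e-12)
  # Fay & Wu's H: n = 4, one site at derived count 3 -> pi 0.5, thetaH 1.5
  haph <- matrix(c(1, 1, 1, 0), ncol = 1)
  gmh <- make_gm(haph, c("A", "A"))
  pol <- tibble::tibble(ancestral = "ref", polarizable = TRUE)
  nt <- neutrality_stats(gmh, c("A_1", "A_2"), pol)
  expect_equal(nt$fay_wu_h, -1.0, tolerance = 1e-12)
  # PBS closed form
  expect_equal(as.numeric(pbs(0.5, 0.5, 0)), log(2), tolerance = 1e-12)
  expect_equal(as.numeric(pbs(0, 0, 0)), 0)
  expect_equal(as.numeric(pbs(0.3, 0.6, 0.2)), as.numeric(pbs(0.6, 0.3, 0.2)))
})

test_that("every statistic matches its brute-force reference on random fixtures", {
  for (seed in 1:8) {
    n_sites <- sample(5:20, 1)
    hap <- random_hap(12, n_sites, seed = seed)
    pos <- sort(sample(1:20000, n_sites))
    gm <- make_gm(hap, c("A", "A", "A", "B", "B", "B"), pos = pos)
    sa <- paste0("A_", 1:3); sb <- paste0("B_", 1:3)
    ha <- hap[1:6, , drop = FALSE]; hb <- hap[7:12, , drop = FALSE]
    L <- 20000
    dv <- diversity_stats(gm, sa, L)
    expect_equal(dv$pi, oracle_pi(ha, L), tolerance = 1e-12)
    expect_equal(dv$theta_w, oracle_thetaw(ha, L), tolerance = 1e-12)
    expect_equal(dv$he, oracle_he(ha), tolerance = 1e-12)
    dx <- dxy_rnd_window(gm, sa, sb, NULL, L)
    expect_equal(dx$dxy, oracle_dxy(ha, hb, L), tolerance = 1e-12)
    fw <- fst_window(gm, sa, sb, estimator = "wc")
    expect_equal(fw$fst, oracle_fst_wc(gm$dosage[1:3, , drop = FALSE],
                                       gm$dosage[4:6, , drop = FALSE]),
                 tolerance = 1e-12)
    fh <- fst_window(gm, sa, sb, estimator = "hudson")
    expect_equal(fh$fst, oracle_fst_hudson(ha, hb), tolerance = 1e-12)
    pol <- tibble::tibble(ancestral = rep("ref", n_sites),
                          polarizable = rep(TRUE, n_sites))
    nt <- neutrality_stats(gm, sa, pol)
    expect_equal(nt$fay_wu_h, oracle_fay_wu_h(ha), tolerance = 1e-12)
    expect_equal(nt$fu_li_d, oracle_fu_li_d(ha), tolerance = 1e-12)
    # r^2 against direct haplotype counting, first eligible pair
    seg <- which(apply(ha, 2, function(x) length(unique(x)) > 1))
    if (length(seg) >= 2) {
      ld <- ld_stats(gm, sa, min_pair_dist = 0, bin_bp = 1e6)
      r2_oracle <- c()
      for (i in seq_along(seg)[-length(seg)])
        for (j in (i + 1):length(seg))
          r2_oracle <- c(r2_oracle, oracle_r2(ha[, seg[i]], ha[, seg[j]]))
      expect_equal(ld$mean_r2, mean(r2_oracle), tolerance = 1e-12)
    }
  }
})

test_that("degenerate and boundary FST cases behave per contract", {
  # populations fixed for different alleles -> FST = 1
  hap <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0), c(1, 1, 1, 1, 0, 0, 0, 0))
  gm <- make_gm(hap, c("A", "A", "B", "B"))
  expect_equal(fst_window(gm, paste0("A_", 1:2), paste0("B_", 1:2),
                          "hudson")$fst, 1)
  expect_equal(fst_window(gm, paste0("A_", 1:2), paste0("B_", 1:2),
                          "wc")$fst, 1)
  # identical allele frequencies, balanced design -> about 0 (>= -0.05);
  # small negative values are the estimator's finite-sample behavior
  hap2 <- random_hap(24, 40, seed = 3)
  hap2 <- rbind(hap2, hap2)  # duplicate: both pops identical
  gm2 <- make_gm(hap2, c(rep("A", 12), rep("B", 12)))
  f2 <- fst_window(gm2, paste0("A_", 1:12), paste0("B_", 1:12), "wc")$fst
  expect_lt(f2, 0.05)
  expect_gte(f2, -0.05)
  # no polymorphic site -> NA, never 0
  gm3 <- make_gm(matrix(0L, 8, 3), c(rep("A", 2), rep("B", 2)))
  expect_true(is.na(fst_window(gm3, paste0("A_", 1:2), paste0("B_", 1:2),
                               "wc")$fst))
  expect_error(fst_window(gm3, paste0("A_", 1:2), paste0("B_", 1:2), "xx"))
})

test_that("n = 2 makes pi and thetaW coincide (Tajima numerator zero)", {
  hap <- random_hap(2, 12, seed = 5)
  gm <- make_gm(hap, "A")
  dv <- diversity_stats(gm, "A_1", 1000)
  expect_equal(dv$pi, dv$theta_w, tolerance = 1e-12)
  expect_true(is.na(neutrality_stats(gm, "A_1")$tajima_d))  # variance undefined
})

test_that("neutral simulations center D and H on zero and match 4 Ne mu", {
  m <- single_pop_model(ne = 10000, mu_per_year = 1e-8)
  w <- simulate_windows(m, sample_config(c(A = 8)), 10000, window_bp = 2000,
                        seed = 14)
  pis <- thetas <- ds <- hs <- numeric(length(w))
  for (k in seq_along(w)) {
    sw <- sim_window_genotypes(w, k)
    samp <- sw$pop_map$sample
    dv <- diversity_stats(sw$gm, samp, 2000)
    pol <- tibble::tibble(ancestral = rep("ref", length(sw$gm$pos)),
                          polarizable = rep(TRUE, length(sw$gm$pos)))
    nt <- neutrality_stats(sw$gm, samp, pol)
    pis[k] <- dv$pi; thetas[k] <- dv$theta_w
    ds[k] <- nt$tajima_d; hs[k] <- nt$fay_wu_h
  }
  theta_true <- 4 * 10000 * 1e-8
  expect_lt(abs(mean(pis) - theta_true), 3 * sd(pis) / sqrt(length(pis)))
  expect_lt(abs(mean(thetas) - theta_true), 3 * sd(thetas) / sqrt(length(thetas)))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 3 * sd(ds, na.rm = TRUE) / sqrt(sum(!is.na(ds))))
  expect_lt(abs(mean(hs, na.rm = TRUE)), 3 * sd(hs, na.rm = TRUE) / sqrt(sum(!is.na(hs))))
})

test_that("two-population dxy matches 4 Ne_anc mu + 2 T mu", {
  mu_gen <- 1e-8
  m <- two_pop_model(ne = c(A = 5000, B = 5000), t_split = 8000,
                     anc_ne = 6000, mu_per_year = 1e-8, generation_years = 1)
  w <- simulate_windows(m, sample_config(c(A = 4, B = 4)), 5000,
                        window_bp = 2000, seed = 15)
  dxys <- vapply(seq_along(w), function(k) {
    sw <- sim_window_genotypes(w, k)
    dxy_rnd_window(sw$gm, paste0("A_", 1:2), paste0("B_", 1:2), NULL, 2000)$dxy
  }, 0)
  expected <- (4 * 6000 + 2 * 8000) * mu_gen
  expect_lt(abs(mean(dxys) - expected), 3 * sd(dxys) / sqrt(length(dxys)))
})

test_that("WC and Hudson agree on balanced designs with n >= 20", {
  m <- two_pop_model(ne = c(A = 5000, B = 5000), t_split = 5000,
                     anc_ne = 5000, mu_per_year = 1e-8)
  w <- simulate_windows(m, sample_config(c(A = 20, B = 20)), 300,
                        window_bp = 5000, seed = 16)
  nw <- nh <- dw <- dh <- 0
  for (k in seq_along(w)) {
    sw <- sim_window_genotypes(w, k)
    sa <- sw$pop_map$sample[sw$pop_map$population == "A"]
    sb <- sw$pop_map$sample[sw$pop_map$population == "B"]
    fw <- fst_window(sw$gm, sa, sb, "wc")
    fh <- fst_window(sw$gm, sa, sb, "hudson")
    nw <- nw + fw$num; dw <- dw + fw$den
    nh <- nh + fh$num; dh <- dh + fh$den
  }
  expect_lt(abs(nw / dw - nh / dh), 0.02)
})

test_that("RND and dxy arithmetic", {
  # one site, A fixed REF, B fixed ALT, outgroup ALT, callable 10 -> dxy 0.1
  hap <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1), ncol = 1)
  gm <- make_gm(hap, c("A", "A", "B", "B", "OUT"))
  r <- dxy_rnd_window(gm, paste0("A_", 1:2), paste0("B_", 1:2), "OUT_1", 10)
  expect_equal(r$dxy, 0.1, tolerance = 1e-12)
  # rnd = dxy_ab / dxy_a_out
  expect_equal(r$rnd, r$dxy / r$dxy_a_out, tolerance = 1e-12)
  # denominator zero -> NA
  hap2 <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0), ncol = 1)
  gm2 <- make_gm(hap2, c("A", "A", "B", "B", "OUT"))
  r2 <- dxy_rnd_window(gm2, paste0("A_", 1:2), paste0("B_", 1:2), "OUT_1", 10)
  expect_true(is.na(r2$rnd) || r2$dxy_a_out > 0)
})

test_that("site classification separates fixed, shared and private", {
  pol <- function(k) tibble::tibble(ancestral = rep("ref", k),
                                    polarizable = rep(TRUE, k))
  hap <- cbind(c(1, 1, 1, 1, 0, 0, 0, 0),  # fixed difference (A derived)
               c(1, 0, 0, 0, 1, 0, 0, 0),  # shared polymorphism
               c(1, 1, 0, 0, 0, 0, 0, 0),  # private A
               c(0, 0, 0, 0, 0, 1, 0, 0),  # private B
               c(0, 0, 0, 0, 0, 0, 0, 0))  # monomorphic
  gm <- make_gm(hap, c("A", "A", "B", "B"))
  cl <- classify_sites(gm, paste0("A_", 1:2), paste0("B_", 1:2), pol(5))
  expect_equal(as.character(cl$site_class),
               c("fixed_difference", "shared_polymorphism", "private_A",
                 "private_B", "monomorphic"))
  expect_equal(cl$fixed_difference, 1L)
  expect_equal(cl$shared_polymorphism, 1L)
})

test_that("LD extremes: perfect association and independence", {
  # AB, AB, ab, ab -> r^2 = 1
  hap <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  gm <- make_gm(hap, c("A", "A"), pos = c(1, 3000))
  expect_equal(ld_stats(gm, paste0("A_", 1:2), min_pair_dist = 1000)$mean_r2,
               1, tolerance = 1e-12)
  # AB, Ab, aB, ab -> D = 0
  hap2 <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  gm2 <- make_gm(hap2, c("A", "A"), pos = c(1, 3000))
  expect_equal(ld_stats(gm2, paste0("A_", 1:2), min_pair_dist = 1000)$mean_r2,
               0, tolerance = 1e-12)
  # no eligible pair -> NA record
  expect_true(is.na(ld_stats(gm2, paste0("A_", 1:2),
                             min_pair_dist = 10000)$mean_r2))
})

test_that("mean r^2 decreases with the recombination rate (SMC windows)", {
  m <- single_pop_model(ne = 10000, mu_per_year = 5e-8)
  cfg <- sample_config(c(A = 16))
  med_r2 <- vapply(c(0, 10, 100), function(rho) {
    res <- simulate_dataset(m, cfg, 120, window_bp = 5000,
                            recombination = "smc", rho_window = rho,
                            seed = 400 + rho, out_dir = withr::local_tempdir())
    gm <- read_vcf(res$vcf, read_pop_map(res$popmap))
    wins <- make_windows(c(sim1 = 120 * 5000), 5000)
    r2s <- vapply(seq_len(nrow(wins)), function(k) {
      wgm <- slice_sites(gm, window_sites(gm, wins[k, ]))
      ld_stats(wgm, gm$sample_ids, min_pair_dist = 500, bin_bp = 500)$mean_r2
    }, 0)
    median(r2s, na.rm = TRUE)
  }, 0)
  expect_true(med_r2[1] > med_r2[2] && med_r2[2] > med_r2[3])
})

test_that("rho estimates order and correlate with the simulated truth", {
  m <- single_pop_model(ne = 10000, mu_per_year = 5e-8)
  cfg <- sample_config(c(A = 16))
  rho_true <- c(5, 20, 80)
  est <- list()
  for (rho in rho_true) {
    res <- simulate_dataset(m, cfg, 100, window_bp = 5000,
                            recombination = "smc", rho_window = rho,
                            seed = 500 + rho, out_dir = withr::local_tempdir())
    gm <- read_vcf(res$vcf, read_pop_map(res$popmap))
    wins <- make_windows(c(sim1 = 100 * 5000), 5000)
    est[[as.character(rho)]] <- vapply(seq_len(nrow(wins)), function(k) {
      wgm <- slice_sites(gm, window_sites(gm, wins[k, ]))
      estimate_rho(wgm, gm$sample_ids, min_snps = 10, bin_bp = 500,
                   callable_length = 5000)$rho
    }, 0)
  }
  meds <- vapply(est, median, 0, na.rm = TRUE)
  expect_true(meds[1] < meds[3])
  truth_vec <- rep(rho_true, each = 100)
  est_vec <- unlist(est)
  ok <- !is.na(est_vec)
  expect_gt(cor(truth_vec[ok], est_vec[ok], method = "spearman"), 0.5)
  # all pairs at r^2 = 1 -> rho 0
  hap <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 0, 0))
  hap <- hap[rep(1:4, 4), ]
  gm1 <- make_gm(hap, rep("A", 8), pos = c(1, 1500, 4000))
  expect_equal(estimate_rho(gm1, paste0("A_", 1:8), min_snps = 3,
                            callable_length = 5000)$rho, 0)
})

test_that("PCA separates structured samples and accounts for all variance", {
  # two internally identical, mutually different groups
  dosA <- matrix(rep(c(2L, 0L, 2L, 0L, 2L), 4), 4, 5, byrow = TRUE)
  dosB <- matrix(rep(c(0L, 2L, 0L, 2L, 0L), 4), 4, 5, byrow = TRUE)
  gm <- genotype_matrix(paste0("s", 1:8), rep("c1", 5), 1:5, rep("A", 5),
                        rep("T", 5), rbind(dosA, dosB))
  pc <- genotype_pca(gm)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  expect_true(all(pc$scores$PC1[1:4] * pc$scores$PC1[5:8] < 0))
  # three simulated populations cluster by label (silhouette > 0.5)
  m <- three_pop_model(mu_per_year = 2e-8)
  w <- simulate_windows(m, sample_config(c(A = 8, B = 8, C = 8)), 60,
                        window_bp = 5000, seed = 17)
  gms <- lapply(seq_along(w), function(k) sim_window_genotypes(w, k))
  dos <- do.call(cbind, lapply(gms, function(x) x$gm$dosage))
  allgm <- genotype_matrix(gms[[1]]$gm$sample_ids,
                           rep("c1", ncol(dos)), seq_len(ncol(dos)),
                           rep("A", ncol(dos)), rep("T", ncol(dos)), dos)
  pm <- gms[[1]]$pop_map
  pc3 <- genotype_pca(allgm, pm)
  xy <- as.matrix(pc3$scores[, c("PC1", "PC2")])
  lab <- pm$population
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    dists <- sqrt(rowSums((xy - matrix(xy[i, ], nrow(xy), 2, byrow = TRUE))^2))
    a <- mean(dists[lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(dists[lab == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
})

test_that("genome-wide FST ordering matches the fitted model's split depths", {
  # FST is invariant to the mutation rate, so the sequence-level check runs
  # the fitted demography at reduced mu (full-rate diversity saturates
  # 10-kb infinite-sites windows; see the methods vignette)
  m <- davidiana_im_model()
  m$mu_per_year <- m$mu_per_year / 100
  cfg <- sample_config(c(N = 8, C = 8, S = 8))
  w <- simulate_windows(m, cfg, 400, window_bp = 10000, seed = 18)
  acc <- list(N_S = c(0, 0), S_C = c(0, 0), N_C = c(0, 0))
  for (k in seq_along(w)) {
    sw <- sim_window_genotypes(w, k)
    smp <- function(p) sw$pop_map$sample[sw$pop_map$population == p]
    for (pair in list(c("N", "S"), c("S", "C"), c("N", "C"))) {
      key <- paste(pair, collapse = "_")
      f <- fst_window(sw$gm, smp(pair[1]), smp(pair[2]), "wc")
      acc[[key]] <- acc[[key]] + c(f$num, f$den)
    }
  }
  fst <- vapply(acc, function(x) x[1] / x[2], 0)
  expect_true(fst[["N_S"]] > fst[["S_C"]])
  expect_true(fst[["S_C"]] > fst[["N_C"]])
})
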