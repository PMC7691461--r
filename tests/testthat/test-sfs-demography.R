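test_that("observed joint SFS tallies derived counts per population", {
  # one site: pop A derived count 2 of 4, pop B 0 of 4
  hap <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0), ncol = 1)
  gm <- make_gm(hap, c("A", "A", "B", "B"))
  pm <- pop_map_of(gm, c("A", "A", "B", "B"))
  pol <- tibble::tibble(ancestral = "ref", polarizable = TRUE)
  s <- observed_joint_sfs(gm, pm, c("A", "B"), pol)
  expect_equal(unclass(s)[3, 1], 1)
  expect_equal(sum(s), 1)
  expect_error(observed_joint_sfs(gm, pm, c("A", "Z"), pol), "absent")
})

test_that("ALT-polarized sites flip to derived counts", {
  hap <- matrix(c(0, 1, 1, 1, 1, 1, 1, 1), ncol = 1)  # ALT count A=3/4, B=4/4
  gm <- make_gm(hap, c("A", "A", "B", "B"))
  pm <- pop_map_of(gm, c("A", "A", "B", "B"))
  pol <- tibble::tibble(ancestral = "alt", polarizable = TRUE)
  s <- observed_joint_sfs(gm, pm, c("A", "B"), pol)
  expect_equal(unclass(s)[2, 1], 1)  # derived = REF: counts (1, 0)
})

test_that("missing genotypes are hypergeometrically projected", {
  # site 1 complete; site 2 has one missing genotype in A -> projected from
  # 2 available haplotypes down to the target size of 2? No: target is the
  # smallest complete count (2 haplotypes after masking), so site 1 (4
  # haplotypes) is projected down as well; mass is conserved either way.
  hap <- cbind(c(1, 1, 0, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0, 0, 0))
  gm <- make_gm(hap, c("A", "A", "B", "B"))
  gm$dosage[1, 2] <- NA_integer_
  gm$haplotypes <- NULL  # force the dosage path, where the NA lives
  pm <- pop_map_of(gm, c("A", "A", "B", "B"))
  pol <- tibble::tibble(ancestral = c("ref", "ref"),
                        polarizable = c(TRUE, TRUE))
  s <- observed_joint_sfs(gm, pm, c("A", "B"), pol)
  expect_equal(sum(s), 2, tolerance = 1e-9)  # both sites kept, mass 1 each
  expect_equal(attr(s, "nsam"), c(2L, 4L))   # A projected to its min count
  # site 1 (2 of 4 derived in A) spreads hypergeometrically over 0..2;
  # site 2 is monomorphic after masking and lands in class (0, 0)
  expect_equal(unclass(s)[, 1],
               stats::dhyper(0:2, 2, 2, 2) + c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("folding maps classes onto their minor configuration", {
  arr <- array(0, dim = c(5, 5))
  arr[4, 5] <- 3  # unfolded class (3, 4) with n = (4, 4)
  s <- joint_sfs(arr, c("A", "B"), type = "counts")
  f <- fold_sfs(s)
  expect_equal(unclass(f)[2, 1], 3)  # folds onto (1, 0)
  expect_equal(sum(f), sum(s))
  # enumeration oracle: folding any random spectrum conserves mass and puts
  # it only on minor-total classes
  withr::with_seed(1, {
    arr2 <- array(stats::rpois(25, 4), dim = c(5, 5))
  })
  f2 <- fold_sfs(joint_sfs(arr2, c("A", "B"), type = "counts"))
  expect_equal(sum(f2), sum(arr2))
  idx <- which(unclass(f2) > 0, arr.ind = TRUE) - 1L
  expect_true(all(rowSums(idx) <= 4))
})

test_that("composite log-likelihood matches hand arithmetic and the MLE property", {
  obs <- joint_sfs(array(c(0, 6, 3, 2, 0), dim = 5), "A", type = "counts")
  ex <- joint_sfs(array(c(0, 6, 3, 2, 0) / 11, dim = 5), "A", type = "expected")
  ll <- composite_loglik(obs, ex)
  expect_equal(ll, 6 * log(6 / 11) + 3 * log(3 / 11) + 2 * log(2 / 11),
               tolerance = 1e-12)
  expect_equal(ll, -10.944, tolerance = 1e-3)
  # no proportion vector beats obs/n (multinomial MLE), by brute-force grid
  grid <- seq(0.05, 0.9, by = 0.05)
  for (p1 in grid) for (p2 in grid) {
    p3 <- 1 - p1 - p2
    if (p3 <= 0) next
    alt <- joint_sfs(array(c(0, p1, p2, p3, 0), dim = 5), "A",
                     type = "expected")
    expect_lte(composite_loglik(obs, alt), ll + 1e-9)
  }
  # zero-count class with tiny expected proportion contributes nothing
  ex2 <- joint_sfs(array(c(0, 6, 3, 1e-12, 0), dim = 5), "A",
                   type = "expected")
  obs0 <- joint_sfs(array(c(0, 6, 3, 0, 0), dim = 5), "A", type = "counts")
  expect_equal(composite_loglik(obs0, ex2),
               6 * log(6 / 9) + 3 * log(3 / 9), tolerance = 1e-9)
  expect_error(
    composite_loglik(obs, joint_sfs(array(1, dim = 3), "A", type = "expected")),
    "dimensions")
})

test_that("AIC table follows the Akaike-weight formulas", {
  f <- function(id, ll, k) list(model_id = id, loglik = ll, n_free = k)
  tb <- model_selection_table(list(f("m1", -100, 5), f("m2", -102, 3)))
  expect_equal(tb$aic, c(210, 210))
  expect_equal(tb$weight, c(0.5, 0.5))
  tb2 <- model_selection_table(list(f("m1", -100, 2), f("m2", -100, 2)))
  expect_equal(tb2$weight, c(0.5, 0.5))
  # a hopeless model (dAIC = 20) leaves the others essentially untouched
  tb3 <- model_selection_table(list(f("m1", -100, 5), f("m2", -102, 3),
                                    f("bad", -110, 5)))
  expect_lt(abs(tb3$weight[1] - 0.5) / 0.5, 1e-4)
  expect_equal(sum(tb3$weight), 1)
  expect_equal(tb3$delta_aic[1], 0)
  # weights invariant to adding a constant to all log-likelihoods
  tb4 <- model_selection_table(list(f("m1", -600, 5), f("m2", -602, 3)))
  expect_equal(tb4$weight, tb$weight)
})

test_that("one-parameter fits recover the generating value within 10%", {
  m <- two_pop_model(ne = c(A = 5000, B = 5000), t_split = 8000,
                     anc_ne = 6000, mu_per_year = 1e-8)
  cfg <- sample_config(c(A = 4, B = 4))
  obs <- simulate_sfs_dataset(m, cfg, 2000, window_bp = 10000, seed = 21)
  ft_ne <- fit_parameters(obs, m, cfg, "Ne_A", optimizer = "grid",
                          n_reps_per_eval = 10000, seed = 22)
  expect_lt(abs(ft_ne$estimates[["Ne_A"]] - 5000) / 5000, 0.10)
  ft_t <- fit_parameters(obs, m, cfg, "T_split_B", optimizer = "grid",
                         n_reps_per_eval = 10000, seed = 22)
  expect_lt(abs(ft_t$estimates[["T_split_B"]] - 8000) / 8000, 0.10)
  # the generating model attains at least the likelihood of a wrong topology
  ll_true <- popdivscan:::.model_loglik(obs, m, cfg, 20000, seed = 23)
  wrong <- two_pop_model(ne = c(A = 5000, B = 5000), t_split = 40000,
                         anc_ne = 500, mu_per_year = 1e-8)
  ll_wrong <- popdivscan:::.model_loglik(obs, wrong, cfg, 20000, seed = 23)
  expect_gte(ll_true, ll_wrong)
})

test_that("coordinate search improves and flags convergence", {
  m <- two_pop_model(mu_per_year = 1e-8)
  cfg <- sample_config(c(A = 4, B = 4))
  obs <- simulate_sfs_dataset(m, cfg, 1000, window_bp = 10000, seed = 31)
  start <- update_model(m, c(Ne_A = 2500))
  ft <- fit_parameters(obs, start, cfg, c("Ne_A"), n_reps_per_eval = 4000,
                       optimizer = "coordinate", max_cycles = 6, seed = 32)
  expect_true(ft$converged)
  expect_lt(abs(ft$estimates[["Ne_A"]] - 5000) / 5000, 0.25)
  expect_gt(nrow(ft$trace), 1)
})

test_that("parametric bootstrap percentile edge cases and determinism", {
  m <- single_pop_model(ne = 8000, mu_per_year = 1e-8)
  cfg <- sample_config(c(A = 4))
  b1 <- parametric_bootstrap(m, cfg, "Ne_A", n_windows = 300,
                             window_bp = 10000, n_boot = 2,
                             n_reps_per_eval = 2000, optimizer = "grid",
                             seed = 41)
  expect_equal(b1$intervals$lower, min(b1$estimates[, "Ne_A"]))
  expect_equal(b1$intervals$upper, max(b1$estimates[, "Ne_A"]))
  b2 <- parametric_bootstrap(m, cfg, "Ne_A", n_windows = 300,
                             window_bp = 10000, n_boot = 2,
                             n_reps_per_eval = 2000, optimizer = "grid",
                             seed = 41)
  expect_identical(b1$intervals, b2$intervals)
  expect_error(parametric_bootstrap(m, cfg, "Ne_A", 100, n_boot = 1), ">= 2")
})

test_that("bootstrap intervals cover the truth at near-nominal rate", {
  m <- single_pop_model(ne = 8000, mu_per_year = 1e-8)
  cfg <- sample_config(c(A = 4))
  covered <- vapply(1:10, function(r) {
    bt <- parametric_bootstrap(m, cfg, "Ne_A", n_windows = 200,
                               window_bp = 10000, n_boot = 16,
                               n_reps_per_eval = 1500, optimizer = "grid",
                               seed = 1000 + r)
    bt$intervals$lower <= 8000 && bt$intervals$upper >= 8000
  }, TRUE)
  expect_gte(sum(covered), 8)  # nominal 95%, small-sample slack
})

test_that("spectra round-trip through the plain-text format", {
  m <- two_pop_model(mu_per_year = 1e-8)
  s <- simulate_sfs_dataset(m, sample_config(c(A = 4, B = 4)), 200,
                            window_bp = 5000, seed = 51)
  path <- withr::local_tempfile(fileext = ".sfs")
  write_sfs(s, path)
  s2 <- read_sfs(path)
  expect_equal(unclass(s2), unclass(s), ignore_attr = TRUE)
  expect_equal(attr(s2, "pops"), attr(s, "pops"))
  expect_equal(attr(s2, "folded"), attr(s, "folded"))
})
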