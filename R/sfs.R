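# Joint site-frequency spectra and composite-likelihood demographic inference.

#' Joint site-frequency spectrum container
#'
#' A K-dimensional array (one dimension per population; dimension `p` indexes
#' derived-allele counts `0..n_p`) carrying population labels and whether the
#' entries are observed counts or expected branch lengths ("expected"; these
#' are normalized to proportions over polymorphic classes at likelihood time
#' or via [normalize_sfs()]).
#'
#' @param entries Numeric array, dims `nsam + 1`.
#' @param pops Character labels, one per dimension.
#' @param type `"counts"` or `"expected"`.
#' @param folded Is the spectrum folded onto minor-allele classes?
#' @return A `joint_sfs` object.
#' @export
joint_sfs <- function(entries, pops, type = c("counts", "expected"),
                      folded = FALSE) {
  type <- match.arg(type)
  entries <- as.array(entries)
  nsam <- dim(entries) - 1L
  if (length(pops) != length(nsam)) stop("pops length must match array dimensions")
  if (any(entries < 0)) stop("SFS entries must be >= 0")
  structure(entries, class = "joint_sfs", pops = pops, nsam = nsam,
            type = type, folded = folded)
}

.sfs_drop_empty <- function(arr, pops, nsam) {
  keep <- nsam > 0
  dim(arr) <- (nsam + 1L)[keep]  # dropped dims all have extent 1
  list(arr = arr, pops = pops[keep], nsam = nsam[keep])
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("Joint SFS (%s%s): pops %s, n = (%s), %g entries total\n",
              attr(x, "type"), if (attr(x, "folded")) ", folded" else "",
              paste(attr(x, "pops"), collapse = "/"),
              paste(attr(x, "nsam"), collapse = ","), sum(x)))
  invisible(x)
}

# corner classes (all-ancestral / all-derived) excluded from likelihoods
.sfs_corner_idx <- function(sfs) {
  d <- dim(sfs)
  c(1L, prod(d))  # linear indices of (0,...,0) and (n1,...,nK)
}

#' Normalize an expected SFS to proportions over polymorphic classes
#'
#' @param sfs A `joint_sfs`.
#' @return The spectrum rescaled so polymorphic classes sum to 1 (corner
#'   classes are zeroed).
#' @export
normalize_sfs <- function(sfs) {
  v <- unclass(sfs)
  v[.sfs_corner_idx(sfs)] <- 0
  s <- sum(v)
  if (s > 0) v <- v / s
  a <- attributes(sfs)
  attributes(v) <- a
  v
}

#' Marginal spectrum over a subset of populations
#'
#' Summing the joint spectrum over the other populations' derived counts;
#' for expected spectra this is the marginal expected branch-length spectrum.
#'
#' @param sfs A `joint_sfs`.
#' @param pops Labels of populations to keep, in order.
#' @return A `joint_sfs` over `pops`.
#' @export
marginal_sfs <- function(sfs, pops) {
  all_pops <- attr(sfs, "pops")
  keep <- match(pops, all_pops)
  if (anyNA(keep)) stop("unknown population in marginal_sfs")
  m <- apply(unclass(sfs), keep, sum)
  m <- array(m, dim = (attr(sfs, "nsam") + 1L)[keep])
  out <- joint_sfs(m, pops = pops, type = attr(sfs, "type"),
                   folded = attr(sfs, "folded"))
  attr(out, "n_reps") <- attr(sfs, "n_reps")
  out
}

#' All pairwise 2D marginals of a joint spectrum
#'
#' @param sfs A `joint_sfs` over three or more populations.
#' @return Named list of 2D `joint_sfs`, one per unordered population pair.
#' @export
pairwise_sfs <- function(sfs) {
  pops <- attr(sfs, "pops")
  prs <- utils::combn(pops, 2, simplify = FALSE)
  out <- lapply(prs, function(p) marginal_sfs(sfs, p))
  names(out) <- vapply(prs, paste, "", collapse = "_")
  out
}

#' Fold a spectrum onto minor-allele classes
#'
#' Each unfolded class is added to its complement-sum minor configuration:
#' class `d` (total derived count above half the total sample size) folds
#' onto `n - d`. Exact-half classes stay in place.
#'
#' @param sfs A `joint_sfs`.
#' @return The folded spectrum (non-canonical cells zero).
#' @export
fold_sfs <- function(sfs) {
  if (attr(sfs, "folded")) return(sfs)
  nsam <- attr(sfs, "nsam")
  N <- sum(nsam)
  x <- unclass(sfs)
  out <- array(0, dim = dim(x))
  idx <- arrayInd(seq_along(x), dim(x)) - 1L
  tot <- rowSums(idx)
  for (i in seq_along(x)) {
    d <- idx[i, ]
    if (tot[i] * 2 < N || (tot[i] * 2 == N && .lex_le(d, nsam - d))) {
      comp <- nsam - d
      ci <- sum(comp * cumprod(c(1, head(nsam + 1L, -1)))) + 1L
      out[i] <- x[i] + if (ci != i) x[ci] else 0
    }
  }
  s <- joint_sfs(out, pops = attr(sfs, "pops"), type = attr(sfs, "type"),
                 folded = TRUE)
  attr(s, "n_reps") <- attr(sfs, "n_reps")
  s
}

.lex_le <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  TRUE
}

#' Observed joint SFS from genotypes
#'
#' Tallies per-site derived-allele counts per population into a joint
#' spectrum. Unfolded spectra use only sites polarizable against the
#' outgroup (or truth states); folded spectra need no polarization. Sites
#' with missing genotypes are hypergeometrically down-projected to a fixed
#' per-population haplotype count (default: the smallest observed complete
#' count), the standard treatment when spectra must have fixed dimensions.
#'
#' @param gm A `genotype_matrix`.
#' @param pop_map A population map (see [read_pop_map()]).
#' @param pops Populations to score, in order.
#' @param pol A `polarized_sites` tibble from [polarize_sites()]; required
#'   unless `fold = TRUE`.
#' @param fold Build the folded (minor-allele) spectrum?
#' @param project_to Optional named vector of target haplotype counts per
#'   population for hypergeometric projection.
#' @return A `joint_sfs` of (possibly fractional) counts.
#' @export
observed_joint_sfs <- function(gm, pop_map, pops, pol = NULL, fold = FALSE,
                               project_to = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_pops <- setdiff(pops, unique(pop_map$population))
  if (length(missing_pops) > 0)
    stop("population(s) absent from map: ", paste(missing_pops, collapse = ", "))
  if (!fold && is.null(pol))
    stop("unfolded spectra require polarized sites (pol)")
  S <- length(gm$pos)
  keep <- rep(TRUE, S)
  if (!fold) keep <- keep & pol$polarizable
  alt <- lapply(pops, function(p) {
    ids <- pop_map$sample[pop_map$population == p]
    .allele_counts(gm, ids)
  })
  d <- lapply(alt, `[[`, "alt")     # ALT-allele counts per site
  nn <- lapply(alt, `[[`, "n")      # available haplotypes per site
  if (!fold) {
    for (p in seq_along(pops)) {
      flip <- pol$ancestral == "alt"
      d[[p]] <- ifelse(flip, nn[[p]] - d[[p]], d[[p]])
    }
  }
  keep <- keep & Reduce(`&`, lapply(nn, function(x) x >= 2))
  n_target <- if (is.null(project_to)) {
    vapply(nn, function(x) if (any(keep)) min(x[keep]) else 0L, 0)
  } else as.numeric(project_to[pops])
  dims <- n_target + 1
  arr <- array(0, dim = dims)
  strides <- cumprod(c(1, head(dims, -1)))
  full <- Reduce(`&`, lapply(seq_along(pops),
                             function(p) nn[[p]] == n_target[p])) & keep
  # fast path: complete sites at target size
  if (any(full)) {
    lin <- rep(1, sum(full))
    for (p in seq_along(pops)) lin <- lin + d[[p]][full] * strides[p]
    tab <- table(lin)
    arr[as.integer(names(tab))] <- arr[as.integer(names(tab))] + as.numeric(tab)
  }
  # projection path
  proj <- keep & !full
  for (s in which(proj)) {
    ws <- lapply(seq_along(pops), function(p) {
      if (nn[[p]][s] < n_target[p]) return(NULL)
      stats::dhyper(0:n_target[p], d[[p]][s], nn[[p]][s] - d[[p]][s], n_target[p])
    })
    if (any(vapply(ws, is.null, TRUE))) next
    cell <- Reduce(function(a, b) outer(a, b), ws)
    arr <- arr + array(cell, dim = dims)
  }
  s <- joint_sfs(arr, pops = pops, type = "counts")
  if (fold) s <- fold_sfs(s)
  s
}

# per-site ALT-allele counts and available haplotypes for a sample set
.allele_counts <- function(gm, sample_ids) {
  idx <- match(sample_ids, gm$sample_ids)
  if (anyNA(idx)) stop("samples absent from genotype matrix: ",
                       paste(sample_ids[is.na(idx)], collapse = ", "))
  dos <- gm$dosage[idx, , drop = FALSE]
  alt <- colSums(dos, na.rm = TRUE)
  n <- 2L * colSums(!is.na(dos))
  list(alt = alt, n = n)
}

#' Multinomial composite log-likelihood of an observed spectrum
#'
#' `sum(n_c * log p_c)` over polymorphic classes, where `p` is the expected
#' spectrum normalized over those classes (corner classes excluded from both
#' sides). Expected proportions that are zero where counts are positive are
#' floored at `1/(10 * n_reps * n_classes)` — Monte-Carlo zeros are sampling
#' artifacts, not structural ones. Accepts matching lists of spectra (e.g.
#' the three pairwise 2D spectra), summing their contributions.
#'
#' @param obs Observed `joint_sfs` counts, or list thereof.
#' @param expected Expected `joint_sfs` (branch lengths or proportions), or
#'   matching list.
#' @return Composite log-likelihood (finite scalar).
#' @export
composite_loglik <- function(obs, expected) {
  if (is.list(obs) && !inherits(obs, "joint_sfs")) {
    if (!is.list(expected) || length(obs) != length(expected))
      stop("obs and expected lists must match")
    return(sum(mapply(composite_loglik, obs, expected)))
  }
  if (!identical(dim(obs), dim(expected)))
    stop("observed and expected spectra have different dimensions")
  corner <- .sfs_corner_idx(obs)
  n <- as.numeric(obs)[-corner]
  e <- as.numeric(expected)[-corner]
  tot <- sum(e)
  if (tot <= 0) stop("expected spectrum is identically zero")
  p <- e / tot
  n_reps <- attr(expected, "n_reps")
  floor_p <- 1 / (10 * max(1, n_reps %||% 1e6) * length(p))
  use <- n > 0
  p_use <- pmax(p[use], floor_p)
  sum(n[use] * log(p_use))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate composite log-likelihood of a model against observed spectra,
# with common random numbers (fixed seed) across calls
.model_loglik <- function(obs, model, config, n_reps, seed) {
  exp_full <- expected_joint_sfs(model, config, n_reps, seed)
  if (is.list(obs) && !inherits(obs, "joint_sfs")) {
    exps <- lapply(obs, function(o) marginal_sfs(exp_full, attr(o, "pops")))
    composite_loglik(obs, exps)
  } else {
    composite_loglik(obs, marginal_sfs(exp_full, attr(obs, "pops")))
  }
}

# vertex of the parabola through three (x, y) points; NA when degenerate
.parabola_vertex <- function(x, y) {
  d1 <- x[2] - x[1]; d2 <- x[3] - x[2]
  num <- d1^2 * (y[2] - y[3]) - d2^2 * (y[2] - y[1])
  den <- d1 * (y[2] - y[3]) + d2 * (y[2] - y[1])
  if (!is.finite(num) || !is.finite(den) || abs(den) < 1e-12) return(NA_real_)
  x[2] - 0.5 * num / den
}

#' Profile one model parameter by composite likelihood
#'
#' Evaluates the composite log-likelihood on a (log-spaced) grid for a single
#' free parameter, all others fixed, using common random numbers so adjacent
#' grid points share Monte-Carlo noise. Optionally refines with a second,
#' narrower grid at doubled replication and interpolates the maximum
#' quadratically from the top three points.
#'
#' @param obs Observed `joint_sfs` (or list of pairwise spectra).
#' @param model Template `demographic_model` (fixed-parameter values).
#' @param config [sample_config()] matching the observed data.
#' @param param Parameter name (see [model_params()]).
#' @param lower,upper Grid bounds (defaults 0.5x-2x the template value).
#' @param grid_points Stage-1 grid size.
#' @param n_reps Monte-Carlo genealogies per grid point (stage 1).
#' @param refine Run the +/-12%% stage-2 grid at `2 * n_reps`?
#' @param seed Seed shared by every evaluation (common random numbers).
#' @return A list: `estimate`, `loglik`, `trace` (tibble of value/loglik),
#'   `param`.
#' @export
profile_parameter <- function(obs, model, config, param, lower = NULL,
                              upper = NULL, grid_points = 13, n_reps = 20000,
                              refine = TRUE, seed = 1) {
  p0 <- model_params(model)[[param]]
  if (is.null(p0) || is.na(p0)) stop("unknown parameter: ", param)
  lower <- lower %||% (0.5 * p0)
  upper <- upper %||% (2.0 * p0)
  grid <- exp(seq(log(lower), log(upper), length.out = grid_points))
  eval_at <- function(v, reps) {
    m <- update_model(model, setNames(v, param))
    .model_loglik(obs, m, config, reps, seed)
  }
  ll <- vapply(grid, eval_at, 0, reps = n_reps)
  trace <- tibble::tibble(value = grid, loglik = ll, stage = 1L)
  best <- grid[which.max(ll)]
  if (refine) {
    g2 <- exp(seq(log(best * 0.88), log(best * 1.12), length.out = 11))
    ll2 <- vapply(g2, eval_at, 0, reps = 2 * n_reps)
    trace <- rbind(trace, tibble::tibble(value = g2, loglik = ll2, stage = 2L))
    i <- which.max(ll2)
    best <- g2[i]
    if (i > 1 && i < length(g2)) {
      v <- .parabola_vertex(log(g2[(i - 1):(i + 1)]), ll2[(i - 1):(i + 1)])
      if (is.finite(v) && v >= log(g2[i - 1]) && v <= log(g2[i + 1]))
        best <- exp(v)
    }
    ll_best <- max(ll2)
  } else {
    i <- which.max(ll)
    if (i > 1 && i < length(grid)) {
      v <- .parabola_vertex(log(grid[(i - 1):(i + 1)]), ll[(i - 1):(i + 1)])
      if (is.finite(v) && v >= log(grid[i - 1]) && v <= log(grid[i + 1]))
        best <- exp(v)
    }
    ll_best <- max(ll)
  }
  list(param = param, estimate = best, loglik = ll_best, trace = trace)
}

#' Fit free parameters of a demographic model by composite likelihood
#'
#' Maximizes the simulation-based composite likelihood over a declared set of
#' free parameters. `optimizer = "grid"` profiles a single free parameter
#' (see [profile_parameter()]); `optimizer = "coordinate"` cycles through the
#' free parameters (conditional maximization), moving each to the best point
#' of a shrinking multiplicative neighborhood, until a cycle improves the
#' log-likelihood by less than `tol` or `max_cycles` is hit. All evaluations
#' share one seed (common random numbers), which smooths the Monte-Carlo
#' likelihood surface.
#'
#' @inheritParams profile_parameter
#' @param free Character vector of free parameter names.
#' @param bounds Optional list of `c(lower, upper)` per free parameter.
#' @param n_reps_per_eval Monte-Carlo genealogies per likelihood evaluation.
#' @param optimizer `"grid"` or `"coordinate"`.
#' @param max_cycles,tol Coordinate-search stopping rule.
#' @return A `fit_result` list: `model_id`, `params` (full vector at the
#'   optimum), `estimates` (free subset), `loglik`, `n_free`, `converged`,
#'   `trace`.
#' @export
fit_parameters <- function(obs, model, config, free, bounds = NULL,
                           n_reps_per_eval = 5000,
                           optimizer = c("coordinate", "grid"),
                           grid_points = 13, max_cycles = 15, tol = 1,
                           seed = 1, model_id = "model") {
  optimizer <- match.arg(optimizer)
  p_all <- model_params(model)
  if (!all(free %in% names(p_all))) stop("unknown free parameter(s)")
  if (optimizer == "grid") {
    if (length(free) != 1) stop("grid optimizer profiles exactly one parameter")
    b <- bounds[[free]] %||% c(NA, NA)
    pr <- profile_parameter(obs, model, config, free,
                            lower = if (is.na(b[1])) NULL else b[1],
                            upper = if (is.na(b[2])) NULL else b[2],
                            grid_points = grid_points,
                            n_reps = n_reps_per_eval, seed = seed)
    m <- update_model(model, setNames(pr$estimate, free))
    return(structure(list(model_id = model_id, params = model_params(m),
                          estimates = setNames(pr$estimate, free),
                          loglik = pr$loglik, n_free = 1L, converged = TRUE,
                          trace = pr$trace), class = "fit_result"))
  }
  cur <- model
  cur_ll <- .model_loglik(obs, cur, config, n_reps_per_eval, seed)
  trace <- tibble::tibble(cycle = 0L, param = NA_character_,
                          value = NA_real_, loglik = cur_ll)
  span <- 0.6  # initial half-width of the multiplicative neighborhood (log units)
  converged <- FALSE
  for (cyc in seq_len(max_cycles)) {
    ll_start <- cur_ll
    for (pm in free) {
      v0 <- model_params(cur)[[pm]]
      cand <- v0 * exp(seq(-span, span, length.out = 7))
      b <- bounds[[pm]]
      if (!is.null(b)) cand <- pmin(pmax(cand, b[1]), b[2])
      cand <- unique(c(v0, cand))
      lls <- vapply(cand, function(v) {
        .model_loglik(obs, update_model(cur, setNames(v, pm)), config,
                      n_reps_per_eval, seed)
      }, 0)
      i <- which.max(lls)
      if (cand[i] != v0) cur <- update_model(cur, setNames(cand[i], pm))
      cur_ll <- lls[i]
      trace <- rbind(trace, tibble::tibble(cycle = cyc, param = pm,
                                           value = cand[i], loglik = cur_ll))
    }
    span <- span * 0.6
    if (cur_ll - ll_start < tol) { converged <- TRUE; break }
  }
  structure(list(model_id = model_id, params = model_params(cur),
                 estimates = model_params(cur)[free], loglik = cur_ll,
                 n_free = length(free), converged = converged, trace = trace),
            class = "fit_result")
}

#' AIC / Akaike-weight model comparison table
#'
#' `AIC = 2k - 2 logL`, `dAIC = AIC - min(AIC)`,
#' `weight = exp(-dAIC/2) / sum(exp(-dAIC/2))`.
#'
#' @param fits List of `fit_result` objects (or lists with `model_id`,
#'   `loglik`, `n_free`).
#' @return Tibble sorted by AIC with columns `model`, `loglik`, `k`, `aic`,
#'   `delta_aic`, `weight`; weights sum to 1 and the best model has
#'   `delta_aic = 0`.
#' @export
model_selection_table <- function(fits) {
  if (length(fits) < 1) stop("need at least one fit")
  tb <- tibble::tibble(
    model = vapply(fits, function(f) f$model_id %||% "model", ""),
    loglik = vapply(fits, function(f) f$loglik, 0),
    k = vapply(fits, function(f) as.integer(f$n_free), 0L))
  tb$aic <- 2 * tb$k - 2 * tb$loglik
  tb$delta_aic <- tb$aic - min(tb$aic)
  w <- exp(-tb$delta_aic / 2)
  tb$weight <- w / sum(w)
  tb[order(tb$aic), ]
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` joint-SFS datasets at the fitted parameter values,
#' refits the same free parameters to each, and reports 2.5/97.5 percentile
#' intervals (nearest-rank, so `n_boot = 2` gives the min/max of the two
#' estimates). Non-converged refits are flagged, excluded and counted.
#'
#' @inheritParams fit_parameters
#' @param n_windows,window_bp Size of each simulated bootstrap dataset.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param pairwise Fit the set of pairwise 2D marginals (default when the
#'   model has 3+ populations)?
#' @return A list with `intervals` (tibble: param, lower, upper),
#'   `estimates` (matrix n_boot x n_free), `n_failed`.
#' @export
parametric_bootstrap <- function(model, config, free, n_windows,
                                 window_bp = 10000, n_boot = 100,
                                 n_reps_per_eval = 5000,
                                 optimizer = c("coordinate", "grid"),
                                 bounds = NULL, seed = 1) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  optimizer <- match.arg(optimizer)
  use_pairwise <- length(model$populations) >= 3
  est <- matrix(NA_real_, n_boot, length(free),
                dimnames = list(NULL, free))
  ok <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    sfs <- simulate_sfs_dataset(model, config, n_windows, window_bp,
                                seed = seed + 7919 * b)
    obs <- if (use_pairwise) pairwise_sfs(sfs) else sfs
    ft <- fit_parameters(obs, model, config, free, bounds = bounds,
                         n_reps_per_eval = n_reps_per_eval,
                         optimizer = optimizer, seed = seed + 104729 * b)
    ok[b] <- isTRUE(ft$converged)
    if (ok[b]) est[b, ] <- ft$estimates
  }
  keep <- est[ok, , drop = FALSE]
  ints <- tibble::tibble(
    param = free,
    lower = unname(apply(keep, 2, quantile, probs = 0.025, type = 1,
                         names = FALSE)),
    upper = unname(apply(keep, 2, quantile, probs = 0.975, type = 1,
                         names = FALSE)))
  list(intervals = ints, estimates = est, n_failed = sum(!ok))
}

#' Write / read a spectrum as plain text
#'
#' Header lines carry the population labels, haplotype counts, entry type and
#' folded flag; the body is the flattened array in column-major order.
#'
#' @param sfs A `joint_sfs`.
#' @param path File path.
#' @return `read_sfs()` returns the `joint_sfs`; `write_sfs()` the path,
#'   invisibly.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#pops:", paste(attr(sfs, "pops"), collapse = " ")),
               paste("#nsam:", paste(attr(sfs, "nsam"), collapse = " ")),
               paste("#type:", attr(sfs, "type")),
               paste("#folded:", attr(sfs, "folded")),
               paste(format(as.numeric(sfs), digits = 17), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  ln <- readLines(path)
  val <- function(tag) sub(paste0("^#", tag, ": ?"), "", ln[startsWith(ln, paste0("#", tag, ":"))])
  pops <- strsplit(val("pops"), " ")[[1]]
  nsam <- as.integer(strsplit(val("nsam"), " ")[[1]])
  type <- val("type")
  folded <- as.logical(val("folded"))
  body <- ln[!startsWith(ln, "#")]
  x <- as.numeric(strsplit(trimws(paste(body, collapse = " ")), "\\s+")[[1]])
  joint_sfs(array(x, dim = nsam + 1L), pops = pops, type = type, folded = folded)
}
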