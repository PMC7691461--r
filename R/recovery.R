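# Parameter-recovery workflow: simulate a joint-SFS dataset under a model and
# profile each headline parameter one at a time by composite likelihood.

#' One-at-a-time parameter recovery by profile composite likelihood
#'
#' Simulates an observed joint-SFS dataset under `model` (window-level
#' Poisson mutation counts; see [simulate_sfs_dataset()]), forms the pairwise
#' 2D spectra, and profiles each requested parameter on a log grid with all
#' other parameters fixed at their generating values — the standard check
#' that the inference machinery recovers what the simulator put in, and the
#' workflow behind reproducing fitted demographies. All likelihood
#' evaluations share common random numbers.
#'
#' @param model Generating `demographic_model` (also the profile template).
#' @param config [sample_config()] (haplotypes per population).
#' @param params Character vector of parameter names to profile (see
#'   [model_params()]).
#' @param n_windows,window_bp Simulated dataset size.
#' @param n_reps Monte-Carlo genealogies per likelihood evaluation (stage-1;
#'   the refinement stage doubles this).
#' @param seed Seed; the dataset uses `seed`, the likelihood evaluations use
#'   `seed + 1` (common across all grid points).
#' @param bounds Optional named list of `c(lower, upper)` grid bounds per
#'   parameter; defaults to 0.5x-2x the generating value (effective
#'   population sizes typically use 0.25x-4x).
#' @return Tibble: `param`, `truth`, `estimate`, `loglik`.
#' @export
profile_recovery <- function(model, config, params, n_windows = 40000,
                             window_bp = 10000, n_reps = 50000, seed = 1,
                             bounds = NULL) {
  obs3 <- simulate_sfs_dataset(model, config, n_windows, window_bp,
                               seed = seed)
  obs <- if (length(attr(obs3, "pops")) >= 3) pairwise_sfs(obs3) else obs3
  truth <- model_params(model)
  rows <- lapply(params, function(pm) {
    b <- bounds[[pm]]
    pr <- profile_parameter(obs, model, config, pm,
                            lower = if (!is.null(b)) b[1] else NULL,
                            upper = if (!is.null(b)) b[2] else NULL,
                            n_reps = n_reps, seed = seed + 1)
    tibble::tibble(param = pm, truth = truth[[pm]], estimate = pr$estimate,
                   loglik = pr$loglik)
  })
  do.call(rbind, rows)
}
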