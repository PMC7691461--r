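# Demographic models: populations with diploid sizes, split events, forward
# migration rates, optional size changes (bottlenecks), mutation rate per year
# and generation time. Time inside a model is always backward, in generations;
# years appear only at the I/O boundary.

#' Construct a demographic model
#'
#' Describes a multi-population isolation-with-migration (IM) demography:
#' present-day diploid effective sizes, population splits (merges, looking
#' backward in time), an asymmetric per-generation migration matrix and
#' optional piecewise-constant size changes (e.g. bottlenecks).
#'
#' @param populations Character vector of population labels (present-day
#'   sampled populations).
#' @param ne Named numeric vector of present-day diploid effective sizes,
#'   one per population.
#' @param migration Square numeric matrix of *forward-time* per-generation
#'   migration rates; `migration[from, to]` is the probability per generation
#'   that an individual in `to` is a new migrant from `from`. Internally the
#'   simulator uses the equivalent backward-time lineage-movement rates
#'   (`backward[i, j] = migration[j, i]`). Default: no migration.
#' @param splits Data frame with columns `time_gen` (backward time in
#'   generations), `derived`, `ancestral` (population labels) and optionally
#'   `ancestral_ne` (diploid size the merged ancestral population takes on at
#'   the split; `NA` keeps its current size).
#' @param size_changes Optional data frame with columns `pop`, `time_gen`,
#'   `ne`: at backward time `time_gen` the population's size becomes `ne`.
#'   Two rows express a bottleneck.
#' @param mu_per_year Mutation rate per site per year.
#' @param generation_years Years per generation.
#'
#' @return An object of class `demographic_model`.
#' @seealso [davidiana_im_model()], [model_params()], [simulate_dataset()]
#' @export
demographic_model <- function(populations, ne, migration = NULL, splits = NULL,
                              size_changes = NULL, mu_per_year = 2.5e-9,
                              generation_years = 15) {
  populations <- as.character(populations)
  if (anyDuplicated(populations)) stop("duplicate population labels")
  ne <- ne[populations]
  if (anyNA(ne)) stop("`ne` must name every population")
  if (is.null(migration)) {
    migration <- matrix(0, length(populations), length(populations),
                        dimnames = list(populations, populations))
  }
  migration <- as.matrix(migration)
  if (!identical(dim(migration), rep(length(populations), 2L)))
    stop("migration matrix dimensions do not match populations")
  dimnames(migration) <- list(populations, populations)
  diag(migration) <- 0
  if (is.null(splits)) {
    splits <- data.frame(time_gen = numeric(), derived = character(),
                         ancestral = character(), ancestral_ne = numeric())
  }
  splits <- as.data.frame(splits)
  if (is.null(splits$ancestral_ne)) splits$ancestral_ne <- rep(NA_real_, nrow(splits))
  splits <- splits[order(splits$time_gen), , drop = FALSE]
  if (!is.null(size_changes)) size_changes <- as.data.frame(size_changes)
  m <- structure(list(populations = populations, ne = ne, migration = migration,
                      splits = splits, size_changes = size_changes,
                      mu_per_year = mu_per_year,
                      generation_years = generation_years),
                 class = "demographic_model")
  validate_model(m)
  m
}

#' Validate a demographic model
#'
#' Checks all model invariants: positive finite sizes and rates, positive,
#' topologically consistent split times (each split references two populations
#' that are still distinct at that time; exactly one lineage pool remains after
#' the final split, so every sample is guaranteed a common ancestor).
#'
#' @param model A `demographic_model`.
#' @return The model, invisibly; errors if an invariant fails.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  with(model, {
    if (any(!is.finite(ne)) || any(ne <= 0)) stop("all Ne must be positive and finite")
    if (any(!is.finite(migration)) || any(migration < 0))
      stop("migration rates must be non-negative and finite")
    if (!is.finite(mu_per_year) || mu_per_year < 0) stop("mu_per_year must be >= 0")
    if (!is.finite(generation_years) || generation_years <= 0)
      stop("generation_years must be positive")
    if (nrow(splits) > 0) {
      if (any(!is.finite(splits$time_gen)) || any(splits$time_gen <= 0))
        stop("split times must be positive and finite")
      open <- populations
      for (i in seq_len(nrow(splits))) {
        d <- splits$derived[i]; a <- splits$ancestral[i]
        if (!(d %in% open)) stop("split derived population '", d,
                                 "' is unknown or already merged")
        if (!(a %in% open) || a == d) stop("split ancestral population '", a,
                                           "' is not open at that time")
        open <- setdiff(open, d)
      }
      if (length(open) != 1)
        stop("splits must reduce the populations to a single ancestor; ",
             length(open), " remain")
    } else if (length(populations) > 1) {
      stop("multiple populations require splits so all lineages can coalesce")
    }
    if (!is.null(size_changes)) {
      if (any(!is.finite(size_changes$ne)) || any(size_changes$ne <= 0))
        stop("size-change Ne must be positive")
      if (any(size_changes$time_gen < 0)) stop("size-change times must be >= 0")
      if (!all(size_changes$pop %in% populations)) stop("size change for unknown population")
    }
  })
  invisible(model)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", length(x$populations), "populations (",
      paste(x$populations, collapse = ", "), ")\n")
  cat("  Ne:", paste(sprintf("%s=%g", x$populations, x$ne), collapse = ", "), "\n")
  if (nrow(x$splits) > 0) {
    for (i in seq_len(nrow(x$splits))) {
      cat(sprintf("  split: %s -> %s at %.1f gen (%.0f yr)%s\n",
                  x$splits$derived[i], x$splits$ancestral[i], x$splits$time_gen[i],
                  years_from_generations(x$splits$time_gen[i], x$generation_years),
                  ifelse(is.na(x$splits$ancestral_ne[i]), "",
                         sprintf(", ancestral Ne=%g", x$splits$ancestral_ne[i]))))
    }
  }
  cat(sprintf("  mu = %g /site/yr, generation = %g yr\n",
              x$mu_per_year, x$generation_years))
  invisible(x)
}

#' Published three-population IM model for *Populus davidiana*
#'
#' The fitted isolation-with-migration demography for the Northeast (N),
#' Central (C) and South (S) populations of *P. davidiana*: an ancestral
#' population (Ne 2,573,682) split into Northern and Southern lineages
#' 792,548 years ago, and the Northern lineage split into N and C 78,933
#' years ago, with asymmetric migration among all pairs. Times are converted
#' to generations at 15 years per generation; the mutation rate is
#' 2.5e-9 per site per year.
#'
#' @return A `demographic_model` with populations `N`, `C`, `S`.
#' @export
davidiana_im_model <- function() {
  g <- 15
  pops <- c("N", "C", "S")
  ne <- c(N = 45278, C = 63365, S = 12666)
  mig <- matrix(0, 3, 3, dimnames = list(pops, pops))
  mig["N", "C"] <- 1.81e-5
  mig["C", "N"] <- 4.02e-6
  mig["N", "S"] <- 1.74e-7
  mig["S", "N"] <- 2.46e-7
  mig["C", "S"] <- 1.13e-6
  mig["S", "C"] <- 1.53e-5
  splits <- data.frame(
    time_gen = c(78933 / g, 792548 / g),
    derived = c("C", "S"),
    ancestral = c("N", "N"),
    ancestral_ne = c(NA, 2573682))
  demographic_model(pops, ne, mig, splits,
                    mu_per_year = 2.5e-9, generation_years = g)
}

#' Convert between generations and years
#'
#' @param t_gen,t_years Time in generations / years (finite, non-negative).
#' @param generation_years Years per generation.
#' @return The converted time.
#' @export
years_from_generations <- function(t_gen, generation_years = 15) {
  if (any(!is.finite(t_gen)) || any(t_gen < 0)) stop("time must be finite and >= 0")
  t_gen * generation_years
}

#' @rdname years_from_generations
#' @export
generations_from_years <- function(t_years, generation_years = 15) {
  if (any(!is.finite(t_years)) || any(t_years < 0)) stop("time must be finite and >= 0")
  t_years / generation_years
}

# --- flat parameterization -------------------------------------------------

#' Flat named parameter vector of a model
#'
#' Exposes the tunable parameters under stable names: `Ne_<pop>` for
#' present-day sizes, `T_split_<derived>` for split times (generations),
#' `Ne_anc_<derived>` for ancestral sizes set at a split, and `m_<from>_<to>`
#' for non-zero forward migration rates. [update_model()] is its inverse.
#'
#' @param model A `demographic_model`.
#' @return Named numeric vector.
#' @export
model_params <- function(model) {
  p <- setNames(as.numeric(model$ne), paste0("Ne_", model$populations))
  if (nrow(model$splits) > 0) {
    p <- c(p, setNames(model$splits$time_gen, paste0("T_split_", model$splits$derived)))
    has_anc <- !is.na(model$splits$ancestral_ne)
    if (any(has_anc))
      p <- c(p, setNames(model$splits$ancestral_ne[has_anc],
                         paste0("Ne_anc_", model$splits$derived[has_anc])))
  }
  mig <- model$migration
  nz <- which(mig > 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    nm <- paste0("m_", rownames(mig)[nz[, 1]], "_", colnames(mig)[nz[, 2]])
    p <- c(p, setNames(mig[nz], nm))
  }
  p
}

#' Update model parameters by name
#'
#' @param model A `demographic_model`.
#' @param params Named numeric vector using the names of [model_params()].
#' @return The updated, re-validated model.
#' @export
update_model <- function(model, params) {
  for (nm in names(params)) {
    v <- as.numeric(params[[nm]])
    if (grepl("^Ne_anc_", nm)) {
      d <- sub("^Ne_anc_", "", nm)
      i <- which(model$splits$derived == d)
      if (length(i) != 1) stop("unknown parameter: ", nm)
      model$splits$ancestral_ne[i] <- v
    } else if (grepl("^Ne_", nm)) {
      pop <- sub("^Ne_", "", nm)
      if (!pop %in% model$populations) stop("unknown parameter: ", nm)
      model$ne[pop] <- v
    } else if (grepl("^T_split_", nm)) {
      d <- sub("^T_split_", "", nm)
      i <- which(model$splits$derived == d)
      if (length(i) != 1) stop("unknown parameter: ", nm)
      model$splits$time_gen[i] <- v
    } else if (grepl("^m_", nm)) {
      parts <- strsplit(sub("^m_", "", nm), "_")[[1]]
      if (length(parts) != 2) stop("unknown parameter: ", nm)
      model$migration[parts[1], parts[2]] <- v
    } else stop("unknown parameter: ", nm)
  }
  # splits may have been re-timed
  model$splits <- model$splits[order(model$splits$time_gen), , drop = FALSE]
  validate_model(model)
  model
}

# --- JSON config -----------------------------------------------------------

#' Read or write a demographic model as JSON
#'
#' The JSON schema mirrors the model fields: `populations`, `ne`, `migration`
#' (forward rates, row = from), `splits`, `size_changes`, `mu_per_year`,
#' `generation_years`.
#'
#' @param path File path.
#' @param model A `demographic_model`.
#' @return `read_model_json()` returns a `demographic_model`;
#'   `write_model_json()` returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mig <- NULL
  if (!is.null(j$migration)) {
    mig <- as.matrix(j$migration)
    dimnames(mig) <- list(j$populations, j$populations)
  }
  demographic_model(j$populations, unlist(j$ne)[j$populations], mig,
                    j$splits, j$size_changes,
                    mu_per_year = j$mu_per_year,
                    generation_years = j$generation_years)
}

#' @rdname read_model_json
#' @export
write_model_json <- function(model, path) {
  j <- list(populations = model$populations,
            ne = as.list(setNames(as.numeric(model$ne), model$populations)),
            migration = unname(apply(model$migration, 1, as.numeric, simplify = FALSE)),
            splits = model$splits,
            size_changes = model$size_changes,
            mu_per_year = model$mu_per_year,
            generation_years = model$generation_years)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Sampling configuration for the simulator
#'
#' @param haplotypes Named integer vector: haplotypes sampled per population.
#' @param include_outgroup Add an outgroup lineage (population `OUT`)?
#' @param outgroup_haplotypes Haplotypes sampled from the outgroup (even, so
#'   diploids can be formed).
#' @param outgroup_split_gen Backward time (generations) at which the outgroup
#'   merges with the ingroup ancestor; must exceed every ingroup split time.
#' @param outgroup_ne Diploid size of the outgroup branch; defaults to the
#'   deepest ancestral size of the model it is used with.
#' @return A `sample_config` object.
#' @export
sample_config <- function(haplotypes, include_outgroup = FALSE,
                          outgroup_haplotypes = 2, outgroup_split_gen = 4e5,
                          outgroup_ne = NULL) {
  if (is.null(names(haplotypes)) || any(haplotypes < 0) || sum(haplotypes) < 1)
    stop("haplotypes must be a named vector with at least one sample")
  structure(list(haplotypes = haplotypes, include_outgroup = include_outgroup,
                 outgroup_haplotypes = outgroup_haplotypes,
                 outgroup_split_gen = outgroup_split_gen,
                 outgroup_ne = outgroup_ne),
            class = "sample_config")
}
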