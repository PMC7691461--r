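# Staged pipeline: simulate -> scan -> outliers -> genes -> report, driven by
# one JSON config, with a run manifest for reproducibility.

.default_config <- function() {
  list(out_dir = "popdivscan_run", seed = 1, window_size = 10000,
       simulate = NULL,  # list(model = "davidiana"|path, haplotypes, n_windows, include_outgroup, ...)
       input = NULL,     # list(vcf, popmap, bed, model)
       filters = list(gq_min = 10, max_missing = 2, indel_flank_bp = 5),
       scan = list(focal = NULL, outgroup = "OUT", estimator = "wc",
                   ld_min_dist = 1000, rho_min_snps = 10,
                   compute_ld = TRUE, compute_rho = TRUE),
       outliers = list(n_sims = 1000, fdr = 0.01, top_fraction = 0.01,
                       low_fst = 0.15, tajd_rule = "either"),
       genes = list(bed = NULL, fst_threshold = 0.95,
                    hka_alpha = 0.01, pbs_percentile = 95))
}

.load_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  def <- .default_config()
  for (nm in names(def)) {
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
    else if (is.list(def[[nm]])) {
      for (k in names(def[[nm]]))
        if (is.null(config[[nm]][[k]])) config[[nm]][[k]] <- def[[nm]][[k]]
    }
  }
  config
}

.config_model <- function(spec) {
  if (is.null(spec)) stop("no demographic model in config")
  if (identical(spec, "davidiana")) return(davidiana_im_model())
  if (is.character(spec)) return(read_model_json(spec))
  stop("model must be 'davidiana' or a path to a model JSON")
}

.config_hash <- function(config) {
  config$out_dir <- NULL  # analytic settings only; the hash tracks the run recipe
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

.require_stage_output <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing '", basename(path), "': run the '", stage_needed,
         "' stage first", call. = FALSE)
  path
}

#' Run pipeline stages
#'
#' Executes the requested stage (or all of them in dependency order) against
#' one output directory. Every run writes `manifest.json` (config hash,
#' seed, package version, per-stage row counts, wall time); identical config
#' and seed give identical outputs.
#'
#' Stages: `simulate` (model -> VCF + popmap + BED + truth), `scan`
#' (VCF -> `windows.tsv` via [scan_windows()]), `outliers`
#' (`windows.tsv` -> `outliers.tsv` via [flag_outlier_windows()] +
#' [null_fst_pvalues()]), `genes` (gene BED -> `genes.tsv` via HKA + PBS),
#' `report` (`summary.txt` + `plots.pdf`).
#'
#' @param config Config list or path to a JSON config; see
#'   the pipeline vignette for the schema.
#' @param stage One of `"simulate"`, `"scan"`, `"outliers"`, `"genes"`,
#'   `"report"`, `"all"`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "scan",
                                           "outliers", "genes", "report")) {
  stage <- match.arg(stage)
  cfg <- .load_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()
  stages <- if (stage == "all") {
    st <- c(if (!is.null(cfg$simulate)) "simulate", "scan", "outliers",
            if (!is.null(cfg$genes$bed)) "genes", "report")
    st
  } else stage

  for (st in stages) {
    message("[popdivscan] stage: ", st)
    counts[[st]] <- switch(st,
      simulate = .stage_simulate(cfg),
      scan = .stage_scan(cfg),
      outliers = .stage_outliers(cfg),
      genes = .stage_genes(cfg),
      report = .stage_report(cfg))
  }
  manifest <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                   package_version = as.character(packageVersion("popdivscan")),
                   stages = counts,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

.stage_simulate <- function(cfg) {
  sc <- cfg$simulate
  model <- .config_model(sc$model)
  hap <- unlist(sc$haplotypes)
  config <- sample_config(hap,
                          include_outgroup = isTRUE(sc$include_outgroup),
                          outgroup_haplotypes = sc$outgroup_haplotypes %||% 2,
                          outgroup_split_gen = sc$outgroup_split_gen %||% 4e5)
  res <- simulate_dataset(model, config, sc$n_windows,
                          window_bp = cfg$window_size, seed = cfg$seed,
                          out_dir = cfg$out_dir)
  list(n_windows = sc$n_windows)
}

.paths <- function(cfg) {
  inp <- cfg$input
  list(vcf = inp$vcf %||% file.path(cfg$out_dir, "sim.vcf"),
       popmap = inp$popmap %||% file.path(cfg$out_dir, "popmap.tsv"),
       bed = inp$bed %||% file.path(cfg$out_dir, "windows.bed"))
}

.stage_scan <- function(cfg) {
  p <- .paths(cfg)
  .require_stage_output(p$vcf, "simulate")
  pop_map <- read_pop_map(p$popmap)
  gm <- read_vcf(p$vcf, pop_map)
  gm <- apply_site_filters(gm, gq_min = cfg$filters$gq_min,
                           max_missing = cfg$filters$max_missing,
                           indel_flank_bp = cfg$filters$indel_flank_bp)
  write_filter_report(gm, file.path(cfg$out_dir, "filter_report.tsv"))
  bed <- read.table(p$bed, sep = "\t",
                    col.names = c("contig", "start", "end"))
  windows <- tibble::as_tibble(bed)
  og <- cfg$scan$outgroup
  if (!og %in% pop_map$population) og <- NULL
  pol <- if (!is.null(og))
    polarize_sites(gm, pop_map$sample[pop_map$population == og]) else NULL
  focal <- cfg$scan$focal
  if (!is.null(focal)) focal <- unlist(focal)
  tab <- scan_windows(gm, pop_map, windows, pol = pol, focal = focal,
                      outgroup = og, estimator = cfg$scan$estimator,
                      ld_min_dist = cfg$scan$ld_min_dist,
                      rho_min_snps = cfg$scan$rho_min_snps,
                      compute_ld = isTRUE(cfg$scan$compute_ld),
                      compute_rho = isTRUE(cfg$scan$compute_rho))
  write.table(tab, file.path(cfg$out_dir, "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(n_windows = nrow(tab), n_snps = sum(tab$n_snps))
}

.scan_focal_pair <- function(cfg, tab) {
  focal <- cfg$scan$focal
  if (!is.null(focal)) return(unlist(focal))
  fst_cols <- grep("^fst_(?!num_|den_)", names(tab), perl = TRUE, value = TRUE)
  strsplit(sub("^fst_", "", fst_cols[1]), "_")[[1]]
}

.stage_outliers <- function(cfg) {
  wt <- file.path(cfg$out_dir, "windows.tsv")
  .require_stage_output(wt, "scan")
  tab <- tibble::as_tibble(read.table(wt, sep = "\t", header = TRUE))
  focal <- .scan_focal_pair(cfg, tab)
  fst_col <- paste0("fst_", focal[1], "_", focal[2])
  if (!fst_col %in% names(tab)) fst_col <- paste0("fst_", focal[2], "_", focal[1])
  tajd_cols <- paste0("tajima_d_", focal)
  flagged <- flag_outlier_windows(tab, fst_col, tajd_cols,
                                  fst_top_fraction = cfg$outliers$top_fraction,
                                  tajd_rule = cfg$outliers$tajd_rule,
                                  low_fst_threshold = cfg$outliers$low_fst)
  model <- .config_model(cfg$simulate$model %||% cfg$input$model)
  hap_cfg <- cfg$simulate$haplotypes
  if (is.null(hap_cfg)) {
    pm <- read_pop_map(.paths(cfg)$popmap)
    counts <- table(pm$population[pm$population != cfg$scan$outgroup])
    hap_cfg <- as.list(2 * as.integer(counts))
    names(hap_cfg) <- names(counts)
  }
  config <- sample_config(unlist(hap_cfg))
  nv <- null_fst_pvalues(flagged[[fst_col]], model, config,
                         n_sims = cfg$outliers$n_sims,
                         window_bp = cfg$window_size, pair = focal,
                         estimator = cfg$scan$estimator,
                         fdr = cfg$outliers$fdr, seed = cfg$seed + 1)
  out <- cbind(flagged[, c("contig", "start", "end", fst_col, tajd_cols,
                           "fst_rank_pct", "high_diff", "low_diff")],
               nv[, c("p_high", "p_low", "q_high", "q_low", "candidate",
                      "direction")])
  write.table(out, file.path(cfg$out_dir, "outliers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(format(attr(nv, "null_fst"), digits = 10),
             file.path(cfg$out_dir, "null_fst.txt"))
  list(n_windows = nrow(out), n_high = sum(out$high_diff),
       n_low = sum(out$low_diff), n_candidates = sum(out$candidate))
}

.stage_genes <- function(cfg) {
  p <- .paths(cfg)
  .require_stage_output(p$vcf, "simulate")
  if (is.null(cfg$genes$bed)) stop("no gene BED configured")
  pop_map <- read_pop_map(p$popmap)
  gm <- read_vcf(p$vcf, pop_map)
  genes <- read_gene_bed(cfg$genes$bed)
  pops <- setdiff(unique(pop_map$population), cfg$scan$outgroup)
  wt <- file.path(cfg$out_dir, "windows.tsv")
  .require_stage_output(wt, "scan")
  tab <- tibble::as_tibble(read.table(wt, sep = "\t", header = TRUE))
  focal <- .scan_focal_pair(cfg, tab)[1]
  others <- setdiff(pops, focal)
  hk <- hka_gene_counts(gm, pop_map, focal, others, genes,
                        fst_threshold = cfg$genes$fst_threshold)
  ht <- hka_test(hk$A, hk$B, attr(hk, "A_tot"), attr(hk, "B_tot"))
  samp <- lapply(setNames(pops, pops),
                 function(pp) pop_map$sample[pop_map$population == pp])
  gene_pbs <- vapply(seq_len(nrow(genes)), function(i) {
    idx <- gm$contig == genes$contig[i] & (gm$pos - 1L) >= genes$start[i] &
      (gm$pos - 1L) < genes$end[i]
    if (!any(idx) || length(pops) != 3) return(NA_real_)
    sg <- slice_sites(gm, idx)
    bc <- setdiff(pops, focal)
    f1 <- fst_window(sg, samp[[focal]], samp[[bc[1]]])$fst
    f2 <- fst_window(sg, samp[[focal]], samp[[bc[2]]])$fst
    f3 <- fst_window(sg, samp[[bc[1]]], samp[[bc[2]]])$fst
    if (anyNA(c(f1, f2, f3))) return(NA_real_)
    as.numeric(pbs(f1, f2, f3))
  }, 0)
  gt <- cbind(hk, tibble::tibble(hka_chisq = ht$chisq, hka_p = ht$p,
                                 pbs = gene_pbs))
  gt <- call_positive_genes(gt, hka_alpha = cfg$genes$hka_alpha,
                            pbs_percentile = cfg$genes$pbs_percentile)
  write.table(gt, file.path(cfg$out_dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(n_genes = nrow(gt), n_positive = sum(gt$positive_selection, na.rm = TRUE))
}

.stage_report <- function(cfg) {
  wt <- file.path(cfg$out_dir, "windows.tsv")
  .require_stage_output(wt, "scan")
  tab <- tibble::as_tibble(read.table(wt, sep = "\t", header = TRUE))
  lines <- c("popdivscan run summary", "======================", "")
  fst_cols <- grep("^fst_num_", names(tab), value = TRUE)
  for (fc in fst_cols) {
    key <- sub("^fst_num_", "", fc)
    pair <- strsplit(key, "_")[[1]]
    gw <- genomewide_fst(tab, pair)
    lines <- c(lines, sprintf("genome-wide FST(%s, %s) = %.4f", pair[1], pair[2], gw))
  }
  ot <- file.path(cfg$out_dir, "outliers.tsv")
  if (file.exists(ot)) {
    o <- read.table(ot, sep = "\t", header = TRUE)
    lines <- c(lines, "",
               sprintf("windows scanned: %d", nrow(o)),
               sprintf("high-differentiation outliers (top FST & D < 0): %d",
                       sum(o$high_diff)),
               sprintf("low-differentiation windows (FST < threshold): %d",
                       sum(o$low_diff)),
               sprintf("null-model candidates (q < %g): %d",
                       cfg$outliers$fdr, sum(o$candidate)))
    if (sum(o$candidate) == 0)
      lines <- c(lines, "no candidate windows at this FDR")
  }
  gt <- file.path(cfg$out_dir, "genes.tsv")
  if (file.exists(gt)) {
    g <- read.table(gt, sep = "\t", header = TRUE)
    lines <- c(lines, sprintf("positively selected genes: %d",
                              sum(g$positive_selection, na.rm = TRUE)))
  }
  writeLines(lines, file.path(cfg$out_dir, "summary.txt"))
  # figures
  pdf_path <- file.path(cfg$out_dir, "plots.pdf")
  fst_plot_cols <- grep("^fst_(?!num_|den_|rank)", names(tab), perl = TRUE,
                        value = TRUE)
  grDevices::pdf(pdf_path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  mid <- (tab$start + tab$end) / 2
  for (fc in fst_plot_cols) {
    df <- data.frame(pos = mid, fst = tab[[fc]])
    print(ggplot2::ggplot(df[!is.na(df$fst), ],
                          ggplot2::aes(x = pos, y = fst)) +
            ggplot2::geom_point(size = 0.4, alpha = 0.6) +
            ggplot2::labs(title = fc, x = "window midpoint (bp)", y = "FST") +
            ggplot2::theme_minimal())
  }
  pi_cols <- grep("^pi_", names(tab), value = TRUE)
  if (length(pi_cols) > 0) {
    df <- do.call(rbind, lapply(pi_cols, function(pc)
      data.frame(pop = sub("^pi_", "", pc), pi = tab[[pc]])))
    print(ggplot2::ggplot(df[!is.na(df$pi), ], ggplot2::aes(x = pop, y = pi)) +
            ggplot2::geom_boxplot() +
            ggplot2::labs(title = "per-window nucleotide diversity",
                          x = NULL, y = expression(pi)) +
            ggplot2::theme_minimal())
  }
  list(summary = "summary.txt", plots = "plots.pdf")
}
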