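# Genotype input/output: VCF via vcfR, population maps, site filters,
# window tiling and outgroup polarization.
#
# Coordinate conventions: VCF POS is 1-based; windows are 0-based half-open
# (BED); a site at POS falls in the window containing POS - 1.

#' Genotype matrix
#'
#' Samples-by-sites diploid allele dosages with optional per-call genotype
#' quality and, for phased data, the underlying haplotypes. The universal
#' carrier between pipeline stages.
#'
#' @param sample_ids Character vector of sample names.
#' @param contig,pos,ref,alt Per-site contig, 1-based position, REF and ALT
#'   alleles (ALT may be comma-separated for multi-allelic records, which are
#'   preserved for downstream filtering).
#' @param dosage Integer matrix (samples x sites) of ALT-dosages in
#'   `{0, 1, 2, NA}`.
#' @param gq Optional integer matrix of per-call genotype qualities.
#' @param n_alleles Per-site allele count annotation (REF + ALTs).
#' @param haplotypes Optional 0/1 matrix (2*samples x sites) of phased
#'   haplotypes; rows `2i-1`, `2i` belong to sample `i`.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, contig, pos, ref, alt, dosage,
                            gq = NULL, n_alleles = NULL, haplotypes = NULL) {
  S <- length(pos)
  stopifnot(length(contig) == S, length(ref) == S, length(alt) == S,
            ncol(dosage) == S, nrow(dosage) == length(sample_ids))
  if (is.null(n_alleles)) n_alleles <- 1L + lengths(strsplit(alt, ","))
  # positions strictly increasing within each contig
  for (ct in unique(contig)) {
    p <- pos[contig == ct]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within contig ", ct)
  }
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(sample_ids = sample_ids, contig = contig, pos = as.integer(pos),
                 ref = ref, alt = alt, dosage = dosage, gq = gq,
                 n_alleles = as.integer(n_alleles), haplotypes = haplotypes,
                 ploidy = 2L),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d sites (%s)%s\n",
              length(x$sample_ids), length(x$pos),
              paste(unique(x$contig), collapse = ","),
              if (!is.null(x$haplotypes)) ", phased" else ""))
  invisible(x)
}

#' Subset a genotype matrix to a set of sites
#'
#' @param gm A `genotype_matrix`.
#' @param idx Site indices (logical or integer).
#' @return The sliced `genotype_matrix`.
#' @export
slice_sites <- function(gm, idx) {
  genotype_matrix(gm$sample_ids, gm$contig[idx], gm$pos[idx], gm$ref[idx],
                  gm$alt[idx], gm$dosage[, idx, drop = FALSE],
                  gq = if (!is.null(gm$gq)) gm$gq[, idx, drop = FALSE],
                  n_alleles = gm$n_alleles[idx],
                  haplotypes = if (!is.null(gm$haplotypes))
                    gm$haplotypes[, idx, drop = FALSE])
}

#' Sites of a genotype matrix falling in one window
#'
#' @param gm A `genotype_matrix`.
#' @param window One row of a window set (`contig`, `start`, `end`; 0-based
#'   half-open).
#' @return Logical site index.
#' @export
window_sites <- function(gm, window) {
  gm$contig == window$contig & (gm$pos - 1L) >= window$start &
    (gm$pos - 1L) < window$end
}

#' Read a sample-to-population map
#'
#' Two-column TSV: `sample_id<TAB>population`.
#'
#' @param path File path.
#' @return Tibble with columns `sample`, `population`.
#' @export
read_pop_map <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample", "population"))
  if (anyDuplicated(tb$sample)) stop("duplicate sample ids in population map")
  tibble::as_tibble(tb)
}

# quick structural scan so malformed rows error with a line number
.check_vcf_structure <- function(path) {
  ln <- readLines(path)
  hdr <- which(startsWith(ln, "#CHROM"))
  if (length(hdr) != 1) stop("malformed VCF: no #CHROM header line in ", path)
  ncol_hdr <- length(strsplit(ln[hdr], "\t", fixed = TRUE)[[1]])
  body <- setdiff(seq_along(ln), which(startsWith(ln, "#")))
  for (i in body) {
    nc <- length(strsplit(ln[i], "\t", fixed = TRUE)[[1]])
    if (nc != ncol_hdr)
      stop("malformed VCF line ", i, ": ", nc, " fields, expected ", ncol_hdr)
  }
  invisible(TRUE)
}

#' Read genotypes from a VCF
#'
#' Parses GT (and GQ when present) for the mapped samples. Dosages are
#' ALT-allele counts; any call carrying an allele index above 1 — or a
#' missing GT — becomes `NA`, and the per-site allele count is kept so
#' multi-allelic records can be filtered downstream. If every GT is phased
#' (`|`), the haplotype matrix is reconstructed.
#'
#' @param path VCF (v4.x) file path.
#' @param pop_map Optional population map; restricts and orders samples, and
#'   errors if a mapped sample is absent from the header.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, pop_map = NULL) {
  .check_vcf_structure(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1]
  if (!is.null(pop_map)) {
    missing <- setdiff(pop_map$sample, samples)
    if (length(missing) > 0)
      stop("samples in population map absent from VCF header: ",
           paste(missing, collapse = ", "))
    samples <- pop_map$sample
  }
  S <- nrow(fix)
  if (S == 0) {
    return(genotype_matrix(samples, character(0), integer(0), character(0),
                           character(0),
                           matrix(NA_integer_, length(samples), 0)))
  }
  gt <- vcfR::extract.gt(v, "GT")[, samples, drop = FALSE]
  gq <- if (any(grepl("GQ", v@gt[, "FORMAT"])))
    suppressWarnings(vcfR::extract.gt(v, "GQ", as.numeric = TRUE)[, samples, drop = FALSE])
  else NULL
  gt_t <- t(gt)  # samples x sites
  alleles1 <- substr(gt_t, 1, 1)
  sep <- substr(gt_t, 2, 2)
  alleles2 <- substr(gt_t, 3, 3)
  num1 <- suppressWarnings(as.integer(alleles1))
  num2 <- suppressWarnings(as.integer(alleles2))
  dos <- num1 + num2
  dos[is.na(num1) | is.na(num2)] <- NA_integer_
  dos[!is.na(num1) & (num1 > 1L) | !is.na(num2) & (num2 > 1L)] <- NA_integer_
  dim(dos) <- dim(gt_t)
  hap <- NULL
  if (all(sep == "|", na.rm = TRUE) && !anyNA(sep)) {
    hap <- matrix(NA_integer_, 2 * length(samples), S)
    hap[seq(1, 2 * length(samples), 2), ] <- ifelse(num1 <= 1L, num1, NA_integer_)
    hap[seq(2, 2 * length(samples), 2), ] <- ifelse(num2 <= 1L, num2, NA_integer_)
  }
  gqm <- NULL
  if (!is.null(gq)) {
    gqm <- t(gq)
    storage.mode(gqm) <- "integer"
    dimnames(gqm) <- list(samples, NULL)
  }
  dimnames(dos) <- list(samples, NULL)
  genotype_matrix(samples, fix[, "CHROM"], as.integer(fix[, "POS"]),
                  fix[, "REF"], fix[, "ALT"], dos, gq = gqm, haplotypes = hap)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Minimal GT(:GQ) records with CHROM/POS/REF/ALT populated, sites ordered by
#' contig then position; phased matrices write `|`-separated genotypes.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  o <- order(match(gm$contig, unique(gm$contig)), gm$pos)
  gm <- slice_sites(gm, o)
  has_gq <- !is.null(gm$gq)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(gm$contig)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           if (has_gq)
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  S <- length(gm$pos)
  n <- length(gm$sample_ids)
  body <- character(0)
  if (S > 0) {
    if (!is.null(gm$haplotypes)) {
      h1 <- gm$haplotypes[seq(1, 2 * n, 2), , drop = FALSE]
      h2 <- gm$haplotypes[seq(2, 2 * n, 2), , drop = FALSE]
      gts <- matrix(paste0(h1, "|", h2), n, S)
      gts[is.na(h1) | is.na(h2)] <- "./."
    } else {
      gts <- matrix(".|.", n, S)
      gts[] <- c("0/0", "0/1", "1/1")[gm$dosage + 1L]
      gts[is.na(gm$dosage)] <- "./."
    }
    if (has_gq) {
      gqs <- matrix(as.character(gm$gq), n, S)
      gqs[is.na(gqs)] <- "."
      gts <- matrix(paste0(gts, ":", gqs), n, S)
    }
    fmt <- if (has_gq) "GT:GQ" else "GT"
    body <- paste(gm$contig, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                  fmt, sep = "\t")
    for (i in seq_len(n)) body <- paste(body, gts[i, ], sep = "\t")
  }
  con <- file(path, "w")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Apply the site filters
#'
#' In order: (i) sites with more than two alleles are removed; (ii) calls
#' with GQ below `gq_min` are set missing; (iii) SNPs within `indel_flank_bp`
#' of a supplied indel position are removed; (iv) sites with more than
#' `max_missing` missing genotypes are removed. The missingness rule counts
#' genotypes after GQ masking. A per-rule removal count is attached as
#' attribute `filter_report`.
#'
#' @param gm A `genotype_matrix` carrying allele counts and (optionally) GQ.
#' @param gq_min Minimum genotype quality; lower calls become missing.
#' @param max_missing Maximum missing genotypes tolerated per site.
#' @param indel_positions Optional data frame (`contig`, `pos`, 1-based) of
#'   indel locations.
#' @param indel_flank_bp Flank width around indels within which SNPs are
#'   dropped.
#' @return The filtered `genotype_matrix`, with attribute `filter_report`
#'   (tibble: rule, sites_removed).
#' @export
apply_site_filters <- function(gm, gq_min = 10, max_missing = 2,
                               indel_positions = NULL, indel_flank_bp = 5) {
  if (gq_min < 0 || max_missing < 0 || indel_flank_bp < 0)
    stop("filter thresholds must be non-negative")
  report <- tibble::tibble(rule = character(), sites_removed = integer())
  # (i) multi-allelic
  keep <- gm$n_alleles <= 2
  report <- rbind(report, tibble::tibble(rule = "multiallelic",
                                         sites_removed = sum(!keep)))
  gm <- slice_sites(gm, keep)
  # (ii) GQ masking (calls, not sites)
  masked <- 0L
  if (!is.null(gm$gq)) {
    low <- !is.na(gm$gq) & gm$gq < gq_min & !is.na(gm$dosage)
    masked <- sum(low)
    gm$dosage[low] <- NA_integer_
    if (!is.null(gm$haplotypes)) {
      n <- length(gm$sample_ids)
      lowh <- matrix(FALSE, 2 * n, ncol(low))
      lowh[seq(1, 2 * n, 2), ] <- low
      lowh[seq(2, 2 * n, 2), ] <- low
      gm$haplotypes[lowh] <- NA_integer_
    }
  }
  report <- rbind(report, tibble::tibble(rule = "gq_masked_calls",
                                         sites_removed = masked))
  # (iii) indel flanks
  if (!is.null(indel_positions) && nrow(indel_positions) > 0) {
    near <- rep(FALSE, length(gm$pos))
    for (i in seq_len(nrow(indel_positions))) {
      near <- near | (gm$contig == indel_positions$contig[i] &
                        abs(gm$pos - indel_positions$pos[i]) <= indel_flank_bp)
    }
    report <- rbind(report, tibble::tibble(rule = "indel_flank",
                                           sites_removed = sum(near)))
    gm <- slice_sites(gm, !near)
  } else {
    report <- rbind(report, tibble::tibble(rule = "indel_flank",
                                           sites_removed = 0L))
  }
  # (iv) missingness
  nmiss <- colSums(is.na(gm$dosage))
  keep <- nmiss <= max_missing
  report <- rbind(report, tibble::tibble(rule = "missingness",
                                         sites_removed = sum(!keep)))
  gm <- slice_sites(gm, keep)
  attr(gm, "filter_report") <- report
  gm
}

#' Write the filter report as TSV
#'
#' @param gm A filtered `genotype_matrix` (carrying `filter_report`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(gm, path) {
  rep <- attr(gm, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run apply_site_filters first")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tile contigs into non-overlapping windows
#'
#' 0-based half-open intervals `[0, size), [size, 2*size), ...`; the final
#' partial window is retained with its true length.
#'
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param size Window size in bp.
#' @return A tibble (`contig`, `start`, `end`) with attribute `window_size`.
#' @export
make_windows <- function(contig_lengths, size = 10000) {
  if (size <= 0) stop("window size must be positive")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  out <- do.call(rbind, lapply(names(contig_lengths), function(ct) {
    L <- contig_lengths[[ct]]
    starts <- seq(0, L - 1, by = size)
    tibble::tibble(contig = ct, start = as.integer(starts),
                   end = as.integer(pmin(starts + size, L)))
  }))
  attr(out, "window_size") <- size
  out
}

#' Write windows as BED3
#'
#' @param windows A window tibble from [make_windows()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  write.table(windows[, c("contig", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Polarize sites against an outgroup
#'
#' The ancestral allele at a site is the allele on which all non-missing
#' outgroup calls agree (strict consensus; no majority rule). Sites with a
#' polymorphic or entirely missing outgroup are flagged non-polarizable.
#'
#' @param gm A `genotype_matrix`.
#' @param outgroup_samples Sample ids of the outgroup (must be present).
#' @return A tibble (`polarized_sites`): `ancestral` (`"ref"`, `"alt"` or
#'   `NA`), `polarizable` (logical).
#' @export
polarize_sites <- function(gm, outgroup_samples) {
  if (length(outgroup_samples) == 0) stop("outgroup sample list is empty")
  idx <- match(outgroup_samples, gm$sample_ids)
  if (anyNA(idx)) stop("outgroup samples absent from matrix: ",
                       paste(outgroup_samples[is.na(idx)], collapse = ", "))
  dos <- gm$dosage[idx, , drop = FALSE]
  n_obs <- colSums(!is.na(dos))
  all_ref <- colSums(dos == 0, na.rm = TRUE) == n_obs & n_obs > 0
  all_alt <- colSums(dos == 2, na.rm = TRUE) == n_obs & n_obs > 0
  anc <- rep(NA_character_, length(gm$pos))
  anc[all_ref] <- "ref"
  anc[all_alt] <- "alt"
  tibble::tibble(ancestral = anc, polarizable = !is.na(anc))
}
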