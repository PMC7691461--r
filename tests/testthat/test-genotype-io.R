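vcf_fixture <- function(lines, path = withr::local_tempfile(fileext = ".vcf",
                                                            .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

hdr3 <- c("##fileformat=VCFv4.2",
          "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
          "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
          "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3")

test_that("GT fields decode to dosages, with missing and multiallelic handling", {
  p <- vcf_fixture(c(hdr3,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:GQ\t0/0:40\t0/1:40\t1/1:40",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:GQ\t./.:.\t0/0:20\t0/1:35",
    "chr1\t300\t.\tG\tC,A\t.\tPASS\t.\tGT:GQ\t0/2:40\t0/0:40\t1/2:40"))
  gm <- read_vcf(p)
  expect_equal(gm$dosage[, 1], c(s1 = 0L, s2 = 1L, s3 = 2L))
  expect_true(is.na(gm$dosage["s1", 2]))
  expect_equal(gm$n_alleles, c(2L, 2L, 3L))
  # calls touching allele index > 1 are unusable as biallelic dosages
  expect_true(is.na(gm$dosage["s1", 3]) && is.na(gm$dosage["s3", 3]))
  expect_equal(gm$gq["s3", ], c(40L, 35L, 40L))
})

test_that("malformed VCF lines and unknown mapped samples raise named errors", {
  p <- vcf_fixture(c(hdr3,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1"))
  expect_error(read_vcf(p), "line 6")
  p2 <- vcf_fixture(c(hdr3,
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"))
  pm <- tibble::tibble(sample = c("s1", "sX"), population = c("A", "A"))
  expect_error(read_vcf(p2, pm), "sX")
})

test_that("write_vcf/read_vcf round-trip preserves the matrix", {
  hap <- random_hap(8, 15, seed = 42)
  gm <- make_gm(hap, c("A", "A", "B", "B"), pos = sort(sample(1:5000, 15)))
  gm$gq <- matrix(30L, 4, 15)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)
  expect_equal(gm2$sample_ids, gm$sample_ids)
  expect_equal(gm2$pos, gm$pos)
  expect_equal(gm2$ref, gm$ref)
  expect_equal(gm2$alt, gm$alt)
  expect_equal(unname(gm2$dosage), unname(gm$dosage))
  expect_equal(unname(gm2$haplotypes), unname(gm$haplotypes))
  expect_equal(unname(gm2$gq), unname(gm$gq))
  # a second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty matrix writes a header-only VCF", {
  gm <- genotype_matrix(c("s1", "s2"), character(0), integer(0), character(0),
                        character(0), matrix(NA_integer_, 2, 0))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  ln <- readLines(path)
  expect_true(all(startsWith(ln, "#")))
  gm2 <- read_vcf(path)
  expect_length(gm2$pos, 0)
})

test_that("site filters apply in order with per-rule accounting", {
  # 10 diploids; site 1 (pos 100) triallelic; site 2 has one GQ-9 call that
  # then trips max_missing = 0; site 3 has 3 missing genotypes; site 4 near
  # an indel; site 5 clean
  n <- 10
  dos <- matrix(0L, n, 5)
  dos[1, 2] <- 1L
  dos[1:3, 3] <- NA_integer_
  dos[, 5] <- rep(c(0L, 1L), 5)
  gq <- matrix(30L, n, 5)
  gq[1, 2] <- 9L
  gm <- genotype_matrix(paste0("s", 1:n), rep("chr1", 5),
                        c(100L, 200L, 300L, 400L, 500L),
                        rep("A", 5), c("T,G", "T", "T", "T", "T"), dos, gq = gq)
  f <- apply_site_filters(gm, gq_min = 10, max_missing = 0,
                          indel_positions = data.frame(contig = "chr1", pos = 398),
                          indel_flank_bp = 5)
  rep <- attr(f, "filter_report")
  expect_equal(rep$sites_removed[rep$rule == "multiallelic"], 1L)
  expect_equal(rep$sites_removed[rep$rule == "gq_masked_calls"], 1L)
  expect_equal(rep$sites_removed[rep$rule == "indel_flank"], 1L)
  # site 2 (GQ-masked call) and the all-NA site both fail max_missing = 0
  expect_equal(rep$sites_removed[rep$rule == "missingness"], 2L)
  expect_equal(f$pos, 500L)
  # relaxed missingness keeps 3-missing sites under the > 2 rule
  f2 <- apply_site_filters(gm, gq_min = 10, max_missing = 3)
  expect_true(300L %in% f2$pos)
  f3 <- apply_site_filters(gm, gq_min = 10, max_missing = 2)
  expect_false(300L %in% f3$pos)
  expect_error(apply_site_filters(gm, gq_min = -1), "non-negative")
})

test_that("filtering is idempotent", {
  hap <- random_hap(12, 30, seed = 7)
  gm <- make_gm(hap, rep(c("A", "B"), each = 3), pos = seq(10, 300, by = 10))
  gm$gq <- matrix(sample(c(5L, 30L), 6 * 30, replace = TRUE), 6, 30)
  f1 <- apply_site_filters(gm, gq_min = 10, max_missing = 2)
  f2 <- apply_site_filters(f1, gq_min = 10, max_missing = 2)
  expect_equal(f2$pos, f1$pos)
  expect_equal(f2$dosage, f1$dosage)
})

test_that("window tiling follows BED conventions, partial window kept", {
  w <- make_windows(c(chr1 = 25000), 10000)
  expect_equal(w$start, c(0L, 10000L, 20000L))
  expect_equal(w$end, c(10000L, 20000L, 25000L))
  expect_equal(nrow(make_windows(c(chr1 = 10000), 10000)), 1L)
  expect_error(make_windows(c(chr1 = 1000), 0), "positive")
  # VCF POS 10000 (1-based) -> 0-based 9999 -> first window;
  # POS 10001 -> second window
  gm <- genotype_matrix("s1", c("chr1", "chr1"), c(10000L, 10001L),
                        c("A", "A"), c("T", "T"), matrix(c(1L, 1L), 1, 2))
  expect_equal(which(window_sites(gm, w[1, ])), 1L)
  expect_equal(which(window_sites(gm, w[2, ])), 2L)
  # every site maps to exactly one window and windows tile the contig
  hits <- sapply(seq_len(nrow(w)), function(k) window_sites(gm, w[k, ]))
  expect_equal(rowSums(hits), c(1, 1))
  expect_equal(w$start[-1], w$end[-nrow(w)])
})

test_that("polarization requires a fixed outgroup consensus", {
  # outgroup diploid OUT_1: site 1 hom-REF, site 2 het, site 3 hom-ALT,
  # site 4 missing
  hap <- rbind(c(0, 1, 1, 0), c(1, 1, 0, 1),   # ingroup A_1
               c(0, 0, 1, 0), c(0, 1, 1, 1))   # outgroup OUT_1
  gm <- make_gm(hap, c("A", "OUT"), pos = 1:4)
  gm$dosage[2, 4] <- NA_integer_
  pol <- polarize_sites(gm, "OUT_1")
  expect_equal(pol$ancestral, c("ref", NA, "alt", NA))
  expect_equal(pol$polarizable, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(polarize_sites(gm, character(0)), "empty")
})

test_that("polarization is perfect on simulated data when the outgroup is fixed", {
  m <- two_pop_model(ne = c(A = 2000, B = 2000), t_split = 3000, anc_ne = 2000,
                     mu_per_year = 5e-8)
  cfg <- sample_config(c(A = 6, B = 6), include_outgroup = TRUE,
                       outgroup_haplotypes = 2,
                       outgroup_split_gen = 2e5)  # >> 2*Ne_anc: no ILS left
  res <- simulate_dataset(m, cfg, 40, window_bp = 5000, seed = 9,
                          out_dir = withr::local_tempdir())
  pm <- read_pop_map(res$popmap)
  gm <- read_vcf(res$vcf, pm)
  pol <- polarize_sites(gm, pm$sample[pm$population == "OUT"])
  truth_anc_is_ref <- unlist(lapply(res$truth$windows, `[[`, "ref_is_ancestral"))
  ing <- pm$sample[pm$population != "OUT"]
  sc <- popdivscan:::.allele_counts(gm, ing)
  seg_in <- sc$alt > 0 & sc$alt < sc$n  # sites where polarization matters
  chk <- pol$polarizable & seg_in
  expect_gt(mean(pol$polarizable), 0.5)
  # with the outgroup split far beyond the ancestral coalescent time scale,
  # every ingroup-segregating site polarizes to the true ancestral allele
  expect_equal(pol$ancestral[chk],
               ifelse(truth_anc_is_ref[chk], "ref", "alt"))
})
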