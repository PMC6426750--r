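test_that("dosage TSV round-trips exactly and builds the expected matrix", {
  g <- tiny_gmat()
  expect_equal(dim(g), c(3L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, path)
  g2 <- load_genotypes(path, "dosage_tsv")
  expect_identical(g2$dosages, g$dosages)
  expect_identical(sample_ids(g2), sample_ids(g))
  expect_identical(marker_ids(g2), marker_ids(g))

  # missing entries survive the round trip too
  d <- g$dosages; d[2, 1] <- NA
  gm <- genotype_matrix(d)
  write_dosage_tsv(gm, path)
  expect_identical(load_genotypes(path, "dosage_tsv")$dosages, gm$dosages)
})

test_that("genotype_matrix validates dosage codes and duplicate ids", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1)), "invalid dosage")
  d <- matrix(0, 2, 2)
  expect_error(genotype_matrix(d, sample_ids = c("a", "a")), "duplicated sample")
  expect_error(genotype_matrix(d, marker_ids = c("x", "x")), "duplicated marker")
})

test_that("VCF GT fields decode to ALT-allele dosages; multi-allelic records rejected", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1/1"
  ), vcf)
  g <- load_genotypes(vcf, "vcf")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(allele_frequencies(g)["rs1"]), 0.5)
  expect_equal(unname(g$dosages[, "rs2"]), c(1, NA, 2))

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "1\t300\trs3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2"
  ), vcf)
  expect_error(load_genotypes(vcf, "vcf"), "rs3")
})

test_that("PLINK .bed round-trips through the SNP-major codec", {
  withr::with_seed(42, {
    d <- matrix(sample(c(0, 1, 2, NA), 9 * 5, replace = TRUE), 9, 5,
                dimnames = list(paste0("ind", 1:9), paste0("snp", 1:5)))
  })
  g <- genotype_matrix(d)
  prefix <- file.path(withr::local_tempdir(), "panel")
  gsfactors:::.write_plink_bed(g, prefix)
  g2 <- load_genotypes(paste0(prefix, ".bed"), "plink_bed")
  expect_identical(g2$dosages, g$dosages)
  # bad magic is rejected
  writeBin(as.raw(c(1, 2, 3, 4)), paste0(prefix, ".bed"))
  expect_error(load_genotypes(paste0(prefix, ".bed"), "plink_bed"), "magic")
})

test_that("allele frequencies come from non-missing calls only", {
  expect_equal(unname(allele_frequencies(gmat_from_cols(list(c(0, 1, 2))))), 0.5)
  expect_equal(unname(allele_frequencies(gmat_from_cols(list(c(2, 2, 2))))), 1.0)
  expect_equal(unname(allele_frequencies(gmat_from_cols(list(c(0, NA, 2))))), 0.5)
  g_allmiss <- gmat_from_cols(list(c(0, 1, 2), c(NA, NA, NA)), ids = c("ok", "void"))
  expect_error(allele_frequencies(g_allmiss), "void")
})

test_that("MAF filter keeps markers at or above the threshold, preserving order", {
  # frequencies 0.005, 0.02, 0.5 via explicit column construction
  n <- 100
  cols <- list(c(rep(1, 1), rep(0, n - 1)),      # p = 0.005
               c(rep(1, 4), rep(0, n - 4)),      # p = 0.02
               c(rep(2, 50), rep(0, n - 50)))    # p = 0.5
  g <- gmat_from_cols(cols, ids = c("rare", "low", "common"))
  expect_identical(marker_ids(filter_by_maf(g, 0.01)), c("low", "common"))
  expect_identical(marker_ids(filter_by_maf(g, 0.2)), "common")
  expect_identical(marker_ids(filter_by_maf(g, 0)), c("rare", "low", "common"))
  expect_error(filter_by_maf(g, 0.6), "0, 0.5")
  expect_error(filter_by_maf(g, -0.1), "0, 0.5")
})

test_that("MAF filtering is idempotent", {
  g <- hwe_genotypes(80, runif(40, 0.02, 0.5), seed = 7)
  g1 <- filter_by_maf(g, 0.1)
  g2 <- filter_by_maf(g1, 0.1)
  expect_identical(g2$dosages, g1$dosages)
})

test_that("call-rate filter boundary is inclusive", {
  col94 <- c(rep(1, 94), rep(NA, 6))
  col95 <- c(rep(1, 95), rep(NA, 5))
  g <- gmat_from_cols(list(col94, col95), ids = c("low", "ok"))
  expect_identical(marker_ids(filter_by_call_rate(g, 0.95)), "ok")
  expect_identical(marker_ids(filter_by_call_rate(g, 0)), c("low", "ok"))
})

test_that("HWE chi-square matches hand-computed counts and conventions", {
  # (25, 50, 25): exactly at HWE proportions -> chi2 = 0, p = 1
  g_hwe <- gmat_from_cols(list(c(rep(2, 25), rep(1, 50), rep(0, 25))))
  expect_equal(unname(hwe_chi2(g_hwe)), 1)
  # (50, 0, 50): chi2 = (50-25)^2/25 + (0-50)^2/50 + (50-25)^2/25 = 100
  g_het0 <- gmat_from_cols(list(c(rep(2, 50), rep(0, 50))))
  expect_equal(unname(hwe_chi2(g_het0)), pchisq(100, 1, lower.tail = FALSE))
  # monomorphic marker -> p-value 1
  g_mono <- gmat_from_cols(list(rep(2, 10)))
  expect_equal(unname(hwe_chi2(g_mono)), 1)
  # missing calls must be handled first
  g_na <- gmat_from_cols(list(c(0, NA, 2)))
  expect_error(hwe_chi2(g_na), "mean_impute")
})

test_that("HWE p-values are uniform under the null", {
  g <- hwe_genotypes(600, runif(300, 0.1, 0.9), seed = 11)
  pv <- hwe_chi2(g)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean imputation fills missing calls with 2p and nothing else", {
  g <- gmat_from_cols(list(c(0, NA, 2), c(2, NA, 2)))
  gi <- mean_impute(g)
  expect_equal(unname(gi$dosages[2, ]), c(1, 2))
  expect_equal(gi$n_imputed, 2L)
  expect_false(anyNA(gi$dosages))
  # complete input is untouched
  g0 <- tiny_gmat()
  expect_identical(mean_impute(g0)$dosages, g0$dosages)
})

test_that("nested subsamples are nested for any seed and reproducible", {
  g <- hwe_genotypes(30, rep(0.3, 200), seed = 3)
  for (seed in c(1, 99, 2024)) {
    sets <- nested_subsample(g, c(10, 50, 120), seed)
    expect_true(all(sets[["10"]] %in% sets[["50"]]))
    expect_true(all(sets[["50"]] %in% sets[["120"]]))
    expect_equal(lengths(sets), c(`10` = 10L, `50` = 50L, `120` = 120L))
  }
  expect_identical(nested_subsample(g, c(10, 50), 5),
                   nested_subsample(g, c(10, 50), 5))
  expect_identical(nested_subsample(g, 200, 5)[["200"]], 1:200)
  expect_error(nested_subsample(g, c(50, 10), 5), "strictly increasing")
  expect_error(nested_subsample(g, c(10, 500), 5), "<=")
})
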