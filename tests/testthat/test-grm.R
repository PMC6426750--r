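# reference implementation of the printed three-case codings, used as the
# independent oracle against the dosage-based construction
three_case_additive <- function(d, p) {
  w <- matrix(NA_real_, nrow(d), ncol(d))
  for (j in seq_len(ncol(d))) {
    w[, j] <- ifelse(d[, j] == 2, 2 - 2 * p[j],
                     ifelse(d[, j] == 1, 1 - 2 * p[j], -2 * p[j]))
  }
  w
}

test_that("additive incidence matches the printed coding and centers columns", {
  g <- gmat_from_cols(list(c(2, 1, 0, 0)))  # p = 3/8
  w <- additive_incidence(g, freqs = 0.25)
  expect_equal(unname(w[, 1]), c(1.5, 0.5, -0.5, -0.5))
  w5 <- additive_incidence(g, freqs = 0.5)
  expect_equal(unname(w5[, 1]), c(1, 0, -1, -1))
  # at observed frequencies every column mean is exactly 0
  gg <- hwe_genotypes(50, runif(20, 0.1, 0.9), seed = 2)
  expect_equal(unname(colMeans(additive_incidence(gg))), rep(0, 20),
               tolerance = 1e-12)
  gna <- gmat_from_cols(list(c(0, NA, 2)))
  expect_error(additive_incidence(gna), "mean_impute")
})

test_that("dominance incidence matches the printed coding", {
  g <- gmat_from_cols(list(c(2, 1, 0)))
  w5 <- dominance_incidence(g, freqs = 0.5)
  expect_equal(unname(w5[, 1]), c(-0.5, 0.5, -0.5))
  w2 <- dominance_incidence(g, freqs = 0.2)
  expect_equal(unname(w2[, 1]), c(-1.28, 0.32, -0.08))
  # columns at exact HWE proportions have mean zero (p = 0.5: counts 1,2,1)
  ghwe <- gmat_from_cols(list(c(2, 1, 1, 0)))
  expect_equal(unname(colMeans(dominance_incidence(ghwe))), 0, tolerance = 1e-12)
})

test_that("VanRaden GRM reproduces the hand-worked single-marker example", {
  g <- gmat_from_cols(list(c(2, 0)))  # AA, BB at p = 0.5
  G <- vanraden_grm(additive_incidence(g, freqs = 0.5), freqs = 0.5)
  expect_equal(G$scaling_denominator, 0.5)
  expect_equal(unname(G$values), matrix(c(2, -2, -2, 2), 2))
  # identical individuals produce identical rows with G_ii = G_ij
  g2 <- gmat_from_cols(list(c(2, 2, 0), c(1, 1, 0)))
  G2 <- make_grm(g2, "additive")
  expect_equal(G2$values[1, ], G2$values[2, ])
  expect_equal(G2$values[1, 1], G2$values[1, 2])
})

test_that("dominance GRM reproduces the hand-worked single-marker example", {
  g <- gmat_from_cols(list(c(1, 2)))  # AB, AA at p = 0.5
  G <- dominance_grm(dominance_incidence(g, freqs = 0.5), freqs = 0.5)
  expect_equal(G$scaling_denominator, 0.25)
  expect_equal(unname(G$values), matrix(c(1, -1, -1, 1), 2))
})

test_that("monomorphic-only panels are rejected (zero denominator)", {
  g <- gmat_from_cols(list(rep(2, 4), rep(0, 4)))
  expect_error(vanraden_grm(additive_incidence(g)), "denominator")
  expect_error(dominance_grm(dominance_incidence(g)), "denominator")
})

test_that("dosage-based W_a equals the printed three-case coding (two-path oracle)", {
  g <- hwe_genotypes(60, runif(30, 0.05, 0.95), seed = 5)
  p <- allele_frequencies(g)
  expect_equal(unclass(additive_incidence(g))[, ],
               three_case_additive(g$dosages, p),
               ignore_attr = TRUE, tolerance = 1e-14)
})

test_that("GRMs are invariant to swapping allele A and B at every marker", {
  g <- hwe_genotypes(40, runif(25, 0.1, 0.9), seed = 6)
  gswap <- genotype_matrix(2 - g$dosages, sample_ids(g), marker_ids(g))
  Ga <- make_grm(g, "additive");  Ga2 <- make_grm(gswap, "additive")
  Gd <- make_grm(g, "dominance"); Gd2 <- make_grm(gswap, "dominance")
  expect_equal(Ga$values, Ga2$values, tolerance = 1e-12)
  expect_equal(Gd$values, Gd2$values, tolerance = 1e-12)
})

test_that("GRMs commute with sample permutation", {
  g <- hwe_genotypes(30, runif(15, 0.2, 0.8), seed = 8)
  perm <- withr::with_seed(1, sample.int(30))
  gp <- genotype_matrix(g$dosages[perm, ], sample_ids(g)[perm], marker_ids(g))
  # center both on the same frequencies (permutation leaves them unchanged)
  G <- make_grm(g, "additive")$values
  Gp <- make_grm(gp, "additive")$values
  expect_equal(Gp, G[perm, perm], tolerance = 1e-12)
})

test_that("simulated HWE panels give mean GRM diagonal near 1 and a PSD matrix", {
  g <- hwe_genotypes(500, runif(3000, 0.05, 0.95), seed = 9)
  G <- make_grm(g, "additive")
  expect_gt(mean(diag(G$values)), 0.95)
  expect_lt(mean(diag(G$values)), 1.05)
  ev <- eigen(G$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(G$values)) / 500)
  Gd <- make_grm(g, "dominance")
  expect_equal(Gd$values, t(Gd$values), tolerance = 1e-12)
  expect_gt(min(eigen(Gd$values, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * sum(diag(Gd$values)) / 500)
})

test_that("stabilize shifts every eigenvalue by exactly epsilon * trace/n", {
  g <- gmat_from_cols(list(c(2, 2, 0, 1), c(1, 1, 0, 2), c(0, 0, 2, 1)))
  # duplicated individuals make G singular
  G <- make_grm(g, "additive")
  ev0 <- eigen(G$values, symmetric = TRUE, only.values = TRUE)$values
  Gs <- stabilize(G, 1e-4)
  ev1 <- eigen(Gs$values, symmetric = TRUE, only.values = TRUE)$values
  shift <- 1e-4 * sum(diag(G$values)) / 4
  expect_equal(ev1, ev0 + shift, tolerance = 1e-12)
  expect_equal(Gs$ridge_added, shift)
  expect_gt(min(ev1), 0)
  expect_identical(stabilize(G, 0)$values, G$values)
})

test_that("GRM TSV writer/reader round-trips losslessly to 12+ significant digits", {
  g <- hwe_genotypes(12, runif(40, 0.1, 0.9), seed = 10)
  G <- make_grm(g, "additive")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grm_tsv(G, path)
  G2 <- read_grm_tsv(path)
  expect_equal(G2$values[rownames(G$values), colnames(G$values)], G$values,
               tolerance = 1e-13)
  expect_equal(G2$scaling_denominator, G$scaling_denominator, tolerance = 1e-13)
  expect_identical(G2$kind, "additive")
})
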