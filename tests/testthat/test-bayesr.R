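test_that("sampler configuration is validated", {
  expect_error(bayesr_config(n_iterations = 100, n_burnin = 100), "exceed")
  expect_error(bayesr_config(fix_pi = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  cfg <- bayesr_config()
  expect_equal(cfg$variance_scalers, c(0, 1e-4, 1e-3, 1e-2))
  expect_equal(cfg$n_iterations, 50000L)
  expect_equal(cfg$n_burnin, 20000L)
})

test_that("a degenerate all-null mixture forces zero effects and flat predictions", {
  g <- simulate_genotypes(genotype_sim_config(60, 40, seed = 50))
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5), seed = 51)
  cfg <- bayesr_config(n_iterations = 600, n_burnin = 200, seed = 1,
                       fix_pi = c(1, 0, 0, 0))
  post <- gibbs_run(tr$phenotype, g, cfg)
  expect_equal(unname(post$posterior_mean_effects), rep(0, 40))
  pred <- predict_gebv(post, g)
  expect_equal(unname(pred), rep(unname(post$fixed_effects[1]), 60))
})

test_that("every sampled mixture-proportion vector lies on the simplex", {
  g <- simulate_genotypes(genotype_sim_config(80, 60, seed = 52))
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5,
                                             class_props = c(0.8, 0.15, 0.03, 0.02)),
                       seed = 53)
  post <- gibbs_run(tr$phenotype, g,
                    bayesr_config(n_iterations = 500, n_burnin = 200, seed = 2))
  sums <- with(post$chain, pi1 + pi2 + pi3 + pi4)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(post$chain[, c("pi1", "pi2", "pi3", "pi4")] >= 0))
  expect_lt(abs(sum(post$posterior_pi) - 1), 1e-12)
})

test_that("with one marker and the largest component fixed, the posterior mean matches the conjugate closed form", {
  n <- 200
  withr::with_seed(54, {
    dose <- rbinom(n, 2, 0.4)
    y <- 0.8 * (dose - mean(dose)) + rnorm(n, 0, 0.5)
  })
  g <- genotype_matrix(matrix(dose, ncol = 1,
                              dimnames = list(paste0("s", 1:n), "qtl")))
  vy <- var(y); sg <- 0.5 * vy; se <- 0.5 * vy
  post <- gibbs_run(y, g, bayesr_config(n_iterations = 6000, n_burnin = 2000,
                                        seed = 3, fix_pi = c(0, 0, 0, 1),
                                        fix_sigma_g = sg, fix_sigma_e = se))
  z <- dose - 2 * allele_frequencies(g)
  lam <- se / (0.01 * sg)
  # closed form with the intercept profiled out (z is centered)
  ghat <- sum(z * (y - mean(y))) / (sum(z^2) + lam)
  psd <- sqrt(se / (sum(z^2) + lam))
  mcse <- psd / sqrt(post$n_kept / 20)
  expect_lt(abs(post$posterior_mean_effects[1] - ghat), 3 * mcse)
})

test_that("posterior genetic plus residual variance accounts for the phenotypic variance", {
  # self-consistent mixture: effect-class proportions are chosen so the
  # implied genetic variance (sum over causal SNPs of gamma_k * Var(z_j))
  # equals sigma_g2 itself, the configuration under which sigma_g2 carries
  # its total-genetic-variance interpretation; the ratio is averaged over
  # trait replicates because sigma_g2 is only softly identified per draw
  g <- simulate_genotypes(genotype_sim_config(500, 1000, maf_range = c(0.4, 0.5),
                                              ld_rho = 0, seed = 55))
  ratios <- vapply(c(57, 157, 257), function(ts) {
    tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5,
                           class_props = c(0.52, 0.1, 0.2, 0.18)), seed = ts)
    post <- gibbs_run(tr$phenotype, g,
                      bayesr_config(n_iterations = 10000, n_burnin = 4000, seed = 4))
    (post$posterior_sigma2_g + post$posterior_sigma2_e) / var(tr$phenotype)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("BayesR matches or beats GBLUP when a few large genes drive the trait", {
  g <- simulate_genotypes(genotype_sim_config(500, 600, maf_range = c(0.1, 0.5),
                                              ld_rho = 0.3, seed = 57))
  # ~5 large-effect QTL on a small polygenic background
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5,
                                             class_props = c(0.852, 0.14, 0, 0.008)),
                       seed = 58)
  plan <- make_cv_plan(500, 5, 1, root_seed = 59)
  acc_g <- run_cv("gblup_a", g, tr$phenotype, plan)
  acc_b <- run_cv("bayesr", g, tr$phenotype, plan,
                  method_config = list(config = bayesr_config(
                    n_iterations = 2000, n_burnin = 800)))
  expect_gte(acc_b$mean_r, acc_g$mean_r - 0.02)
})

test_that("predictions are linear in the posterior effects and aligned by marker id", {
  g <- simulate_genotypes(genotype_sim_config(40, 5, seed = 60))
  post <- structure(list(
    posterior_mean_effects = setNames(c(0, 0.7, 0, 0, 0), marker_ids(g)),
    centers = setNames(rep(0, 5), marker_ids(g)),
    fixed_effects = c(`(Intercept)` = 1.5)
  ), class = "bayesr_posterior")
  pred <- predict_gebv(post, g)
  expect_equal(unname(pred), 1.5 + 0.7 * unname(g$dosages[, 2]))
  g_sub <- gsfactors:::subset_markers(g, c(1, 3))
  expect_error(predict_gebv(post, g_sub), "absent")
})

test_that("training samples re-predicted equal the sampler's in-training genetic values", {
  g <- simulate_genotypes(genotype_sim_config(80, 50, seed = 61))
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.6), seed = 62)
  post <- gibbs_run(tr$phenotype, g,
                    bayesr_config(n_iterations = 800, n_burnin = 300, seed = 5))
  expect_equal(predict_gebv(post, g), post$genomic_values, tolerance = 1e-10)
})

test_that("Geweke diagnostics behave on null, trending and equal-mean chains", {
  # iid chains rarely flagged
  zs <- vapply(1:40, function(i)
    withr::with_seed(100 + i, gsfactors:::geweke_z(rnorm(600))), numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.9)
  # strong linear trend is flagged
  expect_gt(abs(gsfactors:::geweke_z(seq(0, 1, length.out = 600) +
                                     withr::with_seed(7, rnorm(600, 0, 0.01)))), 2)
  # exactly equal segment means give z = 0
  expect_equal(gsfactors:::geweke_z(rep(c(1, -1), 300)), 0)
  expect_equal(gsfactors:::geweke_z(rep(2, 500)), 0)
})

test_that("convergence diagnostics require a usable chain and flag trends", {
  g <- simulate_genotypes(genotype_sim_config(60, 30, seed = 63))
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.5), seed = 64)
  post <- gibbs_run(tr$phenotype, g,
                    bayesr_config(n_iterations = 700, n_burnin = 300, seed = 6))
  dg <- convergence_diagnostic(post)
  expect_setequal(dg$parameter,
                  c("sigma2_g", "sigma2_e", "pi1", "pi2", "pi3", "pi4"))
  expect_true(all(is.finite(dg$z)))
  short <- post; short$chain <- post$chain[1:50, ]
  expect_error(convergence_diagnostic(short), "too short")
})

test_that("iteration-budget tables are one row per budget and reproducible", {
  g <- simulate_genotypes(genotype_sim_config(120, 60, seed = 65))
  tr <- simulate_trait(g, trait_architecture("mixture", h2_target = 0.6), seed = 66)
  plan <- make_cv_plan(120, 5, 1, root_seed = 67)
  tab1 <- iteration_budget_experiment(tr$phenotype, g, c(400, 800), plan,
                                      bayesr_config(n_iterations = 400,
                                                    n_burnin = 100))
  tab2 <- iteration_budget_experiment(tr$phenotype, g, c(400, 800), plan,
                                      bayesr_config(n_iterations = 400,
                                                    n_burnin = 100))
  expect_equal(nrow(tab1), 2)
  expect_equal(tab1$budget, c(400, 800))
  expect_identical(tab1, tab2)
  expect_error(iteration_budget_experiment(tr$phenotype, g, c(800, 400), plan),
               "increasing")
})
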