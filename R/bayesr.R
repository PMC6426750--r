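#' BayesR sampler configuration
#'
#' The SNP-effect prior is the four-component normal mixture
#' `pi_1 N(0, 0) + pi_2 N(0, 1e-4 sigma_g2) + pi_3 N(0, 1e-3 sigma_g2) +
#' pi_4 N(0, 1e-2 sigma_g2)` with the relative variance of each component
#' fixed; `pi` gets a Dirichlet prior. Hyperpriors: `sigma_e2` flat scaled
#' inverse chi-square (`nu = -2, S = 0`); `sigma_g2` scaled inverse
#' chi-square with `nu_g` degrees of freedom and scale set from
#' `0.5 * Var(y)` at run time.
#'
#' @param n_iterations total MCMC iterations (default 50000).
#' @param n_burnin burn-in iterations discarded from posterior summaries
#'   (default 20000; when only a total budget is given elsewhere the
#'   burn-in fraction is 0.4).
#' @param variance_scalers fixed 4-vector of relative component variances.
#' @param dirichlet_alpha Dirichlet pseudo-counts for `pi` (default all 1).
#' @param seed integer seed.
#' @param fix_pi optional 4-vector: hold `pi` fixed (diagnostic mode).
#' @param fix_sigma_g,fix_sigma_e optional values holding a variance fixed.
#' @param nu_g prior degrees of freedom for `sigma_g2` (default 4).
#' @param center logical: center dosage columns by `2 p_j` before sampling
#'   (numerically equivalent model, the intercept absorbs the shift;
#'   improves mixing).
#' @param refresh_every full residual recomputation interval.
#' @return A `bayesr_config` list.
#' @export
bayesr_config <- function(n_iterations = 50000L, n_burnin = 20000L,
                          variance_scalers = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_alpha = rep(1, 4), seed = 1L,
                          fix_pi = NULL, fix_sigma_g = NULL,
                          fix_sigma_e = NULL, nu_g = 4,
                          center = TRUE, refresh_every = 1000L) {
  if (n_iterations <= n_burnin)
    stop_gs("n_iterations must exceed n_burnin")
  stopifnot(length(variance_scalers) == 4,
            length(dirichlet_alpha) == 4)
  if (!is.null(fix_pi)) {
    stopifnot(length(fix_pi) == 4)
    if (abs(sum(fix_pi) - 1) > 1e-8) stop_gs("fix_pi must sum to 1")
  }
  structure(list(
    n_iterations = as.integer(n_iterations),
    n_burnin = as.integer(n_burnin),
    variance_scalers = variance_scalers,
    dirichlet_alpha = dirichlet_alpha,
    seed = as.integer(seed),
    fix_pi = fix_pi,
    fix_sigma_g = fix_sigma_g,
    fix_sigma_e = fix_sigma_e,
    nu_g = nu_g,
    center = isTRUE(center),
    refresh_every = as.integer(refresh_every)
  ), class = "bayesr_config")
}

#' Run the BayesR Gibbs sampler
#'
#' Single-site Gibbs sampling of SNP effects under the four-component
#' mixture prior: per SNP the component indicator is drawn from its
#' marginalized conditional (effect integrated out), then the effect from
#' its conditional normal; fixed effects, `pi`, `sigma_g2` and `sigma_e2`
#' follow from their conjugate conditionals. Posterior means are taken
#' over all post-burn-in samples (no thinning).
#'
#' @param y numeric phenotype vector for the training samples (no `NA`).
#' @param genotypes a complete `genotype_matrix` for the same samples.
#' @param config a [bayesr_config()].
#' @param X optional fixed-effect design (default intercept).
#' @return An object of class `bayesr_posterior`: posterior mean effects,
#'   component probabilities, `posterior_pi`, `posterior_sigma2_g`,
#'   `posterior_sigma2_e`, fixed effects, per-iteration chains for the
#'   scalar parameters, genomic values of the training samples, Geweke
#'   diagnostics and a convergence flag.
#' @export
gibbs_run <- function(y, genotypes, config = bayesr_config(), X = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "bayesr_config"))
  d <- genotypes$dosages
  if (anyNA(d)) stop_gs("missing genotype calls; run mean_impute() first")
  n <- nrow(d)
  if (length(y) != n) stop_gs("length(y) must equal the number of samples")
  if (anyNA(y)) stop_gs("y must be complete for sampling")
  if (n < 30) stop_gs("need at least 30 samples")
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  centers <- if (config$center) 2 * allele_frequencies(genotypes) else
    setNames(rep(0, ncol(d)), marker_ids(genotypes))
  Z <- sweep(d, 2, centers)
  vy <- var(y)
  s2_g_scale <- 0.5 * vy
  pi_init <- config$fix_pi %||%
    (config$dirichlet_alpha / sum(config$dirichlet_alpha))
  sg_init <- config$fix_sigma_g %||% (0.5 * vy)
  se_init <- config$fix_sigma_e %||% (0.5 * vy)

  res <- withr::with_seed(config$seed,
    bayesr_gibbs_cpp(y, X, Z,
                     config$n_iterations, config$n_burnin,
                     config$variance_scalers, config$dirichlet_alpha,
                     config$nu_g, s2_g_scale,
                     sg_init, se_init, pi_init,
                     !is.null(config$fix_pi),
                     !is.null(config$fix_sigma_g),
                     !is.null(config$fix_sigma_e),
                     config$refresh_every))

  keep <- (config$n_burnin + 1):config$n_iterations
  chain <- data.frame(iteration = keep,
                      sigma2_g = res$sg_trace[keep],
                      sigma2_e = res$se_trace[keep],
                      pi1 = res$pi_trace[keep, 1], pi2 = res$pi_trace[keep, 2],
                      pi3 = res$pi_trace[keep, 3], pi4 = res$pi_trace[keep, 4])
  effects <- setNames(res$effects, marker_ids(genotypes))
  gv <- as.numeric(X %*% res$fixed) + as.numeric(Z %*% res$effects)
  post <- structure(list(
    posterior_mean_effects = effects,
    comp_probs = `dimnames<-`(res$comp_prob,
      list(marker_ids(genotypes), paste0("comp", 1:4))),
    posterior_pi = res$pi,
    posterior_sigma2_g = res$sigma_g2,
    posterior_sigma2_e = res$sigma_e2,
    fixed_effects = setNames(res$fixed, colnames(X)),
    genomic_values = setNames(gv, sample_ids(genotypes)),
    chain = chain,
    centers = centers,
    config = config,
    n_kept = res$n_kept
  ), class = "bayesr_posterior")
  if (res$n_kept >= 100) {
    diag <- convergence_diagnostic(post)
    post$diagnostics <- diag
    post$converged <- all(diag$converged)
  } else {
    post$diagnostics <- NULL
    post$converged <- NA
  }
  post
}

#' @export
print.bayesr_posterior <- function(x, ...) {
  cat(sprintf("bayesr_posterior: %d markers, %d kept samples\n",
              length(x$posterior_mean_effects), x$n_kept))
  cat("pi:", paste(sprintf("%.4f", x$posterior_pi), collapse = " "),
      sprintf("| sigma2_g %.4g sigma2_e %.4g | converged: %s\n",
              x$posterior_sigma2_g, x$posterior_sigma2_e,
              format(x$converged)))
  invisible(x)
}

#' Genomic values for new individuals from a BayesR posterior
#'
#' `value_i = fixed-effect term + sum_j Z_ij * posterior_mean_effect_j`,
#' with dosages centered exactly as during training. All training markers
#' must be present in the new panel.
#'
#' @param posterior a `bayesr_posterior`.
#' @param genotypes_new a complete `genotype_matrix`.
#' @return Named numeric vector of genomic values.
#' @export
predict_gebv <- function(posterior, genotypes_new) {
  stopifnot(inherits(posterior, "bayesr_posterior"),
            inherits(genotypes_new, "genotype_matrix"))
  train_ids <- names(posterior$posterior_mean_effects)
  missing_ids <- setdiff(train_ids, marker_ids(genotypes_new))
  if (length(missing_ids))
    stop_gs("markers absent from the new panel: ",
            paste(head(missing_ids, 10), collapse = ", "),
            if (length(missing_ids) > 10) " ..." else "")
  d <- genotypes_new$dosages[, train_ids, drop = FALSE]
  if (anyNA(d)) stop_gs("missing genotype calls; run mean_impute() first")
  Z <- sweep(d, 2, posterior$centers[train_ids])
  mu <- posterior$fixed_effects[1]  # intercept term
  setNames(as.numeric(mu + Z %*% posterior$posterior_mean_effects),
           sample_ids(genotypes_new))
}

# Geweke z-score: compare the mean of the first `frac1` of a chain with
# the last `frac2`, with variances from the spectral density at frequency
# zero (AR-model estimator).
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) return(0)
  s0 <- function(v) {
    if (stats::sd(v) == 0) return(0)
    fit <- tryCatch(stats::ar(v, aic = TRUE,
                              order.max = min(20, length(v) - 1)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(stats::var(v))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  denom <- sqrt(s0(a) / length(a) + s0(b) / length(b))
  if (denom == 0) return(0)
  (mean(a) - mean(b)) / denom
}

#' MCMC convergence diagnostics for a BayesR chain
#'
#' Geweke z-scores (first 10% vs last 50% of the post-burn-in chain) for
#' `sigma2_g`, `sigma2_e` and each mixture proportion; a parameter is
#' flagged converged when `|z| < 2`.
#'
#' @param posterior a `bayesr_posterior` with at least 100 post-burn-in
#'   samples.
#' @return Data frame with columns `parameter`, `z`, `converged`.
#' @export
convergence_diagnostic <- function(posterior) {
  stopifnot(inherits(posterior, "bayesr_posterior"))
  ch <- posterior$chain
  if (nrow(ch) < 100) stop_gs("chain too short for diagnostics (need >= 100 kept samples)")
  pars <- c("sigma2_g", "sigma2_e", "pi1", "pi2", "pi3", "pi4")
  z <- vapply(pars, function(p) geweke_z(ch[[p]]), numeric(1))
  data.frame(parameter = pars, z = as.numeric(z),
             converged = abs(z) < 2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Prediction accuracy as a function of the MCMC iteration budget
#'
#' Runs the full cross-validation protocol at each total-iteration budget
#' (burn-in set to 40% of the budget) and tabulates the mean accuracy and
#' its standard error per budget.
#'
#' @param y named phenotype vector.
#' @param genotypes a complete `genotype_matrix`.
#' @param budgets increasing vector of total iteration counts.
#' @param plan a [make_cv_plan()] cross-validation plan.
#' @param config base [bayesr_config()] (iterations/burn-in overridden per
#'   budget).
#' @return Data frame with one row per budget: `budget`, `mean_r`, `se_r`.
#' @export
iteration_budget_experiment <- function(y, genotypes, budgets, plan,
                                        config = bayesr_config()) {
  budgets <- as.integer(budgets)
  if (length(budgets) > 1 && any(diff(budgets) <= 0))
    stop_gs("budgets must be increasing")
  rows <- lapply(budgets, function(b) {
    cfg <- config
    cfg$n_iterations <- b
    cfg$n_burnin <- as.integer(floor(0.4 * b))
    acc <- run_cv("bayesr", genotypes, y, plan, method_config = list(config = cfg))
    data.frame(budget = b, mean_r = acc$mean_r, se_r = acc$se_r)
  })
  do.call(rbind, rows)
}

#' Write BayesR marker-effect estimates as TSV
#'
#' One row per marker: posterior mean effect and the posterior probability
#' of each mixture component.
#'
#' @param posterior a `bayesr_posterior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(posterior, path) {
  stopifnot(inherits(posterior, "bayesr_posterior"))
  tab <- data.frame(marker_id = names(posterior$posterior_mean_effects),
                    posterior_mean_effect = as.numeric(posterior$posterior_mean_effects),
                    posterior$comp_probs,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
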