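#' Build a replicated k-fold cross-validation plan
#'
#' Per replicate, indices are shuffled with a deterministic child seed of
#' `root_seed` and split into `n_folds` contiguous blocks whose sizes
#' differ by at most one, giving disjoint folds that cover every sample.
#'
#' @param n number of samples.
#' @param n_folds folds per replicate (default 5).
#' @param n_replicates number of replicates (default 10).
#' @param root_seed integer seed; the same seed reproduces the same plan.
#' @return A `cv_plan` object; `assignments` is a list of integer fold
#'   labels (one vector per replicate).
#' @export
make_cv_plan <- function(n, n_folds = 5L, n_replicates = 10L, root_seed) {
  n <- as.integer(n); n_folds <- as.integer(n_folds)
  if (n < n_folds) stop_gs("need n >= n_folds (", n, " < ", n_folds, ")")
  assignments <- lapply(seq_len(n_replicates), function(r) {
    perm <- withr::with_seed(child_seed(root_seed, r), sample.int(n))
    sizes <- rep(n %/% n_folds, n_folds) +
      c(rep(1L, n %% n_folds), rep(0L, n_folds - n %% n_folds))
    fold <- integer(n)
    fold[perm] <- rep(seq_len(n_folds), times = sizes)
    fold
  })
  structure(list(n = n, n_folds = n_folds,
                 n_replicates = as.integer(n_replicates),
                 root_seed = as.integer(root_seed),
                 assignments = assignments),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d samples, %d folds x %d replicates (seed %d)\n",
              x$n, x$n_folds, x$n_replicates, x$root_seed))
  invisible(x)
}

#' Pearson correlation with explicit degenerate-input errors
#'
#' @param a,b numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return The product-moment correlation.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop_gs("inputs differ in length")
  if (length(a) < 3) stop_gs("need at least 3 observations")
  if (anyNA(a) || anyNA(b)) stop_gs("missing values in correlation input")
  if (stats::sd(a) == 0) stop_gs("first input has zero variance")
  if (stats::sd(b) == 0) stop_gs("second input has zero variance")
  stats::cor(a, b)
}

.align_phenotypes <- function(genotypes, phenotypes) {
  ids <- sample_ids(genotypes)
  if (is.data.frame(phenotypes)) {
    stopifnot(all(c("sample_id", "value") %in% names(phenotypes)))
    phenotypes <- setNames(as.numeric(phenotypes$value),
                           as.character(phenotypes$sample_id))
  }
  if (is.null(names(phenotypes))) {
    if (length(phenotypes) != length(ids))
      stop_gs("unnamed phenotype vector must match the genotype sample count")
    return(setNames(as.numeric(phenotypes), ids))
  }
  if (!all(ids %in% names(phenotypes)))
    stop_gs("phenotypes missing for samples: ",
            paste(head(setdiff(ids, names(phenotypes)), 5), collapse = ", "))
  as.numeric(phenotypes[ids]) -> y
  setNames(y, ids)
}

.gblup_kernels <- function(genotypes, method) {
  ga <- make_grm(genotypes, "additive")
  if (method == "gblup_a") list(additive = ga)
  else list(additive = ga, dominance = make_grm(genotypes, "dominance"))
}

#' Replicated cross-validated prediction accuracy
#'
#' The study protocol: per replicate, each fold is held out in turn, the
#' model is fitted on the remaining folds and held-out individuals are
#' predicted; the held-out predictions are pooled across folds into one
#' vector per replicate and correlated (Pearson) with the observed
#' phenotypes. GBLUP relationship matrices are computed once on all
#' samples and sub-indexed per fold (their construction uses no
#' phenotypes); variance components are re-estimated per training fold.
#' BayesR is refitted per fold with a deterministic child seed
#' `(root_seed, replicate, fold)`.
#'
#' @param method one of `"gblup_a"`, `"gblup_ad"`, `"bayesr"`.
#' @param genotypes a complete `genotype_matrix`.
#' @param phenotypes named numeric vector or data frame
#'   (`sample_id`, `value`).
#' @param plan a [make_cv_plan()].
#' @param method_config list of method options. For BayesR, `config` (a
#'   [bayesr_config()]); for GBLUP, optional `min_phenotyped`.
#' @param trait_label,density_label labels carried into the result.
#' @return An `accuracy_result`: `per_replicate_r`, `mean_r`, `se_r`,
#'   plus labels.
#' @export
run_cv <- function(method = c("gblup_a", "gblup_ad", "bayesr"),
                   genotypes, phenotypes, plan, method_config = list(),
                   trait_label = "trait", density_label = NA) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "cv_plan"))
  y <- .align_phenotypes(genotypes, phenotypes)
  n <- length(y)
  if (n != plan$n) stop_gs("plan was built for ", plan$n, " samples, data has ", n)

  kernels <- if (method != "bayesr") .gblup_kernels(genotypes, method) else NULL

  rs <- vapply(seq_len(plan$n_replicates), function(r) {
    fold <- plan$assignments[[r]]
    pred <- rep(NA_real_, n)
    for (f in seq_len(plan$n_folds)) {
      val <- which(fold == f)
      train <- which(fold != f)
      if (method == "bayesr") {
        cfg <- method_config$config %||% bayesr_config()
        cfg$seed <- child_seed(plan$root_seed, r, f)
        gtrain <- subset_samples(genotypes, train)
        post <- tryCatch(gibbs_run(y[train], gtrain, cfg),
                         error = function(e) stop_gs(
                           "bayesr failed at replicate ", r, " fold ", f, ": ",
                           conditionMessage(e)))
        gval <- subset_samples(genotypes, val)
        pred[val] <- predict_gebv(post, gval)
      } else {
        ytrain <- y
        ytrain[val] <- NA
        Ktt <- lapply(kernels, function(k) k$values[train, train, drop = FALSE])
        names(Ktt) <- names(kernels)
        vc <- tryCatch(reml_fit(y[train], Ktt,
                                min_phenotyped = method_config$min_phenotyped %||% 30L),
                       error = function(e) stop_gs(
                         method, " failed at replicate ", r, " fold ", f, ": ",
                         conditionMessage(e)))
        Kfull <- lapply(kernels, function(k) k$values)
        names(Kfull) <- names(kernels)
        bp <- blup_predict(vc, ytrain, Kfull, train_ids = train)
        pred[val] <- bp$ebv[val]
      }
    }
    pearson(pred, y)
  }, numeric(1))

  structure(list(per_replicate_r = rs,
                 mean_r = mean(rs),
                 se_r = if (length(rs) > 1) se_mean(rs) else NA_real_,
                 method = method,
                 trait = trait_label,
                 density = density_label,
                 n_markers = ncol(genotypes$dosages)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("accuracy_result [%s, %s, m=%d]: mean r = %.4f (se %.4g) over %d replicates\n",
              x$method, x$trait, x$n_markers, x$mean_r,
              x$se_r, length(x$per_replicate_r)))
  invisible(x)
}

#' Marker-density experiment
#'
#' Runs the full cross-validation protocol at each marker density. Marker
#' panels are drawn with [nested_subsample()], so every lower-density
#' panel is a subset of every higher-density panel.
#'
#' @param genotypes a complete `genotype_matrix`.
#' @param phenotypes named phenotype vector or data frame.
#' @param sizes strictly increasing density grid.
#' @param methods character vector of methods (see [run_cv()]).
#' @param plan a [make_cv_plan()].
#' @param seed seed for the nested marker subsampling.
#' @param method_configs named list of per-method `method_config` lists.
#' @param trait_label label carried into the table.
#' @return Long-format data frame: `trait`, `method`, `density`, `mean_r`,
#'   `se_r`.
#' @export
density_experiment <- function(genotypes, phenotypes, sizes,
                               methods = "gblup_a", plan, seed,
                               method_configs = list(),
                               trait_label = "trait") {
  idx_sets <- nested_subsample(genotypes, sizes, seed)
  rows <- list()
  for (s in names(idx_sets)) {
    gsub_ <- subset_markers(genotypes, idx_sets[[s]])
    for (mth in methods) {
      gs_msg(sprintf("density experiment: density %s, method %s", s, mth))
      acc <- run_cv(mth, gsub_, phenotypes, plan,
                    method_config = method_configs[[mth]] %||% list(),
                    trait_label = trait_label, density_label = as.integer(s))
      rows[[length(rows) + 1]] <- data.frame(
        trait = trait_label, method = mth, density = as.integer(s),
        mean_r = acc$mean_r, se_r = acc$se_r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Minor-allele-frequency filtering experiment
#'
#' For each MAF threshold: (a) the MAF-filtered marker panel and (b) a
#' random control panel of exactly the same size drawn without MAF
#' restriction are each put through the full cross-validation protocol for
#' every requested method. When the filter removes nothing the control is
#' the identical full panel.
#'
#' @param genotypes a complete `genotype_matrix`.
#' @param phenotypes named phenotype vector or data frame.
#' @param thresholds MAF thresholds in `[0, 0.5]`.
#' @param plan a [make_cv_plan()].
#' @param methods methods to evaluate (default GBLUP-A and BayesR).
#' @param method_configs named list of per-method `method_config` lists.
#' @param control_seed seed for drawing the random control panels.
#' @param trait_label label carried into the table.
#' @return Long-format data frame: `trait`, `method`, `threshold`,
#'   `panel` (`"maf_filtered"`/`"random_control"`), `n_markers`, `mean_r`,
#'   `se_r`.
#' @export
maf_experiment <- function(genotypes, phenotypes, thresholds, plan,
                           methods = c("gblup_a", "bayesr"),
                           method_configs = list(), control_seed = 1L,
                           trait_label = "trait") {
  if (any(thresholds < 0 | thresholds > 0.5))
    stop_gs("thresholds must lie in [0, 0.5]")
  m <- ncol(genotypes$dosages)
  rows <- list()
  for (t_i in seq_along(thresholds)) {
    thr <- thresholds[t_i]
    gf <- filter_by_maf(genotypes, thr)
    mt <- ncol(gf$dosages)
    if (mt == 0) stop_gs("threshold ", thr, " removes all markers")
    ctrl_idx <- if (mt == m) seq_len(m) else
      sort(withr::with_seed(child_seed(control_seed, t_i),
                            sample.int(m, mt)))
    gc_ <- subset_markers(genotypes, ctrl_idx)
    same_panel <- mt == m  # filter removed nothing: control IS the full panel
    panels <- list(maf_filtered = gf, random_control = gc_)
    for (mth in methods) {
      acc_f <- NULL
      for (pn in names(panels)) {
        gs_msg(sprintf("MAF experiment: threshold %g, panel %s, method %s",
                       thr, pn, mth))
        acc <- if (pn == "random_control" && same_panel) acc_f else
          run_cv(mth, panels[[pn]], phenotypes, plan,
                 method_config = method_configs[[mth]] %||% list(),
                 trait_label = trait_label)
        if (pn == "maf_filtered") acc_f <- acc
        rows[[length(rows) + 1]] <- data.frame(
          trait = trait_label, method = mth, threshold = thr, panel = pn,
          n_markers = mt, mean_r = acc$mean_r, se_r = acc$se_r,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
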