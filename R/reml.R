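# ---- kernel handling ---------------------------------------------------

.as_kernel_list <- function(kernels) {
  if (inherits(kernels, "relationship_matrix") || is.matrix(kernels))
    kernels <- list(kernels)
  labels <- names(kernels)
  K <- vector("list", length(kernels))
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    lab <- labels[i]
    if (inherits(k, "relationship_matrix")) {
      if (is.null(lab) || !nzchar(lab)) lab <- k$kind
      k <- k$values
    }
    if (is.null(lab) || !nzchar(lab)) lab <- if (i == 1) "additive" else paste0("vc", i)
    if (!is.matrix(k) || nrow(k) != ncol(k))
      stop_gs("kernel ", i, " is not a square matrix")
    K[[i]] <- k
    labels[i] <- lab
  }
  if (is.null(labels)) labels <- vapply(seq_along(K), function(i)
    if (i == 1) "additive" else paste0("vc", i), character(1))
  list(K = K, labels = labels)
}

# ---- REML --------------------------------------------------------------

#' Fit a genomic mixed model by restricted maximum likelihood
#'
#' Estimates variance components of `y = X b + sum_k Z u_k + e` with
#' `u_k ~ MVN(0, G_k sigma2_k)` and `e ~ MVN(0, I sigma2_e)` using
#' average-information (AI) REML with expectation-maximization fallback
#' steps: the first iteration and any AI proposal that leaves the parameter
#' space fall back to an EM update, which cannot produce negative
#' components. One genomic kernel gives the additive GBLUP model; an
#' additive plus a dominance kernel gives the additive-dominance model.
#'
#' For a single kernel the restricted likelihood is evaluated in the
#' eigenbasis of `G`, making each iteration O(n); with several kernels the
#' dense-matrix form is used.
#'
#' @param y numeric phenotype vector; `NA` marks unphenotyped individuals,
#'   which are excluded from estimation.
#' @param kernels a `relationship_matrix` (or plain symmetric matrix), or a
#'   named list of them, each `n x n` over the same samples as `y`.
#' @param X fixed-effect design matrix (default: intercept only); must have
#'   full column rank.
#' @param max_iter maximum REML iterations (default 200).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default `1e-8`).
#' @param algorithm `"ai"` (default) or `"em"` (pure EM; used mainly to
#'   verify the monotone-likelihood property).
#' @param min_phenotyped minimum number of phenotyped samples required.
#' @return An object of class `variance_components` with elements `sigma2`
#'   (named estimates, components at the lower pin reported as 0),
#'   `sigma2_raw`, `h2` (per genetic term), `h2_total`, `converged`,
#'   `n_iterations`, `loglik`, `loglik_trace`.
#' @export
reml_fit <- function(y, kernels, X = NULL, max_iter = 200L, tol = 1e-8,
                     algorithm = c("ai", "em"), min_phenotyped = 30L) {
  algorithm <- match.arg(algorithm)
  kl <- .as_kernel_list(kernels)
  n_all <- length(y)
  for (k in kl$K) if (nrow(k) != n_all)
    stop_gs("kernel dimension (", nrow(k), ") does not match length(y) (", n_all, ")")
  obs <- which(!is.na(y))
  if (length(obs) < min_phenotyped)
    stop_gs("need at least ", min_phenotyped, " phenotyped samples, got ", length(obs))
  yt <- as.numeric(y[obs])
  vy <- var(yt)
  if (!is.finite(vy) || vy <= 0) stop_gs("phenotype variance is zero")
  if (is.null(X)) X <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  Xt <- X[obs, , drop = FALSE]
  q <- ncol(Xt)
  if (qr(Xt)$rank < q) stop_gs("fixed-effect design is rank deficient")
  Ks <- lapply(kl$K, function(k) k[obs, obs, drop = FALSE])
  nk <- length(Ks)
  n_obs <- length(obs)
  bound <- 1e-10 * vy

  quant <- if (nk == 1) .reml_quant_spectral(Ks[[1]], yt, Xt)
           else .reml_quant_dense(Ks, yt, Xt)

  theta <- rep(vy / (nk + 1), nk + 1)
  qn <- quant(theta)
  ll_trace <- qn$logL
  converged <- FALSE
  it <- 1L
  while (it < max_iter) {
    it <- it + 1L
    em_step <- pmax(theta + theta^2 * (qn$yPGPy - qn$trPG) / n_obs, bound)
    stepped <- FALSE
    if (algorithm == "ai" && it > 2L) {
      # AI step, clamped to the parameter space; accepted only if the
      # restricted likelihood does not decrease
      delta <- tryCatch(solve(qn$AI, qn$score), error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- pmax(theta + as.numeric(delta), bound)
        qn_cand <- quant(cand)
        if (is.finite(qn_cand$logL) &&
            qn_cand$logL >= qn$logL - 1e-9 * (1 + abs(qn$logL))) {
          theta <- cand
          qn <- qn_cand
          stepped <- TRUE
        }
      }
    }
    if (!stepped) {
      theta <- em_step
      qn <- quant(theta)
    }
    ll_trace[it] <- qn$logL
    if (abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }

  labels <- kl$labels
  sigma2_raw <- setNames(theta, c(labels, "residual"))
  at_pin <- sigma2_raw <= bound * (1 + 1e-6)
  sigma2 <- ifelse(at_pin, 0, sigma2_raw)
  tot <- sum(sigma2)
  h2 <- setNames(sigma2[seq_len(nk)] / tot, labels)
  structure(list(
    sigma2 = sigma2,
    sigma2_raw = sigma2_raw,
    h2 = h2,
    h2_total = sum(h2),
    converged = converged,
    n_iterations = it,
    loglik = ll_trace[length(ll_trace)],
    loglik_trace = ll_trace,
    labels = labels,
    bound = bound,
    n_used = n_obs,
    algorithm = algorithm
  ), class = "variance_components")
}

# Spectral engine: one genomic kernel. Work in the eigenbasis of G, where
# V = s_g D + s_e I is diagonal and every REML quantity is O(n q).
.reml_quant_spectral <- function(K, yt, Xt) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)  # clip tiny negative eigenvalues from roundoff
  U <- eg$vectors
  yr <- as.numeric(crossprod(U, yt))
  Xr <- crossprod(U, Xt)
  function(theta) {
    v <- theta[1] * d + theta[2]
    vi <- 1 / v
    ViX <- Xr * vi
    XtViX <- crossprod(Xr, ViX)
    C <- solve(XtViX)
    XtViy <- crossprod(ViX, yr)
    Py <- vi * yr - as.numeric(ViX %*% (C %*% XtViy))
    Pu <- function(u) vi * u - as.numeric(ViX %*% (C %*% crossprod(ViX, u)))
    u_g <- d * Py
    u_e <- Py
    Pug <- Pu(u_g); Pue <- Pu(u_e)
    A <- crossprod(ViX, d * ViX)
    trPG <- c(sum(d * vi) - sum(C * A),
              sum(vi) - sum(C * crossprod(ViX, ViX)))
    yPGPy <- c(sum(Py * u_g), sum(Py * u_e))
    AI <- 0.5 * matrix(c(sum(u_g * Pug), sum(u_g * Pue),
                         sum(u_e * Pug), sum(u_e * Pue)), 2, 2)
    score <- -0.5 * (trPG - yPGPy)
    logL <- -0.5 * (sum(log(v)) +
                    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
                    sum(yr * Py))
    list(logL = logL, score = score, AI = AI, trPG = trPG, yPGPy = yPGPy)
  }
}

# Dense engine: arbitrary number of kernels (used for GBLUP-AD).
.reml_quant_dense <- function(Ks, yt, Xt) {
  n <- length(yt)
  Gs <- c(Ks, list(diag(n)))
  nk <- length(Gs)
  function(theta) {
    V <- theta[nk] * diag(n)
    for (i in seq_len(nk - 1)) V <- V + theta[i] * Gs[[i]]
    R <- chol(V)
    Vi <- chol2inv(R)
    ViX <- Vi %*% Xt
    XtViX <- crossprod(Xt, ViX)
    C <- solve(XtViX)
    P <- Vi - ViX %*% tcrossprod(C, ViX)
    Py <- as.numeric(P %*% yt)
    us <- lapply(Gs, function(G) as.numeric(G %*% Py))
    Pus <- lapply(us, function(u) as.numeric(P %*% u))
    trPG <- vapply(Gs, function(G) sum(P * G), numeric(1))
    yPGPy <- vapply(us, function(u) sum(Py * u), numeric(1))
    AI <- matrix(0, nk, nk)
    for (i in seq_len(nk)) for (j in i:nk) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(us[[i]] * Pus[[j]])
    }
    score <- -0.5 * (trPG - yPGPy)
    logL <- -0.5 * (2 * sum(log(diag(R))) +
                    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
                    sum(yt * Py))
    list(logL = logL, score = score, AI = AI, trPG = trPG, yPGPy = yPGPy)
  }
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (", x$algorithm, "-REML, ",
      x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(x$sigma2, 6))
  cat("h2:", paste(sprintf("%s=%.4f", names(x$h2), x$h2), collapse = ", "),
      sprintf("total=%.4f\n", x$h2_total))
  invisible(x)
}

#' Expected prediction accuracy from heritability
#'
#' When estimated breeding values are (near-)unbiased estimates of the
#' genetic values, the expected Pearson correlation between EBVs and
#' phenotypes equals the square root of heritability.
#'
#' @param h2 heritability value(s) in `[0, 1]`.
#' @return `sqrt(h2)`.
#' @export
#' @examples
#' expected_accuracy(0.25)  # 0.5
expected_accuracy <- function(h2) {
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1))
    stop_gs("h2 must lie in [0, 1]")
  sqrt(h2)
}

#' Summarize heritabilities across cross-validation replicates
#'
#' Arithmetic mean and standard error (`sd/sqrt(r)`) of each heritability
#' component over a list of replicate REML fits, formatted "mean (se)" in
#' the style of per-population heritability tables.
#'
#' @param replicate_fits list (length >= 2) of `variance_components`.
#' @return A data frame with columns `component`, `mean`, `se`,
#'   `formatted`.
#' @export
heritability_summary <- function(replicate_fits) {
  if (length(replicate_fits) == 0) stop_gs("empty list of fits")
  if (length(replicate_fits) < 2) stop_gs("need at least 2 replicate fits")
  stopifnot(all(vapply(replicate_fits, inherits, logical(1), "variance_components")))
  comp_names <- c(names(replicate_fits[[1]]$h2), "total")
  vals <- t(vapply(replicate_fits, function(f) c(f$h2, total = f$h2_total),
                   numeric(length(comp_names))))
  data.frame(
    component = comp_names,
    mean = colMeans(vals),
    se = apply(vals, 2, se_mean),
    formatted = sprintf("%.4g (%.2g)", colMeans(vals), apply(vals, 2, se_mean)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# ---- BLUP prediction ---------------------------------------------------

#' Predict breeding values for unphenotyped individuals
#'
#' Solves the conditional-expectation form of the mixed-model equations on
#' the full relationship matrices: with training residual covariance
#' `V = sum_k sigma2_k G_k[train, train] + sigma2_e I`, fixed effects are
#' the generalized least-squares estimates and each random term is
#' `u_k = sigma2_k G_k[, train] V^{-1} (y - X b)` for every individual,
#' phenotyped or not. This is algebraically identical to solving the mixed
#' model with validation phenotypes treated as missing.
#'
#' @param vc a `variance_components` fit (from [reml_fit()] on the training
#'   samples).
#' @param y phenotype vector over all samples; `NA` for individuals to
#'   predict. Only `train_ids` entries are used.
#' @param kernels the full relationship matrices (same order/labels as in
#'   the fit).
#' @param X fixed-effect design over all samples (default intercept).
#' @param train_ids indices or sample ids of the training individuals
#'   (default: the non-`NA` entries of `y`).
#' @param predict_ids indices or ids that must be predicted (default: all
#'   samples); an error is raised if any are unknown.
#' @return An object of class `blup_solution` with `fixed_estimates`,
#'   `breeding_values` (one column per random term, all samples), `ebv`
#'   (their row sum), and training `residuals`.
#' @export
blup_predict <- function(vc, y, kernels, X = NULL, train_ids = NULL,
                         predict_ids = NULL) {
  stopifnot(inherits(vc, "variance_components"))
  kl <- .as_kernel_list(kernels)
  if (!identical(kl$labels, vc$labels))
    stop_gs("kernel labels (", paste(kl$labels, collapse = ","),
            ") do not match the fit (", paste(vc$labels, collapse = ","), ")")
  n_all <- length(y)
  ids <- rownames(kl$K[[1]]) %||% names(y)
  resolve <- function(sel, what) {
    if (is.null(sel)) return(NULL)
    if (is.character(sel)) {
      if (is.null(ids)) stop_gs("character ids given but samples are unnamed")
      pos <- match(sel, ids)
      if (anyNA(pos)) stop_gs("unknown ", what, ": ",
                              paste(sel[is.na(pos)], collapse = ", "))
      pos
    } else {
      sel <- as.integer(sel)
      if (any(sel < 1 | sel > n_all)) stop_gs("out-of-range ", what)
      sel
    }
  }
  train <- resolve(train_ids, "train_ids") %||% which(!is.na(y))
  pred <- resolve(predict_ids, "predict_ids") %||% seq_len(n_all)
  if (length(train) < 2) stop_gs("need at least 2 training samples")
  yt <- as.numeric(y[train])
  if (anyNA(yt)) stop_gs("training samples have missing phenotypes")
  if (is.null(X)) X <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  Xt <- X[train, , drop = FALSE]
  s2 <- vc$sigma2_raw
  nk <- length(kl$K)
  Vtt <- s2[nk + 1] * diag(length(train))
  for (i in seq_len(nk)) Vtt <- Vtt + s2[i] * kl$K[[i]][train, train]
  R <- chol(Vtt)
  solveV <- function(b) backsolve(R, backsolve(R, b, transpose = TRUE))
  ViX <- solveV(Xt)
  bhat <- solve(crossprod(Xt, ViX), crossprod(ViX, yt))
  r <- solveV(yt - as.numeric(Xt %*% bhat))
  bv <- matrix(0, n_all, nk, dimnames = list(ids, vc$labels))
  for (i in seq_len(nk))
    bv[, i] <- s2[i] * as.numeric(kl$K[[i]][, train, drop = FALSE] %*% r)
  ebv <- rowSums(bv)
  resid_train <- yt - as.numeric(Xt %*% bhat) - ebv[train]
  structure(list(
    fixed_estimates = setNames(as.numeric(bhat), colnames(X)),
    breeding_values = bv,
    ebv = setNames(ebv, ids),
    residuals = setNames(resid_train, if (!is.null(ids)) ids[train] else NULL),
    train_ids = train,
    predict_ids = pred
  ), class = "blup_solution")
}

#' @export
print.blup_solution <- function(x, ...) {
  cat(sprintf("blup_solution: %d samples (%d training), terms: %s\n",
              length(x$ebv), length(x$train_ids),
              paste(colnames(x$breeding_values), collapse = ", ")))
  invisible(x)
}
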