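#' Construct a genotype dosage matrix
#'
#' The central genotype container: an `n x m` matrix of allele-A dosage
#' codes in `{0, 1, 2, NA}` with unique sample and marker identifiers and
#' per-marker frequencies of allele A computed from the non-missing calls.
#'
#' @param dosages numeric matrix, samples in rows, markers in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param sample_ids,marker_ids character identifiers; default to the
#'   dimnames of `dosages`.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `allele_freqs`, `n_imputed`.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3,
#'                             dimnames = list(paste0("s", 1:3), c("m1", "m2"))))
#' allele_frequencies(g)
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            marker_ids = colnames(dosages)) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("marker_", seq_len(m))
  sample_ids <- as.character(sample_ids); marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n) stop_gs("sample_ids length must equal nrow(dosages)")
  if (length(marker_ids) != m) stop_gs("marker_ids length must equal ncol(dosages)")
  if (anyDuplicated(sample_ids)) stop_gs("duplicated sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids)) stop_gs("duplicated marker ids: ",
    paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  ok <- is.na(dosages) | dosages == 0 | dosages == 1 | dosages == 2
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop_gs(sprintf("invalid dosage %s at sample '%s', marker '%s' (must be 0/1/2/NA)",
                    format(dosages[bad[1], bad[2]]), sample_ids[bad[1]], marker_ids[bad[2]]))
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  structure(list(
    dosages = dosages,
    allele_freqs = .raw_freqs(dosages),
    n_imputed = 0L
  ), class = "genotype_matrix")
}

# frequency of allele A per column from non-missing calls; NaN if all missing
.raw_freqs <- function(d) {
  nn <- colSums(!is.na(d))
  colSums(d, na.rm = TRUE) / (2 * nn)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x)
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d missing calls, %d imputed)\n",
              d[1], d[2], nmiss, x$n_imputed))
  invisible(x)
}

#' Sample and marker identifiers
#' @param g a `genotype_matrix`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(g) rownames(g$dosages)

#' @rdname sample_ids
#' @export
marker_ids <- function(g) colnames(g$dosages)

#' Allele-A frequencies from non-missing calls
#'
#' `p_j` is the observed frequency of allele A at marker `j`:
#' sum of non-missing dosages divided by twice the number of non-missing
#' calls.
#'
#' @param g a `genotype_matrix`.
#' @return Numeric vector of length `m`, named by marker id.
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- g$allele_freqs
  if (anyNA(p) || any(is.nan(p))) {
    bad <- marker_ids(g)[is.nan(p) | is.na(p)]
    stop_gs("markers with no non-missing calls: ", paste(bad, collapse = ", "))
  }
  setNames(p, marker_ids(g))
}

# internal subsetting that keeps frequencies consistent
subset_markers <- function(g, idx) {
  d <- g$dosages[, idx, drop = FALSE]
  out <- g
  out$dosages <- d
  out$allele_freqs <- g$allele_freqs[idx]
  out
}

subset_samples <- function(g, idx) {
  d <- g$dosages[idx, , drop = FALSE]
  out <- g
  out$dosages <- d
  out$allele_freqs <- .raw_freqs(d)  # frequencies refer to the retained cohort
  out
}

#' Filter markers by minor allele frequency
#'
#' Retains markers whose minor allele frequency `min(p, 1 - p)` is greater
#' than or equal to `threshold` (inclusive keep; removal uses the strict
#' inequality `MAF < threshold`). Marker order is preserved.
#'
#' @param g a `genotype_matrix`.
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return A filtered `genotype_matrix`.
#' @export
filter_by_maf <- function(g, threshold) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 0.5)
    stop_gs("threshold must be a single value in [0, 0.5]")
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  gs_msg(sprintf("MAF filter (threshold %g): removed %d of %d markers",
                 threshold, sum(!keep), length(keep)))
  subset_markers(g, which(keep))
}

#' Filter markers by genotype call rate
#'
#' Retains markers whose fraction of non-missing calls is at least
#' `min_rate` (boundary inclusive).
#'
#' @param g a `genotype_matrix`.
#' @param min_rate minimum call rate in `[0, 1]`.
#' @return A filtered `genotype_matrix`.
#' @export
filter_by_call_rate <- function(g, min_rate) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.numeric(min_rate) || length(min_rate) != 1 ||
      min_rate < 0 || min_rate > 1)
    stop_gs("min_rate must be a single value in [0, 1]")
  rate <- colMeans(!is.na(g$dosages))
  keep <- rate >= min_rate
  gs_msg(sprintf("call-rate filter (threshold %g): removed %d of %d markers",
                 min_rate, sum(!keep), length(keep)))
  subset_markers(g, which(keep))
}

#' Hardy-Weinberg equilibrium chi-square test per marker
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' `(n_AA, n_AB, n_BB)` against the Hardy-Weinberg expectations
#' `(n p^2, 2 n p (1 - p), n (1 - p)^2)` using the observed allele
#' frequency. Monomorphic markers are assigned p-value 1 (no test possible,
#' and they are removed by any positive MAF filter anyway).
#'
#' @param g a complete `genotype_matrix` (impute or drop missing calls
#'   first).
#' @return Numeric vector of `m` p-values, named by marker id.
#' @export
hwe_chi2 <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (nrow(d) == 0) stop_gs("no samples")
  if (anyNA(d)) stop_gs("missing calls present; run mean_impute() or drop incomplete markers first")
  n <- nrow(d)
  nAA <- colSums(d == 2); nAB <- colSums(d == 1); nBB <- colSums(d == 0)
  p <- (2 * nAA + nAB) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAB <- 2 * n * p * q; eBB <- n * q^2
  chi2 <- numeric(ncol(d))
  poly <- p > 0 & p < 1
  chi2[poly] <- (nAA[poly] - eAA[poly])^2 / eAA[poly] +
    (nAB[poly] - eAB[poly])^2 / eAB[poly] +
    (nBB[poly] - eBB[poly])^2 / eBB[poly]
  pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  pv[!poly] <- 1
  setNames(pv, marker_ids(g))
}

#' Mean-impute missing genotype calls
#'
#' Replaces each missing call at marker `j` by its expectation `2 p_j`
#' under the observed allele frequency. Frequencies are always computed
#' from observed calls only; the number of imputed cells is recorded.
#'
#' @param g a `genotype_matrix`.
#' @return A complete `genotype_matrix` (no missing entries).
#' @export
mean_impute <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- allele_frequencies(g)  # errors on all-missing markers
  d <- g$dosages
  miss <- is.na(d)
  nmiss <- sum(miss)
  if (nmiss > 0) {
    fill <- matrix(rep(2 * p, each = nrow(d)), nrow = nrow(d))
    d[miss] <- fill[miss]
  }
  out <- g
  out$dosages <- d
  out$n_imputed <- out$n_imputed + as.integer(nmiss)
  out$allele_freqs <- p  # unchanged by mean fill
  gs_msg(sprintf("mean imputation: filled %d missing calls", nmiss))
  out
}

#' Nested random marker subsets for density experiments
#'
#' Draws one random permutation of marker indices from `seed` and takes the
#' first `sizes[k]` entries for each requested size, so every low-density
#' marker set is contained in every higher-density set and the same seed
#' reproduces the same sets.
#'
#' @param g a `genotype_matrix`.
#' @param sizes strictly increasing positive integers, all `<= m`.
#' @param seed integer seed for the permutation.
#' @return Named list of integer index vectors, one per size.
#' @export
nested_subsample <- function(g, sizes, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- ncol(g$dosages)
  sizes <- as.integer(sizes)
  if (length(sizes) < 1 || any(sizes <= 0) || any(sizes > m))
    stop_gs("sizes must be positive integers <= number of markers")
  if (length(sizes) > 1 && any(diff(sizes) <= 0))
    stop_gs("sizes must be strictly increasing")
  perm <- withr::with_seed(seed, sample.int(m))
  out <- lapply(sizes, function(s) sort(perm[seq_len(s)]))
  names(out) <- as.character(sizes)
  out
}
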