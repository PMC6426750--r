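#' Additive incidence matrix (VanRaden centering)
#'
#' The additive marker incidence `W_a` codes each genotype at marker `j` as
#' `2 - 2 p_j` (AA), `1 - 2 p_j` (AB) and `-2 p_j` (BB), i.e. the allele-A
#' dosage minus twice the allele-A frequency, so each column has mean zero
#' at the observed frequency.
#'
#' @param g a complete `genotype_matrix` (no missing calls).
#' @param freqs allele-A frequencies to center on; defaults to the observed
#'   frequencies of `g`. Passing the frequencies of a larger reference
#'   panel keeps a single parameterization across marker-density subsets.
#' @return An `incidence_matrix` object (matrix with `kind` and `freqs`
#'   attributes).
#' @export
additive_incidence <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (anyNA(d)) stop_gs("missing calls present; run mean_impute() first")
  stopifnot(length(freqs) == ncol(d))
  w <- sweep(d, 2, 2 * freqs)
  structure(w, kind = "additive", freqs = as.numeric(freqs),
            class = c("incidence_matrix", "matrix", "array"))
}

#' Dominance incidence matrix (Aliloo coding)
#'
#' Codes each genotype at marker `j` as `-2 (1 - p_j)^2` (AA),
#' `2 p_j (1 - p_j)` (AB) and `-2 p_j^2` (BB). Columns have mean zero when
#' genotype proportions are at Hardy-Weinberg expectations.
#'
#' @inheritParams additive_incidence
#' @return An `incidence_matrix` of kind `"dominance"`.
#' @export
dominance_incidence <- function(g, freqs = allele_frequencies(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  if (anyNA(d)) stop_gs("missing calls present; run mean_impute() first")
  stopifnot(length(freqs) == ncol(d))
  p <- as.numeric(freqs); q <- 1 - p
  w <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (code in c(0, 1, 2)) {
    val <- switch(as.character(code),
                  "2" = -2 * q^2,      # AA
                  "1" = 2 * p * q,     # AB
                  "0" = -2 * p^2)      # BB
    hit <- d == code
    w[hit] <- rep(val, each = nrow(d))[hit]
  }
  structure(w, kind = "dominance", freqs = p,
            class = c("incidence_matrix", "matrix", "array"))
}

.new_grm <- function(values, kind, denom, ridge = 0) {
  structure(list(values = values, kind = kind,
                 scaling_denominator = denom, ridge_added = ridge),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s): %d x %d, denominator %.6g, ridge %.3g\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$scaling_denominator, x$ridge_added))
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)

# accept either a relationship_matrix or a plain matrix
grm_values <- function(G) if (inherits(G, "relationship_matrix")) G$values else G

#' Additive genomic relationship matrix (VanRaden)
#'
#' `G_a = W_a W_a' / (2 * sum_j p_j (1 - p_j))`. Under Hardy-Weinberg
#' genotype proportions the expected diagonal is 1.
#'
#' @param w an additive `incidence_matrix` from [additive_incidence()].
#' @param freqs allele frequencies for the scaling denominator; defaults to
#'   those stored in `w`.
#' @return A `relationship_matrix` of kind `"additive"`.
#' @export
vanraden_grm <- function(w, freqs = attr(w, "freqs")) {
  stopifnot(inherits(w, "incidence_matrix"), attr(w, "kind") == "additive")
  p <- as.numeric(freqs)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_gs("all markers monomorphic: VanRaden denominator is zero")
  .new_grm(tcrossprod(unclass(w)) / denom, "additive", denom)
}

#' Dominance genomic relationship matrix (Aliloo)
#'
#' `G_d = W_d W_d' / (4 * sum_j (p_j (1 - p_j))^2)`.
#'
#' @param w a dominance `incidence_matrix` from [dominance_incidence()].
#' @param freqs allele frequencies for the denominator; defaults to those
#'   stored in `w`.
#' @return A `relationship_matrix` of kind `"dominance"`.
#' @export
dominance_grm <- function(w, freqs = attr(w, "freqs")) {
  stopifnot(inherits(w, "incidence_matrix"), attr(w, "kind") == "dominance")
  p <- as.numeric(freqs)
  denom <- 4 * sum((p * (1 - p))^2)
  if (denom <= 0) stop_gs("all markers monomorphic: dominance denominator is zero")
  .new_grm(tcrossprod(unclass(w)) / denom, "dominance", denom)
}

#' Convenience constructor for a GRM straight from genotypes
#'
#' @param g a complete `genotype_matrix`.
#' @param kind `"additive"` or `"dominance"`.
#' @param freqs centering/scaling frequencies (defaults to observed).
#' @return A `relationship_matrix`.
#' @export
make_grm <- function(g, kind = c("additive", "dominance"),
                     freqs = allele_frequencies(g)) {
  kind <- match.arg(kind)
  if (kind == "additive") vanraden_grm(additive_incidence(g, freqs))
  else dominance_grm(dominance_incidence(g, freqs))
}

#' Ridge-stabilize a relationship matrix
#'
#' Adds `epsilon * trace(G)/n` to the diagonal so the matrix is safely
#' positive definite for mixed-model equations; the amount added is
#' recorded in `ridge_added`. Every eigenvalue shifts by exactly the
#' added amount.
#'
#' @param G a `relationship_matrix` (or plain symmetric matrix).
#' @param epsilon nonnegative ridge factor (default `1e-6`).
#' @return A `relationship_matrix` with the ridge applied.
#' @export
stabilize <- function(G, epsilon = 1e-6) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0)
  v <- grm_values(G)
  n <- nrow(v)
  amount <- epsilon * sum(diag(v)) / n
  v2 <- v
  diag(v2) <- diag(v2) + amount
  if (inherits(G, "relationship_matrix")) {
    G$values <- v2
    G$ridge_added <- G$ridge_added + amount
    G
  } else {
    .new_grm(v2, "additive", NA_real_, ridge = amount)
  }
}

#' Write a relationship matrix as a long-format TSV
#'
#' Sample ids plus the dense lower triangle (including the diagonal), one
#' `id_i / id_j / value` row per cell, values printed with 17 significant
#' digits so the round trip through [read_grm_tsv()] is lossless to better
#' than 12 significant digits.
#'
#' @param G a `relationship_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(G, path) {
  stopifnot(inherits(G, "relationship_matrix"))
  v <- G$values
  ids <- rownames(v) %||% paste0("sample_", seq_len(nrow(v)))
  idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  header <- sprintf("# kind=%s denominator=%.17g ridge=%.17g", G$kind,
                    G$scaling_denominator, G$ridge_added)
  lines <- c(header, paste(ids[idx[, 1]], ids[idx[, 2]],
                           sprintf("%.17g", v[idx]), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a relationship matrix written by [write_grm_tsv()]
#'
#' @param path file path.
#' @return A `relationship_matrix`.
#' @export
read_grm_tsv <- function(path) {
  if (!file.exists(path)) stop_gs("file not found: ", path)
  first <- readLines(path, n = 1)
  meta <- regmatches(first, regexec(
    "^# kind=(\\S+) denominator=(\\S+) ridge=(\\S+)", first))[[1]]
  if (length(meta) != 4) stop_gs("'", path, "' is not a gsfactors GRM TSV")
  tab <- read.table(path, header = FALSE, sep = "\t", skip = 1,
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  ids <- unique(c(tab[[1]], tab[[2]]))
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(tab[[1]], ids); j <- match(tab[[2]], ids)
  v[cbind(i, j)] <- tab[[3]]
  v[cbind(j, i)] <- tab[[3]]
  .new_grm(v, meta[2], as.numeric(meta[3]), as.numeric(meta[4]))
}
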