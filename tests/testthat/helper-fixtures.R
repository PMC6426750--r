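# silence QC/experiment logging during tests
options(gsfactors.quiet = TRUE)

# small deterministic genotype matrix with known dosages
tiny_gmat <- function() {
  d <- matrix(c(0, 1, 2,
                2, 1, 0), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("m1", "m2")))
  genotype_matrix(d)
}

# genotype matrix with columns at given dosage patterns (one list entry per marker)
gmat_from_cols <- function(cols, ids = NULL) {
  d <- do.call(cbind, cols)
  colnames(d) <- ids %||% paste0("m", seq_along(cols))
  rownames(d) <- paste0("s", seq_len(nrow(d)))
  genotype_matrix(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate genotypes under exact HWE at given frequencies (independent markers)
hwe_genotypes <- function(n, p, seed) {
  withr::with_seed(seed, {
    d <- vapply(p, function(pj) rbinom(n, 2, pj), numeric(n))
    rownames(d) <- paste0("s", seq_len(n))
    colnames(d) <- paste0("m", seq_along(p))
    genotype_matrix(d)
  })
}

# draw a phenotype with covariance structure G (pure genetic signal)
mvn_from_grm <- function(G, seed, jitter = 1e-8) {
  withr::with_seed(seed, {
    v <- if (inherits(G, "relationship_matrix")) G$values else G
    n <- nrow(v)
    R <- chol(v + diag(jitter * mean(diag(v)), n))
    as.numeric(crossprod(R, rnorm(n)))
  })
}
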