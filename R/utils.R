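`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic child seed
#'
#' Folds a root seed and any number of integer tags (replicate, fold, stage
#' indices) into a new seed in `[1, 2^31 - 19)`. Used so that every source
#' of randomness in an experiment is a pure function of one root seed.
#'
#' @param root integer root seed.
#' @param ... further integer tags.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(42, 1, 3)
child_seed <- function(root, ...) {
  ks <- c(root, ...)
  stopifnot(length(ks) >= 1, all(is.finite(ks)))
  v <- 0
  # 2147483629 is prime and < 2^31; 69069 is a classic LCG multiplier
  for (k in ks) v <- (v * 69069 + abs(as.numeric(k)) + 1) %% 2147483629
  as.integer(v) + 1L
}

# message() unless the package has been silenced; all QC filters and
# experiment stages report through here.
gs_msg <- function(...) {
  if (!isTRUE(getOption("gsfactors.quiet", FALSE))) message(...)
  invisible(NULL)
}

stop_gs <- function(...) stop(..., call. = FALSE)

# standard error of the mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
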