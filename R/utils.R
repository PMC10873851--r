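# internal helpers shared across the package

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the previous
#' RNG state so callers' streams are not disturbed. `seed = NULL` uses the
#' current stream (no save/restore).
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# population standard deviation (divisor n, not n - 1)
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# center each row of a matrix at zero mean
center_rows <- function(x) {
  x - rowMeans(x)
}

# zero-mean, unit-L2-norm rows; rows with zero variance raise an error unless
# `allow_zero` (then they are left at zero)
normalize_maps <- function(x, allow_zero = FALSE) {
  x <- center_rows(x)
  nrm <- sqrt(rowSums(x^2))
  bad <- nrm < .Machine$double.eps * ncol(x)
  if (any(bad)) {
    if (!allow_zero) stop("zero-variance topography cannot be normalized")
    nrm[bad] <- 1
  }
  x / nrm
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}
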