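#' Template set of microstate topographies
#'
#' A template set is a `K x channels` matrix of zero-mean, unit-L2-norm scalp
#' maps, optionally carrying class labels and the fraction of global explained
#' variance (GEV) achieved in the data they were fitted to.
#'
#' @param maps numeric matrix (K x channels); rows are normalized internally.
#' @param class_labels optional character labels (e.g. `c("A","B","C","D")`).
#' @param gev optional scalar in \[0, 1\].
#' @return Object of class `"template_set"`.
#' @export
template_set <- function(maps, class_labels = NULL, gev = NA_real_) {
  maps <- as.matrix(maps)
  maps <- normalize_maps(maps)
  if (!is.null(class_labels)) {
    if (length(class_labels) != nrow(maps)) {
      stop("'class_labels' length must equal the number of maps")
    }
    rownames(maps) <- class_labels
  }
  if (!is.na(gev) && (gev < -1e-12 || gev > 1 + 1e-12)) {
    stop("'gev' must lie in [0, 1]")
  }
  structure(list(maps = maps, class_labels = class_labels, gev = gev),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K = %d maps, %d channels",
              nrow(x$maps), ncol(x$maps)))
  if (!is.na(x$gev)) cat(sprintf(", GEV = %.3f", x$gev))
  cat("\n")
  invisible(x)
}

# coerce template_set / microstates fit / matrix to a normalized map matrix
as_map_matrix <- function(x) {
  if (inherits(x, "template_set")) return(x$maps)
  if (inherits(x, "microstates")) return(x$maps)
  normalize_maps(as.matrix(x))
}

#' Generate synthetic ground-truth templates
#'
#' Draws `k` spatially smooth, mutually orthogonal (hence pairwise
#' |correlation| <= 0.5) topographies on a montage. Maps are random linear
#' combinations of low-order spherical polynomials of the electrode positions
#' (a smooth dipolar/quadrupolar family), centered and orthonormalized.
#'
#' @param montage a [montage()].
#' @param k number of templates (1 <= k <= channels).
#' @param seed integer seed for reproducibility (or `NULL` to use the current
#'   RNG stream).
#' @return A [template_set()] with maps `k x channels`.
#' @examples
#' ts <- make_templates(make_montage(32), k = 4, seed = 1)
#' round(tcrossprod(ts$maps), 10)  # identity: orthonormal maps
#' @export
make_templates <- function(montage, k, seed = NULL) {
  stopifnot(inherits(montage, "montage"))
  nch <- length(montage$labels)
  if (k < 1 || k > nch) stop("'k' must be between 1 and the channel count")
  p <- montage$positions
  basis <- cbind(p[, 1], p[, 2], p[, 3],
                 p[, 1] * p[, 2], p[, 1] * p[, 3], p[, 2] * p[, 3],
                 p[, 1]^2 - p[, 2]^2, 2 * p[, 3]^2 - p[, 1]^2 - p[, 2]^2)
  with_seed(seed, {
    if (k > ncol(basis)) {
      # beyond the polynomial family: extend with smooth kernelized noise
      d2 <- as.matrix(stats::dist(p))^2
      kern <- exp(-d2 / (2 * 0.5^2))
      extra <- kern %*% matrix(stats::rnorm(nch * (k - ncol(basis))),
                               nch, k - ncol(basis))
      basis <- cbind(basis, extra)
    }
    coef <- matrix(stats::rnorm(ncol(basis) * k), ncol(basis), k)
    m <- basis %*% coef
    m <- scale(m, center = TRUE, scale = FALSE)
    q <- qr.Q(qr(m))[, seq_len(k), drop = FALSE]
    labs <- if (k <= 26) LETTERS[seq_len(k)] else sprintf("M%02d", seq_len(k))
    template_set(t(q), class_labels = labs)
  })
}
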