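#' Electrode montage
#'
#' A montage is a set of uniquely labelled electrodes with positions on the
#' unit sphere. Positions are used for spatially smooth noise generation and
#' for plotting; all clustering and statistics are position-agnostic.
#'
#' @param labels character vector of unique channel names (>= 8 channels).
#' @param positions numeric matrix (channels x 3) of unit-norm coordinates.
#' @return An object of class `"montage"`: a list with `labels` and
#'   `positions`.
#' @seealso [make_montage()] for a synthetic spherical-cap layout.
#' @export
montage <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.matrix(positions)
  if (length(labels) < 8L) stop("a montage needs at least 8 channels")
  if (anyDuplicated(labels)) stop("montage labels must be unique")
  if (nrow(positions) != length(labels) || ncol(positions) != 3L) {
    stop("'positions' must be a (channels x 3) matrix matching 'labels'")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("montage positions must lie on the unit sphere (|pos| = 1 ± 1e-9)")
  }
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, positions = positions), class = "montage")
}

#' Synthetic spherical-cap montage
#'
#' Places `n_channels` electrodes on the upper unit hemisphere using a
#' Fibonacci lattice, a regular stand-in for a real sensor net. Channel
#' counts up to 256 are supported; the analysis algorithms are channel-count
#' agnostic.
#'
#' @param n_channels number of electrodes (8 to 256; default 32).
#' @return A [montage()].
#' @examples
#' m <- make_montage(32)
#' range(sqrt(rowSums(m$positions^2)))
#' @export
make_montage <- function(n_channels = 32) {
  if (n_channels < 8 || n_channels > 256) {
    stop("'n_channels' must be between 8 and 256")
  }
  i <- seq_len(n_channels)
  # z descends from just below the vertex through the upper hemisphere
  z <- 1 - (i - 0.5) / n_channels * 0.95
  golden <- pi * (3 - sqrt(5))
  phi <- golden * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(r * cos(phi), r * sin(phi), z)
  pos <- pos / sqrt(rowSums(pos^2))
  montage(sprintf("E%03d", i), pos)
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels (%s ... %s)\n",
              length(x$labels), x$labels[1], x$labels[length(x$labels)]))
  invisible(x)
}

#' Read / write a montage as TSV
#'
#' The on-disk format is a four-column TSV (`label`, `x`, `y`, `z`) with a
#' header row.
#'
#' @param m a [montage()].
#' @param path file path.
#' @return `read_montage` returns a [montage()]; `write_montage` returns
#'   `path` invisibly.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "montage"))
  df <- data.frame(label = m$labels, x = m$positions[, 1],
                   y = m$positions[, 2], z = m$positions[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("montage file must have columns label, x, y, z")
  }
  montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}
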