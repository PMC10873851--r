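#' Multichannel EEG recording
#'
#' Container for a `channels x samples` potential matrix (µV) with sampling
#' rate, optional montage, a per-sample artifact mask (`TRUE` = artifact,
#' excluded from analysis) and metadata identifying subject, condition and
#' epoch.
#'
#' @param data numeric matrix, channels x samples, all finite.
#' @param fs sampling rate in Hz (> 0).
#' @param montage optional [montage()]; channel count must match.
#' @param mask logical vector, one value per sample; default all `FALSE`.
#' @param subject,condition,epoch metadata scalars.
#' @return Object of class `"eeg_recording"`.
#' @export
recording <- function(data, fs, montage = NULL, mask = NULL,
                      subject = NA, condition = NA, epoch = NA) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording data must be finite")
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("'fs' must be positive")
  if (is.null(mask)) mask <- rep(FALSE, ncol(data))
  mask <- as.logical(mask)
  if (length(mask) != ncol(data)) {
    stop("'mask' length must equal the number of samples")
  }
  if (!is.null(montage)) {
    stopifnot(inherits(montage, "montage"))
    if (length(montage$labels) != nrow(data)) {
      stop(sprintf("montage has %d channels but data has %d rows",
                   length(montage$labels), nrow(data)))
    }
    rownames(data) <- montage$labels
  }
  structure(list(data = data, fs = fs, montage = montage, mask = mask,
                 meta = list(subject = subject, condition = condition,
                             epoch = epoch)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %.1f%% masked\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    100 * mean(x$mask)))
  if (!is.na(x$meta$subject)) {
    cat(sprintf("  subject %s, condition %s, epoch %s\n",
                x$meta$subject, x$meta$condition, x$meta$epoch))
  }
  invisible(x)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so each
#' column of the data has zero mean. Idempotent.
#'
#' @param rec an [recording()].
#' @return The recording, average-referenced.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Global field power
#'
#' The GFP at time t is the population standard deviation of the potentials
#' across electrodes at t — a reference-free index of momentary field
#' strength. The population (divisor n) form is used; the choice affects only
#' a global scale, never peak locations.
#'
#' @param rec an [recording()] (average-referenced or not; the channel mean is
#'   removed pointwise either way).
#' @return Numeric vector of per-sample GFP values (µV), all >= 0.
#' @examples
#' r <- recording(matrix(c(1, -1), 2, 1), fs = 200)
#' compute_gfp(r)  # 1
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2)
}

#' Detect GFP peaks
#'
#' Strict interior local maxima of the GFP series. A flat (tied) maximum
#' contributes its first sample only; series endpoints are never peaks; peaks
#' falling on masked samples are removed.
#'
#' @param gfp numeric vector of GFP values.
#' @param mask optional logical vector (`TRUE` = artifact) of the same length.
#' @return Integer vector of strictly increasing peak indices.
#' @examples
#' detect_gfp_peaks(c(1, 3, 1))  # 2
#' @export
detect_gfp_peaks <- function(gfp, mask = NULL) {
  n <- length(gfp)
  if (n < 3) return(integer(0))
  r <- rle(gfp)
  m <- length(r$values)
  if (m < 3) {
    peaks <- integer(0)
  } else {
    starts <- cumsum(c(1L, r$lengths[-m]))
    j <- 2:(m - 1)
    is_peak <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    peaks <- starts[j][is_peak]
  }
  if (!is.null(mask)) {
    if (length(mask) != n) stop("'mask' length must match the GFP series")
    peaks <- peaks[!mask[peaks]]
  }
  as.integer(peaks)
}

#' Extract topographies at GFP peaks
#'
#' @param rec an [recording()].
#' @param peaks integer sample indices (e.g. from [detect_gfp_peaks()]).
#' @return Matrix of peak maps, `length(peaks) x channels`.
#' @export
peak_maps <- function(rec, peaks) {
  stopifnot(inherits(rec, "eeg_recording"))
  t(rec$data[, peaks, drop = FALSE])
}
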