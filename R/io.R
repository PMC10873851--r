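# Plain-text cohort interchange format: one TSV matrix (channels x samples,
# channel labels in the first column) per recording plus a JSON sidecar
# (<path>.json) carrying fs, metadata and the artifact mask as run lengths.

mask_to_rle <- function(mask) {
  r <- rle(as.logical(mask))
  list(values = r$values, lengths = r$lengths)
}

rle_to_mask <- function(x, n) {
  m <- inverse.rle(structure(list(lengths = as.integer(x$lengths),
                                  values = as.logical(x$values)),
                             class = "rle"))
  if (length(m) != n) stop("sidecar mask length does not match the data")
  m
}

#' Write / read a recording in the text cohort format
#'
#' The data file is a TSV with one row per channel (`label` column first); the
#' sidecar `<path>.json` stores sampling rate, subject/condition/epoch
#' metadata, the montage file name if given, and the run-length-encoded
#' artifact mask.
#'
#' @param rec an [recording()].
#' @param path data file path (e.g. `"sub01_neutral_ep1.tsv"`).
#' @param montage_path optional montage TSV recorded in the sidecar.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an [recording()].
#' @export
write_recording <- function(rec, path, montage_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- rownames(rec$data)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(nrow(rec$data)))
  df <- data.frame(label = labels, rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  side <- list(fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data),
               subject = rec$meta$subject, condition = rec$meta$condition,
               epoch = rec$meta$epoch,
               montage_file = montage_path,
               mask = mask_to_rle(rec$mask))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param montage optional [montage()] (or montage TSV path) used to validate
#'   and order channels by label.
#' @export
read_recording <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  labels <- df[[1]]
  data <- as.matrix(df[, -1, drop = FALSE])
  rownames(data) <- labels
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list(fs = NA_real_)
  if (is.null(side$fs) || is.na(side$fs)) {
    stop("sidecar ", sidecar, " with a sampling rate is required")
  }
  mask <- if (!is.null(side$mask)) rle_to_mask(side$mask, ncol(data))
          else rep(FALSE, ncol(data))
  mont <- NULL
  if (!is.null(montage)) {
    mont <- if (inherits(montage, "montage")) montage
            else read_montage(montage)
    if (length(mont$labels) != nrow(data)) {
      stop(sprintf("montage has %d channels but file has %d",
                   length(mont$labels), nrow(data)))
    }
    idx <- match(mont$labels, labels)
    if (anyNA(idx)) stop("channel labels do not match the montage")
    data <- data[idx, , drop = FALSE]
  }
  recording(data, fs = side$fs, montage = mont, mask = mask,
            subject = if (is.null(side$subject)) NA else side$subject,
            condition = if (is.null(side$condition)) NA else side$condition,
            epoch = if (is.null(side$epoch)) NA else side$epoch)
}

#' Write / read the cohort ground-truth table
#'
#' TSV keyed by subject, condition and class with the realized generative
#' mean duration and time coverage.
#'
#' @param truth data.frame as in [simulate_cohort()]'s `truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# ---- minimal EDF (European Data Format) support ----------------------------
# 16-bit EDF with one data record holding the whole recording per signal.
# Only the fields needed for round-tripping continuous multichannel data are
# used; annotations, multiple records and discontinuous files are out of
# scope.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  substr(s, 1, width)
}

#' Write a recording as a minimal EDF file
#'
#' Single-data-record, 16-bit EDF. Physical ranges are set per channel from
#' the data. Intended for interchange with standard EEG tooling and for
#' round-trip tests; the artifact mask and montage are not stored (use the
#' sidecar format for full fidelity).
#'
#' @param rec an [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  ns <- nrow(x)
  nt <- ncol(x)
  labels <- rownames(x)
  if (is.null(labels)) labels <- sprintf("E%03d", seq_len(ns))
  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                                  # version
  wr("synthetic", 80)                         # patient id
  wr("microstatr export", 80)                 # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)        # date, time
  wr(as.character(256 + ns * 256), 8)         # header bytes
  wr("", 44)                                  # reserved
  wr("1", 8)                                  # number of data records
  wr(format(nt / rec$fs, nsmall = 0), 8)      # record duration (s)
  wr(as.character(ns), 4)                     # number of signals
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("EEG", 80)        # transducer
  for (i in seq_len(ns)) wr("uV", 8)          # physical dimension
  for (v in pmin_) wr(sprintf("%.6g", v), 8)
  for (v in pmax_) wr(sprintf("%.6g", v), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)           # prefiltering
  for (i in seq_len(ns)) wr(as.character(nt), 8)  # samples per record
  for (i in seq_len(ns)) wr("", 32)           # reserved
  for (i in seq_len(ns)) {
    dig <- round((x[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a minimal EDF file
#'
#' Supports continuous 16-bit EDF with a constant samples-per-record count per
#' signal. Channels can be aligned to a montage by label.
#'
#' @param path EDF file path.
#' @param montage optional [montage()] or montage TSV path; channels are
#'   reordered by label to match it.
#' @return An [recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  rownames(data) <- labels
  fs <- spr[1] / dur
  mont <- NULL
  if (!is.null(montage)) {
    mont <- if (inherits(montage, "montage")) montage
            else read_montage(montage)
    if (length(mont$labels) != ns) {
      stop(sprintf("montage has %d channels but EDF has %d",
                   length(mont$labels), ns))
    }
    idx <- match(mont$labels, labels)
    if (anyNA(idx)) stop("EDF channel labels do not match the montage")
    data <- data[idx, , drop = FALSE]
  }
  recording(data, fs = fs, montage = mont)
}
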