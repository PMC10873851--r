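#' Winner-takes-all backfitting
#'
#' Assigns every unmasked sample of a recording to the template with the
#' highest absolute spatial correlation. Masked samples stay unlabeled (`NA`).
#' Ties — including all-zero samples, whose correlation with every template is
#' treated as 0 — break toward the lowest class index, deterministically.
#'
#' @param rec an [recording()].
#' @param templates a [microstates()] fit, [template_set()], or map matrix
#'   with the recording's channel count.
#' @return Object of class `"ms_segmentation"`: list with `labels` (integer,
#'   `NA` where masked), `fit_corr` (winning |spatial correlation|), `fs`,
#'   `mask`, `k`.
#' @export
backfit <- function(rec, templates) {
  stopifnot(inherits(rec, "eeg_recording"))
  a <- normalize_maps(as_map_matrix_raw(templates))
  if (ncol(a) != nrow(rec$data)) {
    stop(sprintf("templates have %d channels but recording has %d",
                 ncol(a), nrow(rec$data)))
  }
  x <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  norms <- sqrt(colSums(x^2))
  proj <- a %*% x                      # k x T signed projections
  corr <- abs(proj)
  nz <- norms > .Machine$double.eps * nrow(rec$data)
  corr[, nz] <- corr[, nz, drop = FALSE] /
    rep(norms[nz], each = nrow(a))
  corr[, !nz] <- 0
  labels <- max.col(t(corr), ties.method = "first")
  fit_corr <- corr[cbind(labels, seq_along(labels))]
  labels[rec$mask] <- NA_integer_
  fit_corr[rec$mask] <- NA_real_
  structure(list(labels = labels, fit_corr = fit_corr, fs = rec$fs,
                 mask = rec$mask, k = nrow(a)),
            class = "ms_segmentation")
}

#' @rdname backfit
#' @param object a [microstates()] fit.
#' @param newdata an [recording()].
#' @param ... unused.
#' @export
predict.microstates <- function(object, newdata, ...) {
  backfit(newdata, object)
}

#' @export
print.ms_segmentation <- function(x, ...) {
  lab <- x$labels[!is.na(x$labels)]
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, K = %d, %.1f%% labeled\n",
              length(x$labels), x$fs, x$k,
              100 * length(lab) / length(x$labels)))
  invisible(x)
}

# enumerate runs of one segmentation: data.frame(class, length, censored);
# a run is a maximal constant-label stretch of contiguous unmasked samples,
# censored when it abuts a mask boundary or the epoch edge
segmentation_runs <- function(seg) {
  lab <- seg$labels
  n <- length(lab)
  blocks <- rle(!is.na(lab))
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L
  out <- list()
  for (b in which(blocks$values)) {
    r <- rle(lab[starts[b]:ends[b]])
    m <- length(r$lengths)
    cens <- rep(FALSE, m)
    cens[1] <- TRUE
    cens[m] <- TRUE
    out[[length(out) + 1L]] <- data.frame(class = r$values,
                                          length = r$lengths,
                                          censored = cens)
  }
  if (!length(out)) return(data.frame(class = integer(0), length = integer(0),
                                      censored = logical(0)))
  do.call(rbind, out)
}

#' Temporal parameters of a segmentation
#'
#' For each class: mean duration (ms) over *interior* runs — runs truncated by
#' a mask boundary or epoch edge censor the true dwell time and are excluded —
#' and time coverage as the fraction of labeled (unmasked) samples. Coverages
#' therefore sum to one over labeled time. A class observed only in censored
#' runs gets `NA` duration and `censored = TRUE`; the degenerate single-class
#' epoch reports the full labeled length as its duration, flagged censored.
#'
#' @param seg an `"ms_segmentation"` from [backfit()], or a list of them
#'   (epochs are pooled: runs and sample counts are combined).
#' @param k number of classes; taken from the segmentation when missing.
#' @return Object of class `"ms_temporal_params"`: data.frame with columns
#'   `class`, `mean_duration` (ms), `time_coverage`, `n_runs` (interior runs),
#'   `censored`; attribute `labeled_time_s`.
#' @examples
#' seg <- structure(list(labels = c(1, 1, 1, 2, 2, 1, 1), fs = 200,
#'                       mask = rep(FALSE, 7), k = 2,
#'                       fit_corr = rep(1, 7)), class = "ms_segmentation")
#' temporal_params(seg)  # class 2: 10 ms, coverage 2/7
#' @export
temporal_params <- function(seg, k = NULL) {
  segs <- if (inherits(seg, "ms_segmentation")) list(seg) else seg
  stopifnot(all(vapply(segs, inherits, logical(1), "ms_segmentation")))
  if (is.null(k)) k <- max(vapply(segs, function(s) as.integer(s$k),
                                  integer(1)))
  fs <- segs[[1]]$fs
  runs <- do.call(rbind, lapply(segs, segmentation_runs))
  all_labels <- unlist(lapply(segs, `[[`, "labels"))
  labeled <- sum(!is.na(all_labels))
  if (labeled == 0) stop("no labeled samples")
  cov_counts <- tabulate(all_labels[!is.na(all_labels)], nbins = k)
  interior <- runs[!runs$censored, , drop = FALSE]
  md <- nr <- rep(NA_real_, k)
  cens <- rep(FALSE, k)
  for (j in seq_len(k)) {
    lens <- interior$length[interior$class == j]
    nr[j] <- length(lens)
    if (length(lens)) {
      md[j] <- mean(lens) * 1000 / fs
    } else if (cov_counts[j] > 0) {
      cens[j] <- TRUE
      if (cov_counts[j] == labeled) {
        # degenerate: one class covers all labeled time
        md[j] <- labeled * 1000 / fs
      }
    }
  }
  out <- data.frame(class = seq_len(k), mean_duration = md,
                    time_coverage = cov_counts / labeled,
                    n_runs = as.integer(nr), censored = cens)
  attr(out, "labeled_time_s") <- labeled / fs
  class(out) <- c("ms_temporal_params", "data.frame")
  out
}

# split one segmentation into first/second halves (by sample index)
split_segmentation <- function(seg) {
  n <- length(seg$labels)
  h <- n %/% 2L
  mk <- function(idx) {
    structure(list(labels = seg$labels[idx], fit_corr = seg$fit_corr[idx],
                   fs = seg$fs, mask = seg$mask[idx], k = seg$k),
              class = "ms_segmentation")
  }
  list(first = mk(seq_len(h)), second = mk(seq(h + 1L, n)))
}

#' Split-half reliability of temporal parameters
#'
#' Computes mean duration and time coverage separately on the first and second
#' half of every epoch, pooled per subject, and reports the across-subject
#' Pearson correlation per class and parameter — an internal-consistency check
#' of the microstate parameters.
#'
#' @param segs_by_subject list (one element per subject) of lists of
#'   `"ms_segmentation"` epochs.
#' @param k number of classes.
#' @return List with `first`, `second` (data.frames: subject, class,
#'   mean_duration, time_coverage) and `reliability` (data.frame: class,
#'   parameter, r).
#' @export
split_half_params <- function(segs_by_subject, k = NULL) {
  halves <- lapply(segs_by_subject, function(epochs) {
    sp <- lapply(epochs, split_segmentation)
    list(first = lapply(sp, `[[`, "first"),
         second = lapply(sp, `[[`, "second"))
  })
  per_side <- function(side) {
    do.call(rbind, lapply(seq_along(halves), function(s) {
      tp <- temporal_params(halves[[s]][[side]], k = k)
      data.frame(subject = s, class = tp$class,
                 mean_duration = tp$mean_duration,
                 time_coverage = tp$time_coverage)
    }))
  }
  first <- per_side("first")
  second <- per_side("second")
  kk <- max(first$class)
  rel <- do.call(rbind, lapply(seq_len(kk), function(j) {
    f <- first[first$class == j, ]
    s <- second[second$class == j, ]
    data.frame(class = j,
               parameter = c("mean_duration", "time_coverage"),
               r = c(stats::cor(f$mean_duration, s$mean_duration,
                                use = "complete.obs"),
                     stats::cor(f$time_coverage, s$time_coverage,
                                use = "complete.obs")))
  }))
  list(first = first, second = second, reliability = rel)
}
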