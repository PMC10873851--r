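#' Spatial correlation between two topographies
#'
#' Pearson correlation across channels of two zero-meaned maps. Microstate
#' comparisons that must ignore polarity use its absolute value.
#'
#' @param u,v numeric vectors of equal length (one value per channel); each
#'   must have nonzero variance.
#' @return Scalar in \[-1, 1\].
#' @examples
#' spatial_correlation(c(1, 0, -1), c(-1, 0, 1))  # -1
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("topographies must have equal channel count")
  u <- u - mean(u); v <- v - mean(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-variance topography: correlation undefined")
  sum(u * v) / (nu * nv)
}

# dominant right singular vector of a (maps x channels) block; returns a
# unit-norm vector (zero-mean because the rows are zero-mean)
dominant_map <- function(x) {
  if (nrow(x) == 1L) {
    v <- x[1, ]
    return(v / sqrt(sum(v^2)))
  }
  svd(x, nu = 0, nv = 1)$v[, 1]
}

# single k-means run from given initial templates; x: zero-mean-row maps
# (n x C), a0: k x C. Returns list(maps, labels, gev, iters, converged).
kmeans_once <- function(x, a0, tot_ss, max_iter, tol) {
  k <- nrow(a0)
  a <- a0
  gev_old <- -Inf
  labels <- NULL
  for (it in seq_len(max_iter)) {
    proj <- x %*% t(a)                       # n x k signed projections
    labels <- max.col(abs(proj), ties.method = "first")
    # re-seed empty clusters from the worst-fitting map
    fit2 <- proj[cbind(seq_len(nrow(x)), labels)]^2
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        worst <- which.min(fit2 / rowSums(x^2))
        labels[worst] <- j
        fit2[worst] <- sum(x[worst, ]^2)
      }
    }
    for (j in seq_len(k)) {
      a[j, ] <- dominant_map(x[labels == j, , drop = FALSE])
    }
    proj <- x %*% t(a)
    labels <- max.col(abs(proj), ties.method = "first")
    gev_new <- sum(proj[cbind(seq_len(nrow(x)), labels)]^2) / tot_ss
    if (gev_new - gev_old < tol) {
      return(list(maps = a, labels = labels, gev = gev_new, iters = it,
                  converged = TRUE))
    }
    gev_old <- gev_new
  }
  list(maps = a, labels = labels, gev = gev_old, iters = max_iter,
       converged = FALSE)
}

#' Fit microstate templates by polarity-invariant modified k-means
#'
#' Clusters topographies (typically sampled at GFP peaks) into `k` classes,
#' ignoring map polarity: maps are assigned to the template maximizing the
#' absolute spatial correlation, and each template is updated as the dominant
#' eigenvector of the outer-product sum of its assigned maps (the
#' polarity-invariant centroid), renormalized to zero mean and unit norm.
#' Iteration is coordinate ascent on the global explained variance (GEV) and
#' stops when the GEV improvement falls below `tol`.
#'
#' Each restart fits a random subsample of the maps (default 90%) and is then
#' consensus-refit on the full set; the restart with the highest full-set GEV
#' wins. Ties in assignment are broken toward the lowest class index.
#' For tiny two-class problems (`k = 2`, at most 10 maps) the fit switches to
#' an exact mode that ascends from every 2-partition, which provably attains
#' the global GEV optimum.
#'
#' @param x maps matrix (`n x channels`, rows are topographies), a
#'   [template_set()], or an [recording()] (GFP-peak maps are extracted).
#' @param k number of classes (`k <= n`).
#' @param n_restarts random restarts (default 50).
#' @param tol convergence tolerance on GEV (default 1e-6).
#' @param max_iter iteration cap per restart.
#' @param subsample fraction of maps used per restart before the consensus
#'   refit (1 disables subsampling).
#' @param init optional initial template matrix (`k x channels`) tried as an
#'   extra restart (used by [choose_k()] warm starts).
#' @param seed integer seed, or `NULL`.
#' @return Object of class `"microstates"`: list with `maps` (`k x channels`
#'   zero-mean unit-norm templates), `labels` (per-map class), `fit_corr`
#'   (per-map winning |spatial correlation|), `gev`, `k`, `n_maps`,
#'   `restarts`, `seed`, `call`.
#' @examples
#' ts <- make_templates(make_montage(16), 2, seed = 1)
#' x <- ts$maps[c(1, 1, 2, 2, 1), ] * c(1, -1, 1, -1, 1)  # sign flips
#' fit <- microstates(x, k = 2, n_restarts = 5, seed = 2)
#' fit$gev  # 1: noiseless two-template data is perfectly explained
#' @export
microstates <- function(x, k, n_restarts = 50, tol = 1e-6, max_iter = 300,
                        subsample = 0.9, init = NULL, seed = NULL) {
  if (inherits(x, "eeg_recording")) {
    gfp <- compute_gfp(x)
    pk <- detect_gfp_peaks(gfp, x$mask)
    x <- peak_maps(x, pk)
  }
  x <- as_map_matrix_raw(x)
  n <- nrow(x)
  if (k > n) stop(sprintf("k = %d exceeds the number of maps (%d)", k, n))
  xc <- center_rows(x)
  tot_ss <- sum(xc^2)
  if (tot_ss == 0) stop("all maps have zero variance")
  best <- NULL
  # exact small-instance mode: for k = 2 and few maps, ascend from every
  # 2-partition's eigenvector templates. Monotone GEV ascent from the optimal
  # partition cannot leave it, so the global optimum is attained by
  # construction (the analogue of exact enumeration in the permutation test).
  exact_small <- k == 2L && n <= 10L
  with_seed(seed, {
    n_sub <- max(k, floor(subsample * n))
    inits <- list()
    if (exact_small) {
      for (code in 0:(2^(n - 1) - 1)) {
        lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
        if (length(unique(lab)) < 2L) next
        a0 <- rbind(dominant_map(xc[lab == 1L, , drop = FALSE]),
                    dominant_map(xc[lab == 2L, , drop = FALSE]))
        inits[[length(inits) + 1L]] <- a0
      }
    } else {
      for (r in seq_len(n_restarts)) {
        sub <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
        a0 <- normalize_maps(xc[sample(sub, k), , drop = FALSE])
        if (n_sub < n) {
          pre <- kmeans_once(xc[sub, , drop = FALSE], a0,
                             sum(xc[sub, ]^2), max_iter, tol)
          a0 <- pre$maps
        }
        inits[[r]] <- a0
      }
    }
    if (!is.null(init)) inits[[length(inits) + 1L]] <- normalize_maps(init)
    for (a0 in inits) {
      run <- kmeans_once(xc, a0, tot_ss, max_iter, tol)
      if (is.null(best) || run$gev > best$gev) best <- run
    }
  })
  proj <- xc %*% t(best$maps)
  norms <- sqrt(rowSums(xc^2))
  fit_corr <- abs(proj[cbind(seq_len(n), best$labels)]) / norms
  structure(list(maps = best$maps, labels = best$labels,
                 fit_corr = fit_corr, gev = best$gev, k = k, n_maps = n,
                 converged = best$converged, restarts = n_restarts,
                 seed = seed, call = match.call()),
            class = "microstates")
}

# raw (uncentered-ok) map matrix extraction without normalizing
as_map_matrix_raw <- function(x) {
  if (inherits(x, "template_set")) return(x$maps)
  if (inherits(x, "microstates")) return(x$maps)
  as.matrix(x)
}

#' Global explained variance of a template fit
#'
#' `GEV = sum_t (GFP_t * corr_t)^2 / sum_t GFP_t^2`, where `corr_t` is the
#' spatial correlation between map `t` and its assigned template. With maps
#' zero-meaned per row this equals the fraction of total squared map norm
#' captured by projection onto the winning templates.
#'
#' @param x maps matrix (`n x channels`).
#' @param templates a [template_set()], [microstates()] fit, or map matrix.
#' @param assignment optional per-map class indices; when `NULL` each map is
#'   assigned by maximal absolute spatial correlation.
#' @return Scalar in \[0, 1\].
#' @export
gev <- function(x, templates, assignment = NULL) {
  x <- center_rows(as.matrix(x))
  a <- normalize_maps(as_map_matrix_raw(templates))
  proj <- x %*% t(a)
  if (is.null(assignment)) {
    assignment <- max.col(abs(proj), ties.method = "first")
  }
  sum(proj[cbind(seq_len(nrow(x)), assignment)]^2) / sum(x^2)
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("<microstates> K = %d templates fit to %d maps (%d channels)\n",
              x$k, x$n_maps, ncol(x$maps)))
  cat(sprintf("  GEV = %.4f | mean |corr| = %.3f | %s\n", x$gev,
              mean(x$fit_corr),
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  counts <- tabulate(object$labels, nbins = object$k)
  out <- data.frame(class = seq_len(object$k), n_maps = counts,
                    share = counts / object$n_maps,
                    mean_fit_corr = vapply(seq_len(object$k), function(j) {
                      if (counts[j] == 0) NA_real_
                      else mean(object$fit_corr[object$labels == j])
                    }, numeric(1)))
  structure(list(table = out, gev = object$gev, k = object$k),
            class = "summary.microstates")
}

#' @export
print.summary.microstates <- function(x, ...) {
  cat(sprintf("Microstate fit: K = %d, GEV = %.4f\n", x$k, x$gev))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$maps

#' @export
residuals.microstates <- function(object, x, ...) {
  xc <- center_rows(as.matrix(x))
  proj <- xc %*% t(object$maps)
  lab <- max.col(abs(proj), ties.method = "first")
  xc - proj[cbind(seq_len(nrow(xc)), lab)] * object$maps[lab, , drop = FALSE]
}

#' Plot fitted microstate templates
#'
#' Draws each template as a colored electrode map (azimuthal projection of
#' the montage positions). Without a montage, channel profiles are drawn as
#' lines.
#'
#' @param x a [microstates()] fit or [template_set()].
#' @param montage optional [montage()] supplying electrode positions.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.microstates <- function(x, montage = NULL, ...) {
  maps <- as_map_matrix_raw(x)
  k <- nrow(maps)
  if (is.null(montage)) {
    graphics::matplot(t(maps), type = "l", lty = 1, xlab = "channel",
                      ylab = "normalized potential", ...)
    graphics::legend("topright", legend = paste("class", seq_len(k)),
                     col = seq_len(k), lty = 1, cex = 0.8)
    return(invisible(x))
  }
  p <- montage$positions
  xy <- p[, 1:2] / (1 + p[, 3])  # stereographic-like projection
  old <- graphics::par(mfrow = c(1, k), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  for (j in seq_len(k)) {
    v <- maps[j, ]
    col <- pal[cut(v, breaks = seq(-max(abs(v)), max(abs(v)), length.out = 65),
                   include.lowest = TRUE)]
    graphics::plot(xy, pch = 21, bg = col, cex = 2, axes = FALSE,
                   xlab = "", ylab = "", asp = 1,
                   main = paste("class", j), ...)
  }
  invisible(x)
}

#' @export
plot.template_set <- function(x, montage = NULL, ...) {
  plot.microstates(x, montage = montage, ...)
}

#' Simulate EEG from a fitted microstate model
#'
#' Uses the fitted templates as ground truth for the semi-Markov generator,
#' producing surrogate recordings with the fitted topographies.
#'
#' @param object a [microstates()] fit.
#' @param nsim number of epochs to simulate.
#' @param seed integer seed.
#' @param montage a [montage()] matching the fit's channel count.
#' @param duration_s epoch length in seconds.
#' @param fs sampling rate, Hz.
#' @param mean_durations,coverages,carrier_freq,snr generator parameters, see
#'   [ground_truth()].
#' @param ... unused.
#' @return List of [recording()] objects of length `nsim`.
#' @export
simulate.microstates <- function(object, nsim = 1, seed = NULL, montage,
                                 duration_s = 10, fs = 200,
                                 mean_durations = rep(75, object$k),
                                 coverages = rep(1 / object$k, object$k),
                                 carrier_freq = 10.7, snr = 2, ...) {
  ts <- template_set(object$maps)
  gt <- ground_truth(montage, k = object$k, templates = ts,
                     mean_durations = mean_durations, coverages = coverages,
                     carrier_freq = carrier_freq, snr = snr)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      lab <- sample_state_sequence(gt, round(duration_s * fs), fs)
      render_eeg(lab, gt, fs)
    })
  })
}
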