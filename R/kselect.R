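#' Select the number of microstate classes
#'
#' Fits [microstates()] for every k in `k_range` and selects the k minimizing
#' the cross-validation criterion
#' `CV(k) = sigma2_hat * ((C - 1) / (C - 1 - k))^2`, where `sigma2_hat` is the
#' residual topographic variance per degree of freedom and C the channel
#' count — a predictive-residual trade-off between cluster count and variance
#' explained. The GEV curve is reported alongside so users can override the
#' choice (`force_k`).
#'
#' Each k's fit is warm-started from the previous k's templates plus the then
#' worst-fitting map (as one extra restart), which keeps the GEV curve
#' nondecreasing in k up to restart noise.
#'
#' @param x maps matrix (`n x channels`) or [recording()].
#' @param k_range candidate cluster counts (default 1:12; values above
#'   `channels - 2` are dropped because the CV penalty degenerates there).
#' @param n_restarts restarts per k (default 10; the scan refits many k's, the
#'   final model can be refit with more).
#' @param force_k optional user override of the selected k.
#' @param seed integer seed.
#' @param ... passed to [microstates()].
#' @return Object of class `"ms_kselect"`: list with `k_range`, `gev_per_k`,
#'   `criterion_per_k`, `chosen_k`, `fits` (one [microstates()] per k),
#'   `n_restarts`, `seed`.
#' @export
choose_k <- function(x, k_range = 1:12, n_restarts = 10, force_k = NULL,
                     seed = NULL, ...) {
  if (inherits(x, "eeg_recording")) {
    gfp <- compute_gfp(x)
    x <- peak_maps(x, detect_gfp_peaks(gfp, x$mask))
  }
  x <- as.matrix(x)
  nch <- ncol(x)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1 & k_range <= min(n, nch - 2)]
  if (!length(k_range)) stop("no feasible k in 'k_range'")
  xc <- center_rows(x)
  tot_ss <- sum(xc^2)
  fits <- vector("list", length(k_range))
  gev_k <- cv_k <- numeric(length(k_range))
  prev <- NULL
  with_seed(seed, {
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      init <- NULL
      if (!is.null(prev) && nrow(prev$maps) == k - 1L) {
        proj <- xc %*% t(prev$maps)
        fit2 <- proj[cbind(seq_len(n), max.col(abs(proj), "first"))]^2
        worst <- which.min(fit2 / rowSums(xc^2))
        init <- rbind(prev$maps, xc[worst, ] / sqrt(sum(xc[worst, ]^2)))
      }
      fits[[i]] <- microstates(xc, k, n_restarts = n_restarts, init = init,
                               ...)
      prev <- fits[[i]]
      gev_k[i] <- fits[[i]]$gev
      sigma2 <- max(0, tot_ss * (1 - gev_k[i])) / (n * (nch - 1))
      cv_k[i] <- sigma2 * ((nch - 1) / (nch - 1 - k))^2
    }
  })
  chosen <- if (!is.null(force_k)) as.integer(force_k)
            else k_range[which.min(cv_k)]
  structure(list(k_range = k_range, gev_per_k = gev_k,
                 criterion_per_k = cv_k, chosen_k = chosen, fits = fits,
                 n_restarts = n_restarts, seed = seed,
                 forced = !is.null(force_k)),
            class = "ms_kselect")
}

#' @export
print.ms_kselect <- function(x, ...) {
  cat(sprintf("<ms_kselect> chosen k = %d%s\n", x$chosen_k,
              if (x$forced) " (user override)" else " (CV criterion)"))
  df <- data.frame(k = x$k_range, gev = round(x$gev_per_k, 4),
                   cv = signif(x$criterion_per_k, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Two-level (subject to group) clustering
#'
#' Stage 1 clusters each subject's (or subject-by-condition's) GFP-peak maps
#' into `k` templates; stage 2 pools the resulting subject templates — each
#' zero-mean and unit-norm, hence equally weighted — and clusters them with
#' the same polarity-invariant algorithm into `k` group templates.
#'
#' @param peak_maps_list list (one element per subject) of maps matrices or
#'   [recording()]s; length >= 2.
#' @param k number of classes.
#' @param n_restarts restarts for both stages.
#' @param seed integer seed.
#' @param ... passed to [microstates()].
#' @return List with `group` (a [microstates()] fit on the pooled subject
#'   templates) and `subject` (list of per-subject fits).
#' @export
two_level_clustering <- function(peak_maps_list, k, n_restarts = 50,
                                 seed = NULL, ...) {
  if (length(peak_maps_list) < 2) stop("need at least 2 subjects")
  with_seed(seed, {
    subject_fits <- lapply(peak_maps_list, function(x) {
      microstates(x, k, n_restarts = n_restarts, ...)
    })
    pooled <- do.call(rbind, lapply(subject_fits, coef))
    group <- microstates(pooled, k, n_restarts = n_restarts, ...)
    list(group = group, subject = subject_fits)
  })
}

# Hungarian algorithm (shortest augmenting path, O(n^3)) for the square
# linear assignment problem; returns for each row the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j]] <- j
  match
}

#' Pair microstate classes across two conditions
#'
#' Finds the one-to-one assignment between the classes of two template sets
#' maximizing the total absolute spatial correlation (optimal assignment via
#' the Hungarian algorithm, not greedy matching), and returns the full
#' K x K correlation matrix.
#'
#' @param set_a,set_b [template_set()], [microstates()] fit, or map matrix;
#'   equal K and channel count.
#' @return List with `pairing` (integer vector: class j of `set_a` pairs with
#'   class `pairing[j]` of `set_b`), `corr_matrix` (signed K x K spatial
#'   correlations, rows = `set_a` classes), and `total_abs_corr`.
#' @examples
#' ts <- make_templates(make_montage(16), 3, seed = 1)
#' pair_conditions(ts, ts$maps[c(2, 3, 1), ])$pairing  # 2 3 1
#' @export
pair_conditions <- function(set_a, set_b) {
  a <- normalize_maps(as_map_matrix_raw(set_a))
  b <- normalize_maps(as_map_matrix_raw(set_b))
  if (nrow(a) != nrow(b)) stop("template sets must have equal K")
  if (ncol(a) != ncol(b)) stop("template sets must have equal channel count")
  corr <- tcrossprod(a, b)  # Pearson: rows zero-mean unit-norm
  pairing <- hungarian(-abs(corr))
  list(pairing = pairing, corr_matrix = corr,
       total_abs_corr = sum(abs(corr[cbind(seq_len(nrow(a)), pairing)])))
}
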