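#' Ground truth for the synthetic EEG generator
#'
#' Bundles everything the generator needs: the montage, K template
#' topographies, per-class mean dwell times and target time coverages, the
#' oscillatory carrier frequency and the signal-to-noise amplitude ratio.
#'
#' Defaults emulate resting-state alpha-band microstate dynamics: four
#' classes, 75 ms mean dwell, equal coverages, a 10.7 Hz carrier (upper alpha,
#' deliberately incommensurate with a 200 Hz sampling grid so the carrier
#' rarely hits exact zeros) and snr = 2.
#'
#' @param montage a [montage()].
#' @param k number of microstate classes (>= 2 for dynamics; 1 allowed).
#' @param templates optional [template_set()]; generated via
#'   [make_templates()] when `NULL`.
#' @param mean_durations per-class expected dwell time, ms (> 0).
#' @param coverages per-class target time-coverage fractions (sum to 1).
#' @param carrier_freq carrier frequency, Hz.
#' @param snr signal-to-noise amplitude ratio (`Inf` = noiseless, `0` = noise
#'   only).
#' @param seed seed used when generating templates.
#' @return Object of class `"ms_ground_truth"`.
#' @export
ground_truth <- function(montage, k = 4, templates = NULL,
                         mean_durations = rep(75, k),
                         coverages = rep(1 / k, k),
                         carrier_freq = 10.7, snr = 2, seed = NULL) {
  stopifnot(inherits(montage, "montage"))
  if (is.null(templates)) templates <- make_templates(montage, k, seed = seed)
  stopifnot(inherits(templates, "template_set"))
  k <- nrow(templates$maps)
  if (length(mean_durations) != k || length(coverages) != k) {
    stop("'mean_durations' and 'coverages' must have one entry per class")
  }
  if (any(mean_durations <= 0)) stop("'mean_durations' must be positive")
  if (abs(sum(coverages) - 1) > 1e-9 || any(coverages <= 0)) {
    stop("'coverages' must be positive and sum to 1")
  }
  stopifnot_scalar(carrier_freq, "carrier_freq")
  if (!(is.numeric(snr) && length(snr) == 1L && snr >= 0)) {
    stop("'snr' must be a single nonnegative number (Inf allowed)")
  }
  structure(list(montage = montage, templates = templates,
                 mean_durations = mean_durations, coverages = coverages,
                 carrier_freq = carrier_freq, snr = snr, k = k),
            class = "ms_ground_truth")
}

# Solve entry weights so the semi-Markov chain's long-run occupancy matches
# the target coverages, accounting for the no-self-transition constraint.
# Returns a k-vector of weights; transition prob i -> j is w_j / sum_{m!=i} w_m.
state_entry_weights <- function(coverages, dwell_samples) {
  k <- length(coverages)
  if (k == 1L) return(1)
  w <- coverages / dwell_samples
  w <- w / sum(w)
  for (iter in 1:100) {
    q <- matrix(w, k, k, byrow = TRUE)
    diag(q) <- 0
    q <- q / rowSums(q)
    e <- eigen(t(q))
    i1 <- which.min(abs(e$values - 1))
    pi_emb <- abs(Re(e$vectors[, i1]))
    pi_emb <- pi_emb / sum(pi_emb)
    occ <- pi_emb * dwell_samples
    occ <- occ / sum(occ)
    if (max(abs(occ - coverages)) < 1e-12) break
    w <- w * coverages / occ
    w <- w / sum(w)
  }
  w
}

#' Sample a semi-Markov microstate label sequence
#'
#' Dwell times are discrete gamma-shaped (shape 2) with the per-class mean and
#' a minimum of one sample; successive states always differ; transition
#' weights are solved so the long-run per-class coverage converges to the
#' targets in the ground truth.
#'
#' @param gt an [ground_truth()].
#' @param n_samples sequence length (> 0).
#' @param fs sampling rate in Hz (converts dwell means from ms to samples).
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return Integer vector of class indices in `1..k`, length `n_samples`.
#' @export
sample_state_sequence <- function(gt, n_samples, fs, seed = NULL) {
  stopifnot(inherits(gt, "ms_ground_truth"))
  if (n_samples <= 0) stop("'n_samples' must be positive")
  k <- gt$k
  if (k == 1L) return(rep(1L, n_samples))
  d <- gt$mean_durations * fs / 1000
  with_seed(seed, {
    w <- state_entry_weights(gt$coverages, d)
    labels <- integer(n_samples)
    state <- sample.int(k, 1, prob = gt$coverages)
    pos <- 1L
    while (pos <= n_samples) {
      dwell <- max(1L, as.integer(round(stats::rgamma(1, shape = 2,
                                                      scale = d[state] / 2))))
      end <- min(n_samples, pos + dwell - 1L)
      labels[pos:end] <- state
      pos <- end + 1L
      wnext <- w
      wnext[state] <- 0
      state <- sample.int(k, 1, prob = wnext)
    }
    labels
  })
}

#' Render a label sequence as multichannel EEG
#'
#' The signal at time t is `A * sin(2*pi*f*t) * template[label(t)]`: the
#' topography is constant up to sign within a state while its polarity
#' alternates with the carrier half-cycles, so GFP maxima sit at carrier
#' amplitude maxima. Noise is zero-mean, spatially smooth (Gaussian kernel on
#' the electrode cap) and shares the carrier envelope, emulating
#' amplitude-modulated broadband background; its amplitude is set from the
#' ground truth's snr. The output is average-referenced.
#'
#' @param labels integer class sequence (from [sample_state_sequence()]).
#' @param gt an [ground_truth()].
#' @param fs sampling rate in Hz.
#' @param seed integer seed for the noise, or `NULL`.
#' @param amplitude carrier amplitude in µV.
#' @param noise_length spatial correlation length of the noise kernel
#'   (chord distance on the unit sphere).
#' @return An [recording()].
#' @export
render_eeg <- function(labels, gt, fs, seed = NULL, amplitude = 15,
                       noise_length = 0.4) {
  stopifnot(inherits(gt, "ms_ground_truth"))
  nt <- length(labels)
  if (nt == 0) stop("'labels' must be non-empty")
  maps <- gt$templates$maps  # k x channels, zero-mean unit-norm rows
  nch <- ncol(maps)
  tt <- (seq_len(nt) - 1) / fs
  carrier <- sin(2 * pi * gt$carrier_freq * tt)
  signal <- t(maps[labels, , drop = FALSE]) *
    rep(amplitude * carrier, each = nch)
  dimnames(signal) <- NULL
  with_seed(seed, {
    if (is.infinite(gt$snr)) {
      x <- signal
    } else {
      d2 <- as.matrix(stats::dist(gt$montage$positions))^2
      kern <- exp(-d2 / (2 * noise_length^2)) + diag(1e-8, nch)
      cl <- chol(kern)
      raw <- crossprod(cl, matrix(stats::rnorm(nch * nt), nch, nt))
      raw <- sweep(raw, 2, colMeans(raw))  # spatially zero-mean
      noise <- raw * rep(abs(carrier), each = nch)
      if (gt$snr == 0) {
        x <- noise
      } else {
        sig_rms <- sqrt(mean(signal^2))
        noise_rms <- sqrt(mean(noise^2))
        x <- signal + noise * (sig_rms / (gt$snr * noise_rms))
      }
    }
    average_reference(recording(x, fs, montage = gt$montage))
  })
}

#' Cohort design specification
#'
#' Describes the simulated study: subjects, balanced epochs per emotional
#' condition, epoch length, sampling rate, a per-subject trait score in
#' \[8, 40\], multiplicative condition effects on the parameters of two
#' targeted classes, and per-trait-unit slopes. Defaults mirror a 36-subject
#' design with 6 epochs of 45 s resting state per condition at 200 Hz.
#'
#' @param n_subjects number of subjects.
#' @param n_epochs_per_condition epochs per condition per subject.
#' @param epoch_s epoch length in seconds (`epoch_s * fs` must be integral).
#' @param fs sampling rate, Hz.
#' @param trait_scores optional per-subject trait values in \[8, 40\]; drawn
#'   uniform-integer in \[8, 40\] when `NULL`.
#' @param effect_c,effect_d relative shifts applied to the targeted classes'
#'   dwell and coverage parameters in the `"fear"` condition only (e.g.
#'   `-0.15` = 15% decrease).
#' @param trait_slope_c,trait_slope_d relative shift per unit of (trait -
#'   cohort mean trait), applied in both conditions.
#' @param subject_sd between-subject variability: per subject and class, a
#'   lognormal factor `exp(N(0, subject_sd))` multiplies the baseline dwell
#'   and coverage parameters in both conditions (coverages renormalized).
#'   Stable individual differences of this size are what make split-half
#'   reliability and trait correlations measurable at realistic cohort sizes.
#' @param class_c,class_d indices of the targeted classes.
#' @param conditions condition names; the second is the affected ("fear")
#'   condition.
#' @param seed integer seed governing every random draw in the cohort.
#' @return Object of class `"ms_cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 36, n_epochs_per_condition = 6,
                        epoch_s = 45, fs = 200, trait_scores = NULL,
                        effect_c = -0.15, effect_d = 0.15,
                        trait_slope_c = 0.01, trait_slope_d = -0.01,
                        subject_sd = 0.15, class_c = 3, class_d = 4,
                        conditions = c("neutral", "fear"), seed = 1) {
  if (abs(epoch_s * fs - round(epoch_s * fs)) > 1e-9) {
    stop("'epoch_s' * 'fs' must be an integer number of samples")
  }
  if (!is.null(trait_scores)) {
    if (length(trait_scores) != n_subjects ||
        any(trait_scores < 8 | trait_scores > 40)) {
      stop("'trait_scores' must give one value in [8, 40] per subject")
    }
  }
  if (length(conditions) != 2L) stop("exactly two conditions are supported")
  structure(list(n_subjects = n_subjects,
                 n_epochs_per_condition = n_epochs_per_condition,
                 epoch_s = epoch_s, fs = fs, trait_scores = trait_scores,
                 effect_c = effect_c, effect_d = effect_d,
                 trait_slope_c = trait_slope_c, trait_slope_d = trait_slope_d,
                 subject_sd = subject_sd,
                 class_c = class_c, class_d = class_d,
                 conditions = conditions, seed = seed),
            class = "ms_cohort_spec")
}

# apply condition/trait perturbations to one subject-condition parameter set;
# non-targeted classes' coverages are rescaled proportionally to preserve sum 1
perturb_params <- function(gt, spec, trait_centered, fear) {
  cov <- gt$coverages
  dur <- gt$mean_durations
  fc <- (1 + spec$effect_c * fear) * (1 + spec$trait_slope_c * trait_centered)
  fd <- (1 + spec$effect_d * fear) * (1 + spec$trait_slope_d * trait_centered)
  ic <- spec$class_c; id <- spec$class_d
  cov[ic] <- cov[ic] * fc
  cov[id] <- cov[id] * fd
  dur[ic] <- dur[ic] * fc
  dur[id] <- dur[id] * fd
  if (any(cov <= 0) || cov[ic] + cov[id] >= 1) {
    stop("effect/trait perturbation drove coverages out of range")
  }
  others <- setdiff(seq_along(cov), c(ic, id))
  cov[others] <- cov[others] * (1 - cov[ic] - cov[id]) /
    sum(gt$coverages[others])
  list(coverages = cov, mean_durations = dur)
}

#' Simulate a cohort of recordings with known ground truth
#'
#' For each subject and condition the per-class dwell and coverage parameters
#' are perturbed by the condition effects (affected condition only) and by the
#' trait slopes times the subject's centered trait score, then epochs are
#' generated with [sample_state_sequence()] and [render_eeg()]. The realized
#' per-subject parameters are returned alongside the signals.
#'
#' @param spec an [cohort_spec()].
#' @param gt an [ground_truth()].
#' @return Object of class `"ms_cohort"`: list with `recordings` (list of
#'   [recording()]), `truth` (data.frame: subject, condition, class,
#'   mean_duration, time_coverage), `trait` (data.frame: subject, trait),
#'   `spec`, `gt`.
#' @export
simulate_cohort <- function(spec, gt) {
  stopifnot(inherits(spec, "ms_cohort_spec"), inherits(gt, "ms_ground_truth"))
  with_seed(spec$seed, {
    trait <- spec$trait_scores
    if (is.null(trait)) trait <- sample(8:40, spec$n_subjects, replace = TRUE)
    tbar <- mean(trait)
    n_per_epoch <- as.integer(round(spec$epoch_s * spec$fs))
    recs <- list()
    truth <- list()
    for (s in seq_len(spec$n_subjects)) {
      # stable individual baseline: one lognormal factor per class, shared by
      # both conditions, applied to dwell and coverage alike
      jit <- exp(stats::rnorm(gt$k, 0, spec$subject_sd))
      gt_base <- gt
      gt_base$coverages <- gt$coverages * jit / sum(gt$coverages * jit)
      gt_base$mean_durations <- gt$mean_durations * jit
      for (ci in seq_along(spec$conditions)) {
        cond <- spec$conditions[ci]
        pp <- perturb_params(gt_base, spec, trait[s] - tbar, fear = (ci == 2L))
        gt_s <- gt
        gt_s$coverages <- pp$coverages
        gt_s$mean_durations <- pp$mean_durations
        truth[[length(truth) + 1L]] <- data.frame(
          subject = s, condition = cond, class = seq_len(gt$k),
          mean_duration = pp$mean_durations, time_coverage = pp$coverages)
        for (ep in seq_len(spec$n_epochs_per_condition)) {
          lab <- sample_state_sequence(gt_s, n_per_epoch, spec$fs)
          rec <- render_eeg(lab, gt_s, spec$fs)
          rec$meta <- list(subject = s, condition = cond, epoch = ep)
          attr(rec, "true_labels") <- lab
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
    structure(list(recordings = recs, truth = do.call(rbind, truth),
                   trait = data.frame(subject = seq_len(spec$n_subjects),
                                      trait = trait),
                   spec = spec, gt = gt),
              class = "ms_cohort")
  })
}

#' @export
print.ms_cohort <- function(x, ...) {
  cat(sprintf(
    "<ms_cohort> %d subjects x %s conditions x %d epochs (%g s @ %g Hz), K = %d\n",
    x$spec$n_subjects, paste(x$spec$conditions, collapse = "/"),
    x$spec$n_epochs_per_condition, x$spec$epoch_s, x$spec$fs, x$gt$k))
  invisible(x)
}
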