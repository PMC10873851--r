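test_that("winner-takes-all labeling is exact on pure-template data", {
  ts <- make_templates(tiny_montage, 3, seed = 1)
  sig <- t(ts$maps[2, , drop = FALSE]) %*% t(c(3, -2, 1, -4, 2))
  rec <- recording(sig, 200)
  seg <- backfit(rec, ts)
  expect_true(all(seg$labels == 2L))
  expect_equal(seg$fit_corr, rep(1, 5), tolerance = 1e-9)
  # masked middle third stays unlabeled
  rec$mask <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  seg2 <- backfit(rec, ts)
  expect_identical(is.na(seg2$labels), rec$mask)
  expect_error(backfit(recording(matrix(rnorm(8 * 4), 8), 200), ts),
               "channels")
})

test_that("labels survive the noiseless construction and data symmetries", {
  gtn <- std_gt
  gtn$snr <- Inf
  lab <- sample_state_sequence(gtn, 2000, 200, seed = 2)
  rec <- render_eeg(lab, gtn, 200)
  seg <- backfit(rec, gtn$templates)
  carrier <- sin(2 * pi * gtn$carrier_freq * (0:1999) / 200)
  nz <- abs(carrier) > 1e-12
  expect_identical(seg$labels[nz], lab[nz])
  # global sign flip and positive rescaling leave labels unchanged
  rec_f <- rec; rec_f$data <- -rec$data
  rec_s <- rec; rec_s$data <- 0.31 * rec$data
  expect_identical(backfit(rec_f, gtn$templates)$labels, seg$labels)
  expect_identical(backfit(rec_s, gtn$templates)$labels, seg$labels)
  # noiseless single-template data: backfit GEV is 1
  rec1 <- render_eeg(rep(3L, 400), gtn, 200)
  keep <- compute_gfp(rec1) > 1e-9
  expect_equal(gev(t(rec1$data[, keep]), gtn$templates), 1, tolerance = 1e-9)
})

test_that("temporal parameters follow the censoring rule on the worked case", {
  seg <- manual_segmentation(c(1, 1, 1, 2, 2, 1, 1), fs = 200, k = 2)
  tp <- temporal_params(seg)
  expect_equal(tp$mean_duration[2], 10)          # one interior 2-run of 10 ms
  expect_true(is.na(tp$mean_duration[1]))        # class-1 runs touch edges
  expect_true(tp$censored[1])
  expect_equal(tp$time_coverage, c(5 / 7, 2 / 7))
  # degenerate single-class epoch reports the labeled length, flagged
  tp1 <- temporal_params(manual_segmentation(rep(1L, 400), fs = 200, k = 1))
  expect_equal(tp1$time_coverage, 1)
  expect_equal(tp1$mean_duration, 2000)
  expect_true(tp1$censored)
  expect_error(temporal_params(manual_segmentation(c(1, 1), k = 1,
                                                   mask = c(TRUE, TRUE))),
               "no labeled")
})

test_that("temporal parameters agree with a direct-scan run-length oracle", {
  set.seed(3)
  for (i in 1:8) {
    n <- sample(50:1000, 1)
    k <- sample(2:4, 1)
    labels <- cumsum(c(1, rexp(n - 1) < 0.15)) %% k + 1L
    mask <- runif(n) < 0.08
    seg <- manual_segmentation(as.integer(labels), fs = 250, mask = mask,
                               k = k)
    tp <- temporal_params(seg)
    oracle <- runlength_oracle(as.integer(labels), mask, 250, k)
    expect_equal(tp$mean_duration, oracle$mean_duration, tolerance = 1e-12)
    expect_equal(tp$time_coverage, oracle$time_coverage, tolerance = 1e-12)
    expect_equal(sum(tp$time_coverage), 1, tolerance = 1e-9)
  }
})

test_that("epoch pooling combines runs and labeled time", {
  s1 <- manual_segmentation(c(1, 2, 2, 1), fs = 100, k = 2)
  s2 <- manual_segmentation(c(2, 1, 1, 1, 2), fs = 100, k = 2)
  tp <- temporal_params(list(s1, s2))
  # interior runs: class 2 len 2 (s1), class 1 len 3 (s2)
  expect_equal(tp$mean_duration, c(30, 20))
  expect_equal(tp$time_coverage, c(5 / 9, 4 / 9))
})

test_that("split-half reliability is 1 on mirrored halves and ~0 under the null", {
  # identical halves by construction
  segs <- lapply(1:8, function(s) {
    half <- as.integer(cumsum(c(1, runif(199) < 0.1)) %% 3 + 1)
    list(manual_segmentation(c(half, half), fs = 200, k = 3))
  })
  sh <- split_half_params(segs, k = 3)
  expect_true(all(abs(sh$reliability$r - 1) < 1e-9))
  # independent random halves: correlations stay small
  set.seed(4)
  segs0 <- lapply(1:36, function(s) {
    lapply(1:2, function(e) {
      manual_segmentation(as.integer(cumsum(c(1, runif(1999) < 0.07)) %% 4 + 1),
                          fs = 200, k = 4)
    })
  })
  sh0 <- split_half_params(segs0, k = 4)
  expect_true(all(abs(sh0$reliability$r) < 0.5))
})

test_that("calibrated cohorts reproduce strong split-half internal consistency", {
  gt <- ground_truth(std_montage, 4, seed = 100)
  spec <- cohort_spec(n_subjects = 20, n_epochs_per_condition = 3,
                      epoch_s = 45, seed = 7)
  coh <- simulate_cohort(spec, gt)
  segs <- lapply(1:20, function(s) {
    rs <- Filter(function(r) r$meta$subject == s &&
                   r$meta$condition == "neutral", coh$recordings)
    lapply(rs, function(r) backfit(r, gt$templates))
  })
  sh <- split_half_params(segs, k = 4)
  expect_true(all(sh$reliability$r > 0.70))
})
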