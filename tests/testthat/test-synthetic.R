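test_that("generated templates are zero-mean, unit-norm and well separated", {
  for (k in c(1, 2, 4, 8)) {
    ts <- make_templates(std_montage, k, seed = k)
    expect_equal(rowMeans(ts$maps), rep(0, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(rowSums(ts$maps^2), rep(1, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
    if (k > 1) {
      cc <- abs(tcrossprod(ts$maps))
      expect_true(max(cc[upper.tri(cc)]) <= 0.5)
    }
  }
  expect_error(make_templates(tiny_montage, 17), "between 1 and")
  expect_identical(make_templates(std_montage, 4, seed = 9)$maps,
                   make_templates(std_montage, 4, seed = 9)$maps)
})

test_that("state sequences honour dwell means, coverages and the no-repeat rule", {
  gt1 <- ground_truth(std_montage, k = 4, seed = 1,
                      mean_durations = rep(75, 4), coverages = rep(0.25, 4))
  lab <- sample_state_sequence(gt1, 200000, 200, seed = 2)
  cover <- tabulate(lab, 4) / length(lab)
  expect_true(all(abs(cover - 0.25) <= 0.02))
  r <- rle(lab)
  interior <- r$lengths[-c(1, length(r$lengths))]
  expect_true(abs(mean(interior) * 5 - 75) / 75 <= 0.10)
  expect_true(all(diff(r$values) != 0))  # consecutive states differ
  expect_identical(lab[1:5000],
                   sample_state_sequence(gt1, 5000, 200, seed = 2)[1:5000])
  # K = 1 degenerates to a constant sequence
  g1 <- ground_truth(std_montage, k = 1, mean_durations = 75, coverages = 1,
                     seed = 3)
  expect_true(all(sample_state_sequence(g1, 100, 200, seed = 1) == 1L))
})

test_that("unequal target coverages are matched in the long run", {
  gtu <- ground_truth(std_montage, k = 4, seed = 4,
                      mean_durations = c(60, 70, 90, 80),
                      coverages = c(0.15, 0.2, 0.35, 0.3))
  lab <- sample_state_sequence(gtu, 200000, 200, seed = 5)
  expect_true(all(abs(tabulate(lab, 4) / length(lab) -
                        gtu$coverages) <= 0.02))
})

test_that("rendered EEG has carrier-locked GFP peaks matching the templates", {
  # noiseless single class: every GFP-peak map is the template up to sign
  g <- ground_truth(std_montage, k = 4, seed = 1, carrier_freq = 10, snr = Inf)
  rec <- render_eeg(rep(2L, 200), g, 200)
  pk <- detect_gfp_peaks(compute_gfp(rec))
  expect_equal(length(pk), 20, tolerance = 1)  # 10 Hz rectified, 1 s
  cors <- apply(peak_maps(rec, pk), 1, spatial_correlation,
                v = g$templates$maps[2, ])
  expect_equal(abs(cors), rep(1, length(pk)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # snr = 0: peak maps decorrelated from every template
  g0 <- ground_truth(std_montage, k = 4, seed = 1, snr = 0)
  rec0 <- render_eeg(rep(2L, 2000), g0, 200, seed = 6)
  pk0 <- detect_gfp_peaks(compute_gfp(rec0))
  cors0 <- apply(peak_maps(rec0, pk0), 1, spatial_correlation,
                 v = g0$templates$maps[2, ])
  expect_lt(mean(abs(cors0)), 0.5)
  expect_identical(render_eeg(rep(1L, 500), g0, 200, seed = 7)$data,
                   render_eeg(rep(1L, 500), g0, 200, seed = 7)$data)
})

test_that("higher snr monotonically improves peak-map fidelity", {
  lab <- sample_state_sequence(std_gt, 4000, 200, seed = 8)
  fid <- vapply(c(0.5, 1.5, 4), function(s) {
    g <- std_gt; g$snr <- s
    rec <- render_eeg(lab, g, 200, seed = 9)
    pk <- detect_gfp_peaks(compute_gfp(rec))
    pm <- normalize_maps_test(peak_maps(rec, pk))
    mean(abs((pm %*% t(std_gt$templates$maps))[cbind(seq_along(pk),
                                                     lab[pk])]))
  }, numeric(1))
  expect_true(all(diff(fid) > 0))
})

test_that("cohort ground truth carries the designed effects", {
  spec0 <- cohort_spec(n_subjects = 4, n_epochs_per_condition = 1,
                       epoch_s = 2, effect_c = 0, effect_d = 0,
                       trait_slope_c = 0, trait_slope_d = 0,
                       subject_sd = 0.15, seed = 11)
  coh0 <- simulate_cohort(spec0, std_gt)
  tn <- coh0$truth[coh0$truth$condition == "neutral", ]
  tf <- coh0$truth[coh0$truth$condition == "fear", ]
  expect_equal(tn$time_coverage, tf$time_coverage, tolerance = 1e-12)
  expect_equal(tn$mean_duration, tf$mean_duration, tolerance = 1e-12)
  spec1 <- cohort_spec(n_subjects = 5, n_epochs_per_condition = 1,
                       epoch_s = 2, seed = 12)
  coh1 <- simulate_cohort(spec1, std_gt)
  for (s in 1:5) {
    tn <- coh1$truth[coh1$truth$subject == s &
                       coh1$truth$condition == "neutral", ]
    tf <- coh1$truth[coh1$truth$subject == s &
                       coh1$truth$condition == "fear", ]
    expect_gt(tf$time_coverage[4], tn$time_coverage[4])  # class D up
    expect_lt(tf$time_coverage[3], tn$time_coverage[3])  # class C down
  }
  # coverages sum to one before and after perturbation
  sums <- tapply(coh1$truth$time_coverage,
                 list(coh1$truth$subject, coh1$truth$condition), sum)
  expect_equal(as.numeric(sums), rep(1, 10), tolerance = 1e-9)
  # determinism
  coh1b <- simulate_cohort(spec1, std_gt)
  expect_identical(coh1$recordings[[1]]$data, coh1b$recordings[[1]]$data)
  expect_identical(coh1$truth, coh1b$truth)
  expect_true(all(coh1$trait$trait >= 8 & coh1$trait$trait <= 40))
})

test_that("montage invariants hold and bad montages are rejected", {
  expect_equal(sqrt(rowSums(std_montage$positions^2)),
               rep(1, 32), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(montage(c("a", "a", letters[1:6]), matrix(0, 8, 3)), "unique")
  expect_error(make_montage(4), "between 8 and 256")
})
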