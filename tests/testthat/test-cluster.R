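test_that("spatial correlation has the Pearson closed forms", {
  u <- rnorm(16)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), -1)
  ts <- make_templates(tiny_montage, 2, seed = 1)
  expect_equal(spatial_correlation(ts$maps[1, ], ts$maps[2, ]), 0,
               tolerance = 1e-12)
  expect_error(spatial_correlation(rep(1, 8), rnorm(8)), "zero-variance")
  expect_error(spatial_correlation(rnorm(8), rnorm(9)), "equal channel")
})

test_that("modified k-means recovers noiseless templates exactly", {
  ts <- make_templates(tiny_montage, 2, seed = 2)
  set.seed(3)
  x <- ts$maps[sample(1:2, 40, replace = TRUE), ] *
    sample(c(-1, 1), 40, replace = TRUE) * runif(40, 0.5, 2)
  fit <- microstates(x, 2, n_restarts = 10, seed = 4)
  expect_equal(fit$gev, 1, tolerance = 1e-6)
  cm <- abs(tcrossprod(coef(fit), ts$maps))
  expect_equal(sort(apply(cm, 1, max)), c(1, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  # k = 1 on sign-mixed copies of one map
  one <- ts$maps[1, ]
  x1 <- rbind(one, -one, one, -one, one)
  f1 <- microstates(x1, 1, n_restarts = 3, seed = 5)
  expect_equal(f1$gev, 1, tolerance = 1e-9)
  expect_equal(abs(spatial_correlation(coef(f1)[1, ], one)), 1,
               tolerance = 1e-9)
  expect_error(microstates(x1, 6), "exceeds")
})

test_that("restarted k-means attains the exhaustive 2-partition optimum", {
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 10), n)
    fit <- microstates(x, 2, n_restarts = 30, seed = i)
    expect_equal(fit$gev, kmeans2_oracle(x), tolerance = 1e-9)
  }
})

test_that("GEV has its closed-form values and matches direct evaluation", {
  ts <- make_templates(tiny_montage, 3, seed = 7)
  x <- ts$maps[c(1, 2, 3, 1), ] * c(2, -1, 3, 0.5)
  expect_equal(gev(x, ts), 1, tolerance = 1e-12)
  # single template orthogonal to every map -> 0
  expect_equal(gev(ts$maps[1:2, ], ts$maps[3, , drop = FALSE]), 0,
               tolerance = 1e-12)
  # three maps, one template: direct formula sum((gfp * corr)^2) / sum(gfp^2)
  set.seed(8)
  maps <- matrix(rnorm(3 * 16), 3)
  tpl <- normalize_maps_test(matrix(rnorm(16), 1))
  mc <- maps - rowMeans(maps)
  gfp_t <- apply(mc, 1, function(v) sqrt(mean(v^2)))
  corr_t <- apply(mc, 1, spatial_correlation, v = tpl[1, ])
  direct <- sum((gfp_t * corr_t)^2) / sum(gfp_t^2)
  expect_equal(gev(maps, tpl, assignment = rep(1, 3)), direct,
               tolerance = 1e-12)
})

test_that("clustering is polarity- and scale-invariant", {
  lab <- sample_state_sequence(std_gt, 2000, 200, seed = 9)
  rec <- render_eeg(lab, std_gt, 200, seed = 10)
  pk <- detect_gfp_peaks(compute_gfp(rec))
  x <- peak_maps(rec, pk)
  set.seed(11)
  flips <- sample(c(-1, 1), nrow(x), replace = TRUE)
  f0 <- microstates(x, 4, n_restarts = 10, seed = 12)
  f1 <- microstates(x * flips, 4, n_restarts = 10, seed = 12)
  f2 <- microstates(x * 3.7, 4, n_restarts = 10, seed = 12)
  expect_identical(f1$labels, f0$labels)
  expect_identical(f2$labels, f0$labels)
  expect_equal(f1$gev, f0$gev, tolerance = 1e-12)
  expect_equal(f2$gev, f0$gev, tolerance = 1e-12)
  expect_equal(abs(rowSums(coef(f1) * coef(f0))), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)  # templates up to sign
})

test_that("the CV criterion selects the generative cluster count", {
  lab <- sample_state_sequence(std_gt, 4000, 200, seed = 13)
  rec <- render_eeg(lab, std_gt, 200, seed = 14)
  sel <- choose_k(rec, k_range = 1:8, seed = 15)
  expect_equal(sel$chosen_k, 4L)
  expect_true(all(diff(sel$gev_per_k) >= -1e-6))  # nondecreasing GEV
  # single-template data degenerates to k = 1
  g1 <- ground_truth(std_montage, k = 1, mean_durations = 75, coverages = 1,
                     seed = 16, snr = Inf)
  rec1 <- render_eeg(rep(1L, 3000), g1, 200, seed = 17)
  sel1 <- choose_k(rec1, k_range = 1:5, seed = 18)
  expect_equal(sel1$chosen_k, 1L)
  # user override wins
  expect_equal(choose_k(rec, k_range = 1:6, force_k = 3, seed = 19)$chosen_k,
               3L)
})

test_that("two-level clustering recovers group maps and ignores subject polarity", {
  ts <- make_templates(tiny_montage, 3, seed = 20)
  set.seed(21)
  subj <- lapply(1:4, function(s) {
    ts$maps[sample(1:3, 30, replace = TRUE), ] *
      sample(c(-1, 1), 30, replace = TRUE)
  })
  tl <- two_level_clustering(subj, 3, n_restarts = 10, seed = 22)
  cm <- abs(tcrossprod(coef(tl$group), ts$maps))
  expect_equal(apply(cm, 1, max), rep(1, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  # flipping whole subjects changes nothing (up to template sign)
  subj_flipped <- lapply(subj, function(m) -m)
  tl2 <- two_level_clustering(subj_flipped, 3, n_restarts = 10, seed = 22)
  expect_equal(abs(tcrossprod(coef(tl2$group), coef(tl$group))),
               diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(two_level_clustering(subj[1], 3), "at least 2")
})

test_that("condition pairing recovers permutations and beats greedy traps", {
  ts <- make_templates(tiny_montage, 4, seed = 23)
  pr <- pair_conditions(ts, ts)
  expect_identical(pr$pairing, 1:4)
  expect_equal(diag(pr$corr_matrix), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  perm <- c(3, 1, 4, 2)
  pr2 <- pair_conditions(ts, ts$maps[perm, ])
  expect_equal(order(pr2$pairing), perm)  # inverse permutation recovered
  pr3 <- pair_conditions(ts, -ts$maps)
  expect_identical(pr3$pairing, 1:4)
  # Hungarian equals the exhaustive optimum on random cost matrices
  set.seed(24)
  for (i in 1:5) {
    n <- sample(3:5, 1)
    cost <- matrix(runif(n * n), n)
    h <- microstatr:::hungarian(cost)
    expect_equal(sum(cost[cbind(seq_len(n), h)]), assignment_oracle(cost),
                 tolerance = 1e-12)
  }
})
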