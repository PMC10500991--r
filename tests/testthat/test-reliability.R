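test_that("task-time budget reproduces the published worked examples", {
  worst <- task_time_budget(40, accuracy = 0.71, rejection_fraction = 0.44)
  expect_equal(worst$post_accuracy_trials, 52)
  expect_equal(worst$presented_trials, 75)
  expect_equal(worst$coherent_seconds, 225)
  expect_equal(worst$random_seconds, 210)
  expect_equal(worst$total_seconds, 435)

  avg <- task_time_budget(40, accuracy = 0.96, rejection_fraction = 0.15)
  expect_equal(avg$post_accuracy_trials, 42)
  expect_equal(avg$presented_trials, 48)
  expect_equal(avg$coherent_seconds, 144)
  # the published 277.6 s total contains a 1.8 x 16 = 28 transcription slip;
  # the correct arithmetic gives 16 x (1.8 + 2.8 + 3.8) = 134.4 -> 278.4 s
  expect_equal(avg$random_seconds, 134.4)
  expect_equal(avg$total_seconds, 278.4)

  # no inflation, presented not divisible by 3: remainder goes to the
  # shortest ITIs first
  none <- task_time_budget(39, accuracy = 1, rejection_fraction = 0)
  expect_equal(none$presented_trials, 39)
  expect_equal(none$total_seconds, 39 * 3 + 13 * 8.4)
  odd <- task_time_budget(40, accuracy = 1, rejection_fraction = 0)
  expect_equal(unname(odd$iti_allocation), c(14, 13, 13))
  expect_equal(odd$random_seconds, 14 * 1.8 + 13 * 2.8 + 13 * 3.8)

  expect_error(task_time_budget(40, accuracy = 0, rejection_fraction = 0.1))
  expect_error(task_time_budget(40, accuracy = 0.9, rejection_fraction = 1))
})

test_that("trial-type enumeration is the Cartesian product", {
  expect_equal(enumerate_trial_types()$count, 12)
  expect_equal(enumerate_trial_types(1.8, "left", "up")$count, 1)
  expect_equal(enumerate_trial_types(c(1, 2), c("l", "r"), c("u", "d"))$count, 8)
})

make_pool <- function(n_subj = 6, pool = 40, slope_center = -0.05,
                      slope_spread = 0.03, noise = 0.02, rt_base = 500,
                      seed = 10) {
  set.seed(seed)
  subs <- list()
  for (s in seq_len(n_subj)) {
    true_slope <- slope_center + slope_spread * (s - (n_subj + 1) / 2)
    # cross-subject coupling: slower subjects have shallower slopes
    rt_mean <- rt_base - 2000 * true_slope
    subs[[sprintf("S%02d", s)]] <- list(
      slopes = true_slope + rnorm(pool, 0, noise),
      rt_ms = rt_mean + rnorm(pool, 0, 60)
    )
  }
  subs
}

test_that("subsampling draws are conserved, deterministic, and exhaustive at the pool", {
  subs <- make_pool()
  res <- subsample_estimates(subs, bin_sizes = c(10, 20, 40), n_perm = 50,
                             pool_size = 40, seed = 2)
  expect_equal(dim(res$est_rt), c(6, 3, 50))
  # bin = pool: every permutation equals the full-pool mean, SD = 0
  full_means <- vapply(subs, function(s) mean(s$rt_ms), numeric(1))
  expect_equal(apply(res$est_rt[, 3, ], 1, sd), rep(0, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(res$est_rt[, 3, 1], full_means, tolerance = 1e-12,
               ignore_attr = TRUE)
  # SNR at the exhausted bin is flagged NA
  expect_true(all(is.na(res$snr_rt[, 3])))
  expect_true(all(is.finite(res$snr_rt[, 1:2])))

  res2 <- subsample_estimates(subs, bin_sizes = c(10, 20, 40), n_perm = 50,
                              pool_size = 40, seed = 2)
  expect_identical(res$est_slope, res2$est_slope)

  # subjects lacking the pool are skipped and logged
  subs$S01$rt_ms <- subs$S01$rt_ms[1:20]
  subs$S01$slopes <- subs$S01$slopes[1:20]
  res3 <- subsample_estimates(subs, bin_sizes = c(10, 20), n_perm = 20,
                              pool_size = 40, seed = 2)
  expect_equal(res3$skipped, "S01")
  expect_equal(length(res3$subjects_used), 5)
})

test_that("subsampling computes the CPP slope from response-locked epochs", {
  # noiseless constructed subject: identical ramp on every trial
  n_tr <- 30
  ep <- make_epochs(function(t, i) 0.04 * t, n_trials = n_tr,
                    window = c(-300, 100), alignment = "response")
  subs <- list(A = list(epochs = ep, rt_ms = NULL),
               B = list(slopes = rnorm(30), rt_ms = rnorm(30, 500)),
               C = list(slopes = rnorm(30), rt_ms = rnorm(30, 500)))
  subs$A$epochs$meta$rt_ms <- rnorm(n_tr, 600)
  res <- subsample_estimates(subs, bin_sizes = c(5, 30), n_perm = 25,
                             pool_size = 30, seed = 1)
  # slope identical across permutations at every bin (noiseless)
  expect_equal(as.vector(res$est_slope["A", , ]), rep(0.04, 2 * 25),
               tolerance = 1e-10)
})

test_that("effect sizes per bin: perfect coupling gives r = -1, none gives ~0", {
  # perfectly linear, noiseless cross-subject relation
  subs <- make_pool(noise = 0, seed = 3)
  for (s in seq_along(subs)) {
    subs[[s]]$rt_ms <- rep(500 - 2000 * mean(subs[[s]]$slopes), 40)
    subs[[s]]$slopes <- rep(mean(subs[[s]]$slopes), 40)
  }
  res <- subsample_estimates(subs, bin_sizes = c(10, 40), n_perm = 20,
                             pool_size = 40, seed = 4)
  expect_equal(as.vector(res$r), rep(-1, 2 * 20), tolerance = 1e-10)

  # slope independent of RT: permutation means concentrate on the full-pool
  # chance correlation, which itself is near zero with enough subjects
  set.seed(6)
  subs0 <- lapply(1:60, function(s) {
    list(slopes = rnorm(40, 0, 0.05), rt_ms = rnorm(40, 500, 60))
  })
  names(subs0) <- sprintf("S%02d", 1:60)
  res0 <- subsample_estimates(subs0, bin_sizes = c(10, 40), n_perm = 300,
                              pool_size = 40, seed = 7)
  pool_r <- cor(vapply(subs0, function(s) mean(s$slopes), numeric(1)),
                vapply(subs0, function(s) mean(s$rt_ms), numeric(1)))
  expect_lt(max(abs(rowMeans(res0$r))), abs(pool_r) + 0.1)
  expect_lt(max(abs(rowMeans(res0$r))), 0.25)

  es <- effect_size_by_bin(res0, threshold = -0.55)
  expect_equal(es$bin, c(10, 40))
  # r distributions far from -0.55 give decisive threshold Bayes factors;
  # the exhausted bin (40 = pool) degenerates to Inf by convention
  expect_true(is.finite(es$bf10[1]) && es$bf10[1] > 100)
  expect_true(es$bf10[2] > 100)
})

test_that("distribution shift tests flag planted variance inflation", {
  subs <- make_pool(n_subj = 10, pool = 120, seed = 8)
  res <- subsample_estimates(subs, bin_sizes = c(10, 30, 120), n_perm = 200,
                             pool_size = 120, seed = 9)
  ds <- distribution_shift_tests(res, metric = "rt")
  expect_true(all(ds$ks$statistic >= 0 & ds$ks$statistic <= 1))
  # small bins have visibly wider estimate distributions than larger ones
  expect_lt(ds$ks$p[1], 0.001)
  # SNR rises with bin size
  expect_gt(mean(res$snr_rt[, 2], na.rm = TRUE),
            mean(res$snr_rt[, 1], na.rm = TRUE))
  expect_lt(ds$snr_trend$p.value, 0.05)
})
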