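#' Trial-subsampling estimates of RT and CPP build-up rate
#'
#' For every subject with at least `pool_size` valid response-locked trials,
#' draws `n_perm` random subsamples (without replacement within a draw) of
#' each size in `bin_sizes` from a fixed `pool_size`-trial pool, and records
#' the subsample mean RT and CPP build-up rate. The build-up rate of a draw
#' equals the mean of the drawn trials' single-trial OLS slopes over
#' `slope_window`, which is algebraically identical to fitting the slope on
#' the averaged waveform (OLS is linear in the data).
#'
#' Per subject and bin the signal-to-noise ratio (mean / SD over
#' permutations) is computed; where the SD is zero (e.g. bin = pool) the
#' SNR is `NA` and flagged. Per bin and permutation the cross-subject
#' Pearson correlation between CPP slope and mean RT is recorded.
#'
#' @param subject_data list, one element per subject, each a list with
#'   `epochs` (a response-aligned `epoch_set` containing Pz) and `rt_ms`
#'   (per-trial RTs of the same trials), or with precomputed `slopes`.
#' @param bin_sizes subsample sizes.
#' @param n_perm permutations per bin size.
#' @param pool_size required trial pool; subjects below it are skipped and
#'   logged.
#' @param seed integer seed.
#' @param slope_window CPP slope window, ms around response.
#' @return object of class `subsampling_result`: arrays `est_rt` and
#'   `est_slope` (subject x bin x perm), `snr_rt`/`snr_slope`
#'   (subject x bin), `r` (bin x perm), `bin_sizes`, `subjects_used`,
#'   `skipped`.
#' @export
subsample_estimates <- function(subject_data, bin_sizes = c(20, 40, 60, 80, 100, 120),
                                n_perm = 1000, pool_size = 129, seed = 1L,
                                slope_window = c(-150, 50)) {
  stopifnot(all(bin_sizes <= pool_size), n_perm > 0)
  prep <- list(); skipped <- character(0)
  for (nm in names(subject_data) %||% as.character(seq_along(subject_data))) {
    sd_i <- subject_data[[nm]]
    slopes <- sd_i$slopes
    rt <- sd_i$rt_ms
    if (is.null(slopes)) {
      m <- get_channel(sd_i$epochs, "Pz")
      tt <- sd_i$epochs$time_ms
      mask <- time_mask(tt, slope_window)
      X <- cbind(1, tt[mask])
      w <- solve(crossprod(X), t(X))[2, ] # OLS slope weights
      slopes <- as.numeric(m[, mask, drop = FALSE] %*% w)
      rt <- sd_i$epochs$meta$rt_ms
    }
    if (length(slopes) < pool_size || length(rt) < pool_size) {
      skipped <- c(skipped, nm)
      next
    }
    prep[[nm]] <- list(slopes = slopes[seq_len(pool_size)],
                       rt = rt[seq_len(pool_size)])
  }
  if (length(prep) < 3) stop("fewer than 3 subjects pass the pool-size gate")
  n_s <- length(prep); n_b <- length(bin_sizes)
  est_rt <- array(NA_real_, c(n_s, n_b, n_perm),
                  dimnames = list(names(prep), bin_sizes, NULL))
  est_slope <- est_rt
  set.seed(seed)
  for (bi in seq_len(n_b)) {
    nn <- bin_sizes[bi]
    for (si in seq_len(n_s)) {
      ps <- prep[[si]]
      for (pi in seq_len(n_perm)) {
        draw <- sample.int(pool_size, nn)
        est_rt[si, bi, pi] <- mean(ps$rt[draw])
        est_slope[si, bi, pi] <- mean(ps$slopes[draw])
      }
    }
  }
  snr <- function(a) {
    mu <- apply(a, c(1, 2), mean); sdv <- apply(a, c(1, 2), stats::sd)
    out <- mu / sdv
    out[sdv == 0] <- NA_real_
    out
  }
  r <- matrix(NA_real_, n_b, n_perm, dimnames = list(bin_sizes, NULL))
  for (bi in seq_len(n_b)) {
    r[bi, ] <- vapply(seq_len(n_perm), function(pi) {
      stats::cor(est_slope[, bi, pi], est_rt[, bi, pi])
    }, numeric(1))
  }
  structure(list(est_rt = est_rt, est_slope = est_slope,
                 snr_rt = snr(est_rt), snr_slope = snr(est_slope),
                 r = r, bin_sizes = bin_sizes,
                 subjects_used = names(prep), skipped = skipped,
                 n_perm = n_perm, pool_size = pool_size, seed = seed),
            class = "subsampling_result")
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat(sprintf("<subsampling_result> %d subjects x %d bins x %d perms (pool %d)\n",
              length(x$subjects_used), length(x$bin_sizes), x$n_perm,
              x$pool_size))
  cat("  mean SNR (RT):   ", paste(sprintf("%.1f", colMeans(x$snr_rt, na.rm = TRUE)),
                                   collapse = " "), "\n")
  cat("  mean r(slope,RT):", paste(sprintf("%.2f", rowMeans(x$r)), collapse = " "), "\n")
  invisible(x)
}

#' Distribution-shift tests across subsampling bins
#'
#' Two-sample Kolmogorov-Smirnov tests between the estimate distributions
#' of adjacent bin sizes (estimates pooled over subjects after centring
#' each subject at its across-bin grand mean), plus a repeated-measures
#' linear trend test on the SNR: the per-subject OLS slope of SNR against
#' bin size, tested against zero with a one-sample t test.
#'
#' @param result a `subsampling_result`.
#' @param metric `"slope"` or `"rt"`.
#' @return list with `ks` (data.frame per adjacent pair) and `snr_trend`
#'   (htest).
#' @export
distribution_shift_tests <- function(result, metric = c("slope", "rt")) {
  metric <- match.arg(metric)
  est <- if (metric == "slope") result$est_slope else result$est_rt
  snr <- if (metric == "slope") result$snr_slope else result$snr_rt
  centred <- est - as.vector(apply(est, 1, mean)) # recycle over bins/perms
  n_b <- length(result$bin_sizes)
  ks <- data.frame(bin_small = result$bin_sizes[-n_b],
                   bin_large = result$bin_sizes[-1],
                   statistic = NA_real_, p = NA_real_)
  for (i in seq_len(n_b - 1)) {
    kt <- suppressWarnings(stats::ks.test(as.numeric(centred[, i, ]),
                                          as.numeric(centred[, i + 1, ])))
    ks$statistic[i] <- unname(kt$statistic)
    ks$p[i] <- kt$p.value
  }
  # bins where any subject's SNR is undefined (SD = 0, e.g. bin = pool) are
  # excluded from the trend test
  ok_bins <- colSums(!is.finite(snr)) == 0
  if (sum(ok_bins) < 2) stop("fewer than 2 bins with finite SNR for the trend test")
  bins_use <- result$bin_sizes[ok_bins]
  slopes <- apply(snr[, ok_bins, drop = FALSE], 1, function(row) {
    unname(stats::coef(stats::lm.fit(cbind(1, bins_use), row))[2])
  })
  list(ks = ks, snr_trend = stats::t.test(slopes, mu = 0))
}

#' Effect-size distribution per bin with threshold Bayes factors
#'
#' Summarises the per-permutation cross-subject Pearson correlations and
#' tests, per bin, whether their distribution exceeds a threshold effect
#' size (default -0.55, i.e. more negative) with a one-sample JZS Bayes
#' factor.
#'
#' @param result a `subsampling_result`.
#' @param threshold correlation threshold.
#' @param direction sidedness of the Bayes-factor alternative.
#' @param cauchy_scale JZS prior scale.
#' @return data.frame per bin: `bin`, `mean_r`, `sd_r`, `bf10`.
#' @export
effect_size_by_bin <- function(result, threshold = -0.55,
                               direction = "two.sided",
                               cauchy_scale = 0.707) {
  out <- data.frame(bin = result$bin_sizes,
                    mean_r = rowMeans(result$r),
                    sd_r = apply(result$r, 1, stats::sd),
                    bf10 = NA_real_)
  for (i in seq_len(nrow(out))) {
    if (out$sd_r[i] == 0) {
      # exhausted pool: every permutation identical; the t test degenerates
      out$bf10[i] <- if (out$mean_r[i] != threshold) Inf else NA_real_
      next
    }
    out$bf10[i] <- jzs_bf_ttest(result$r[i, ] - threshold, mu = 0,
                                cauchy_scale = cauchy_scale,
                                direction = direction)$bf10
  }
  out
}

#' Task-time budget for a target number of valid trials
#'
#' Inflates the required valid-trial count for expected misses
#' (`1 + (1 - accuracy)`) and then for preprocessing rejection
#' (`1 + rejection_fraction`), rounding to the nearest integer at each
#' step. Coherent-motion time is `presented * coherent_s`; random-motion
#' time allocates the presented trials over the ITI set as evenly as
#' possible, spreading any remainder over the earliest (shortest) ITIs
#' first.
#'
#' @param required_valid number of clean response-locked trials needed.
#' @param accuracy expected detection accuracy (0-1].
#' @param rejection_fraction expected fraction of trials lost to cleaning
#'   [0-1).
#' @param coherent_s coherent-motion duration per trial, s.
#' @param itis random-motion foreperiod set, s.
#' @return object of class `task_timing_plan` with `required_valid`,
#'   `post_accuracy_trials`, `presented_trials`, `coherent_seconds`,
#'   `random_seconds`, `total_seconds`, `iti_allocation`.
#' @export
task_time_budget <- function(required_valid = 40, accuracy,
                             rejection_fraction, coherent_s = 3.0,
                             itis = c(1.8, 2.8, 3.8)) {
  if (accuracy <= 0 || accuracy > 1) stop("accuracy must be in (0, 1]")
  if (rejection_fraction < 0 || rejection_fraction >= 1) {
    stop("rejection_fraction must be in [0, 1)")
  }
  post_acc <- round(required_valid * (1 + (1 - accuracy)))
  presented <- round(post_acc * (1 + rejection_fraction))
  coherent <- presented * coherent_s
  k <- length(itis)
  base <- presented %/% k
  rem <- presented %% k
  alloc <- rep(base, k) + c(rep(1, rem), rep(0, k - rem)) # earliest-first
  random <- sum(alloc * sort(itis))
  structure(list(required_valid = required_valid, accuracy = accuracy,
                 rejection_fraction = rejection_fraction,
                 post_accuracy_trials = post_acc,
                 presented_trials = presented,
                 coherent_seconds = coherent, random_seconds = random,
                 total_seconds = coherent + random,
                 iti_allocation = stats::setNames(alloc, sort(itis))),
            class = "task_timing_plan")
}

#' @export
print.task_timing_plan <- function(x, ...) {
  cat(sprintf("<task_timing_plan> %d valid -> %d after accuracy -> %d presented\n",
              x$required_valid, x$post_accuracy_trials, x$presented_trials))
  cat(sprintf("  coherent %g s + random %g s = %g s (%.2f min)\n",
              x$coherent_seconds, x$random_seconds, x$total_seconds,
              x$total_seconds / 60))
  invisible(x)
}

#' Enumerate the factorial trial types
#'
#' @param itis foreperiod set, s.
#' @param locations target hemifields.
#' @param directions coherent-motion directions.
#' @return list with `count` and `types` (data.frame of the Cartesian
#'   product).
#' @export
enumerate_trial_types <- function(itis = c(1.8, 2.8, 3.8),
                                  locations = c("left", "right"),
                                  directions = c("up", "down")) {
  types <- expand.grid(iti_s = itis, location = locations,
                       direction = directions, stringsAsFactors = FALSE)
  list(count = nrow(types), types = types)
}
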