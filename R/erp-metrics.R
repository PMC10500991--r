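#' Contralateral N2c waveform
#'
#' Averages the electrode contralateral to the target hemifield (P8 for
#' left-hemifield targets, P7 for right-hemifield targets) and collapses
#' the two hemifield averages. With unbalanced trial counts the collapse is
#' the unweighted mean of the two per-hemifield averages (average of
#' averages), so each hemifield contributes equally.
#'
#' @param epochs stimulus-aligned `epoch_set` with `hemifield` metadata and
#'   electrodes P7/P8.
#' @return a `waveform`.
#' @export
n2c_waveform <- function(epochs) {
  if (epochs$alignment != "stimulus") stop("epochs must be stimulus-aligned")
  if (!all(c("P7", "P8") %in% epochs$channels)) stop("electrodes P7/P8 required")
  meta <- epochs$meta
  valid <- meta$valid
  waves <- list(); n_used <- 0L
  left <- valid & meta$hemifield == "left"
  right <- valid & meta$hemifield == "right"
  if (any(left)) {
    m <- get_channel(epochs, "P8", valid_only = FALSE)[left, , drop = FALSE]
    waves$left <- colMeans(m); n_used <- n_used + sum(left)
  }
  if (any(right)) {
    m <- get_channel(epochs, "P7", valid_only = FALSE)[right, , drop = FALSE]
    waves$right <- colMeans(m); n_used <- n_used + sum(right)
  }
  if (length(waves) == 0L) stop("no valid trials with hemifield metadata")
  amp <- Reduce(`+`, waves) / length(waves)
  waveform(amp, epochs$time_ms, "stimulus", "N2c(P7/P8)", n_used)
}

#' N2c peak latency
#'
#' Time of the most negative amplitude in the stimulus-locked waveform
#' inside `window` (default 150-400 ms). Ties resolve to the earliest
#' sample; an entirely flat segment returns the earliest sample with a
#' warning.
#'
#' @param wave a stimulus-aligned `waveform`.
#' @param window search window, ms.
#' @return latency in ms.
#' @export
n2c_latency <- function(wave, window = c(150, 400)) {
  if (wave$alignment != "stimulus") stop("waveform must be stimulus-aligned")
  mask <- which(time_mask(wave$time_ms, window))
  seg <- wave$amplitude[mask]
  if (diff(range(seg)) == 0) {
    warning("flat waveform in N2c search window; returning earliest sample")
  }
  wave$time_ms[mask[which.min(seg)]]
}

#' N2c mean amplitude around the grand-average peak
#'
#' Mean amplitude inside a 100 ms window centred on the cohort-level
#' grand-average peak latency. A window extending past the epoch is
#' truncated with a warning.
#'
#' @param wave a `waveform`.
#' @param grand_peak grand-average N2c peak latency, ms (see
#'   [grand_n2c_peak()]).
#' @param half_width half of the measurement window, ms.
#' @return mean amplitude, uV.
#' @export
n2c_amplitude <- function(wave, grand_peak, half_width = 50) {
  lo <- grand_peak - half_width; hi <- grand_peak + half_width
  if (lo < min(wave$time_ms) || hi > max(wave$time_ms)) {
    warning("amplitude window truncated to epoch limits")
  }
  mean(wave$amplitude[time_mask(wave$time_ms, c(lo, hi))])
}

#' Grand-average N2c peak latency for a cohort
#'
#' @param waves list of per-subject N2c `waveform`s on a common time axis.
#' @param window search window, ms.
#' @return peak latency of the grand-average waveform, ms.
#' @export
grand_n2c_peak <- function(waves, window = c(150, 400)) {
  amp <- Reduce(`+`, lapply(waves, `[[`, "amplitude")) / length(waves)
  n2c_latency(waveform(amp, waves[[1]]$time_ms, "stimulus", "N2c(grand)",
                       length(waves)),
              window)
}

#' CPP onset latency by running t tests
#'
#' At each sample of the stimulus-locked single-trial Pz matrix, the mean
#' of a 25 ms window centred on that sample is computed per trial and
#' tested against zero with a two-sided one-sample t test across trials.
#' Onset is the first sample (inside `search`) from which the p value stays
#' below `alpha` for `run_length` consecutive samples (the run may extend
#' past the search window). Degenerate zero-variance windows count as
#' significant when their mean is nonzero.
#'
#' @param epochs stimulus-aligned `epoch_set` containing Pz.
#' @param win_ms sliding-window width, ms.
#' @param alpha significance level.
#' @param run_length required consecutive significant samples.
#' @param search onset search range, ms post-stimulus.
#' @return onset latency in ms, or `NA` if undetected.
#' @export
cpp_onset <- function(epochs, win_ms = 25, alpha = 0.05, run_length = 90,
                      search = c(0, 1000)) {
  if (epochs$alignment != "stimulus") stop("epochs must be stimulus-aligned")
  m <- get_channel(epochs, "Pz")
  n_tr <- nrow(m)
  if (n_tr < 10) stop("need at least 10 valid trials for onset detection")
  dt <- 1000 / epochs$sfreq
  half <- floor(win_ms / dt / 2)
  k <- 2 * half + 1
  # centred moving average per trial via stats::filter
  sm <- t(apply(m, 1, function(row) {
    as.numeric(stats::filter(row, rep(1 / k, k), sides = 2))
  }))
  mu <- colMeans(sm)
  sdv <- apply(sm, 2, stats::sd)
  tval <- mu / (sdv / sqrt(n_tr))
  p <- 2 * stats::pt(abs(tval), df = n_tr - 1, lower.tail = FALSE)
  p[is.na(p) & !is.na(mu)] <- ifelse(abs(mu[is.na(p) & !is.na(mu)]) > 0, 0, 1)
  sig <- !is.na(p) & p < alpha
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  in_search <- time_mask(epochs$time_ms, search)
  for (j in seq_along(run$values)) {
    if (!run$values[j]) next
    # first significant sample of the run inside the search range
    cand <- starts[j]:ends[j]
    cand <- cand[in_search[cand]]
    if (length(cand) == 0) next
    s <- cand[1]
    if (ends[j] - s + 1 >= run_length) return(epochs$time_ms[s])
  }
  NA_real_
}

#' CPP build-up rate
#'
#' Ordinary-least-squares slope of the response-locked trial-average Pz
#' waveform over `window` (default -150..+50 ms around the response).
#'
#' @param wave a response-aligned `waveform` (Pz average), or an
#'   `epoch_set` from which the Pz average is taken.
#' @param window fit window, ms.
#' @return slope in uV/ms.
#' @export
cpp_slope <- function(wave, window = c(-150, 50)) {
  wave <- as_pz_wave(wave)
  if (wave$alignment != "response") stop("response-aligned waveform required")
  mask <- time_mask(wave$time_ms, window)
  if (sum(mask) < 3) stop("fewer than 3 samples in slope window")
  unname(stats::coef(stats::lm.fit(cbind(1, wave$time_ms[mask]),
                                   wave$amplitude[mask]))[2])
}

#' CPP amplitude at response
#'
#' Mean of the response-locked Pz average over `window`
#' (default -50..+50 ms).
#'
#' @param wave response-aligned `waveform` or `epoch_set`.
#' @param window measurement window, ms.
#' @return mean amplitude, uV.
#' @export
cpp_amplitude <- function(wave, window = c(-50, 50)) {
  wave <- as_pz_wave(wave)
  if (wave$alignment != "response") stop("response-aligned waveform required")
  mask <- time_mask(wave$time_ms, window)
  if (sum(mask) < 3) stop("fewer than 3 samples in amplitude window")
  mean(wave$amplitude[mask])
}

as_pz_wave <- function(x) {
  if (inherits(x, "epoch_set")) average_waveform(x, "Pz") else x
}

#' Extract the eight per-subject neural metrics
#'
#' Convenience wrapper combining the N2c, CPP and left-hemisphere beta
#' extractors for one subject.
#'
#' Two response-locked re-slices are used: a short window for the CPP
#' measures (so almost no trial is lost) and a longer one for the beta TSE,
#' whose -450..-350 ms baseline needs more pre-response signal.
#'
#' @param stim_epochs stimulus-aligned `epoch_set` (baselined, exclusions
#'   applied).
#' @param grand_peak cohort grand-average N2c peak latency, ms.
#' @param resp_window_cpp response-locked window for CPP measures, ms.
#' @param resp_window_lhb response-locked window for beta TSE, ms.
#' @return one-row data.frame with `n2c_latency`, `n2c_amplitude`,
#'   `cpp_onset`, `cpp_slope`, `cpp_amplitude`, `lhb_latency`, `lhb_slope`,
#'   `lhb_amplitude`.
#' @export
neural_metrics <- function(stim_epochs, grand_peak = NULL,
                           resp_window_cpp = c(-200, 100),
                           resp_window_lhb = c(-600, 300)) {
  n2c <- n2c_waveform(stim_epochs)
  if (is.null(grand_peak)) grand_peak <- n2c_latency(n2c)
  resp <- response_lock(stim_epochs, window = resp_window_cpp)
  resp_lhb <- response_lock(stim_epochs, window = resp_window_lhb)
  tse_stim <- tse_power(stim_epochs)
  tse_resp <- tse_power(resp_lhb)
  data.frame(
    n2c_latency = n2c_latency(n2c),
    n2c_amplitude = n2c_amplitude(n2c, grand_peak),
    cpp_onset = cpp_onset(stim_epochs),
    cpp_slope = cpp_slope(resp),
    cpp_amplitude = cpp_amplitude(resp),
    lhb_latency = lhb_latency(tse_stim),
    lhb_slope = lhb_slope(tse_resp),
    lhb_amplitude = lhb_amplitude(tse_resp)
  )
}
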