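#' Hamming windowed-sinc FIR kernel
#'
#' Designs a linear-phase FIR kernel by the windowed-sinc method with a
#' Hamming window. Order is chosen from the transition bandwidth as
#' `3.3 / (tbw / sfreq)` (the Hamming normalised transition width), forced
#' odd so the kernel has a centre tap and symmetric (zero-phase)
#' application is exact.
#'
#' @param sfreq sampling rate, Hz.
#' @param type `"low"`, `"high"`, `"stop"` or `"pass"`.
#' @param freq cutoff (Hz): one value for low/high, two for stop/pass.
#' @param tbw transition bandwidth, Hz.
#' @return numeric kernel (odd length, sums to 1 for low-pass).
#' @export
fir_kernel <- function(sfreq, type = c("low", "high", "stop", "pass"),
                       freq, tbw = 1) {
  type <- match.arg(type)
  n_tap <- ceiling(3.3 * sfreq / tbw)
  if (n_tap %% 2 == 0) n_tap <- n_tap + 1
  m <- (n_tap - 1) / 2
  k <- seq(-m, m)
  win <- 0.54 + 0.46 * cos(pi * k / m)
  lp <- function(fc) {
    h <- 2 * fc / sfreq * sinc(2 * fc / sfreq * k) * win
    h / sum(h)
  }
  delta <- numeric(n_tap); delta[m + 1] <- 1
  switch(type,
    low  = lp(freq[1]),
    high = delta - lp(freq[1]),
    pass = lp(freq[2]) - lp(freq[1]),
    stop = delta - (lp(freq[2]) - lp(freq[1]))
  )
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Zero-phase FIR filtering
#'
#' Convolves each row of `x` with a symmetric kernel, centred so the output
#' is zero-phase. Edges are handled by mirror padding; FFT convolution keeps
#' the long 0.1 Hz high-pass kernel affordable.
#'
#' @param x numeric vector or channels x time matrix.
#' @param kernel symmetric FIR kernel of odd length (from [fir_kernel()]).
#' @return filtered data, same shape as `x`.
#' @export
apply_fir <- function(x, kernel) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  m <- (length(kernel) - 1) / 2
  if (ncol(x) <= m) {
    stop(sprintf("signal (%d samples) shorter than half filter length (%d)",
                 ncol(x), m))
  }
  out <- t(apply(x, 1, function(row) {
    padded <- c(rev(row[2:(m + 1)]), row, rev(row[(length(row) - m):(length(row) - 1)]))
    full <- stats::convolve(padded, rev(kernel), type = "open")
    full[(2 * m + 1):(2 * m + length(row))]
  }))
  if (vec) as.numeric(out) else out
}

#' Standard continuous-EEG filter chain
#'
#' Applies, in order: linear detrend, notch filters at 50/100/150 Hz
#' (band-stop of half-width `notch_hw`), a 0.1 Hz high-pass, and a 35 Hz
#' low-pass; all Hamming windowed-sinc FIR, zero-phase.
#'
#' @param x channels x time matrix (or vector) of continuous data.
#' @param sfreq sampling rate, Hz.
#' @param notch frequencies (Hz) to notch out; `NULL` to skip.
#' @param notch_hw half-width of each notch, Hz.
#' @param hp high-pass cutoff, Hz (`NULL` to skip).
#' @param hp_tbw transition bandwidth of the high-pass, Hz.
#' @param lp low-pass cutoff, Hz (`NULL` to skip).
#' @param lp_tbw transition bandwidth of the low-pass, Hz.
#' @return filtered data, same shape.
#' @export
filter_continuous <- function(x, sfreq, notch = c(50, 100, 150),
                              notch_hw = 2.5, hp = 0.1, hp_tbw = 0.1,
                              lp = 35, lp_tbw = 5) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  tt <- seq_len(n)
  x <- t(apply(x, 1, function(row) stats::lsfit(tt, row)$residuals))
  for (f0 in notch) {
    x <- apply_fir(x, fir_kernel(sfreq, "stop", c(f0 - notch_hw, f0 + notch_hw),
                                 tbw = notch_hw))
  }
  if (!is.null(hp)) x <- apply_fir(x, fir_kernel(sfreq, "high", hp, tbw = hp_tbw))
  if (!is.null(lp)) x <- apply_fir(x, fir_kernel(sfreq, "low", lp, tbw = lp_tbw))
  if (vec) as.numeric(x) else x
}

#' Extract fixed-window epochs from continuous data
#'
#' Slices `window` ms around each event and baselines every trial/channel
#' with the mean over `baseline`. Events whose window leaves the recording
#' are dropped and listed in the returned object's `dropped_events`
#' attribute (with reasons).
#'
#' @param continuous channels x time matrix.
#' @param sfreq sampling rate, Hz.
#' @param channel_labels one label per row of `continuous`.
#' @param event_ms event (lock) times in ms from recording start.
#' @param alignment `"stimulus"` or `"response"`.
#' @param window epoch window, ms relative to the event.
#' @param baseline baseline window, ms relative to the event (`NULL` skips).
#' @param meta optional data.frame of per-event metadata (subset to kept
#'   events).
#' @return an `epoch_set`.
#' @export
extract_epochs <- function(continuous, sfreq, channel_labels, event_ms,
                           alignment = "stimulus",
                           window = c(-200, 1500), baseline = c(-100, 0),
                           meta = NULL) {
  stopifnot(is.matrix(continuous), nrow(continuous) == length(channel_labels))
  dt <- 1000 / sfreq
  rel_idx <- round(window[1] / dt):round(window[2] / dt)
  t_rel <- rel_idx * dt
  n_samp <- ncol(continuous)
  ev_idx <- round(event_ms / dt) + 1L
  lo <- ev_idx + rel_idx[1]
  hi <- ev_idx + rel_idx[length(rel_idx)]
  keep <- lo >= 1L & hi <= n_samp
  dropped <- data.frame(event_ms = event_ms[!keep],
                        reason = rep("window outside recording", sum(!keep)))
  kept_idx <- ev_idx[keep]
  dat <- array(NA_real_, dim = c(length(kept_idx), nrow(continuous), length(rel_idx)))
  for (i in seq_along(kept_idx)) {
    dat[i, , ] <- continuous[, kept_idx[i] + rel_idx, drop = FALSE]
  }
  if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
  ep <- epoch_set(dat, t_rel, sfreq, alignment, channel_labels, meta)
  if (!is.null(baseline)) ep <- baseline_epochs(ep, baseline)
  attr(ep, "dropped_events") <- dropped
  ep
}

#' Flag trials for exclusion by RT and amplitude criteria
#'
#' A trial is invalidated when (1) its RT is at or below `rt_min` ms
#' (pre-emptive) or at or above `rt_max` ms (post-offset), (2) it has no
#' response at all, or (3) any channel's absolute amplitude strictly
#' exceeds `amp_limit` uV between 100 ms before target onset and 100 ms
#' after the response. "Exceeds" is read as a strict inequality on the
#' absolute value, so a sample at exactly the limit is retained. The
#' operation is idempotent: reasons are recomputed from metadata, never
#' accumulated.
#'
#' @param epochs stimulus-aligned `epoch_set` with `rt_ms`/`responded`
#'   metadata.
#' @param rt_min,rt_max RT bounds in ms (excluded when `<=` / `>=`).
#' @param amp_limit artifact threshold, uV.
#' @return the `epoch_set` with updated `valid`/`exclusion_reason` and an
#'   `exclusion_log` attribute (counts per reason).
#' @export
exclude_trials <- function(epochs, rt_min = 150, rt_max = 1800,
                           amp_limit = 100) {
  if (epochs$alignment != "stimulus") stop("epochs must be stimulus-aligned")
  meta <- epochs$meta
  n <- nrow(meta)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (!isTRUE(meta$responded[i]) || is.na(meta$rt_ms[i])) {
      r <- c(r, "no_response")
      win_end <- max(epochs$time_ms)
    } else {
      if (meta$rt_ms[i] <= rt_min) r <- c(r, "rt_too_fast")
      if (meta$rt_ms[i] >= rt_max) r <- c(r, "rt_too_slow")
      win_end <- min(meta$rt_ms[i] + 100, max(epochs$time_ms))
    }
    mask <- time_mask(epochs$time_ms, c(-100, win_end))
    if (any(abs(epochs$data[i, , mask]) > amp_limit)) r <- c(r, "artifact")
    reasons[i] <- paste(r, collapse = ";")
  }
  meta$valid <- reasons == ""
  meta$exclusion_reason <- ifelse(meta$valid, NA_character_, reasons)
  epochs$meta <- meta
  log <- table(unlist(strsplit(reasons[reasons != ""], ";")))
  attr(epochs, "exclusion_log") <- c(
    as.list(log),
    list(n_input = n, n_retained = sum(meta$valid),
         n_excluded = sum(!meta$valid))
  )
  epochs
}

#' Extreme-outlier flags by the 3 x IQR rule
#'
#' Flags values below `Q1 - k*IQR` or above `Q3 + k*IQR`, with quartiles by
#' linear interpolation (type-7, the common statistics-package default).
#'
#' @param values numeric vector (length >= 4).
#' @param k IQR multiplier (default 3, the extreme-outlier rule).
#' @return logical vector of flags.
#' @export
iqr_outlier_flags <- function(values, k = 3) {
  if (length(values) < 4) stop("need at least 4 values for IQR outlier detection")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}
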