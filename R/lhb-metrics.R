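#' Temporal spectral evolution of band amplitude
#'
#' Band-passes each trial (Hamming windowed-sinc FIR, zero-phase), rectifies
#' (absolute value), then smooths by averaging inside a 100 ms window moved
#' forward in 50 ms increments. The resulting trial x time grid is baselined
#' by subtraction (stimulus-locked: -100..0 ms; response-locked:
#' -450..-350 ms) and finally trimmed by 200 ms at each end to drop filter
#' warm-up; baselining precedes trimming because the stimulus-locked
#' baseline window lies inside the trimmed region.
#'
#' @param epochs an `epoch_set` containing `electrode`.
#' @param band band edges in Hz (default 20-35, the beta band).
#' @param electrode channel label (default C3, left motor cortex for a
#'   right-hand response).
#' @param win_ms smoothing window width, ms.
#' @param step_ms smoothing grid step, ms.
#' @param trim_ms edge trim after smoothing, ms.
#' @param baseline `TRUE` for the alignment-appropriate default window,
#'   `FALSE`/`NULL` for none, or a length-2 window in ms.
#' @return a `tse_power` object: list with `power` (trials x grid),
#'   `time_ms` (window centres), `band`, `electrode`, `alignment`.
#' @export
tse_power <- function(epochs, band = c(20, 35), electrode = "C3",
                      win_ms = 100, step_ms = 50, trim_ms = 200,
                      baseline = TRUE) {
  if (band[2] >= epochs$sfreq / 2) stop("band edge at or above Nyquist")
  m <- get_channel(epochs, electrode)
  kernel <- fir_kernel(epochs$sfreq, "pass", band, tbw = 5)
  rect <- abs(apply_fir(m, kernel))
  t_ms <- epochs$time_ms
  half <- win_ms / 2
  lo <- min(t_ms); hi <- max(t_ms)
  centers <- seq(ceiling((lo + half) / step_ms) * step_ms, hi - half,
                 by = step_ms)
  if (length(centers) < 2) stop("epoch too short for TSE smoothing grid")
  # half-open smoothing window [c - 50, c + 50): exactly win_ms of signal,
  # i.e. a whole number of rectified-carrier periods for the 25 Hz band
  # centre, so the smoothed trace is ripple-free for constant envelopes
  pow <- sapply(centers, function(ct) {
    mask <- t_ms >= ct - half - 1e-9 & t_ms < ct + half - 1e-9
    rowMeans(rect[, mask, drop = FALSE])
  })
  if (is.null(dim(pow))) pow <- matrix(pow, nrow = 1)
  if (isTRUE(baseline)) {
    baseline <- if (epochs$alignment == "stimulus") c(-100, 0) else c(-450, -350)
  }
  if (is.numeric(baseline)) {
    bmask <- time_mask(centers, baseline)
    if (!any(bmask)) stop("TSE baseline window not on the smoothing grid")
    pow <- pow - rowMeans(pow[, bmask, drop = FALSE])
  }
  keep <- centers >= lo + trim_ms - 1e-9 & centers <= hi - trim_ms + 1e-9
  structure(list(power = pow[, keep, drop = FALSE], time_ms = centers[keep],
                 band = band, electrode = electrode,
                 alignment = epochs$alignment, step_ms = step_ms),
            class = "tse_power")
}

#' @export
print.tse_power <- function(x, ...) {
  cat(sprintf("<tse_power> %s %g-%g Hz, %s-aligned, %d trials x %d bins (%g..%g ms)\n",
              x$electrode, x$band[1], x$band[2], x$alignment,
              nrow(x$power), ncol(x$power), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Trial-averaged TSE trace
#' @param tse a `tse_power`.
#' @return numeric vector, the mean band-amplitude time course.
#' @export
tse_mean <- function(tse) colMeans(tse$power)

#' Beta desynchronisation latency
#'
#' Time of the most negative point of the trial-averaged, baselined TSE
#' trace inside `window` (default 0-1000 ms post-stimulus). Ties resolve to
#' the earliest bin; a flat trace returns the earliest bin with a warning.
#'
#' @param tse stimulus-aligned `tse_power`.
#' @param window search window, ms.
#' @return latency in ms (on the 50 ms smoothing grid).
#' @export
lhb_latency <- function(tse, window = c(0, 1000)) {
  if (tse$alignment != "stimulus") stop("stimulus-aligned TSE required")
  mask <- which(time_mask(tse$time_ms, window))
  seg <- tse_mean(tse)[mask]
  if (diff(range(seg)) == 0) {
    warning("flat TSE in latency window; returning earliest bin")
  }
  tse$time_ms[mask[which.min(seg)]]
}

#' Beta build-up (desynchronisation) slope
#'
#' OLS slope of the trial-averaged response-locked TSE over `window`
#' (default -300..-50 ms preresponse).
#'
#' @param tse response-aligned `tse_power`.
#' @param window fit window, ms.
#' @return slope in power units per ms.
#' @export
lhb_slope <- function(tse, window = c(-300, -50)) {
  if (tse$alignment != "response") stop("response-aligned TSE required")
  mask <- time_mask(tse$time_ms, window)
  if (sum(mask) < 3) stop("fewer than 3 TSE bins in slope window")
  unname(stats::coef(stats::lm.fit(cbind(1, tse$time_ms[mask]),
                                   tse_mean(tse)[mask]))[2])
}

#' Beta amplitude at response
#'
#' Mean of the trial-averaged response-locked TSE inside a 100 ms window
#' centred on the response.
#'
#' @param tse response-aligned `tse_power`.
#' @param window measurement window, ms.
#' @return mean amplitude in power units.
#' @export
lhb_amplitude <- function(tse, window = c(-50, 50)) {
  if (tse$alignment != "response") stop("response-aligned TSE required")
  mask <- time_mask(tse$time_ms, window)
  if (!any(mask)) stop("no TSE bins in amplitude window")
  mean(tse_mean(tse)[mask])
}
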