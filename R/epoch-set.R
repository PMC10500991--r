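#' Epoched EEG container
#'
#' An `epoch_set` holds a trials x channels x time block of epoched EEG
#' together with its time axis, alignment event, channel labels, and
#' per-trial metadata. All downstream metric extractors consume this class.
#'
#' @param data numeric array, trials x channels x time, amplitudes in uV.
#' @param time_ms numeric vector of sample times in ms relative to the lock
#'   event (0 = lock), strictly increasing and uniformly spaced.
#' @param sfreq sampling rate in Hz.
#' @param alignment `"stimulus"` or `"response"`.
#' @param channels character vector of channel labels, one per data column.
#' @param meta data.frame with one row per trial. Expected columns (created
#'   empty when absent): `rt_ms`, `responded`, `hemifield`, `direction`,
#'   `iti_s`, `valid`, `exclusion_reason`.
#' @param baseline length-2 numeric (ms) recording the window already used
#'   for baselining, or `NULL` if the data are not baselined.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, sfreq, alignment = c("stimulus", "response"),
                      channels, meta = NULL, baseline = NULL) {
  alignment <- match.arg(alignment)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels)) {
    stop("channel label count does not match data dimension 2")
  }
  if (dim(data)[3] != length(time_ms)) {
    stop("time axis length does not match data dimension 3")
  }
  dt <- diff(time_ms)
  if (any(dt <= 0) || max(abs(dt - 1000 / sfreq)) > 1e-6) {
    stop("time_ms must be strictly increasing and uniform at 1000/sfreq")
  }
  n_trials <- dim(data)[1]
  if (is.null(meta)) {
    meta <- data.frame(rt_ms = rep(NA_real_, n_trials))
  }
  if (nrow(meta) != n_trials) stop("meta must have one row per trial")
  for (col in c("rt_ms", "iti_s")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  }
  if (is.null(meta$responded)) meta$responded <- !is.na(meta$rt_ms)
  for (col in c("hemifield", "direction", "exclusion_reason")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  if (is.null(meta$valid)) meta$valid <- TRUE
  structure(
    list(data = data, time_ms = time_ms, sfreq = sfreq, alignment = alignment,
         channels = channels, meta = meta, baseline = baseline),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples (%s-aligned, %g Hz)\n",
              d[1], d[2], d[3], x$alignment, x$sfreq))
  cat(sprintf("  time %g..%g ms; channels: %s\n", min(x$time_ms), max(x$time_ms),
              paste(x$channels, collapse = ", ")))
  cat(sprintf("  valid trials: %d/%d; baseline: %s\n", sum(x$meta$valid), d[1],
              if (is.null(x$baseline)) "none" else paste(x$baseline, collapse = "..")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

#' Number of trials in an epoch_set
#' @param epochs an `epoch_set`.
#' @param valid_only count only trials flagged valid.
#' @return integer count.
#' @export
n_trials <- function(epochs, valid_only = FALSE) {
  if (valid_only) sum(epochs$meta$valid) else dim(epochs$data)[1]
}

#' Extract a single channel as a trials x time matrix
#'
#' @param epochs an `epoch_set`.
#' @param label channel label.
#' @param valid_only drop trials not flagged valid.
#' @return numeric matrix trials x time.
#' @export
get_channel <- function(epochs, label, valid_only = TRUE) {
  idx <- match(label, epochs$channels)
  if (is.na(idx)) stop(sprintf("channel '%s' not present", label))
  m <- epochs$data[, idx, , drop = FALSE]
  m <- array(m, dim = dim(m)[c(1, 3)])
  if (valid_only) m <- m[epochs$meta$valid, , drop = FALSE]
  m
}

#' Index of the sample closest to a time in ms
#' @keywords internal
time_index <- function(time_ms, t) which.min(abs(time_ms - t))

#' Logical mask of samples inside a closed window
#' @keywords internal
time_mask <- function(time_ms, window) {
  time_ms >= window[1] - 1e-9 & time_ms <= window[2] + 1e-9
}

#' Baseline-correct an epoch_set
#'
#' Subtracts, per trial and channel, the mean amplitude inside `window`
#' (closed interval in ms relative to the lock event).
#'
#' @param epochs an `epoch_set`.
#' @param window length-2 numeric window in ms, e.g. `c(-100, 0)`.
#' @return the baselined `epoch_set` (the `baseline` field records `window`).
#' @export
baseline_epochs <- function(epochs, window = c(-100, 0)) {
  mask <- time_mask(epochs$time_ms, window)
  if (!any(mask)) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , mask, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl) # recycles over time (3rd dim last)
  epochs$baseline <- window
  epochs
}

#' Re-align stimulus-locked epochs to the response
#'
#' Response-locked epochs are derived by re-slicing each responded trial's
#' stimulus-locked data at its RT; no separate recording pass is used.
#' Trials whose response-locked window would leave the stimulus epoch are
#' dropped and logged in the returned object's `dropped` attribute.
#'
#' @param epochs stimulus-aligned `epoch_set` with `rt_ms` metadata.
#' @param window length-2 numeric window in ms around the response.
#' @param baseline optional baseline window (ms, response-relative) applied
#'   after re-slicing; `NULL` keeps the stimulus-locked baseline.
#' @return a response-aligned `epoch_set` of the surviving trials.
#' @export
response_lock <- function(epochs, window = c(-600, 200), baseline = NULL) {
  if (epochs$alignment != "stimulus") stop("epochs must be stimulus-aligned")
  dt <- 1000 / epochs$sfreq
  rel <- seq(window[1], window[2], by = dt)
  meta <- epochs$meta
  keep <- which(meta$valid & meta$responded & !is.na(meta$rt_ms))
  ok <- logical(length(keep))
  n_t <- length(epochs$time_ms)
  out <- array(NA_real_, dim = c(length(keep), dim(epochs$data)[2], length(rel)))
  for (k in seq_along(keep)) {
    i <- keep[k]
    r0 <- time_index(epochs$time_ms, meta$rt_ms[i])
    idx <- r0 + round(rel / dt)
    if (idx[1] >= 1 && idx[length(idx)] <= n_t) {
      ok[k] <- TRUE
      out[k, , ] <- epochs$data[i, , idx]
    }
  }
  res <- epoch_set(out[ok, , , drop = FALSE], rel, epochs$sfreq, "response",
                   epochs$channels, meta[keep[ok], , drop = FALSE],
                   baseline = epochs$baseline)
  if (!is.null(baseline)) res <- baseline_epochs(res, baseline)
  attr(res, "dropped") <- keep[!ok]
  res
}

#' Trial-average waveform of one channel
#'
#' @param epochs an `epoch_set`.
#' @param electrode channel label.
#' @param trials optional integer subset of (valid) trial rows to average.
#' @return a `waveform` object: list with `amplitude`, `time_ms`,
#'   `alignment`, `electrode`, `n_trials`.
#' @export
average_waveform <- function(epochs, electrode, trials = NULL) {
  m <- get_channel(epochs, electrode, valid_only = TRUE)
  if (!is.null(trials)) m <- m[trials, , drop = FALSE]
  if (nrow(m) == 0L) stop("no valid trials to average")
  waveform(colMeans(m), epochs$time_ms, epochs$alignment, electrode, nrow(m))
}

#' Construct a waveform object
#' @param amplitude numeric vector (uV per sample).
#' @param time_ms time axis in ms.
#' @param alignment `"stimulus"` or `"response"`.
#' @param electrode channel label.
#' @param n_trials number of trials averaged.
#' @return object of class `waveform`.
#' @export
waveform <- function(amplitude, time_ms, alignment, electrode, n_trials = 1L) {
  stopifnot(length(amplitude) == length(time_ms), n_trials > 0)
  structure(list(amplitude = amplitude, time_ms = time_ms,
                 alignment = alignment, electrode = electrode,
                 n_trials = n_trials),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s, %s-aligned, %d samples, %d trials\n",
              x$electrode, x$alignment, length(x$amplitude), x$n_trials))
  invisible(x)
}
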