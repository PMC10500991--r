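# Shared fixture builders. Everything is generated in code; no data files.

# Tiny cohort configuration for fast tests.
tiny_config <- function(..., trials_per_subject = 60, noise_sd = 0,
                        seed = 42L) {
  cohort_config(n_older = 3, n_younger = 2,
                trials_per_subject = trials_per_subject,
                noise_sd = noise_sd, seed = seed, ...)
}

# Build an epoch_set directly from a per-trial signal function.
# signal_fun(t_ms, trial) -> amplitude vector; same signal on every listed
# channel unless channel_fun is given.
make_epochs <- function(signal_fun, n_trials = 20,
                        channels = c("Pz", "C3", "P7", "P8"),
                        sfreq = 500, window = c(-200, 1500),
                        rt_ms = rep(600, n_trials),
                        hemifield = rep(c("left", "right"), length.out = n_trials),
                        alignment = "stimulus", channel_fun = NULL) {
  t_ms <- seq(window[1], window[2], by = 1000 / sfreq)
  dat <- array(0, dim = c(n_trials, length(channels), length(t_ms)))
  for (i in seq_len(n_trials)) {
    for (ci in seq_along(channels)) {
      dat[i, ci, ] <- if (is.null(channel_fun)) {
        signal_fun(t_ms, i)
      } else {
        channel_fun(t_ms, i, channels[ci])
      }
    }
  }
  meta <- data.frame(rt_ms = rt_ms, responded = !is.na(rt_ms),
                     hemifield = hemifield,
                     direction = rep("up", n_trials),
                     iti_s = rep(1.8, n_trials),
                     valid = TRUE, exclusion_reason = NA_character_,
                     stringsAsFactors = FALSE)
  epoch_set(dat, t_ms, sfreq, alignment, channels, meta)
}

# One simulated subject with planted signals; returns subject row,
# behaviour and (optionally excluded) epochs.
make_subject <- function(config = tiny_config(), idx = 1, seed = 7L,
                         exclude = TRUE) {
  subj <- draw_cohort(config)
  s <- subj[idx, ]
  beh <- simulate_behavior(s, config, seed = seed)
  ep <- synthesize_epochs(s, beh, config, seed = seed + 1000L)
  if (exclude) ep <- exclude_trials(ep)
  list(params = s, behavior = beh, epochs = ep)
}

# Analytic TSE expectation of a known envelope: 2/pi times the envelope
# averaged over each smoothing window (the rectified-carrier mean).
expected_tse <- function(env_fun, centers, half = 50) {
  vapply(centers, function(ct) {
    tt <- seq(ct - half, ct + half, by = 2)
    2 / pi * mean(env_fun(tt))
  }, numeric(1))
}

# Planted C3 envelope for a responded trial of the synthetic generator.
planted_envelope <- function(t_ms, rt, depth, base = 1.5, fall = 300) {
  ifelse(t_ms < 0, base,
  ifelse(t_ms <= rt, base - depth * t_ms / rt,
         pmin(base, base - depth * pmax(0, 1 - (t_ms - rt) / fall))))
}
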