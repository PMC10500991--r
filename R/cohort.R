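#' Configuration for a synthetic response-speed cohort
#'
#' Bundles the task design (trial types, timings, channels) and the
#' generator's cohort-level coupling. The moderation coefficients link each
#' subject's mean RT (ms) to their true CPP build-up rate and leisure-based
#' environmental-enrichment score via
#' `RT = i1 + b1*slope + b2*EE + b3*slope*EE + noise`; defaults are the
#' published moderation estimates (intercept 1259.45, slope -5420.91,
#' EE -4.34, interaction 32.00).
#'
#' @param n_older,n_younger subject counts per group (defaults 41 / 31).
#' @param trials_per_subject trials per subject; must be divisible by 12 so
#'   the ITI x hemifield x direction design is balanced.
#' @param sampling_rate EEG sampling rate, Hz.
#' @param channels channel labels; must include Pz, C3, P7, P8.
#' @param iti_set random-motion foreperiods in s.
#' @param target_duration coherent-motion duration, s.
#' @param deadline response deadline, ms.
#' @param moderation_coeffs named numeric `c(i1, b1, b2, b3)`.
#' @param rt_noise_sd between-subject residual SD of mean RT, ms.
#' @param noise_sd additive white-noise SD per EEG sample, uV.
#' @param epoch_window stimulus-locked epoch window, ms.
#' @param seed integer seed for all draws derived from this config.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_older = 41, n_younger = 31,
                          trials_per_subject = 168,
                          sampling_rate = 500,
                          channels = c("Pz", "C3", "P7", "P8"),
                          iti_set = c(1.8, 2.8, 3.8),
                          target_duration = 3.0,
                          deadline = 1800,
                          moderation_coeffs = c(i1 = 1259.45, b1 = -5420.91,
                                                b2 = -4.34, b3 = 32.00),
                          rt_noise_sd = 90,
                          noise_sd = 15,
                          epoch_window = c(-200, 1500),
                          seed = 1L) {
  if (n_older <= 0 || n_younger <= 0 || trials_per_subject <= 0) {
    stop("subject and trial counts must be positive")
  }
  if (trials_per_subject %% 12 != 0) {
    stop("trials_per_subject must be divisible by 12 (3 ITIs x 2 hemifields x 2 directions)")
  }
  required <- c("Pz", "C3", "P7", "P8")
  if (!all(required %in% channels)) {
    stop("channels must include ", paste(setdiff(required, channels), collapse = ", "))
  }
  stopifnot(length(moderation_coeffs) == 4, rt_noise_sd >= 0, noise_sd >= 0,
            deadline > 0, sampling_rate > 0)
  names(moderation_coeffs) <- c("i1", "b1", "b2", "b3")
  structure(list(
    n_older = n_older, n_younger = n_younger,
    trials_per_subject = trials_per_subject,
    sampling_rate = sampling_rate, channels = channels,
    iti_set = iti_set, target_duration = target_duration,
    deadline = deadline, moderation_coeffs = moderation_coeffs,
    rt_noise_sd = rt_noise_sd, noise_sd = noise_sd,
    epoch_window = epoch_window, seed = as.integer(seed)
  ), class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Draw per-subject generative parameters for a cohort
#'
#' Older subjects get shallower true CPP build-up rates, later CPP onsets,
#' later N2c latencies and higher response caution than younger subjects,
#' mimicking the published group structure. Each subject's target mean RT is
#' produced by the moderation equation in [cohort_config()] and the drift
#' rate is then derived as `v = a / (RT/1000 - t0)` so that the one-boundary
#' diffusion reproduces that mean RT in expectation.
#'
#' @param config a [cohort_config()].
#' @return data.frame of class `subject_params`, one row per subject.
#' @export
draw_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_o <- config$n_older
  n_y <- config$n_younger
  n <- n_o + n_y
  group <- c(rep("older", n_o), rep("younger", n_y))
  older <- group == "older"

  age <- numeric(n)
  age[older] <- round(rnorm_trunc(n_o, 73, 5, 63, 87))
  age[!older] <- round(rnorm_trunc(n_y, 24, 3, 19, 28))

  # CRI subscales: leisure centred on the published older-cohort median (138)
  cri_leisure <- rnorm_trunc(n, 138, 20, 80, 200)
  cri_education <- rnorm_trunc(n, 120, 15, 70, 180)
  cri_occupation <- rnorm_trunc(n, 115, 15, 70, 180)

  cpp_slope_true <- numeric(n)
  cpp_slope_true[older] <- rnorm_trunc(n_o, 0.0724, 0.069, 0.005, 0.20)
  cpp_slope_true[!older] <- rnorm_trunc(n_y, 0.1100, 0.070, 0.010, 0.25)

  cpp_onset_true <- numeric(n)
  cpp_onset_true[older] <- rnorm_trunc(n_o, 350, 50, 150, 600)
  cpp_onset_true[!older] <- rnorm_trunc(n_y, 280, 40, 150, 600)

  n2c_latency_true <- numeric(n)
  n2c_latency_true[older] <- rnorm_trunc(n_o, 300, 30, 200, 350)
  n2c_latency_true[!older] <- rnorm_trunc(n_y, 260, 30, 200, 350)
  n2c_amp_true <- rnorm_trunc(n, -2.8, 0.8, -6, -0.5)

  lhb_depth_true <- rnorm_trunc(n, 0.8, 0.2, 0.2, 1.4)

  v <- numeric(n)
  v[older] <- rnorm_trunc(n_o, 7.38, 2.05, 2.5, 15)
  v[!older] <- rnorm_trunc(n_y, 8.49, 1.99, 2.5, 15)
  t0 <- numeric(n)
  t0[older] <- rnorm_trunc(n_o, 0.11, 0.06, 0.03, 0.25)
  t0[!older] <- rnorm_trunc(n_y, 0.10, 0.03, 0.03, 0.25)

  cf <- config$moderation_coeffs
  mean_rt <- cf["i1"] + cf["b1"] * cpp_slope_true + cf["b2"] * cri_leisure +
    cf["b3"] * cpp_slope_true * cri_leisure +
    stats::rnorm(n, 0, config$rt_noise_sd)
  mean_rt <- pmin(pmax(mean_rt, 250), 1400)
  # decision time must stay positive: keep at least 80 ms above t0
  decision_s <- pmax(mean_rt / 1000 - t0, 0.08)
  # response caution absorbs the subject's mean decision time so that
  # E[RT] = t0 + a/v reproduces the moderation equation exactly, while v
  # keeps the published group structure (older drift lower on average)
  a <- pmin(pmax(v * decision_s, 0.8), 8)
  v <- a / decision_s
  # The accumulation ramp must be underway well before even the fastest
  # plausible response, or neither the planted slope nor the planted onset
  # could be read back out of the epochs: cap each onset 150 ms (the depth
  # of the build-up-rate window) below the subject's 1e-4 RT quantile
  # (floor 50 ms; faster subjects fall outside the generator's recoverable
  # regime, see the methods vignette).
  rt_q <- vapply(seq_len(n), function(i) {
    qwald(1e-4, a = a[i], v = v[i], t0 = t0[i])
  }, numeric(1))
  cpp_onset_true <- pmax(pmin(cpp_onset_true, rt_q * 1000 - 150), 50)

  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, age = age,
    v = unname(v), a = a, t0 = t0,
    cpp_slope_true = cpp_slope_true, cpp_onset_true = cpp_onset_true,
    n2c_latency_true = n2c_latency_true, n2c_amp_true = n2c_amp_true,
    lhb_depth_true = lhb_depth_true,
    cri_leisure = cri_leisure, cri_education = cri_education,
    cri_occupation = cri_occupation,
    mean_rt_target = unname(mean_rt),
    noise_sd = config$noise_sd,
    stringsAsFactors = FALSE
  )
  class(out) <- c("subject_params", "data.frame")
  out
}

#' Build the balanced trial design for one subject
#' @keywords internal
trial_design <- function(config, shuffle = TRUE) {
  base <- expand.grid(iti_s = config$iti_set,
                      hemifield = c("left", "right"),
                      direction = c("up", "down"),
                      stringsAsFactors = FALSE)
  reps <- config$trials_per_subject / nrow(base)
  d <- base[rep(seq_len(nrow(base)), reps), ]
  if (shuffle) d <- d[sample.int(nrow(d)), ]
  rownames(d) <- NULL
  d
}

#' Simulate one subject's detection behaviour
#'
#' RTs are first-passage times of a one-boundary diffusion with unit
#' within-trial noise: `t0` plus an inverse-Gaussian (shifted-Wald) draw
#' with mean `a/v` and shape `a^2`. Trials whose passage time exceeds the
#' deadline are misses. `method = "euler"` instead simulates discretised
#' paths (the independent oracle route).
#'
#' @param subject one row of the [draw_cohort()] frame (or any list with
#'   `a`, `v`, `t0`).
#' @param config a [cohort_config()].
#' @param method `"wald"` (closed-form sampler, default) or `"euler"`.
#' @param seed optional integer; when `NULL` the current RNG stream is used.
#' @return a `subject_behavior` object: list with `trials` (data.frame:
#'   `iti_s`, `hemifield`, `direction`, `rt_ms`, `responded`), `accuracy`,
#'   `n_valid`, `subject_id`.
#' @export
simulate_behavior <- function(subject, config, method = c("wald", "euler"),
                              seed = NULL) {
  method <- match.arg(method)
  stopifnot(subject$a > 0, subject$v > 0, subject$t0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  design <- trial_design(config)
  n <- nrow(design)
  if (method == "wald") {
    rt_s <- subject$t0 + rinvgauss(n, mean = subject$a / subject$v,
                                   shape = subject$a^2)
  } else {
    rt_s <- simulate_ddm(subject$a, subject$v, subject$t0, n,
                         deadline_s = config$deadline / 1000, dt = 0.001)$rt_s
  }
  rt_ms <- rt_s * 1000
  responded <- !is.na(rt_ms) & rt_ms < config$deadline
  rt_ms[!responded] <- NA_real_
  design$rt_ms <- rt_ms
  design$responded <- responded
  structure(list(trials = design,
                 accuracy = mean(responded),
                 n_valid = sum(responded),
                 subject_id = subject$subject_id %||% "S000"),
            class = "subject_behavior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-Gaussian random variates
#'
#' Michael-Schucany-Haas transformation sampler; parameterised by mean
#' `mu = a/v` and shape `lambda = a^2` for the unit-noise diffusion.
#' @param n number of draws.
#' @param mean,shape distribution parameters (both > 0).
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  stopifnot(mean > 0, shape > 0)
  y <- stats::rnorm(n)^2
  x <- mean + (mean^2 * y) / (2 * shape) -
    (mean / (2 * shape)) * sqrt(4 * mean * shape * y + mean^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mean / (mean + x), x, mean^2 / x)
}

#' Synthesize an epoched EEG block for one subject
#'
#' Plants the three decision signals the metric extractors target:
#' \itemize{
#'   \item Pz: a CPP that is zero until `cpp_onset_true`, ramps linearly at
#'     `cpp_slope_true` (uV/ms) to a peak at the trial's RT, then decays
#'     linearly back to zero over 300 ms (responded trials only);
#'   \item P7/P8: a Gaussian negativity (SD 42.5 ms, i.e. ~100 ms FWHM) of
#'     amplitude `n2c_amp_true` centred at `n2c_latency_true` on the
#'     electrode contralateral to the target hemifield;
#'   \item C3: a 25 Hz carrier whose envelope declines linearly from 1.5 uV
#'     at target onset to `1.5 - lhb_depth_true` at RT, recovering over
#'     300 ms (misses keep a flat envelope).
#' }
#' Independent Gaussian noise of SD `noise_sd` is added per sample, and the
#' result is baselined over -100..0 ms.
#'
#' @param subject one row of [draw_cohort()].
#' @param behavior matching [simulate_behavior()] output.
#' @param config a [cohort_config()].
#' @param noise_sd per-sample noise SD (uV); default from `subject`.
#' @param pink use 1/f-shaped rather than white noise.
#' @param seed optional integer seed.
#' @return a stimulus-aligned, baselined `epoch_set`.
#' @export
synthesize_epochs <- function(subject, behavior, config,
                              noise_sd = subject$noise_sd,
                              pink = FALSE, seed = NULL) {
  stopifnot(inherits(behavior, "subject_behavior"))
  if (!is.null(seed)) set.seed(seed)
  required <- c("Pz", "C3", "P7", "P8")
  if (!all(required %in% config$channels)) {
    stop("config channels must include ", paste(required, collapse = ", "))
  }
  dt <- 1000 / config$sampling_rate
  t_ms <- seq(config$epoch_window[1], config$epoch_window[2], by = dt)
  n_t <- length(t_ms)
  trials <- behavior$trials
  n_tr <- nrow(trials)
  chs <- config$channels
  dat <- array(0, dim = c(n_tr, length(chs), n_t))
  i_pz <- match("Pz", chs); i_c3 <- match("C3", chs)
  i_p7 <- match("P7", chs); i_p8 <- match("P8", chs)

  beta_base <- 1.5
  carrier_f <- 25 / 1000 # cycles per ms
  n2c_sd <- 42.5
  fall_ms <- 300

  for (i in seq_len(n_tr)) {
    rt <- trials$rt_ms[i]
    # CPP at Pz (responded trials only). The ramp tops out 50 ms after the
    # response -- the upper edge of the build-up-rate window -- so the
    # -150..+50 ms slope fit sees a pure line on noiseless data. On
    # unusually fast trials the ramp start is pulled forward to keep at
    # least 200 ms of build-up before the response, so the slope window
    # never straddles the flat pre-onset segment.
    if (trials$responded[i]) {
      onset <- min(subject$cpp_onset_true, rt - 200)
      top <- rt + 50
      peak <- subject$cpp_slope_true * (top - onset)
      ramp <- ifelse(t_ms < onset, 0,
              ifelse(t_ms <= top, subject$cpp_slope_true * (t_ms - onset),
                     pmax(0, peak * (1 - (t_ms - top) / fall_ms))))
      dat[i, i_pz, ] <- dat[i, i_pz, ] + ramp
    }
    # N2c contralateral to target hemifield
    i_n2 <- if (trials$hemifield[i] == "left") i_p8 else i_p7
    dat[i, i_n2, ] <- dat[i, i_n2, ] +
      subject$n2c_amp_true * exp(-(t_ms - subject$n2c_latency_true)^2 / (2 * n2c_sd^2))
    # beta envelope at C3
    if (trials$responded[i]) {
      env <- ifelse(t_ms < 0, beta_base,
             ifelse(t_ms <= rt, beta_base - subject$lhb_depth_true * t_ms / rt,
                    pmin(beta_base,
                         beta_base - subject$lhb_depth_true *
                           pmax(0, 1 - (t_ms - rt) / fall_ms))))
    } else {
      env <- rep(beta_base, n_t)
    }
    phase <- stats::runif(1, 0, 2 * pi)
    dat[i, i_c3, ] <- dat[i, i_c3, ] + env * sin(2 * pi * carrier_f * t_ms + phase)
  }
  if (noise_sd > 0) {
    noise <- if (pink) {
      array(pink_noise(n_tr * length(chs) * n_t, config$sampling_rate) * noise_sd,
            dim = dim(dat))
    } else {
      array(stats::rnorm(length(dat), 0, noise_sd), dim = dim(dat))
    }
    dat <- dat + noise
  }
  ep <- epoch_set(dat, t_ms, config$sampling_rate, "stimulus", chs,
                  meta = data.frame(trials,
                                    valid = TRUE,
                                    exclusion_reason = NA_character_,
                                    stringsAsFactors = FALSE))
  baseline_epochs(ep, c(-100, 0))
}

#' 1/f-shaped noise via FFT spectrum shaping
#' @keywords internal
pink_noise <- function(n, sfreq) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) # avoid division by zero at DC
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate a full cohort
#'
#' Convenience wrapper: draws subject parameters, simulates behaviour and
#' (optionally) EEG epochs for every subject, with per-subject seeds derived
#' deterministically from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param epochs also synthesize EEG epochs (slower).
#' @return list with `config`, `subjects`, `behaviors` (list), and
#'   `epochs` (list or NULL).
#' @export
simulate_cohort <- function(config, epochs = TRUE) {
  subjects <- draw_cohort(config)
  behaviors <- vector("list", nrow(subjects))
  eps <- if (epochs) vector("list", nrow(subjects)) else NULL
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    seed_i <- (config$seed * 1000L + i) %% .Machine$integer.max
    behaviors[[i]] <- simulate_behavior(s, config, seed = seed_i)
    if (epochs) {
      eps[[i]] <- synthesize_epochs(s, behaviors[[i]], config,
                                    seed = seed_i + 500000L)
    }
  }
  names(behaviors) <- subjects$subject_id
  if (epochs) names(eps) <- subjects$subject_id
  list(config = config, subjects = subjects, behaviors = behaviors,
       epochs = eps)
}
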