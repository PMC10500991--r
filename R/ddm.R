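#' Shifted-Wald (one-boundary diffusion) density and distribution
#'
#' First-passage time law of a single-accumulator diffusion with bound `a`,
#' drift `v` and unit within-trial noise, shifted by the nondecision time
#' `t0`: the inverse-Gaussian density
#' `a / sqrt(2*pi*x^3) * exp(-(a - v*x)^2 / (2*x))` with `x = rt - t0`.
#' For `v > 0` the CDF reaches 1; `rt <= t0` has density and probability 0.
#'
#' @param rt response time(s), s.
#' @param a bound (response caution), > 0.
#' @param v drift rate (evidence/s), > 0 for a proper distribution.
#' @param t0 nondecision time, s.
#' @return numeric vector of densities (`dwald`) or cumulative
#'   probabilities (`pwald`).
#' @export
dwald <- function(rt, a, v, t0 = 0) {
  stopifnot(a > 0)
  x <- rt - t0
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  out[pos] <- a / sqrt(2 * pi * xp^3) * exp(-(a - v * xp)^2 / (2 * xp))
  out
}

#' @rdname dwald
#' @export
pwald <- function(rt, a, v, t0 = 0) {
  stopifnot(a > 0)
  x <- rt - t0
  out <- numeric(length(x))
  pos <- which(x > 0)
  xp <- x[pos]
  sq <- sqrt(xp)
  # second term computed on the log scale: exp(2av) overflows for large a*v
  term1 <- stats::pnorm((v * xp - a) / sq)
  term2 <- exp(2 * a * v + stats::pnorm(-(v * xp + a) / sq, log.p = TRUE))
  out[pos] <- pmin(1, term1 + term2)
  out
}

#' Shifted-Wald quantile function
#'
#' Inverse of [pwald()] by bisection; used to place planted EEG components
#' safely below the fast tail of a subject's RT distribution.
#'
#' @param p probability in (0, 1).
#' @param a,v,t0 diffusion parameters.
#' @return the RT (s) at cumulative probability `p`.
#' @export
qwald <- function(p, a, v, t0 = 0) {
  stopifnot(p > 0, p < 1)
  upper <- t0 + a / v
  while (pwald(upper, a, v, t0) < p) upper <- t0 + (upper - t0) * 2
  stats::uniroot(function(x) pwald(x, a, v, t0) - p,
                 lower = t0 + 1e-12, upper = upper, tol = 1e-10)$root
}

#' Euler-Maruyama simulation of the one-boundary diffusion
#'
#' Independent oracle for [pwald()] and the path-simulation behaviour mode:
#' accumulates `v*dt + sqrt(dt)*N(0,1)` from 0 until the bound `a` is
#' crossed or `deadline_s` is reached (a miss, `NA`). Within-step excursions
#' above the bound are caught by the Brownian-bridge crossing probability
#' `exp(-2*(a - x_old)*(a - x_new)/dt)`, removing the O(sqrt(dt))
#' first-passage bias of the naive scheme.
#'
#' @param a,v,t0 diffusion parameters (unit noise scaling).
#' @param n number of trials.
#' @param deadline_s response deadline in s (passage after it is a miss).
#' @param dt integration step, s.
#' @param seed optional integer seed.
#' @return list with `rt_s` (NA for misses) and `p_miss`.
#' @export
simulate_ddm <- function(a, v, t0, n, deadline_s = 1.8, dt = 0.001,
                         seed = NULL) {
  stopifnot(a > 0, t0 >= 0, dt > 0, deadline_s > t0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- ceiling((deadline_s - t0) / dt)
  rt <- rep(NA_real_, n)
  x <- numeric(n)
  active <- seq_len(n)
  sdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    x_old <- x[active]
    x_new <- x_old + v * dt + sdt * stats::rnorm(length(active))
    hit <- x_new >= a
    bridge <- !hit
    if (any(bridge)) {
      p_cross <- exp(-2 * (a - x_old[bridge]) * (a - x_new[bridge]) / dt)
      hit[bridge] <- stats::runif(sum(bridge)) < p_cross
    }
    x[active] <- x_new
    crossed <- active[hit]
    if (length(crossed)) {
      rt[crossed] <- t0 + s * dt
      active <- active[!hit]
      if (!length(active)) break
    }
  }
  rt[!is.na(rt) & rt > deadline_s] <- NA_real_
  list(rt_s = rt, p_miss = mean(is.na(rt)))
}

#' Observed RT quantile bins
#'
#' Splits the responded-trial RT distribution at the quantiles 0.1, 0.3,
#' 0.5, 0.7, 0.9. The five cutpoints delimit six response intervals with
#' observed proportions 0.1, 0.2, 0.2, 0.2, 0.2, 0.1 of responders; a miss
#' bin is appended, so observed and expected frequencies both sum to the
#' total trial count. (Descriptions of this layout often count "five
#' response bins" by omitting the upper tail interval whose proportion the
#' quantile construction fixes at 0.1.)
#'
#' @param behavior a `subject_behavior` (or data.frame with `rt_ms` and
#'   `responded`).
#' @param deadline response deadline, ms.
#' @param probs interior quantiles.
#' @return object of class `quantile_bins`: list with `quantiles`,
#'   `cutpoints` (s), `observed` (7 frequencies, miss bin last),
#'   `expected` (NULL until [expected_frequencies()]), `n_total`.
#' @export
bin_observed <- function(behavior, deadline = 1800,
                         probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  trials <- if (inherits(behavior, "subject_behavior")) behavior$trials else behavior
  rt_s <- trials$rt_ms[trials$responded] / 1000
  n_resp <- length(rt_s)
  n_miss <- sum(!trials$responded)
  if (n_resp < 10) stop("need at least 10 responded trials to bin")
  cuts <- stats::quantile(rt_s, probs, type = 7, names = FALSE)
  if (any(diff(cuts) <= 0)) stop("degenerate RT quantiles (ties across cutpoints)")
  obs <- c(probs[1], diff(probs), 1 - probs[length(probs)]) * n_resp
  structure(list(quantiles = probs, cutpoints = cuts,
                 observed = c(obs, n_miss), expected = NULL,
                 n_total = n_resp + n_miss,
                 deadline_s = deadline / 1000),
            class = "quantile_bins")
}

#' Expected bin frequencies under a shifted-Wald fit
#'
#' `E_i = n_total * (F(c_i) - F(c_(i-1)))` over the response bins with
#' `c_0 = 0` and `c_5 = deadline`, and `E_miss = n_total * (1 - F(deadline))`.
#' Expected counts are floored at 1e-10 so the G-square log stays finite.
#'
#' @param params list/vector with `a`, `v`, `t0`.
#' @param bins a `quantile_bins` from [bin_observed()].
#' @return `bins` with the `expected` side filled in.
#' @export
expected_frequencies <- function(params, bins) {
  edges <- c(0, bins$cutpoints, bins$deadline_s)
  Fv <- pwald(edges, params[["a"]], params[["v"]], params[["t0"]])
  p <- diff(Fv)
  e <- c(p, 1 - Fv[length(Fv)]) * bins$n_total
  bins$expected <- pmax(e, 1e-10)
  bins
}

#' Likelihood-ratio goodness-of-fit statistic
#'
#' `G2 = 2 * sum(O_i * ln(O_i / E_i))` over the six bins; empty observed
#' bins contribute zero.
#'
#' @param bins a `quantile_bins` with both sides filled.
#' @return the G-square value.
#' @export
g_square <- function(bins) {
  o <- bins$observed; e <- bins$expected
  if (is.null(e)) stop("expected frequencies not computed")
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / e[nz]))
}

#' Fit the detection diffusion model by G-square minimisation
#'
#' Minimises [g_square()] over (a, v, t0) with Powell's method from a small
#' multi-start grid (default 3 x 3 x 3 over plausible caution, drift and
#' nondecision values, with t0 capped below the fastest observed RT).
#' Infeasible parameters are penalised, keeping the objective finite
#' everywhere.
#'
#' @param behavior a `subject_behavior` (or trial data.frame).
#' @param deadline response deadline, ms.
#' @param init_grid optional data.frame of starts with columns `a`, `v`,
#'   `t0`.
#' @param ... passed to [bin_observed()].
#' @return object of class `ddm_fit`: list with `a`, `v`, `t0`, `g2`,
#'   `converged`, `n_starts_used`, `bins`.
#' @export
fit_ddm <- function(behavior, deadline = 1800, init_grid = NULL, ...) {
  bins <- bin_observed(behavior, deadline = deadline, ...)
  trials <- if (inherits(behavior, "subject_behavior")) behavior$trials else behavior
  min_rt <- min(trials$rt_ms[trials$responded]) / 1000
  if (is.null(init_grid)) {
    init_grid <- expand.grid(a = c(1, 2, 3.5),
                             v = c(4, 8, 14),
                             t0 = c(0.3, 0.6, 0.9) * min_rt)
  }
  obj <- function(p) {
    if (p[1] <= 0 || p[2] <= 0 || p[3] < 0 || p[3] >= min_rt) return(1e10)
    g_square(expected_frequencies(list(a = p[1], v = p[2], t0 = p[3]), bins))
  }
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(init_grid))) {
    start <- as.numeric(init_grid[i, c("a", "v", "t0")])
    res <- tryCatch(
      powell(start, obj, scale = c(0.5, 2, 0.05), tol = 1e-9, maxit = 100),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_used <- n_used + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all Powell starts failed for the G-square fit")
  structure(list(a = best$par[1], v = best$par[2], t0 = best$par[3],
                 g2 = best$value, converged = best$convergence == 0L,
                 n_starts_used = n_used, bins = bins),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> a = %.3f, v = %.3f, t0 = %.3f; G2 = %.3f (%s, %d starts)\n",
              x$a, x$v, x$t0, x$g2,
              if (x$converged) "converged" else "cycle limit",
              x$n_starts_used))
  invisible(x)
}
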