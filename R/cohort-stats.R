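#' Assemble the per-subject cohort table
#'
#' Joins subject parameters, behavioural summaries, neural metrics and DDM
#' fits into the one-row-per-subject substrate of the between-subject
#' statistics. Adds centred age (`age_c`).
#'
#' @param subjects [draw_cohort()] frame (or any data.frame with
#'   `subject_id`, `group`, `age`, CRI columns).
#' @param behaviors named list of `subject_behavior` objects.
#' @param metrics data.frame of [neural_metrics()] rows (same order), or
#'   NULL.
#' @param ddm_fits named list of `ddm_fit` objects, or NULL.
#' @return a `cohort_table` data.frame.
#' @export
build_cohort_table <- function(subjects, behaviors, metrics = NULL,
                               ddm_fits = NULL) {
  tab <- data.frame(
    subject_id = subjects$subject_id,
    group = subjects$group,
    age = subjects$age,
    age_c = subjects$age - mean(subjects$age),
    cri_leisure = subjects$cri_leisure,
    cri_education = subjects$cri_education,
    cri_occupation = subjects$cri_occupation,
    stringsAsFactors = FALSE
  )
  tab$cri_composite <- rowMeans(tab[, c("cri_leisure", "cri_education",
                                        "cri_occupation")])
  tab$mean_rt <- vapply(behaviors, function(b) {
    mean(b$trials$rt_ms[b$trials$responded])
  }, numeric(1))[tab$subject_id]
  tab$accuracy <- vapply(behaviors, function(b) b$accuracy,
                         numeric(1))[tab$subject_id]
  if (!is.null(metrics)) tab <- cbind(tab, metrics)
  if (!is.null(ddm_fits)) {
    tab$ddm_a <- vapply(ddm_fits, `[[`, numeric(1), "a")[tab$subject_id]
    tab$ddm_v <- vapply(ddm_fits, `[[`, numeric(1), "v")[tab$subject_id]
    tab$ddm_t0 <- vapply(ddm_fits, `[[`, numeric(1), "t0")[tab$subject_id]
    tab$ddm_g2 <- vapply(ddm_fits, `[[`, numeric(1), "g2")[tab$subject_id]
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Hierarchical (blockwise) linear regression with R-squared change
#'
#' Fits OLS models over cumulative predictor blocks and tests each block's
#' R-squared change with the nested-model F test. Standardised betas come
#' from refitting on z-scored outcome and predictors; raw-scale confidence
#' intervals are reported alongside.
#'
#' @param table data.frame of complete cases.
#' @param outcome outcome column name.
#' @param blocks list of character vectors, one per entry step.
#' @return object of class `hier_reg`: list of steps, each with `label`,
#'   `r2`, `adj_r2`, `r2_change`, `f_change`, `df_change`, `p_change`, and
#'   a `coefficients` data.frame (estimate, se, t, p, ci_lo, ci_hi,
#'   std_beta).
#' @export
hierarchical_regression <- function(table, outcome, blocks) {
  if (is.null(names(blocks))) {
    names(blocks) <- vapply(blocks, paste, "", collapse = "+")
  }
  terms_so_far <- character(0)
  prev_fit <- stats::lm(stats::reformulate("1", outcome), data = table)
  prev_r2 <- 0
  steps <- list()
  for (bi in seq_along(blocks)) {
    new_terms <- setdiff(blocks[[bi]], terms_so_far)
    terms_so_far <- c(terms_so_far, new_terms)
    fit <- stats::lm(stats::reformulate(terms_so_far, outcome), data = table)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient model; collinear terms: ", paste(bad, collapse = ", "))
    }
    sm <- summary(fit)
    r2 <- sm$r.squared
    an <- stats::anova(prev_fit, fit)
    f_change <- if (length(new_terms)) an$F[2] else 0
    p_change <- if (length(new_terms)) an$`Pr(>F)`[2] else 1
    df_change <- if (length(new_terms)) c(an$Df[2], an$Res.Df[2]) else c(0, an$Res.Df[1])
    # standardised refit
    zt <- table
    for (cn in c(outcome, terms_so_far)) {
      if (is.numeric(zt[[cn]])) zt[[cn]] <- as.numeric(scale(zt[[cn]]))
    }
    zfit <- stats::lm(stats::reformulate(terms_so_far, outcome), data = zt)
    ci <- stats::confint(fit)
    co <- sm$coefficients
    coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                        t = co[, 3], p = co[, 4],
                        ci_lo = ci[, 1], ci_hi = ci[, 2],
                        std_beta = stats::coef(zfit)[rownames(co)],
                        row.names = NULL)
    steps[[bi]] <- list(label = names(blocks)[bi], terms = terms_so_far,
                        r2 = r2, adj_r2 = sm$adj.r.squared,
                        r2_change = r2 - prev_r2,
                        f_change = if (is.na(f_change)) 0 else f_change,
                        df_change = df_change,
                        p_change = if (is.na(p_change)) 1 else p_change,
                        coefficients = coefs, fit = fit)
    prev_fit <- fit; prev_r2 <- r2
  }
  structure(steps, class = "hier_reg")
}

#' @export
print.hier_reg <- function(x, ...) {
  cat("<hier_reg> blockwise OLS\n")
  for (s in x) {
    cat(sprintf("  %-28s R2 = %.3f (adj %.3f)  dR2 = %.3f  F = %.2f  p = %.4g\n",
                s$label, s$r2, s$adj_r2, s$r2_change, s$f_change, s$p_change))
  }
  invisible(x)
}

#' Moderation (interaction) model with conditional effects
#'
#' OLS of `outcome ~ predictor * moderator (+ covariates)` on raw
#' (uncentred) variables, with the conditional effect of the predictor
#' probed at moderator mean - SD, mean, mean + SD. The conditional effect
#' at moderator value m is `b2 + b3 * m`, with SE from the coefficient
#' covariance.
#'
#' @param table cohort data.frame.
#' @param outcome,predictor,moderator column names.
#' @param covariates optional character vector of covariate columns.
#' @param center centre predictor and moderator before fitting.
#' @return object of class `moderation_result`: list with `coefficients`
#'   (i1, b1 = moderator, b2 = predictor, b3 = interaction),
#'   `conditional` data.frame, `r2`, `mse`, `f`, `df`, `p`, `n`.
#' @export
moderation <- function(table, outcome = "mean_rt", predictor = "cri_leisure",
                       moderator = "cpp_slope", covariates = NULL,
                       center = FALSE) {
  d <- data.frame(y = table[[outcome]], x = table[[predictor]],
                  m = table[[moderator]])
  if (center) { d$x <- d$x - mean(d$x); d$m <- d$m - mean(d$m) }
  form <- y ~ m + x + m:x
  if (!is.null(covariates)) {
    d <- cbind(d, table[covariates])
    form <- stats::reformulate(c("m", "x", "m:x", covariates), "y")
  }
  fit <- stats::lm(form, data = d)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  co <- sm$coefficients
  labels <- c("(Intercept)" = "i1", "m" = "b1_moderator", "x" = "b2_predictor",
              "m:x" = "b3_interaction")
  coefs <- data.frame(term = rownames(co),
                      role = unname(labels[rownames(co)]),
                      estimate = co[, 1], se = co[, 2], t = co[, 3],
                      p = co[, 4], ci_lo = ci[, 1], ci_hi = ci[, 2],
                      row.names = NULL)
  V <- stats::vcov(fit)
  b2 <- co["x", 1]; b3 <- co["m:x", 1]
  mv <- mean(d$m); sv <- stats::sd(d$m)
  probes <- c(mv - sv, mv, mv + sv)
  eff <- b2 + b3 * probes
  se_eff <- sqrt(V["x", "x"] + probes^2 * V["m:x", "m:x"] +
                 2 * probes * V["x", "m:x"])
  df_res <- fit$df.residual
  t_eff <- eff / se_eff
  conditional <- data.frame(
    moderator_value = probes,
    label = c("mean-1SD", "mean", "mean+1SD"),
    effect = eff, se = se_eff, t = t_eff,
    p = 2 * stats::pt(abs(t_eff), df_res, lower.tail = FALSE),
    ci_lo = eff - stats::qt(0.975, df_res) * se_eff,
    ci_hi = eff + stats::qt(0.975, df_res) * se_eff
  )
  fstat <- sm$fstatistic
  structure(list(coefficients = coefs, conditional = conditional,
                 r2 = sm$r.squared,
                 mse = sum(stats::residuals(fit)^2) / df_res,
                 f = unname(fstat[1]), df = unname(fstat[2:3]),
                 p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                 n = nrow(d), fit = fit),
            class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("<moderation_result> R2 = %.3f, MSE = %.2f, F(%g,%g) = %.2f, p = %.4g\n",
              x$r2, x$mse, x$df[1], x$df[2], x$f, x$p))
  print(x$coefficients, digits = 4)
  cat("conditional effects of predictor at moderator probes:\n")
  print(x$conditional, digits = 4)
  invisible(x)
}

# covariance-based slope paths for (x -> m, m -> y | x); rows of the idx
# matrix are bootstrap resamples
ab_paths <- function(x, m, y, idx = NULL) {
  if (is.null(idx)) {
    sxx <- stats::var(x); sxm <- stats::cov(x, m); smm <- stats::var(m)
    sxy <- stats::cov(x, y); smy <- stats::cov(m, y)
  } else {
    n <- ncol(idx)
    xb <- matrix(x[idx], nrow(idx)); mb <- matrix(m[idx], nrow(idx))
    yb <- matrix(y[idx], nrow(idx))
    cx <- xb - rowMeans(xb); cm <- mb - rowMeans(mb); cy <- yb - rowMeans(yb)
    sxx <- rowSums(cx * cx) / (n - 1); sxm <- rowSums(cx * cm) / (n - 1)
    smm <- rowSums(cm * cm) / (n - 1); sxy <- rowSums(cx * cy) / (n - 1)
    smy <- rowSums(cm * cy) / (n - 1)
  }
  a <- sxm / sxx
  det <- sxx * smm - sxm^2
  b <- (sxx * smy - sxm * sxy) / det
  # perfectly collinear x and m: y ~ m + x is singular; the mediator absorbs
  # the whole path, so b falls back to the simple m -> y slope
  sing <- det <= .Machine$double.eps * sxx * smm
  if (any(sing)) b[sing] <- (smy / smm)[sing]
  list(a = a, b = b, indirect = a * b)
}

#' Bootstrapped mediation (indirect effect)
#'
#' Indirect effect of `x` on `y` through `mediator`: the product of the
#' x -> mediator slope and the mediator -> y slope controlling for x.
#' Subjects are resampled with replacement; the percentile interval of the
#' resampled indirect effects is reported. Degenerate resamples (constant
#' x or mediator) are redrawn and counted.
#'
#' @param table cohort data.frame.
#' @param x,mediator,y column names.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for the resampling.
#' @param conf confidence level of the percentile interval.
#' @return object of class `mediation_result`: list with `indirect`,
#'   `boot_se`, `ci`, `a`, `b`, `n_boot`, `n_redrawn`, `seed`.
#' @export
mediation_bootstrap <- function(table, x, mediator, y, n_boot = 5000,
                                seed = 1L, conf = 0.95) {
  xv <- table[[x]]; mv <- table[[mediator]]; yv <- table[[y]]
  n <- length(xv)
  if (n < 10) stop("need at least 10 subjects for mediation")
  point <- ab_paths(xv, mv, yv)
  set.seed(seed)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
  n_redrawn <- 0L
  repeat {
    bad <- which(apply(idx, 1, function(r) length(unique(xv[r])) < 2 ||
                                            length(unique(mv[r])) < 2))
    if (!length(bad)) break
    n_redrawn <- n_redrawn + length(bad)
    idx[bad, ] <- sample.int(n, length(bad) * n, replace = TRUE)
  }
  boots <- ab_paths(xv, mv, yv, idx)$indirect
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  structure(list(indirect = point$indirect, a = point$a, b = point$b,
                 boot_se = stats::sd(boots), ci = ci, n_boot = n_boot,
                 n_redrawn = n_redrawn, seed = seed, boots = boots),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> indirect = %.3f (a = %.3f, b = %.3f), boot SE = %.3f, CI [%.3f, %.3f], %d resamples\n",
              x$indirect, x$a, x$b, x$boot_se, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' One-way group comparison
#'
#' One-way ANOVA with partial eta-squared
#' (`SS_effect / (SS_effect + SS_error)`; identical to eta-squared with a
#' single factor), plus Student and Welch t variants for two groups.
#'
#' @param values numeric outcome.
#' @param group factor/character group labels.
#' @return list of class `group_comparison` with `f`, `df`, `p`,
#'   `partial_eta2`, `t_student`, `t_welch` (NULL unless two groups).
#' @export
group_compare <- function(values, group) {
  group <- factor(group)
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  ss_eff <- an["group", "Sum Sq"]; ss_err <- an["Residuals", "Sum Sq"]
  out <- list(f = an["group", "F value"],
              df = c(an["group", "Df"], an["Residuals", "Df"]),
              p = an["group", "Pr(>F)"],
              partial_eta2 = ss_eff / (ss_eff + ss_err),
              t_student = NULL, t_welch = NULL)
  if (nlevels(group) == 2) {
    out$t_student <- stats::t.test(values ~ group, var.equal = TRUE)
    out$t_welch <- stats::t.test(values ~ group, var.equal = FALSE)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%g,%g) = %.3f, p = %.4g, partial eta2 = %.3f\n",
              x$df[1], x$df[2], x$f, x$p, x$partial_eta2))
  invisible(x)
}

#' JZS Bayes factor t test
#'
#' Bayes factor (BF10) for a one-sample or independent-samples t test with
#' the Jeffreys-Zellner-Siow prior: a Cauchy prior of scale `cauchy_scale`
#' on the standardised effect size. Computed by numerical integration of
#' the noncentral-t likelihood over the prior; directional tests restrict
#' the prior to a half-line.
#'
#' @param x numeric sample (or first sample).
#' @param y optional second sample (independent-samples test).
#' @param mu null value (one-sample only).
#' @param cauchy_scale prior scale (default 0.707 = sqrt(2)/2).
#' @param direction `"two.sided"`, `"greater"` or `"less"` (sign of the
#'   effect under the alternative).
#' @return list of class `bf_ttest` with `bf10`, `t`, `df`, `n_eff`.
#' @export
jzs_bf_ttest <- function(x, y = NULL, mu = 0, cauchy_scale = 0.707,
                         direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (is.null(y)) {
    if (length(x) < 3) stop("need at least 3 observations")
    n_eff <- length(x)
    df <- n_eff - 1
    tt <- (mean(x) - mu) / (stats::sd(x) / sqrt(n_eff))
  } else {
    if (length(x) < 3 || length(y) < 3) stop("need at least 3 observations per group")
    n1 <- length(x); n2 <- length(y)
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
    tt <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  }
  bf <- jzs_bf_from_t(tt, n_eff, df, cauchy_scale, direction)
  structure(list(bf10 = bf, t = tt, df = df, n_eff = n_eff,
                 direction = direction, cauchy_scale = cauchy_scale),
            class = "bf_ttest")
}

#' @export
print.bf_ttest <- function(x, ...) {
  cat(sprintf("<bf_ttest> t = %.3f (df = %g), BF10 = %.4g (%s, scale %.3f)\n",
              x$t, x$df, x$bf10, x$direction, x$cauchy_scale))
  invisible(x)
}

#' JZS Bayes factor from a t statistic
#'
#' @param t observed t statistic.
#' @param n_eff effective sample size (n, or n1*n2/(n1+n2)).
#' @param df degrees of freedom.
#' @param cauchy_scale Cauchy prior scale on effect size.
#' @param direction sidedness of the alternative.
#' @return BF10 (alternative over null).
#' @export
jzs_bf_from_t <- function(t, n_eff, df, cauchy_scale = 0.707,
                          direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  null_lik <- stats::dt(t, df)
  bf <- NA_real_
  if (abs(t) < 30 && null_lik > 1e-280) {
    integrand <- function(delta) {
      suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n_eff))) *
        stats::dcauchy(delta, 0, cauchy_scale)
    }
    lims <- switch(direction,
                   two.sided = c(-Inf, Inf),
                   greater = c(0, Inf),
                   less = c(-Inf, 0))
    alt_lik <- stats::integrate(integrand, lims[1], lims[2],
                                rel.tol = 1e-8, stop.on.error = FALSE)$value
    if (direction != "two.sided") alt_lik <- 2 * alt_lik # renormalised half-Cauchy
    bf <- alt_lik / null_lik
  }
  if (!is.finite(bf) || bf <= 0) {
    # extreme t: the noncentral-t route underflows; use the numerically
    # stable inverse-gamma mixture form on the log scale. For |t| this
    # large the posterior mass sits entirely on the observed sign, so the
    # directional factor is 2 (matching sign) or ~0 (opposing sign).
    r2 <- cauchy_scale^2
    log_num <- function(g) {
      -0.5 * log1p(n_eff * g * r2) -
        (df + 1) / 2 * log1p(t^2 / (df * (1 + n_eff * g * r2))) -
        0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g)
    }
    log_den <- -(df + 1) / 2 * log1p(t^2 / df)
    g_mode <- max(t^2 / n_eff / r2, 1)
    c0 <- log_num(g_mode)
    val <- stats::integrate(function(g) exp(log_num(g) - c0), 0, Inf,
                            rel.tol = 1e-9, stop.on.error = FALSE)$value
    bf <- exp(c0 + log(val) - log_den)
    if (direction == "greater") bf <- if (t > 0) 2 * bf else 0
    if (direction == "less") bf <- if (t < 0) 2 * bf else 0
  }
  bf
}

#' Percentage of adult life spent on an activity
#'
#' `(years / (age - 18)) * 100`; values above 100 are permitted because
#' questionnaire rounding can inflate activity years.
#'
#' @param years_activity years of engagement.
#' @param age age in years, > 18.
#' @return percentage.
#' @export
life_percentage <- function(years_activity, age) {
  if (any(age <= 18)) stop("age must exceed 18")
  years_activity / (age - 18) * 100
}
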