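test_that("hierarchical regression tracks R2 change with the nested F test", {
  set.seed(21)
  n <- 100
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 2 * d$x1 + d$x2 + rnorm(n)
  hr <- hierarchical_regression(d, "y", list(A = "x1", B = "x2", C = "x3"))

  # R2 is non-decreasing and changes sum to the full-model R2
  r2 <- vapply(hr, `[[`, numeric(1), "r2")
  expect_true(all(diff(r2) >= -1e-12))
  expect_equal(sum(vapply(hr, `[[`, numeric(1), "r2_change")), r2[3],
               tolerance = 1e-12)

  # independent nested-model F oracle for step 2
  f1 <- lm(y ~ x1, d); f2 <- lm(y ~ x1 + x2, d)
  rss1 <- sum(resid(f1)^2); rss2 <- sum(resid(f2)^2)
  f_oracle <- (rss1 - rss2) / (rss2 / f2$df.residual)
  expect_equal(hr[[2]]$f_change, f_oracle, tolerance = 1e-10)
  expect_equal(hr[[2]]$p_change,
               pf(f_oracle, 1, f2$df.residual, lower.tail = FALSE),
               tolerance = 1e-10)

  # standardized betas within 2 SE of the population values
  bx1 <- hr[[3]]$coefficients[hr[[3]]$coefficients$term == "x1", ]
  beta_pop <- 2 * sd(d$x1) / sd(d$y)
  expect_lt(abs(bx1$std_beta - beta_pop), 2 * bx1$se * sd(d$x1) / sd(d$y))

  # duplicate predictor block adds nothing
  hr2 <- hierarchical_regression(d, "y", list(A = "x1", B = "x1"))
  expect_equal(hr2[[2]]$r2_change, 0, tolerance = 1e-12)
  expect_equal(hr2[[2]]$f_change, 0)

  # standardized beta invariant to affine rescaling of a predictor
  d2 <- d; d2$x1 <- d2$x1 * 100 + 7
  hr3 <- hierarchical_regression(d2, "y", list(A = c("x1", "x2")))
  expect_equal(hr3[[1]]$coefficients$std_beta[2],
               hierarchical_regression(d, "y", list(A = c("x1", "x2")))[[1]]$coefficients$std_beta[2],
               tolerance = 1e-10)

  # collinearity is named
  d$dup <- d$x1
  expect_error(hierarchical_regression(d, "y", list(A = c("x1", "dup"))),
               "collinear")
})

test_that("moderation reports exact conditional effects and sane coefficients", {
  set.seed(5)
  n <- 60
  d <- data.frame(cri_leisure = rnorm(n, 130, 20),
                  cpp_slope = rnorm(n, 0.07, 0.05))
  d$mean_rt <- 1259.45 - 5420.91 * d$cpp_slope - 4.34 * d$cri_leisure +
    32 * d$cpp_slope * d$cri_leisure + rnorm(n, 0, 60)
  m <- moderation(d)
  co <- m$coefficients
  est <- function(role) co$estimate[co$role == role]
  # conditional effect identity b2 + b3 * m holds to machine precision
  for (i in 1:3) {
    expect_equal(m$conditional$effect[i],
                 est("b2_predictor") +
                   est("b3_interaction") * m$conditional$moderator_value[i],
                 tolerance = 1e-12)
  }
  # coefficients near truth (generous: single replicate)
  expect_lt(abs(est("b3_interaction") - 32),
            3 * co$se[co$role == "b3_interaction"])
  expect_equal(m$n, n)
  expect_gt(m$r2, 0.5)

  # moderation with a covariate keeps the interaction term
  d$age_c <- rnorm(n)
  mc <- moderation(d, covariates = "age_c")
  expect_true("age_c" %in% mc$coefficients$term)
})

test_that("mediation bootstrap: deterministic chain and lm oracle", {
  x <- seq(-2, 2, length.out = 24)
  d <- data.frame(x = x, m = x, y = x)
  med <- mediation_bootstrap(d, "x", "m", "y", n_boot = 200, seed = 3)
  expect_equal(med$indirect, 1, tolerance = 1e-10)
  expect_lt(diff(med$ci), 1e-10)

  # point estimate equals the two-regression product computed with lm
  set.seed(9)
  d2 <- data.frame(x = rnorm(30))
  d2$m <- 0.8 * d2$x + rnorm(30, 0, 0.5)
  d2$y <- 0.5 * d2$m + 0.3 * d2$x + rnorm(30, 0, 0.5)
  med2 <- mediation_bootstrap(d2, "x", "m", "y", n_boot = 500, seed = 4)
  a_lm <- unname(coef(lm(m ~ x, d2))["x"])
  b_lm <- unname(coef(lm(y ~ m + x, d2))["m"])
  expect_equal(med2$indirect, a_lm * b_lm, tolerance = 1e-10)
  expect_true(med2$ci[1] <= med2$indirect && med2$indirect <= med2$ci[2])

  # reproducible bit-wise under a fixed seed
  med3 <- mediation_bootstrap(d2, "x", "m", "y", n_boot = 500, seed = 4)
  expect_identical(med2$boots, med3$boots)
})

test_that("group comparison matches the t^2 identity and a hand oracle", {
  set.seed(2)
  g <- rep(c("a", "b"), each = 40)
  v <- rnorm(80) + (g == "b") * 1
  gc <- group_compare(v, g)
  expect_equal(gc$f, gc$t_student$statistic[[1]]^2, tolerance = 1e-10)

  # identical groups: F = 0, eta2 = 0
  same <- group_compare(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$f, 0, tolerance = 1e-12)
  expect_equal(same$partial_eta2, 0, tolerance = 1e-12)

  # textbook 3-per-group example
  va <- c(1, 2, 3); vb <- c(4, 5, 6)
  hand_ssb <- 3 * ((mean(va) - mean(c(va, vb)))^2 + (mean(vb) - mean(c(va, vb)))^2)
  hand_ssw <- sum((va - mean(va))^2) + sum((vb - mean(vb))^2)
  hand_f <- (hand_ssb / 1) / (hand_ssw / 4)
  gc2 <- group_compare(c(va, vb), rep(c("a", "b"), each = 3))
  expect_equal(gc2$f, hand_f, tolerance = 1e-12)
  expect_equal(gc2$partial_eta2, hand_ssb / (hand_ssb + hand_ssw),
               tolerance = 1e-12)
})

# independent oracle: Rouder et al.'s g-form of the JZS Bayes factor,
# integrating over the inverse-gamma mixing variable instead of the effect
jzs_g_oracle <- function(t, n_eff, df, r = 0.707) {
  num <- integrate(function(g) {
    (1 + n_eff * g * r^2)^(-1 / 2) *
      (1 + t^2 / (df * (1 + n_eff * g * r^2)))^(-(df + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / df)^(-(df + 1) / 2)
  num / den
}

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  # n = 80, t = 3.0: agreement to 4 significant digits
  bf <- jzs_bf_from_t(3.0, 80, 79)
  expect_equal(bf, jzs_g_oracle(3.0, 80, 79), tolerance = 1e-4)
  for (tt in c(0.5, 2.2)) {
    expect_equal(jzs_bf_from_t(tt, 25, 24), jzs_g_oracle(tt, 25, 24),
                 tolerance = 1e-4)
  }
  # null-favouring at t = 0; monotone increasing in |t|
  expect_lt(jzs_bf_from_t(0, 40, 39), 1)
  bfs <- vapply(seq(0, 4, by = 0.5), jzs_bf_from_t, numeric(1),
                n_eff = 40, df = 39)
  expect_true(all(diff(bfs) > 0))
})

test_that("jzs_bf_ttest handles samples, modes and directions", {
  set.seed(31)
  x <- rnorm(50, 0.5)
  one <- jzs_bf_ttest(x)
  expect_equal(one$t, t.test(x)$statistic[[1]], tolerance = 1e-10)
  expect_gt(one$bf10, 1)

  y <- rnorm(45)
  two <- jzs_bf_ttest(x, y)
  expect_equal(two$t, t.test(x, y, var.equal = TRUE)$statistic[[1]],
               tolerance = 1e-10)

  # directional: prior mass on the observed side raises BF10
  gt <- jzs_bf_ttest(x, direction = "greater")
  lt <- jzs_bf_ttest(x, direction = "less")
  expect_gt(gt$bf10, one$bf10)
  expect_lt(lt$bf10, one$bf10)
  expect_error(jzs_bf_ttest(c(1, 2)), "at least 3")
})

test_that("life percentage follows the stated formula", {
  expect_equal(life_percentage(26, 70), 50)
  expect_equal(life_percentage(0, 70), 0)
  expect_equal(life_percentage(54, 70), 103.846, tolerance = 1e-4)
  expect_error(life_percentage(10, 18), "exceed 18")
})

test_that("cohort table assembles subjects, behaviour and fits", {
  cfg <- tiny_config(trials_per_subject = 120, seed = 61)
  sim <- simulate_cohort(cfg, epochs = FALSE)
  fits <- lapply(sim$behaviors, fit_ddm)
  tab <- build_cohort_table(sim$subjects, sim$behaviors, ddm_fits = fits)
  expect_equal(nrow(tab), 5)
  expect_equal(mean(tab$age_c), 0, tolerance = 1e-10)
  expect_true(all(is.finite(tab$mean_rt)))
  expect_true(all(tab$ddm_a > 0))
})
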