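test_that("shifted-Wald density and CDF have the right support and limits", {
  expect_equal(pwald(0.1, 2, 8, 0.1), 0)
  expect_equal(pwald(100, 2, 8, 0.1), 1, tolerance = 1e-12)
  expect_equal(dwald(0.05, 2, 8, 0.1), 0)
  # mode strictly above t0, density finite
  grid <- seq(0.101, 1.5, by = 0.001)
  d <- dwald(grid, 2, 8, 0.1)
  expect_true(all(is.finite(d)))
  expect_gt(grid[which.max(d)], 0.1)
  # CDF is the integral of the density
  expect_equal(pwald(0.4, 2, 8, 0.1),
               integrate(dwald, 0.1, 0.4, a = 2, v = 8, t0 = 0.1)$value,
               tolerance = 1e-6)
  # large drift-bound products stay finite (log-scale second term)
  expect_true(is.finite(pwald(0.5, 20, 40, 0)))
})

test_that("qwald inverts pwald", {
  for (p in c(1e-4, 0.1, 0.5, 0.9)) {
    q <- qwald(p, 2.77, 7.38, 0.11)
    expect_equal(pwald(q, 2.77, 7.38, 0.11), p, tolerance = 1e-8)
  }
})

test_that("analytic CDF matches Euler-Maruyama paths (small oracle)", {
  sim <- simulate_ddm(2, 8, 0.1, n = 20000, deadline_s = 1.8, dt = 5e-4,
                      seed = 123)
  rts <- sim$rt_s[!is.na(sim$rt_s)]
  grid <- seq(0.15, 1.0, by = 0.01)
  emp <- ecdf(rts)(grid) * (1 - sim$p_miss)
  ana <- pwald(grid, 2, 8, 0.1)
  expect_lt(max(abs(emp - ana)), 0.02)
})

test_that("observed binning yields the 0.1/0.2/0.2/0.2/0.2 + miss layout", {
  rt <- seq(300, 1200, length.out = 100)
  beh <- data.frame(rt_ms = c(rt, rep(NA, 10)),
                    responded = c(rep(TRUE, 100), rep(FALSE, 10)))
  bins <- bin_observed(beh)
  # six response intervals (0.1/0.2/0.2/0.2/0.2/0.1 of responders) + misses;
  # totals are conserved exactly
  expect_equal(bins$observed, c(10, 20, 20, 20, 20, 10, 10))
  expect_equal(sum(bins$observed), bins$n_total)
  expect_equal(bins$n_total, 110)
  expect_equal(length(bins$cutpoints), 5)

  no_miss <- bin_observed(data.frame(rt_ms = rt, responded = TRUE))
  expect_equal(no_miss$observed[7], 0)

  same <- data.frame(rt_ms = rep(500, 50), responded = TRUE)
  expect_error(bin_observed(same), "degenerate")
  expect_error(bin_observed(data.frame(rt_ms = rep(NA, 20), responded = FALSE)),
               "at least 10")
})

test_that("expected frequencies telescope to the total and match at truth", {
  rt <- seq(300, 1200, length.out = 100)
  beh <- data.frame(rt_ms = c(rt, rep(NA, 10)),
                    responded = c(rep(TRUE, 100), rep(FALSE, 10)))
  bins <- expected_frequencies(list(a = 2, v = 5, t0 = 0.15),
                               bin_observed(beh))
  expect_equal(sum(bins$expected), bins$n_total, tolerance = 1e-6)

  # with data generated by the model, E approaches O (consistency)
  cfg <- cohort_config(n_older = 1, n_younger = 1,
                       trials_per_subject = 42000, seed = 1)
  big <- simulate_behavior(list(a = 2.77, v = 7.38, t0 = 0.11), cfg, seed = 6)
  bb <- expected_frequencies(list(a = 2.77, v = 7.38, t0 = 0.11),
                             bin_observed(big))
  expect_lt(max(abs(bb$expected - bb$observed) / bb$n_total), 0.01)

  # enormous drift concentrates all mass before the first cutpoint
  fast <- expected_frequencies(list(a = 2, v = 500, t0 = 0.1),
                               bin_observed(beh))
  expect_equal(fast$expected[1], fast$n_total, tolerance = 1e-3)
})

test_that("G-square is zero at O = E, matches hand computation, and is >= 0", {
  rt <- seq(300, 1200, length.out = 100)
  beh <- data.frame(rt_ms = c(rt, rep(NA, 10)),
                    responded = c(rep(TRUE, 100), rep(FALSE, 10)))
  bins <- bin_observed(beh)
  bins$expected <- bins$observed
  expect_equal(g_square(bins), 0)

  bins$observed <- c(10, 20, 20, 20, 20, 10)
  bins$expected <- c(12, 18, 22, 18, 20, 10)
  hand <- 2 * (10 * log(10 / 12) + 20 * log(20 / 18) + 20 * log(20 / 22) +
               20 * log(20 / 18) + 20 * log(20 / 20) + 10 * log(10 / 10))
  expect_equal(g_square(bins), hand, tolerance = 1e-12)

  # zero observed cells contribute nothing
  bins$observed <- c(0, 30, 20, 20, 20, 20)
  bins$expected <- c(5, 25, 20, 20, 20, 20)
  expect_true(is.finite(g_square(bins)))

  set.seed(4)
  for (i in 1:200) {
    o <- rmultinom(1, 110, runif(6))[, 1]
    e <- rmultinom(1, 110, runif(6))[, 1] + 1e-10
    bins$observed <- o; bins$expected <- e
    expect_gte(g_square(bins), -1e-10)
  }
})

test_that("powell minimises smooth objectives", {
  # quadratic bowl: exact minimum
  quad <- function(p) sum((p - c(1, -2, 3))^2)
  res <- powell(c(0, 0, 0), quad, scale = c(1, 1, 1))
  expect_equal(res$par, c(1, -2, 3), tolerance = 1e-5)
  expect_equal(res$value, 0, tolerance = 1e-9)

  # Rosenbrock: matches (or beats) Nelder-Mead
  rosen <- function(p) (1 - p[1])^2 + 100 * (p[2] - p[1]^2)^2
  rp <- powell(c(-1.2, 1), rosen, scale = c(0.5, 0.5), maxit = 500)
  nm <- optim(c(-1.2, 1), rosen)
  expect_lte(rp$value, nm$value + 1e-6)
  expect_equal(rp$par, c(1, 1), tolerance = 1e-3)
})

test_that("fit_ddm honours the minimizer contract and beats perturbations", {
  cfg <- cohort_config(n_older = 1, n_younger = 1,
                       trials_per_subject = 2004, seed = 3)
  truth <- list(a = 2.77, v = 7.38, t0 = 0.11)
  beh <- simulate_behavior(truth, cfg, seed = 17)
  fit <- fit_ddm(beh)
  bins <- fit$bins

  g_at <- function(p) g_square(expected_frequencies(p, bins))
  # fitted G2 no worse than at any default grid start
  min_rt <- min(beh$trials$rt_ms[beh$trials$responded]) / 1000
  grid <- expand.grid(a = c(1, 2, 3.5), v = c(4, 8, 14),
                      t0 = c(0.3, 0.6, 0.9) * min_rt)
  for (i in seq_len(nrow(grid))) {
    expect_lte(fit$g2, g_at(as.list(grid[i, ])) + 1e-9)
  }
  # and no worse than +-25% single-parameter perturbations of the truth
  for (par in names(truth)) {
    for (f in c(0.75, 1.25)) {
      p <- truth; p[[par]] <- p[[par]] * f
      expect_lte(fit$g2, g_at(p) + 1e-9)
    }
  }
  # single-replicate recovery: within ~3 asymptotic SDs of the binned design
  # (SDs at this n: a 0.63, v 0.61, t0 0.055)
  expect_lt(abs(fit$a - truth$a), 1.9)
  expect_lt(abs(fit$v - truth$v), 1.9)
  expect_lt(abs(fit$t0 - truth$t0), 0.17)
})
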