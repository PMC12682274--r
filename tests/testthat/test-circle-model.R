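test_that("normalized distances follow the per-ego convention", {
  nd <- normalize_distances(c(2, 4, 6))
  expect_equal(nd$sigma, 4)
  expect_equal(nd$s_max, 6)
  expect_equal(nd$s_min, 2)

  nd <- normalize_distances(c(1, 1, 10))
  expect_equal(nd$t_values, c(1, 1, 0))
  expect_equal(nd$t_bar, 2 / 3)
  # t_bar is both the mean of t and (s_max - sigma)/(s_max - s_min)
  expect_equal(nd$t_bar, mean(nd$t_values))
  expect_equal(nd$t_bar, (nd$s_max - nd$sigma) / (nd$s_max - nd$s_min))

  expect_error(normalize_distances(c(3, 3, 3)),
               class = "groomcircles_degenerate_weights")
  expect_error(normalize_distances(5), "at least 2")
  expect_error(normalize_distances(c(1, -2, 3)), "positive")
})

test_that("dataset-wide bounds are honored and validated", {
  nd <- normalize_distances(c(2, 4, 6), s_max = 10, s_min = 1)
  expect_equal(nd$t_values, (10 - c(2, 4, 6)) / 9)
  expect_equal(nd$t_bar, (10 - 4) / 9)
  expect_error(normalize_distances(c(2, 4, 6), s_max = 5, s_min = 1),
               "enclose")
  expect_error(normalize_distances(c(2, 4, 6), s_max = 10), "both")
})

test_that("mean distance curve matches the raw formula, limits and symmetry", {
  expect_equal(mean_distance_curve(0), 0.5)
  expect_equal(mean_distance_curve(6), exp(6) / (exp(6) - 1) - 1 / 6,
               tolerance = 1e-12)
  expect_equal(mean_distance_curve(6), 0.8358182, tolerance = 1e-6)
  expect_equal(mean_distance_curve(-6), 0.1641818, tolerance = 1e-6)

  grid <- seq(-40, 40, length.out = 401)
  # antisymmetry about 1/2
  expect_equal(mean_distance_curve(-grid), 1 - mean_distance_curve(grid),
               tolerance = 1e-12)
  # strictly increasing, bounded in (0, 1)
  vals <- mean_distance_curve(grid)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 1))
  # series and closed-form branches agree across the switch-over region
  # (reference: series through the eta^5 term, truncation error < 1e-18 here)
  near <- c(seq(-0.02, -0.005, by = 0.001), seq(0.005, 0.02, by = 0.001))
  ref <- 0.5 + near / 12 - near^3 / 720 + near^5 / 30240
  expect_lt(max(abs(mean_distance_curve(near) - ref)), 1e-10)
  # no overflow at extreme eta
  expect_true(is.finite(mean_distance_curve(700)))
  expect_true(is.finite(mean_distance_curve(-700)))
})

test_that("solve_eta inverts the implicit equation", {
  expect_identical(solve_eta(0.5), 0)
  expect_equal(solve_eta(0.8358182), 6, tolerance = 1e-4)
  expect_equal(solve_eta(2 / 3), oracle_solve_eta(2 / 3, 2, 2.2),
               tolerance = 1e-6)
  expect_equal(solve_eta(2 / 3), 2.149, tolerance = 1e-2)
  # sign follows t_bar - 1/2; monotone in t_bar
  ts <- seq(0.05, 0.95, by = 0.05)
  etas <- vapply(ts, solve_eta, numeric(1))
  expect_true(all(diff(etas) > 0))
  expect_equal(sign(etas), sign(ts - 0.5))
  expect_error(solve_eta(0), "inside")
  expect_error(solve_eta(1), "inside")
  # extreme t_bar still solved (bracket widens past the default)
  e_big <- solve_eta(1 - 1e-4)
  expect_equal(mean_distance_curve(e_big), 1 - 1e-4, tolerance = 1e-9)
})

test_that("solve_eta round trip and antisymmetry hold across the range", {
  etas <- seq(-30, 30, by = 0.5)
  back <- vapply(mean_distance_curve(etas), solve_eta, numeric(1))
  expect_equal(back, etas, tolerance = 1e-6)

  ts <- seq(0.01, 0.49, length.out = 100)
  left <- vapply(1 - ts, solve_eta, numeric(1))
  right <- vapply(ts, solve_eta, numeric(1))
  expect_equal(left, -right, tolerance = 1e-6)
})

test_that("chi_continuous matches closed form, limits and monotonicity", {
  expect_equal(chi_continuous(1, 17.3), 1)
  expect_equal(chi_continuous(0, 17.3), 0)
  expect_equal(chi_continuous(0.5, 6), (exp(3) - 1) / (exp(6) - 1),
               tolerance = 1e-12)
  expect_equal(chi_continuous(0.5, 6), 0.047426, tolerance = 1e-5)
  expect_equal(chi_continuous(0.3, 0), 0.3)
  ts <- seq(0, 1, by = 0.01)
  for (eta in c(-8, -1, 0.5, 12)) {
    vals <- chi_continuous(ts, eta)
    expect_true(all(diff(vals) > 0))
  }
  # no overflow for large eta
  expect_equal(chi_continuous(0.5, 500), exp(-250), tolerance = 1e-10)
})

test_that("log-derivative of chi has the scaling-ratio asymptotics", {
  expect_equal(log_derivative_chi(1, 50), 50, tolerance = 1e-10 * 50)
  expect_lt(log_derivative_chi(1, -50), 1e-10)
  expect_equal(log_derivative_chi(0.5, 2), 2 * exp(1) / (exp(1) - 1),
               tolerance = 1e-12)
  expect_error(log_derivative_chi(0, 2), "singular")
})

test_that("log-likelihood evaluates correctly and peaks at the implicit solution", {
  expect_equal(log_likelihood(0.5, 1), 0.5 - log(exp(1) - 1), tolerance = 1e-5)
  expect_equal(log_likelihood(c(0.2, 0.8), 1e-9), 0, tolerance = 1e-8)
  # stationarity: argmax equals the implicit-equation solution
  set.seed(41)
  for (i in 1:30) {
    eta_true <- runif(1, -8, 8)
    L <- sample(10:300, 1)
    t_vals <- sample_tie_distances(eta_true, L)
    expect_equal(oracle_ml_eta(t_vals), solve_eta(mean(t_vals)),
                 tolerance = 1e-6)
  }
})

test_that("likelihood-ratio confidence intervals nest, shrink and bracket the estimate", {
  set.seed(11)
  t_vals <- sample_tie_distances(3, 10000)
  nd_hat <- solve_eta(mean(t_vals))
  ci <- eta_confidence_interval(t_vals, nd_hat, delta = 0.025)
  expect_lt(ci[1], nd_hat)
  expect_gt(ci[2], nd_hat)
  expect_gt(3, ci[1])
  expect_lt(3, ci[2])
  expect_lt(ci[2] - ci[1], 0.2)
  # narrower delta band nests strictly inside
  ci50 <- eta_confidence_interval(t_vals, nd_hat, delta = 0.25)
  expect_gt(ci50[1], ci[1])
  expect_lt(ci50[2], ci[2])
  # width shrinks like L^{-1/2}
  t_small <- sample_tie_distances(3, 100)
  ci_small <- eta_confidence_interval(t_small, solve_eta(mean(t_small)))
  ratio <- (ci_small[2] - ci_small[1]) / (ci[2] - ci[1])
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("fit_ego chains estimation and labels regimes; mirroring flips the sign", {
  fit <- fit_ego(c(1, 1, 10))
  expect_s3_class(fit, "circle_fit")
  expect_equal(fit$eta, 2.149, tolerance = 1e-2)
  expect_identical(fit$regime, "normal")
  expect_lt(fit$ci_low, fit$eta)
  expect_gt(fit$ci_high, fit$eta)

  w <- c(2, 3, 5, 11, 17)
  mirrored <- min(w) + max(w) - w # sends t to 1 - t
  expect_equal(fit_ego(mirrored)$eta, -fit_ego(w)$eta, tolerance = 1e-6)

  tw <- tidy(fit)
  expect_equal(tw$eta, fit$eta)
  expect_equal(nrow(tw), 1)
  g <- glance(fit)
  expect_equal(g$ci_width, fit$ci_high - fit$ci_low)
})

test_that("fit_ego recovers a planted eta at large L", {
  set.seed(99)
  t_vals <- sample_tie_distances(6, 1000)
  w <- 50 - t_vals * 49 # map distances onto a 1..50 weight scale
  fit <- fit_ego(w, s_max = 50, s_min = 1)
  expect_lt(abs(fit$eta - 6), 0.3)
  expect_gt(6, fit$ci_low)
  expect_lt(6, fit$ci_high)
})

test_that("discrete layer probabilities are a normalized Boltzmann weighting", {
  lm0 <- discrete_layer_probs(c(3, 2, 1), 0)
  expect_equal(lm0$probs, rep(1 / 3, 3))
  lm2 <- discrete_layer_probs(c(1, 0), log(2))
  expect_equal(lm2$probs, c(1 / 3, 2 / 3), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    r <- sample(2:8, 1)
    costs <- sort(runif(r, 0, 10), decreasing = TRUE)
    lm <- discrete_layer_probs(costs, runif(1, -3, 3))
    expect_equal(sum(lm$probs), 1, tolerance = 1e-12)
    expect_true(all(lm$probs >= 0))
    expect_equal(lm$mu, lm$mu_hat * (costs[1] - costs[r]) / (r - 1))
    expect_equal(lm$circle_sizes[r], 1)
    expect_true(all(diff(lm$circle_sizes) >= 0))
  }
  expect_error(discrete_layer_probs(c(1, 2), 1), "decreasing")
  expect_error(discrete_layer_probs(3, 1), "at least")
})

test_that("discrete circle sizes match the closed form and its limits", {
  expect_equal(chi_discrete(4, 4, 2.7), 1)
  expect_equal(chi_discrete(1:4, 4, log(3)), (3^(1:4) - 1) / 80,
               tolerance = 1e-12)
  expect_equal(chi_discrete(1:4, 4, log(3)), c(0.025, 0.1, 0.325, 1))
  expect_equal(chi_discrete(1:4, 4, 0), (1:4) / 4)
  expect_error(chi_discrete(5, 4, 1), "\\[1, 4\\]")
  expect_error(chi_discrete(0, 4, 1), "\\[1, 4\\]")
  # stable at large mu where e^{r mu} overflows
  expect_equal(chi_discrete(3, 4, 300), exp(-300), tolerance = 1e-12)
})

test_that("scaling ratios of consecutive circles approach e^mu", {
  for (mu in c(5, 7, 10)) {
    for (k in 1:3) {
      ratio <- chi_discrete(k + 1, 4, mu) / chi_discrete(k, 4, mu)
      # at k = 1 the relative error equals e^{-mu} exactly
      expect_lte(abs(ratio / exp(mu) - 1), exp(-mu * k) * (1 + 1e-12))
    }
  }
})

test_that("the discrete-continuous map gives the canonical eta of 6", {
  expect_equal(eta_from_mu(log(3), 4), 6, tolerance = 1e-12)
  expect_equal(eta_from_mu(0, 7), 0)
  expect_equal(eta_from_mu(1, 4), 3 * (exp(1) - 1), tolerance = 1e-12)
})
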