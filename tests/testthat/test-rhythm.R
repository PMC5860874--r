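# Spectral analysis, the two-peak activity model, shuffling experiments
# and correlation statistics.

test_that("threshold power follows the analytic formula", {
  expect_equal(threshold_power(0.05, 1), -log(0.05))
  expect_equal(threshold_power(0.05, 100),
               -log(1 - 0.95^(1 / 100)))
  expect_equal(round(threshold_power(0.05, 100), 3), 7.576)
  for (N in c(1, 10, 100, 1000)) {
    expect_gt(threshold_power(0.01, N), threshold_power(0.05, N))
  }
  expect_error(threshold_power(0, 10), "between 0 and 1")
  expect_error(threshold_power(1.2, 10), "between 0 and 1")
  expect_error(threshold_power(0.05, 0), "at least 1")
})

test_that("a pure 24-h sinusoid peaks at 24 h and is highly significant", {
  s <- generate_rhythmic_series(24, days = 4, bin_min = 30, amplitude = 1,
                                noise_sd = 0.02, seed = 3)
  pg <- lomb_scargle(s)
  dp <- dominant_period(pg)
  expect_lt(abs(dp$period_h - 24), 0.5)
  expect_equal(dp$significant_at, "0.01")
  # variance normalization: doubling the amplitude leaves power unchanged
  s2 <- s; s2$value <- 2 * s2$value
  expect_equal(lomb_scargle(s2)$power, pg$power)
  expect_error(lomb_scargle(binned_series(rep(0.3, 96))), "constant")
})

test_that("white-noise series stay below the p = 0.05 threshold usually", {
  hits <- 0
  for (i in 1:60) {
    x <- binned_series(rnorm(192) + 10)
    pg <- lomb_scargle(x)
    if (max(pg$power) > attr(pg, "threshold_p05")) hits <- hits + 1
  }
  expect_lte(hits, 60 * 0.15)  # ~5% expected
})

test_that("dominant period handles bands and ties deterministically", {
  s <- generate_rhythmic_series(24, days = 4, seed = 9)
  pg <- lomb_scargle(s)
  expect_error(dominant_period(pg, c(100, 200)), "band")
  pg2 <- pg[1:5, ]
  attr(pg2, "threshold_p05") <- attr(pg, "threshold_p05")
  attr(pg2, "threshold_p01") <- attr(pg, "threshold_p01")
  pg2$power <- c(1, 5, 3, 5, 2)
  dp <- dominant_period(pg2, range(pg2$period_h))
  expect_equal(dp$period_h, min(pg2$period_h[pg2$power == 5]))
})

test_that("two-peak template has plateaus and exponential flanks", {
  p <- c(b_MD = 0.5, b_MR = 0.4, b_ER = 0.3, b_ED = 0.6, T0 = 24,
         T_M = 4, T_E = 2, H_M = 2, H_E = 1)
  v <- two_peak_model(c(0, 1.9, 12, 12.9), p)
  expect_gte(v[1], 2)          # on the morning plateau (plus evening tail)
  expect_gte(v[3], 1)          # on the evening plateau
  # periodic in T0
  expect_equal(two_peak_model(5, p), two_peak_model(5 + 24, p))
  # monotone decay after the morning plateau, rise before the evening one
  expect_gt(two_peak_model(2.5, p), two_peak_model(3.5, p))
  expect_lt(two_peak_model(8, p), two_peak_model(10, p))
})

test_that("two-peak parameters are recovered from template data", {
  truth <- c(b_MD = 0.6, b_MR = 0.8, b_ER = 0.7, b_ED = 0.5, T0 = 24,
             T_M = 4, T_E = 3, H_M = 0.6, H_E = 0.4)
  t_h <- (0:191) * 0.5
  set.seed(14)
  y <- two_peak_model(t_h, truth) * (1 + rnorm(192, 0, 0.05))
  fit <- fit_two_peak_model(binned_series(y))
  expect_true(fit$converged)
  est <- fit$params
  for (nm in c("b_MD", "b_MR", "b_ER", "b_ED", "H_M", "H_E")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]) / truth[[nm]], 0.25)
  }
  for (nm in c("T0", "T_M", "T_E")) {
    expect_lt(abs(est[[nm]] - truth[[nm]]), 0.5)
  }
  # refitting its own fitted curve reproduces the parameters
  refit <- fit_two_peak_model(binned_series(fit$fitted), init = est)
  expect_equal(unname(refit$params), unname(est), tolerance = 1e-4)
  expect_lt(refit$fit_error, 1e-6)
})

test_that("a flat series yields a degenerate two-peak fit", {
  y <- rep(0.3, 192) + rnorm(192, 0, 1e-4)
  fit <- fit_two_peak_model(binned_series(y), init = c(
    b_MD = 0.3, b_MR = 0.3, b_ER = 0.3, b_ED = 0.3, T0 = 24,
    T_M = 3, T_E = 3, H_M = 0.01, H_E = 0.01))
  expect_lt(fit$params[["H_M"]], 0.32)
  expect_lt(fit$params[["H_E"]], 0.32)
})

test_that("shuffle experiments conserve totals and respect bounds", {
  set.seed(21)
  g <- runif(96, 0, 0.2)
  l <- runif(96, 0.2, 0.5)
  w <- pmin(1, l + g + runif(96, 0, 0.2))
  sh <- shuffle_experiment(g, l, w, mode = "locomotion", seed = 4)
  expect_equal(sh$locomotion + sh$randomized_grooming, l + g)
  expect_identical(sh$wake, w)                # untouched companion
  expect_true(all(sh$locomotion >= 0 & sh$locomotion <= 1))
  expect_equal(sort(sh$randomized_grooming), sort(g))
  shw <- shuffle_experiment(g, l, w, mode = "wake", seed = 4)
  expect_identical(shw$locomotion, l)
  expect_true(all(shw$wake >= 0 & shw$wake <= 1))
  # identity permutation leaves everything unchanged
  id <- shuffle_experiment(g, l, w, mode = "wake", perm = seq_along(g))
  expect_equal(id$wake, w)
  expect_equal(id$randomized_grooming, g)
  expect_error(shuffle_experiment(g, l[1:10], w, "wake"), "aligned")
})

test_that("shuffling destroys grooming rhythm but not modified locomotion", {
  # levels chosen so every permutation keeps the modified series in [0,1]
  g <- generate_rhythmic_series(24, 4, amplitude = 0.5, baseline = 0.12,
                                noise_sd = 0.01, seed = 31)$value
  l <- generate_rhythmic_series(24, 4, amplitude = 0.5, baseline = 0.4,
                                noise_sd = 0.01, seed = 32)$value
  w <- pmin(1, g + l + 0.1)
  sh <- shuffle_experiment(g, l, w, mode = "locomotion", seed = 5)
  pg_rand <- lomb_scargle(binned_series(sh$randomized_grooming))
  pg_mod <- lomb_scargle(binned_series(sh$locomotion))
  expect_equal(dominant_period(pg_mod)$significant_at %in% c("0.01", "0.05"),
               TRUE)
  expect_equal(dominant_period(pg_rand)$significant_at, "none")
})

test_that("pearson_r matches the longhand definition", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  x <- c(1, 2, 4, 7); y <- c(3, 1, 5, 8)
  longhand <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(pearson_r(x, y), longhand)
  expect_error(pearson_r(1:3, rep(2, 3)), "variance")
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("bootstrap p-values are deterministic, floored and calibrated", {
  set.seed(77)
  x <- rnorm(40); y <- x + rnorm(40, 0, 0.1)
  b1 <- bootstrap_correlation_p(x, y, n_resamples = 999, seed = 6)
  b2 <- bootstrap_correlation_p(x, y, n_resamples = 999, seed = 6)
  expect_identical(b1$p_boot, b2$p_boot)
  expect_equal(b1$p_boot, 1 / 1000)   # resolution floor for a strong effect
  # independent x, y: p below 0.05 in roughly 5% of replicates
  hits <- 0
  for (i in 1:100) {
    xx <- rnorm(25); yy <- rnorm(25)
    p <- bootstrap_correlation_p(xx, yy, n_resamples = 199,
                                 seed = 1000 + i)$p_boot
    if (p < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 15)
})
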