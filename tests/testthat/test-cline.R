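test_that("cline expectation has the tanh sigmoid shape", {
  m <- cline_model(c = 30, w = 5)
  expect_equal(cline_expectation(30, m), 0.5)
  expect_equal(cline_expectation(1e6, m), 1)
  expect_equal(cline_expectation(-1e6, m), 0)
  # half a width east of the center: (1 + tanh(1)) / 2
  expect_equal(cline_expectation(30 + 2.5, m), 0.5 * (1 + tanh(1)))
  # slope at the center is (p_max - p_min) / w
  h <- 1e-6
  slope <- (cline_expectation(30 + h, m) - cline_expectation(30 - h, m)) / (2 * h)
  expect_equal(slope, 1 / 5, tolerance = 1e-8)

  m2 <- cline_model(c = 0, w = 2, p_min = 0.2, p_max = 0.9)
  expect_equal(cline_expectation(0, m2), 0.55)
  expect_equal(cline_expectation(1e6, m2), 0.9)
})

test_that("log-likelihood matches term-by-term Gaussian arithmetic", {
  m <- cline_model(c = 0, w = 4, sigma = 1)
  on_curve <- data.frame(x_km = 2, value = cline_expectation(2, m), n = 1)
  expect_equal(cline_log_likelihood(m, on_curve), -0.5 * log(2 * pi))

  # three hand-specified sites, hand-summed oracle
  m3 <- cline_model(c = 10, w = 6, p_min = 0.1, p_max = 0.8, sigma = 0.2)
  obs <- data.frame(x_km = c(4, 10, 18), value = c(0.15, 0.5, 0.75),
                    n = c(5, 12, 7))
  pred <- 0.1 + 0.7 * 0.5 * (1 + tanh(2 * (obs$x_km - 10) / 6))
  oracle <- sum(-0.5 * log(2 * pi * 0.04 / obs$n) -
                  obs$n * (obs$value - pred)^2 / (2 * 0.04))
  expect_equal(cline_log_likelihood(m3, obs), oracle)

  # additivity: appending a site adds exactly that site's term
  extra <- data.frame(x_km = 25, value = 0.9, n = 3)
  expect_equal(cline_log_likelihood(m3, rbind(obs, extra)),
               cline_log_likelihood(m3, obs) + cline_log_likelihood(m3, extra))

  # unweighted mode treats every site as n = 1
  expect_equal(cline_log_likelihood(m3, obs, weighted = FALSE),
               cline_log_likelihood(m3, transform(obs, n = 1)))
})

test_that("spline initialization finds the steepest region", {
  obs <- exact_cline_obs(seq(0, 60, by = 3), c = 30, w = 6)
  expect_equal(spline_center_init(obs), 30, tolerance = 0.5)

  # perfectly linear data: constant slope, plateau midpoint convention
  lin <- data.frame(x_km = seq(0, 40, by = 5), value = seq(0, 1, length.out = 9),
                    n = 5)
  expect_equal(spline_center_init(lin), 20, tolerance = 1e-6)

  # mirroring the values leaves the steepest position unchanged
  mir <- transform(obs, value = 1 - value)
  expect_equal(spline_center_init(mir), spline_center_init(obs))

  expect_error(spline_center_init(exact_cline_obs(c(1, 2, 3), c = 2, w = 1)),
               "4 distinct")
})

test_that("maximum-likelihood fit recovers generating parameters", {
  obs <- simulate_cline_observations(seq(10, 50, length.out = 20), n = 15,
                                     c = 30, w = 5, sigma = 0.02, seed = 21)
  fit <- fit_cline(obs, fit_config(seed = 21))
  expect_lt(abs(fit$c - 30), 1)
  expect_lt(abs(fit$w - 5), 2)
  expect_equal(fit$p_min, 0, tolerance = 0.05)
  expect_equal(fit$p_max, 1, tolerance = 0.05)
  expect_false(attr(fit, "degenerate"))
  # achieved likelihood dominates the true-model likelihood
  truth <- cline_model(c = 30, w = 5, sigma = fit$sigma)
  expect_gte(attr(fit, "logLik"), cline_log_likelihood(truth, obs))
})

test_that("same seed and data give a bit-identical fit", {
  obs <- recovery_obs(seed = 5)
  f1 <- fit_cline(obs, fit_config(seed = 9))
  f2 <- fit_cline(obs, fit_config(seed = 9))
  expect_identical(f1, f2)
  p1 <- profile_center(obs, fast_cfg(seed = 9), fit = f1)
  p2 <- profile_center(obs, fast_cfg(seed = 9), fit = f1)
  expect_identical(p1, p2)
})

test_that("constant trait values are flagged as a degenerate fit", {
  obs <- data.frame(x_km = seq(0, 50, by = 5), value = 0.4, n = 10)
  fit <- fit_cline(obs, fit_config(seed = 3))
  expect_true(attr(fit, "degenerate"))
  expect_equal(fit$p_min, fit$p_max, tolerance = 1e-6)
})

test_that("width is the inverse of the numerically maximized slope", {
  for (w in c(0.5, 2, 5, 29)) {
    m <- cline_model(c = 12, w = w)
    h <- 1e-5 * w
    slope <- function(x) (cline_expectation(x + h, m) -
                            cline_expectation(x - h, m)) / (2 * h)
    peak <- optimize(slope, c(12 - w, 12 + w), maximum = TRUE,
                     tol = 1e-12)$objective
    expect_lt(abs(peak - 1 / w), 1e-9)
  }
})

test_that("fits are translation-equivariant and reflection-symmetric", {
  obs <- recovery_obs(seed = 13)
  cfg <- fit_config(seed = 13)
  fit <- fit_cline(obs, cfg)

  shifted <- transform(obs, x_km = x_km + 256)
  fs <- fit_cline(shifted, cfg)
  expect_equal(fs$c, fit$c + 256, tolerance = 1e-3)
  expect_equal(fs$w, fit$w, tolerance = 1e-3)
  expect_equal(fs$p_min, fit$p_min, tolerance = 1e-3)
  expect_equal(fs$p_max, fit$p_max, tolerance = 1e-3)

  mirrored <- transform(obs, x_km = -x_km)
  fm <- fit_cline(mirrored, cfg)
  expect_equal(fm$c, -fit$c, tolerance = 1e-2)
  expect_equal(fm$w, fit$w, tolerance = 1e-2)
  expect_equal(fm$p_min, fit$p_max, tolerance = 1e-3)
  expect_equal(fm$p_max, fit$p_min, tolerance = 1e-3)
})

test_that("profile argmax and maximum agree with the direct fit", {
  obs <- recovery_obs(seed = 31)
  cfg <- fit_config(seed = 31)
  fit <- fit_cline(obs, cfg)
  prof <- profile_center(obs, cfg, fit = fit)
  expect_lte(abs(prof$c_hat - fit$c), cfg$center_grid_step)
  expect_lte(attr(fit, "logLik"), prof$lmax + 0.01)
  expect_gte(prof$lmax, attr(fit, "logLik") - 0.01)
  # support limits bracket the maximum-likelihood center
  expect_lte(prof$support$low, prof$c_hat)
  expect_gte(prof$support$high, prof$c_hat)
})

test_that("profile is invariant to site ordering", {
  obs <- recovery_obs(seed = 8)
  cfg <- fast_cfg(seed = 8)
  fit <- fit_cline(obs, cfg)
  p1 <- profile_center(obs, cfg, fit = fit)
  p2 <- profile_center(obs[rev(seq_len(nrow(obs))), ], cfg, fit = fit)
  expect_equal(p1$grid, p2$grid)
  expect_equal(p1$logl, p2$logl)
})

test_that("a grid excluding the center puts the argmax at the nearest boundary", {
  obs <- recovery_obs(seed = 2)   # true center 40 km
  cfg <- fast_cfg(seed = 2)
  fit <- fit_cline(obs, cfg)
  expect_warning(
    prof <- profile_center(obs, cfg, fit = fit, grid = seq(60, 90, by = 1)),
    "below fit log-likelihood")
  expect_equal(prof$c_hat, 60)
  expect_true(prof$support$open_low)
})

test_that("support limits are exact on an analytic quadratic profile", {
  prof <- quadratic_profile(10)   # logl = -(c - 10)^2 / 2 * ... kappa = 1
  # logl >= -2  <=>  |c - 10| <= 2 / sqrt(kappa) with logl = -(c-10)^2/2
  s <- support_limits(prof)
  expect_equal(s$low, 10 - 2, tolerance = 1e-3)
  expect_equal(s$high, 10 + 2, tolerance = 1e-3)
  expect_false(s$open_low || s$open_high)

  # pure -(c - 10)^2 drops by 2 at 10 +/- sqrt(2)
  g <- seq(0, 20, by = 0.01)
  s2 <- support_limits(cline_profile(g, -(g - 10)^2))
  expect_equal(s2$low, 10 - sqrt(2), tolerance = 1e-3)
  expect_equal(s2$high, 10 + sqrt(2), tolerance = 1e-3)

  flat <- cline_profile(seq(0, 10, 1), rep(-5, 11))
  sf <- support_limits(flat)
  expect_equal(c(sf$low, sf$high), c(0, 10))
  expect_true(sf$open_low && sf$open_high)
})
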