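test_that("composite profile sums aligned log-likelihoods", {
  p <- quadratic_profile(5)
  doubled <- composite_profile(p, p)
  expect_equal(doubled$logl, 2 * stats::approx(p$grid, p$logl, doubled$grid)$y)

  # two quadratics peak at the average of their centers
  pa <- quadratic_profile(3); pb <- quadratic_profile(7)
  comp <- composite_profile(pa, pb)
  expect_equal(comp$c_hat, 5, tolerance = 0.02)

  # offset grids: values at shared points match hand interpolation
  a <- cline_profile(c(0, 1, 2, 3), c(0, -1, -4, -9))
  b <- cline_profile(c(0.5, 1.5, 2.5, 3.5), c(-2, -1, -2, -5))
  comp2 <- composite_profile(a, b)
  expect_equal(comp2$grid, c(0.5, 1, 1.5, 2, 2.5, 3))
  expect_equal(comp2$logl[comp2$grid == 1], -1 + (-2 + -1) / 2)
  expect_equal(comp2$logl[comp2$grid == 2.5], (-4 + -9) / 2 + -2)

  far <- cline_profile(c(100, 101), c(0, 0))
  expect_error(composite_profile(a, far), "overlap")
})

test_that("coincidence LRT matches the closed form for quadratic profiles", {
  g <- seq(-15, 15, by = 0.005)
  for (ab in list(c(0, 2), c(-3, 1), c(0.5, 0.75))) {
    pa <- cline_profile(g, -(g - ab[1])^2 / 2)
    pb <- cline_profile(g, -(g - ab[2])^2 / 2)
    res <- lrt_coincidence(pa, pb)
    expect_equal(res$r_stat, (ab[1] - ab[2])^2 / 2, tolerance = 1e-6)
  }
  # identical profiles: coincident clines
  pa <- cline_profile(g, -(g - 1)^2 / 2)
  res0 <- lrt_coincidence(pa, pa)
  expect_equal(res0$r_stat, 0)
  expect_equal(res0$p_value, 1)

  # centers 0 and 2: R = 2, p from the chi-squared(1) upper tail
  res2 <- lrt_coincidence(cline_profile(g, -g^2 / 2),
                          cline_profile(g, -(g - 2)^2 / 2))
  expect_equal(res2$r_stat, 2, tolerance = 1e-6)
  expect_equal(res2$p_value, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-5)
})

test_that("R follows the two-curvature closed form and shrinks as profiles flatten", {
  g <- seq(-30, 30, by = 0.005)
  for (par in list(c(1, 1, 0, 2), c(2, 0.5, -1, 3), c(0.2, 1.5, 2, -2))) {
    ka <- par[1]; kb <- par[2]; a <- par[3]; b <- par[4]
    res <- lrt_coincidence(cline_profile(g, -ka * (g - a)^2 / 2),
                           cline_profile(g, -kb * (g - b)^2 / 2))
    expect_equal(res$r_stat, ka * kb * (a - b)^2 / (ka + kb), tolerance = 1e-5)
  }
  # flattening either profile (smaller curvature) decreases R, same centers
  rs <- sapply(c(2, 1, 0.5, 0.25), function(k)
    lrt_coincidence(cline_profile(g, -k * g^2 / 2),
                    cline_profile(g, -(g - 3)^2 / 2))$r_stat)
  expect_true(all(diff(rs) < 0))
})

test_that("R is non-negative, and zero only for coincident argmaxes", {
  g <- seq(-10, 10, by = 0.01)
  set.seed(14)
  for (i in 1:20) {
    a <- runif(1, -5, 5); b <- runif(1, -5, 5)
    res <- lrt_coincidence(cline_profile(g, -(g - a)^2),
                           cline_profile(g, -(g - b)^2))
    expect_gte(res$r_stat, 0)
    if (abs(a - b) > 0.05) expect_gt(res$r_stat, 0)
  }
})

test_that("sequential Bonferroni reproduces hand-stepped Holm decisions", {
  expect_equal(sequential_bonferroni(0.04), TRUE)
  expect_equal(sequential_bonferroni(0.06), FALSE)
  # 0.01 < 0.05/3, 0.02 < 0.05/2, 0.04 < 0.05 -> all significant
  expect_equal(sequential_bonferroni(c(0.01, 0.02, 0.04)), rep(TRUE, 3))
  # 0.03 > 0.05/3 stops the step-down immediately
  expect_equal(sequential_bonferroni(c(0.03, 0.03, 0.03)), rep(FALSE, 3))
  # flags come back in input order
  expect_equal(sequential_bonferroni(c(0.04, 0.001, 0.2)),
               c(FALSE, TRUE, FALSE))
  expect_equal(sequential_bonferroni(numeric(0)), logical(0))
})

test_that("pairwise comparisons flag the outlier and never pool corrections across groups", {
  g <- seq(-20, 40, by = 0.01)
  profs <- list(a1 = cline_profile(g, -20 * (g - 5)^2),
                a2 = cline_profile(g, -20 * (g - 5)^2),
                out = cline_profile(g, -20 * (g - 25)^2))
  cm <- compare_all(profs)
  pr <- cm$pairs
  expect_equal(pr$r_stat[pr$a == "a1" & pr$b == "a2"], 0)
  expect_equal(pr$p_value[pr$a == "a1" & pr$b == "a2"], 1)
  expect_true(all(pr$significant_holm[pr$b == "out" | pr$a == "out"]))
  expect_false(any(pr$significant_holm[pr$a == "a1" & pr$b == "a2"]))

  # marginal p-values: pooled correction would kill them, per-group keeps them
  gg <- seq(-10, 10, by = 0.01)
  shift <- sqrt(2 * qchisq(0.96, 1))   # p just under 0.05 per pair
  mk <- function(c0) cline_profile(gg, -(gg - c0)^2 / 2)
  profs2 <- list(m1 = mk(0), m2 = mk(shift), h1 = mk(0), h2 = mk(shift))
  plan <- data.frame(a = c("m1", "h1"), b = c("m2", "h2"),
                     group = c("morph", "hab"))
  sep <- compare_all(profs2, plan)
  expect_true(all(sep$pairs$significant_holm))
  pooled <- compare_all(profs2, transform(plan, group = "all"))
  expect_false(any(pooled$pairs$significant_holm))

  expect_error(compare_all(profs, data.frame(a = "a1", b = "nope")), "unknown")
})

test_that("type-I error of the coincidence test is near nominal under a shared center", {
  # Both profiles come from independent datasets sharing a true center. The
  # chi-squared(1) reference for the profile LRT is asymptotic in the number
  # of sites, so the calibration runs on a densely sampled transect (200
  # sites); sparse transects inflate the tail by the usual F-type
  # small-sample correction.
  n_rep <- 200
  crit <- qchisq(0.95, 1)
  x <- seq(0, 99.5, by = 0.5)
  cfg <- fit_config(seed = 0, iterations = 400, chains = 1,
                    profile_iterations = 20, center_grid_step = 4)
  rejections <- 0
  for (r in seq_len(n_rep)) {
    oa <- simulate_cline_observations(x, n = 15, c = 50, w = 10, sigma = 0.05,
                                      seed = 1000 + r)
    ob <- simulate_cline_observations(x, n = 15, c = 50, w = 10, sigma = 0.05,
                                      seed = 5000 + r)
    ca <- cfg; ca$seed <- 1000L + r
    cb <- cfg; cb$seed <- 5000L + r
    pa <- profile_center(oa, ca)
    pb <- profile_center(ob, cb)
    if (lrt_coincidence(pa, pb)$r_stat > crit) rejections <- rejections + 1
  }
  expect_lte(abs(rejections / n_rep - 0.05), 0.03)
})
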