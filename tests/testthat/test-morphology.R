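test_that("SVL-50 normalization scales non-SVL measurements and keeps SVL", {
  sp <- data.frame(SVL = c(50, 60, 40), CCS = c(3.0, 3.6, 2.0),
                   CCP = c(5, 6, 4.0))
  out <- normalize_to_svl50(sp)
  expect_equal(out$CCS, c(3.0, 3.0, 2.5))
  expect_equal(out$CCP[3], 5.0)
  expect_equal(out$SVL, sp$SVL)

  # renormalizing (SVL retained) is a no-op only at the reference size,
  # and applying twice to SVL = 50 rows equals applying once
  at50 <- normalize_to_svl50(out[1, ])
  expect_equal(at50, out[1, ])
  expect_false(isTRUE(all.equal(normalize_to_svl50(out)$CCS, out$CCS)))

  expect_error(normalize_to_svl50(data.frame(SVL = 0, CCS = 1)), "SVL")
})

test_that("adult-male filter is strict on SVL and sex, preserving order", {
  sp <- make_specimens(CCS = c(1, 2, 3, 4),
                       SVL = c(43.0, 43.1, 60, 60),
                       sex = c("male", "male", "female", "male"),
                       site_id = c("a", "b", "c", "d"))
  kept <- filter_adult_males(sp)
  expect_equal(kept$site_id, c("b", "d"))
  expect_equal(nrow(filter_adult_males(make_specimens(1, SVL = 30))), 0)
})

test_that("univariate discriminant statistics match hand-computed sums of squares", {
  # SS_within = 2 + 2 = 4, SS_total = 17.5, Lambda = 4/17.5, F = 4 * 13.5/4
  d <- univariate_discriminant(c(1, 2, 3), c(4, 5, 6))
  expect_equal(d$wilks_lambda, 4 / 17.5)
  expect_equal(d$f_stat, 13.5)
  expect_equal(d$canonical_r, sqrt(1 - 4 / 17.5))
  expect_equal(d$pct_misclassified, 0)

  same <- univariate_discriminant(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$wilks_lambda, 1)
  expect_equal(same$f_stat, 0)

  sep <- univariate_discriminant(c(1, 1, 1), c(5, 5, 5))
  expect_equal(sep$wilks_lambda, 0)
  expect_equal(sep$pct_misclassified, 0)

  expect_error(univariate_discriminant(c(2, 2), c(2, 2)), "variance")
})

test_that("canonical r^2 + lambda = 1 and lambda shrinks with group separation", {
  set.seed(7)
  for (i in 1:25) {
    a <- rnorm(10 + i); b <- rnorm(8 + i, mean = runif(1, -3, 3))
    d <- univariate_discriminant(a, b)
    expect_equal(d$canonical_r^2 + d$wilks_lambda, 1, tolerance = 1e-12)
  }
  # fixed spreads, growing separation
  set.seed(8)
  base_a <- rnorm(30); base_b <- rnorm(30)
  lambdas <- sapply(seq(0, 5, by = 0.5), function(sh)
    univariate_discriminant(base_a, base_b + sh)$wilks_lambda)
  expect_true(all(diff(lambdas) < 0))
})

test_that("trait scaling maps reference endpoints to 0 and 1 without clipping", {
  expect_equal(scale_trait(0.0), 0)
  expect_equal(scale_trait(3.1), 1)
  expect_equal(scale_trait(1.55), 0.5)
  expect_gt(scale_trait(3.5), 1)    # deliberately unclipped
  expect_lt(scale_trait(-0.1), 0)
  expect_error(scale_trait(1, ref_low = 2, ref_high = 2), "exceed")
})

test_that("site aggregation averages the character, drops small sites, projects x", {
  five <- make_specimens(CCS = c(3, 3, 3, 3, 3), site_id = "big",
                         longitude = -96.19)
  four <- make_specimens(CCS = c(1, 1, 1, 1), site_id = "small",
                         longitude = -96.72)
  obs <- aggregate_sites(rbind(five, four))
  expect_equal(nrow(obs), 1)
  expect_equal(obs$site_id, "big")
  expect_equal(obs$value, scale_trait(3))
  expect_equal(obs$n, 5)
  expect_equal(obs$x_km, transect_x_km(-96.19, 49.88))

  # two qualifying sites: means match direct arithmetic
  b <- make_specimens(CCS = c(0, 1, 2, 3, 4), site_id = "west",
                      longitude = -96.9)
  obs2 <- aggregate_sites(rbind(five, b))
  expect_equal(sort(obs2$value), sort(scale_trait(c(mean(c(0:4)), 3))))

  expect_error(aggregate_sites(four), "at least 5")
})

test_that("character screening ranks the diagnostic character first", {
  refs <- generate_reference_specimens(scenario_config(seed = 11))
  scr <- screen_characters(normalize_to_svl50(refs$americanus),
                           normalize_to_svl50(refs$hemiophrys))
  expect_equal(scr$character[1], "CCS")
  expect_lt(scr$wilks_lambda[1], 0.2)
  expect_equal(scr$character[2], "CCP")
  # non-diagnostic characters barely discriminate
  expect_true(all(scr$wilks_lambda[scr$character %in%
                                     c("HW", "PGL", "PGR", "SVL")] > 0.9))
})
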