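# Shared fixtures built in code.

# a profile with exactly quadratic log-likelihood -kappa (c - a)^2 / 2
quadratic_profile <- function(a, kappa = 1, grid = seq(a - 12, a + 12, by = 0.01)) {
  cline_profile(grid, -kappa * (grid - a)^2 / 2)
}

# noise-free observations lying exactly on a tanh cline
exact_cline_obs <- function(x, c, w, p_min = 0, p_max = 1, n = 10) {
  m <- cline_model(c = c, w = w, p_min = p_min, p_max = p_max, sigma = 1)
  data.frame(site_id = sprintf("S%02d", seq_along(x)), period = "t",
             x_km = x, value = cline_expectation(x, m),
             n = rep_len(n, length(x)))
}

# minimal specimen table builder
make_specimens <- function(CCS, SVL = 50, sex = "male", site_id = "A",
                           period = "p1", longitude = -96.5, latitude = 49.88) {
  k <- max(length(CCS), length(SVL), length(sex))
  data.frame(site_id = rep_len(site_id, k), period = rep_len(period, k),
             longitude = rep_len(longitude, k), latitude = rep_len(latitude, k),
             sex = rep_len(sex, k),
             CCS = rep_len(CCS, k), SVL = rep_len(SVL, k))
}

# standard recovery-scenario dataset: 20 sites, 15 specimens per site,
# residual scale 0.05, true center 40 km, width 10 km
recovery_obs <- function(seed, c = 40, w = 10, sigma = 0.05) {
  simulate_cline_observations(seq(0, 95, by = 5), n = 15, c = c, w = w,
                              sigma = sigma, seed = seed)
}

fast_cfg <- function(seed = 1, ...) {
  fit_config(seed = seed, iterations = 500, chains = 1,
             profile_iterations = 60, center_grid_step = 1, ...)
}
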