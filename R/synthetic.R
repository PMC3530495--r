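#' Scenario configuration for the synthetic hybrid zone
#'
#' Defines the study conditions the generator emulates: a hybrid zone between
#' a forest-dwelling eastern species (*Anaxyrus americanus*, separated cranial
#' crests, CCS about 3.1 mm) and a prairie western species (*A. hemiophrys*,
#' fused crests, CCS about 0 mm) along an east-west transect, sampled in four
#' collection windows during which the cline center moved 68 -> 55 -> 30 ->
#' 40 km east of the projection center, plus a forest-prairie habitat
#' transition quantified from quadrat maps in four eras, narrowing over time
#' (widths 31 -> 25.5 -> 17 -> 10.5 km).
#'
#' @param periods Data frame of toad collection windows: `label`,
#'   `center_km`, `width_km`, `midpoint_yr`.
#' @param eras Data frame of habitat map eras: `label`, `center_km`,
#'   `width_km`, `noise_sd`, `midpoint_yr`.
#' @param site_x Transect positions (km) of toad sampling sites.
#' @param n_range Per-site specimen count range, drawn uniformly (default
#'   5 to 30).
#' @param americanus,hemiophrys Parental CCS distributions, `c(mean, sd)` mm.
#' @param residual_sd Site-level residual scale for
#'   [generate_site_observations()] (trait units; default 0.05).
#' @param seed Integer seed; every generator draw descends from it.
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(
    periods = data.frame(
      label = c("1960-1962", "1968-1970", "1977-1979", "2007-2008"),
      center_km = c(68, 55, 30, 40),
      width_km = c(29, 5, 5, 5),
      midpoint_yr = c(1961, 1969, 1978, 2007.5)),
    eras = data.frame(
      label = c("1948-1957", "1969-1974", "1980-1990", "1995-2001"),
      center_km = c(46, 50, 45, 43),
      width_km = c(31, 25.5, 17, 10.5),
      noise_sd = 0.05,
      midpoint_yr = c(1952.5, 1971.5, 1985, 1998)),
    site_x = seq(-20, 120, by = 5),
    n_range = c(5, 30),
    americanus = c(mean = 3.1, sd = 0.6),
    hemiophrys = c(mean = 0.0, sd = 0.1),
    residual_sd = 0.05,
    seed = 1) {
  stopifnot(is.data.frame(periods),
            all(c("label", "center_km", "width_km", "midpoint_yr") %in% names(periods)),
            all(periods$width_km > 0),
            is.data.frame(eras),
            all(c("label", "center_km", "width_km", "noise_sd", "midpoint_yr") %in% names(eras)),
            all(eras$width_km > 0), all(eras$noise_sd >= 0),
            length(site_x) >= 5, all(is.finite(site_x)),
            length(n_range) == 2, n_range[1] >= 1, n_range[1] <= n_range[2],
            americanus[["sd"]] >= 0, hemiophrys[["sd"]] >= 0,
            residual_sd >= 0)
  structure(list(periods = periods, eras = eras, site_x = sort(site_x),
                 n_range = as.integer(n_range),
                 americanus = americanus, hemiophrys = hemiophrys,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Synthetic hybrid-zone scenario: %d periods, %d habitat eras, %d sites, seed %d\n",
              nrow(x$periods), nrow(x$eras), length(x$site_x), x$seed))
  cat("  toad cline centers (km):", paste(x$periods$center_km, collapse = ", "), "\n")
  cat("  habitat centers (km):   ", paste(x$eras$center_km, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate site observations from a single cline
#'
#' Draws one site-observation table from the sigmoid cline: each site's value
#' is the cline expectation plus Gaussian sampling noise of standard deviation
#' `sigma / sqrt(n)` (the distribution of a mean of `n` specimens with
#' individual residual scale `sigma`).
#'
#' @param x Site positions (km).
#' @param n Specimens per site (scalar or vector).
#' @param c,w,p_min,p_max Cline parameters (see [cline_model()]).
#' @param sigma Individual-level residual scale (default 0.05).
#' @param seed Integer seed.
#' @param period Period label attached to the observations.
#'
#' @return Site-observation data frame (`site_id`, `period`, `x_km`, `value`,
#'   `n`).
#' @export
simulate_cline_observations <- function(x, n = 15, c, w, p_min = 0, p_max = 1,
                                        sigma = 0.05, seed = 1,
                                        period = "sim") {
  stopifnot(length(x) >= 1, all(is.finite(x)), all(n >= 1), w > 0, sigma >= 0)
  n <- rep_len(as.integer(n), length(x))
  model <- cline_model(c = c, w = w, p_min = p_min, p_max = p_max,
                       sigma = max(sigma, 1e-12))
  value <- .with_seed(seed, {
    cline_expectation(x, model) + stats::rnorm(length(x), 0, sigma / sqrt(n))
  })
  data.frame(site_id = sprintf("S%02d", seq_along(x)), period = period,
             x_km = x, value = value, n = n)
}

#' Generate specimen records for every collection period
#'
#' Individual-level generator: per period and site, draws a specimen count
#' uniformly from `n_range`, then individual CCS values around the cline
#' expectation (parental endpoint means interpolated along the cline, with the
#' individual standard deviation likewise interpolated between the parental
#' SDs) truncated at 0 mm — crest separation cannot be negative, and the fused
#' western morph legitimately measures 0. SVL is uniform on 44-75 mm and all
#' records are adult males, matching the analysis filter. Non-diagnostic
#' characters (CCP, CCA, HW, PGL, PGR) are drawn with realistic means and a
#' weak (CCP) or absent species signal so that character screening has
#' something to rank. Site coordinates place each site at its transect
#' position on the center latitude.
#'
#' @param cfg A [scenario_config()].
#' @param center Projection center used to back-convert site x to longitude.
#'
#' @return Specimen data frame: `site_id`, `period`, `longitude`, `latitude`,
#'   `sex`, `CCA`, `CCP`, `CCS`, `HW`, `PGL`, `PGR`, `SVL`.
#' @export
generate_specimens <- function(cfg = scenario_config(),
                               center = projection_center()) {
  stopifnot(inherits(cfg, "scenario_config"))
  am <- cfg$americanus; hem <- cfg$hemiophrys
  lon <- transect_x_to_longitude(cfg$site_x, center)

  .with_seed(cfg$seed, {
    out <- list()
    for (pi in seq_len(nrow(cfg$periods))) {
      per <- cfg$periods[pi, ]
      model <- cline_model(c = per$center_km, w = per$width_km,
                           p_min = 0, p_max = 1, sigma = 1)
      p <- cline_expectation(cfg$site_x, model)
      for (si in seq_along(cfg$site_x)) {
        n <- sample(cfg$n_range[1]:cfg$n_range[2], 1)
        mu_ccs <- hem[["mean"]] + (am[["mean"]] - hem[["mean"]]) * p[si]
        sd_ccs <- hem[["sd"]] + (am[["sd"]] - hem[["sd"]]) * min(max(p[si], 0), 1)
        ccs <- pmax(0, stats::rnorm(n, mu_ccs, sd_ccs))
        # CCP carries a weaker species signal (6.2 vs 4.7 mm, common sd 0.9)
        mu_ccp <- 4.7 + (6.2 - 4.7) * p[si]
        out[[length(out) + 1]] <- data.frame(
          site_id = sprintf("P%dS%02d", pi, si),
          period = per$label,
          longitude = lon[si], latitude = center$latitude,
          sex = "male",
          CCA = stats::rnorm(n, 6.5, 0.7),
          CCP = stats::rnorm(n, mu_ccp, 0.9),
          CCS = ccs,
          HW = stats::rnorm(n, 16, 1.2),
          PGL = stats::rnorm(n, 9, 1),
          PGR = stats::rnorm(n, 9, 1),
          SVL = stats::runif(n, 44, 75))
      }
    }
    do.call(rbind, out)
  })
}

#' Generate parental reference specimens
#'
#' Pure-species samples away from the hybrid zone, used to screen characters
#' and to fix the 0-1 trait-scaling endpoints: CCS near 3.1 +/- 0.6 mm for
#' *A. americanus* and 0.0 +/- 0.1 mm (truncated at 0) for *A. hemiophrys*,
#' CCP 6.2 vs 4.7 +/- 0.9 mm, other characters without a species signal.
#'
#' @param cfg A [scenario_config()].
#' @param n_per_species Reference sample size per species (default 80).
#'
#' @return List with specimen data frames `americanus` and `hemiophrys`.
#' @export
generate_reference_specimens <- function(cfg = scenario_config(),
                                         n_per_species = 80) {
  stopifnot(inherits(cfg, "scenario_config"), n_per_species >= 2)
  draw <- function(n, ccs_mean, ccs_sd, ccp_mean, species) {
    data.frame(site_id = paste0("ref_", species), period = "reference",
               longitude = NA_real_, latitude = NA_real_, sex = "male",
               CCA = stats::rnorm(n, 6.5, 0.7),
               CCP = stats::rnorm(n, ccp_mean, 0.9),
               CCS = pmax(0, stats::rnorm(n, ccs_mean, ccs_sd)),
               HW = stats::rnorm(n, 16, 1.2),
               PGL = stats::rnorm(n, 9, 1),
               PGR = stats::rnorm(n, 9, 1),
               SVL = stats::runif(n, 44, 75))
  }
  .with_seed(cfg$seed + 2L, {
    list(americanus = draw(n_per_species, cfg$americanus[["mean"]],
                           cfg$americanus[["sd"]], 6.2, "americanus"),
         hemiophrys = draw(n_per_species, cfg$hemiophrys[["mean"]],
                           cfg$hemiophrys[["sd"]], 4.7, "hemiophrys"))
  })
}

#' Generate site observations for every collection period
#'
#' Site-level generator that bypasses the specimen level for fast tests: per
#' period, site values follow the period's cline with sampling noise of
#' standard deviation `residual_sd / sqrt(n_i)`.
#'
#' @param cfg A [scenario_config()].
#' @return Site-observation data frame across all periods.
#' @export
generate_site_observations <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  .with_seed(cfg$seed + 1L, {
    out <- lapply(seq_len(nrow(cfg$periods)), function(pi) {
      per <- cfg$periods[pi, ]
      n <- sample(cfg$n_range[1]:cfg$n_range[2], length(cfg$site_x),
                  replace = TRUE)
      obs <- simulate_cline_observations(
        cfg$site_x, n = n, c = per$center_km, w = per$width_km,
        sigma = cfg$residual_sd,
        seed = sample.int(.Machine$integer.max - 1L, 1),
        period = per$label)
      obs$site_id <- sprintf("P%dS%02d", pi, seq_along(cfg$site_x))
      obs
    })
    do.call(rbind, out)
  })
}

#' Generate habitat quadrat sets for every map era
#'
#' Lays out 17 quadrat sets per era spanning the forest-prairie transition:
#' 15 sets every 10 km along the transect plus two intercalated 5 km to either
#' side of the centermost set, each set anchored just south of the reference
#' latitude band. Per quadrat, the forest fraction follows the era's habitat
#' cline — prairie (0) in the west, forest (1) in the east — plus truncated
#' Gaussian noise, and is converted to hectares of forest/other/water with a
#' random water share of 0-20 ha per 100-ha quadrat.
#'
#' @param cfg A [scenario_config()].
#' @param center Projection center used to place sets geographically.
#'
#' @return Long-format quadrat data frame: `set_id`, `era`, `lon_deg`,
#'   `lat_deg`, `quadrat_index`, `forest_ha`, `other_ha`, `water_ha`.
#' @export
generate_habitat_quadrats <- function(cfg = scenario_config(),
                                      center = projection_center()) {
  stopifnot(inherits(cfg, "scenario_config"))
  base_x <- seq(-20, 120, by = 10)
  mid <- base_x[which.min(abs(base_x - stats::median(cfg$eras$center_km)))]
  set_x <- sort(unique(c(base_x, mid - 5, mid + 5)))
  # anchor about 25 km south of the projection latitude (the highway band)
  anchor <- gnomonic_inverse(set_x * 1000, -25000, center)

  .with_seed(cfg$seed + 3L, {
    out <- list()
    for (ei in seq_len(nrow(cfg$eras))) {
      era <- cfg$eras[ei, ]
      model <- cline_model(c = era$center_km, w = era$width_km,
                           p_min = 0, p_max = 1, sigma = 1)
      f0 <- cline_expectation(set_x, model)
      for (si in seq_along(set_x)) {
        f <- pmin(pmax(f0[si] + stats::rnorm(10, 0, era$noise_sd), 0), 1)
        water <- stats::runif(10, 0, 20)
        forest <- f * (100 - water)
        out[[length(out) + 1]] <- data.frame(
          set_id = sprintf("Q%02d", si),
          era = era$label,
          lon_deg = anchor$longitude[si],
          lat_deg = anchor$latitude[si],
          quadrat_index = 1:10,
          forest_ha = forest,
          other_ha = 100 - water - forest,
          water_ha = water)
      }
    }
    do.call(rbind, out)
  })
}
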