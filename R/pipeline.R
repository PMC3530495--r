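#' Displacement summary of a cline-center trajectory
#'
#' Summarizes how a cline center moved across collection windows: signed
#' consecutive moves (east positive, west negative, matching the transect x
#' axis), per-interval rates `|move| / years` using the windows' midpoint
#' calendar years, the net displacement (last minus first center) and the
#' total path length (sum of absolute moves).
#'
#' @param centers Numeric vector of cline centers (km east of the projection
#'   center), one per period, in chronological order.
#' @param midpoints Midpoint calendar years of the collection windows,
#'   strictly increasing.
#' @param labels Optional period labels.
#'
#' @return An object of class `displacement_summary`: list with `intervals`
#'   (data frame: from, to, move_km signed, years, rate_km_per_yr),
#'   `net_km` (signed) and `total_km`.
#' @export
#' @examples
#' displacement_summary(c(68, 55, 30, 40), c(1961, 1969, 1978, 2007.5))
displacement_summary <- function(centers, midpoints,
                                 labels = as.character(midpoints)) {
  stopifnot(length(centers) >= 2, length(centers) == length(midpoints),
            length(labels) == length(centers),
            all(is.finite(centers)), all(is.finite(midpoints)))
  if (any(diff(midpoints) <= 0))
    stop("period midpoints must be strictly increasing")
  move <- diff(centers)
  years <- diff(midpoints)
  structure(list(
    intervals = data.frame(from = labels[-length(labels)], to = labels[-1],
                           move_km = move, years = years,
                           rate_km_per_yr = abs(move) / years),
    net_km = centers[length(centers)] - centers[1],
    total_km = sum(abs(move))),
    class = "displacement_summary")
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat("Cline-center displacement (east positive, west negative):\n")
  print(x$intervals, row.names = FALSE)
  cat(sprintf("  net %+.1f km, total path %.1f km\n", x$net_km, x$total_km))
  invisible(x)
}

.nearest_in_time <- function(period_mid, era_mids) which.min(abs(era_mids - period_mid))

#' Run the full hybrid-zone analysis pipeline
#'
#' Orchestrates the study reproduction end-to-end. Inputs are either files
#' (specimen and quadrat tables) or, by default, tables from the synthetic
#' generator. Stages: morphometric normalization, adult-male filtering and
#' per-site aggregation of the diagnostic character for each collection
#' period; forest-fraction aggregation of quadrat sets for each map era;
#' maximum-likelihood cline fits and center likelihood profiles for every
#' period and era; pairwise coincidence tests within three comparison groups
#' (morphology vs. morphology, habitat vs. habitat, and each morphology
#' period against the habitat era nearest in time), each group corrected by
#' sequential Bonferroni separately; and a displacement summary of the
#' morphology centers over time. Deterministic given the seed.
#'
#' @param config List (or path to a JSON file with the same fields):
#'   \describe{
#'     \item{specimen_file, quadrat_file}{Optional input table paths; when
#'       absent, tables are generated from `scenario`.}
#'     \item{scenario}{A [scenario_config()] (default scenario if absent).}
#'     \item{character}{Diagnostic character to aggregate (default "CCS").}
#'     \item{min_svl, min_per_site}{Filters (defaults 43 mm, 5).}
#'     \item{ref_low, ref_high}{Trait-scaling endpoints in mm (defaults 0.0
#'       and 3.1, the parental reference means).}
#'     \item{fit}{A [fit_config()]; its seed drives all fitting.}
#'     \item{alpha}{Significance level (default 0.05).}
#'     \item{out_dir}{Optional directory; when set, per-cline profiles (TSV),
#'       the cline table, comparison matrices and the displacement summary
#'       (TSV/JSON) are written there.}
#'   }
#'
#' @return An object of class `study_result`: list with `clines` (data frame:
#'   label, group, c_hat_km, c_hat_lon, w_km, support_low_km,
#'   support_high_km, lmax, n_sites), `profiles` (named list), `comparisons`
#'   (named list of [compare_all()] results per group), `displacement`
#'   (morphology centers over time) and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  scenario <- config$scenario
  if (is.null(scenario)) scenario <- scenario_config()
  if (!inherits(scenario, "scenario_config"))
    scenario <- do.call(scenario_config, scenario)   # e.g. parsed from JSON
  fitcfg <- config$fit
  if (is.null(fitcfg)) fitcfg <- fit_config(seed = scenario$seed)
  if (!inherits(fitcfg, "fit_config"))
    fitcfg <- do.call(fit_config, fitcfg)
  character <- config$character %||% "CCS"
  min_svl <- config$min_svl %||% 43
  min_per_site <- config$min_per_site %||% 5
  ref_low <- config$ref_low %||% 0.0
  ref_high <- config$ref_high %||% 3.1
  alpha <- config$alpha %||% 0.05
  center <- projection_center()

  # --- morphology: specimens -> per-period site observations ----------------
  specimens <- if (!is.null(config$specimen_file)) {
    read_specimens(config$specimen_file)
  } else {
    generate_specimens(scenario, center)
  }
  specimens <- filter_adult_males(specimens, min_svl)
  specimens <- normalize_to_svl50(specimens)
  morph_obs <- aggregate_sites(specimens, character = character,
                               min_per_site = min_per_site,
                               ref_low = ref_low, ref_high = ref_high,
                               center = center)

  # --- habitat: quadrats -> per-era site observations -----------------------
  quadrats <- if (!is.null(config$quadrat_file)) {
    read_quadrats(config$quadrat_file)
  } else {
    generate_habitat_quadrats(scenario, center)
  }
  hab_obs <- habitat_observations(quadrats, center)

  # --- cline fits and center profiles ---------------------------------------
  fit_one <- function(obs_all, label, group, task_seed) {
    obs <- obs_all[obs_all$period == label, , drop = FALSE]
    if (nrow(obs) < 5)
      stop("stage cline_fit [", group, "/", label, "]: fewer than 5 sites")
    cfg <- fitcfg
    cfg$seed <- as.integer(fitcfg$seed + task_seed)
    fit <- fit_cline(obs, cfg)
    prof <- profile_center(obs, cfg, fit = fit)
    list(label = label, group = group, fit = fit, profile = prof,
         n_sites = nrow(obs))
  }
  periods <- unique(morph_obs$period)
  eras <- unique(hab_obs$period)
  tasks <- c(lapply(seq_along(periods), function(i)
               fit_one(morph_obs, periods[i], "morphology", i)),
             lapply(seq_along(eras), function(i)
               fit_one(hab_obs, eras[i], "habitat", 100L + i)))

  clines <- do.call(rbind, lapply(tasks, function(t) {
    s <- t$profile$support
    data.frame(label = t$label, group = t$group,
               c_hat_km = t$profile$c_hat,
               c_hat_lon = transect_x_to_longitude(t$profile$c_hat, center),
               w_km = t$fit$w,
               support_low_km = s$low, support_high_km = s$high,
               lmax = t$profile$lmax, n_sites = t$n_sites)
  }))
  profiles <- stats::setNames(lapply(tasks, `[[`, "profile"),
                              paste(vapply(tasks, `[[`, "", "group"),
                                    vapply(tasks, `[[`, "", "label"), sep = ":"))

  # --- coincidence tests in three separately corrected groups ---------------
  key <- function(group, label) paste(group, label, sep = ":")
  morph_keys <- key("morphology", periods)
  hab_keys <- key("habitat", eras)
  pair_plan <- function(keys) {
    if (length(keys) < 2) return(NULL)
    cmb <- utils::combn(keys, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  }
  comparisons <- list()
  mm <- pair_plan(morph_keys)
  if (!is.null(mm)) {
    mm$group <- "morphology-morphology"
    comparisons[["morphology-morphology"]] <-
      compare_all(profiles[morph_keys], mm, alpha)
  }
  hh <- pair_plan(hab_keys)
  if (!is.null(hh)) {
    hh$group <- "habitat-habitat"
    comparisons[["habitat-habitat"]] <-
      compare_all(profiles[hab_keys], hh, alpha)
  }
  # each toad period against the forest-cover era nearest in time
  pm <- scenario$periods$midpoint_yr[match(periods, scenario$periods$label)]
  em <- scenario$eras$midpoint_yr[match(eras, scenario$eras$label)]
  if (!any(is.na(pm)) && !any(is.na(em)) && length(eras) >= 1) {
    mh <- data.frame(a = morph_keys,
                     b = hab_keys[vapply(pm, .nearest_in_time, 1L, era_mids = em)],
                     group = "morphology-habitat")
    comparisons[["morphology-habitat"]] <-
      compare_all(profiles[unique(c(mh$a, mh$b))], mh, alpha)
  }

  # --- morphology center trajectory -----------------------------------------
  displacement <- NULL
  if (length(periods) >= 2 && !any(is.na(pm))) {
    o <- order(pm)
    displacement <- displacement_summary(
      clines$c_hat_km[match(periods, clines$label)][o], pm[o], periods[o])
  }

  result <- structure(list(clines = clines, profiles = profiles,
                           comparisons = comparisons,
                           displacement = displacement,
                           config = list(character = character,
                                         min_svl = min_svl,
                                         min_per_site = min_per_site,
                                         ref_low = ref_low, ref_high = ref_high,
                                         alpha = alpha,
                                         seed = fitcfg$seed)),
                      class = "study_result")

  if (!is.null(config$out_dir)) .write_study_result(result, config$out_dir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_study_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$clines, file.path(out_dir, "clines.tsv"))
  for (nm in names(result$profiles)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    write_profile(result$profiles[[nm]],
                  file.path(out_dir, paste0("profile_", safe, ".tsv")))
  }
  for (nm in names(result$comparisons)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", nm)
    .write_tsv(result$comparisons[[nm]]$pairs,
               file.path(out_dir, paste0("comparisons_", safe, ".tsv")))
  }
  if (!is.null(result$displacement)) {
    .write_tsv(result$displacement$intervals,
               file.path(out_dir, "displacement.tsv"))
  }
  jsonlite::write_json(
    list(clines = result$clines,
         displacement = if (is.null(result$displacement)) NULL else
           list(intervals = result$displacement$intervals,
                net_km = result$displacement$net_km,
                total_km = result$displacement$total_km),
         config = result$config),
    file.path(out_dir, "study_result.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Hybrid-zone study result\n")
  cat("Fitted clines (centers to 1 km, longitudes to 0.01 deg, widths to 0.5 km):\n")
  tab <- x$clines
  tab$c_hat_km <- round(tab$c_hat_km)
  tab$c_hat_lon <- round(tab$c_hat_lon, 2)
  tab$w_km <- round(tab$w_km / 0.5) * 0.5
  tab$support_low_km <- round(tab$support_low_km, 1)
  tab$support_high_km <- round(tab$support_high_km, 1)
  tab$lmax <- round(tab$lmax, 2)
  print(tab, row.names = FALSE)
  if (!is.null(x$displacement)) print(x$displacement)
  for (nm in names(x$comparisons)) {
    cat("\n[", nm, "]\n", sep = "")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}
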