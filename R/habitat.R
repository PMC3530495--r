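#' Forest fraction of a land-cover quadrat
#'
#' Each 1-km^2 quadrat is partitioned into forest, other terrain and open
#' water, in hectares summing to 100. The forest fraction is forest area
#' relative to *land* area, i.e. water is removed from the denominator:
#' `forest_ha / (100 - water_ha)`. 0 is a completely unforested quadrat and 1
#' a completely forested one. An all-water quadrat has no defined fraction and
#' returns `NA` so that [set_average()] can skip it.
#'
#' @param forest_ha,other_ha,water_ha Numeric vectors of hectares (each >= 0;
#'   per quadrat they must sum to 100 within `tol`).
#' @param tol Tolerance on the 100-ha closure check.
#'
#' @return Numeric vector of forest fractions in `[0, 1]`, `NA` where the
#'   quadrat is entirely water.
#' @export
#' @examples
#' forest_fraction(30, 50, 20)  # 0.375
forest_fraction <- function(forest_ha, other_ha, water_ha, tol = 1e-6) {
  stopifnot(length(forest_ha) == length(other_ha),
            length(forest_ha) == length(water_ha))
  if (any(forest_ha < 0 | other_ha < 0 | water_ha < 0))
    stop("areas must be non-negative")
  total <- forest_ha + other_ha + water_ha
  if (any(abs(total - 100) > tol))
    stop("quadrat areas must sum to 100 ha")
  # land area: total minus water, expressed as forest + other so the
  # fraction is scale-free in the areas
  land <- forest_ha + other_ha
  ifelse(land > 1e-9, forest_ha / land, NA_real_)
}

#' Average forest cover over a set of quadrats
#'
#' Collapses one quadrat set (nominally ten 1-km^2 quadrats in a north-south
#' line anchored at the set's northernmost quadrat) to a single habitat site
#' observation: the arithmetic mean of the defined forest fractions, with `n`
#' the number of quadrats contributing. All-water quadrats are skipped, not
#' counted as zero forest.
#'
#' @param quadrats Data frame for one set, with columns `forest_ha`,
#'   `other_ha`, `water_ha` and (for positioning) `lon_deg`, `lat_deg` on the
#'   anchor row(s).
#' @param set_id,era Labels carried into the output.
#' @param center Projection center for the transect axis.
#'
#' @return One-row site-observation data frame (`site_id`, `period`, `x_km`,
#'   `value`, `n`).
#' @export
set_average <- function(quadrats, set_id = quadrats$set_id[1],
                        era = quadrats$era[1], center = projection_center()) {
  stopifnot(is.data.frame(quadrats),
            all(c("forest_ha", "other_ha", "water_ha") %in% names(quadrats)))
  fr <- forest_fraction(quadrats$forest_ha, quadrats$other_ha, quadrats$water_ha)
  fr <- fr[!is.na(fr)]
  if (length(fr) == 0)
    stop("all quadrats in set are water; forest cover undefined")
  data.frame(site_id = as.character(set_id),
             period = as.character(era),
             x_km = transect_x_km(quadrats$lon_deg[1], quadrats$lat_deg[1], center),
             value = mean(fr),
             n = length(fr))
}

#' Habitat site observations from a quadrat table
#'
#' Applies [set_average()] to every (set, era) group of a long-format quadrat
#' table, yielding forest-cover site observations spanning the forest-prairie
#' transition for each map era.
#'
#' @param quadrats Long-format data frame, one row per quadrat, with columns
#'   `set_id`, `era`, `lon_deg`, `lat_deg`, `quadrat_index`, `forest_ha`,
#'   `other_ha`, `water_ha`.
#' @param center Projection center for the transect axis.
#'
#' @return Site-observation data frame ordered by era then x.
#' @export
habitat_observations <- function(quadrats, center = projection_center()) {
  needed <- c("set_id", "era", "lon_deg", "lat_deg",
              "forest_ha", "other_ha", "water_ha")
  stopifnot(is.data.frame(quadrats), all(needed %in% names(quadrats)))
  key <- interaction(quadrats$set_id, quadrats$era, drop = TRUE)
  obs <- do.call(rbind, lapply(split(quadrats, key), set_average, center = center))
  rownames(obs) <- NULL
  obs[order(obs$period, obs$x_km), , drop = FALSE]
}
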