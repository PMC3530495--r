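#' @name morphology
#' @title Morphometric normalization, filtering and character screening
#'
#' @description
#' Specimen tables carry one row per measured toad: a site label, geographic
#' coordinates, a collection-period label, sex, and measurements in mm of the
#' diagnostic characters CCA, CCP, CCS (cranial crest anterior / posterior /
#' separation), HW (head width), PGL and PGR (parotoid gland lengths) and SVL
#' (snout-vent length). The cranial crest separation CCS is the diagnostic
#' character for the *Anaxyrus americanus* / *A. hemiophrys* pair: crests are
#' separated in *americanus* and fused into a boss (CCS = 0) in *hemiophrys*.
#' A CCS of exactly 0 mm is a legitimate measurement, not missing data.
NULL

.measure_cols <- c("CCA", "CCP", "CCS", "HW", "PGL", "PGR", "SVL")

#' Normalize measurements to an idealized 50 mm SVL
#'
#' Controls for individual body size by scaling every non-SVL measurement by
#' 50 / SVL, i.e. to the value it would take on a toad of snout-vent length
#' 50 mm under isometry. SVL itself is retained unchanged so that adult-size
#' filtering can still be applied afterwards.
#'
#' @param specimens Data frame with (at least) numeric columns among
#'   `CCA, CCP, CCS, HW, PGL, PGR` plus a positive `SVL` column (all mm).
#' @param ref_svl Reference snout-vent length in mm (default 50).
#'
#' @return The data frame with scaled measurement columns; `SVL` unchanged.
#' @export
#' @examples
#' normalize_to_svl50(data.frame(SVL = 60, CCS = 3.6))$CCS  # 3.0
normalize_to_svl50 <- function(specimens, ref_svl = 50) {
  stopifnot(is.data.frame(specimens), "SVL" %in% names(specimens))
  svl <- specimens$SVL
  if (any(!is.finite(svl)) || any(svl <= 0))
    stop("SVL must be positive and finite for all specimens")
  for (col in setdiff(intersect(.measure_cols, names(specimens)), "SVL")) {
    specimens[[col]] <- specimens[[col]] * (ref_svl / svl)
  }
  specimens
}

#' Filter to adult males
#'
#' Keeps male specimens with SVL strictly greater than `min_svl` (default
#' 43 mm, the adult-male size threshold for these toads). Row order is
#' preserved; an empty result is allowed.
#'
#' @param specimens Data frame with columns `sex` and `SVL`.
#' @param min_svl Minimum SVL in mm (exclusive).
#'
#' @return The qualifying subset of rows.
#' @export
filter_adult_males <- function(specimens, min_svl = 43) {
  stopifnot(is.data.frame(specimens), all(c("sex", "SVL") %in% names(specimens)),
            min_svl > 0)
  specimens[specimens$sex == "male" & specimens$SVL > min_svl, , drop = FALSE]
}

#' Univariate two-group discriminant statistics
#'
#' Screens a single character for its power to separate two reference samples
#' (e.g. the two parental species) with the univariate special case of
#' discriminant analysis. Wilks' Lambda is the ratio of within-group to total
#' sum of squares; the canonical correlation satisfies the two-group identity
#' `canonical_r^2 = 1 - wilks_lambda`. The misclassification rate applies the
#' equal-prior, equal-variance rule: the cutoff is the midpoint of the two
#' group means, with boundary values assigned to group A.
#'
#' @param group_a,group_b Numeric vectors of at least 2 finite values each.
#'
#' @return A one-row data frame with columns `wilks_lambda`, `f_stat`,
#'   `canonical_r`, `pct_misclassified` (percent of all values on the wrong
#'   side of the midpoint cutoff).
#' @export
#' @examples
#' univariate_discriminant(c(1, 2, 3), c(4, 5, 6))
univariate_discriminant <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2 || any(!is.finite(c(a, b))))
    stop("each group needs at least 2 finite values")
  all_v <- c(a, b)
  ss_total <- sum((all_v - mean(all_v))^2)
  if (ss_total == 0)
    stop("zero total variance: discriminant statistics undefined")
  ss_within <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  lambda <- ss_within / ss_total
  n <- length(all_v)
  f_stat <- if (lambda == 0) Inf else (n - 2) * (1 - lambda) / lambda

  cutoff <- (mean(a) + mean(b)) / 2
  if (mean(a) <= mean(b)) {
    # ties (values exactly on the cutoff) go to group A
    wrong <- sum(a > cutoff) + sum(b <= cutoff)
  } else {
    wrong <- sum(a < cutoff) + sum(b >= cutoff)
  }
  data.frame(wilks_lambda = lambda,
             f_stat = f_stat,
             canonical_r = sqrt(1 - lambda),
             pct_misclassified = 100 * wrong / n)
}

#' Screen several characters against two reference samples
#'
#' Applies [univariate_discriminant()] to each measurement column shared by
#' two reference-specimen tables, returning one row per character sorted by
#' increasing Wilks' Lambda (strongest discriminator first).
#'
#' @param ref_a,ref_b Data frames of (normalized) reference specimens for the
#'   two groups.
#' @param characters Character vector of columns to screen; defaults to all
#'   measurement columns present in both tables.
#'
#' @return Data frame with a `character` column plus the discriminant
#'   statistics.
#' @export
screen_characters <- function(ref_a, ref_b,
                              characters = intersect(.measure_cols,
                                                     intersect(names(ref_a), names(ref_b)))) {
  stopifnot(length(characters) >= 1)
  res <- do.call(rbind, lapply(characters, function(ch) {
    cbind(character = ch, univariate_discriminant(ref_a[[ch]], ref_b[[ch]]))
  }))
  res[order(res$wilks_lambda), , drop = FALSE]
}

#' Scale site means of a character to the 0-1 trait axis
#'
#' Maps a character's site means onto the nominal 0-1 trait scale by linear
#' interpolation between reference endpoints: the *hemiophrys* reference mean
#' (default 0.0 mm CCS) maps to 0 and the *americanus* reference mean (default
#' 3.1 mm CCS) maps to 1. Values are deliberately not clipped; the cline
#' model's tail parameters absorb deviations beyond the endpoints.
#'
#' @param site_means Numeric vector of per-site character means (mm).
#' @param ref_low Reference mean mapping to 0 (mm).
#' @param ref_high Reference mean mapping to 1 (mm).
#'
#' @return Numeric vector of scaled trait values.
#' @export
scale_trait <- function(site_means, ref_low = 0.0, ref_high = 3.1) {
  if (!is.numeric(site_means)) stop("site_means must be numeric")
  if (!(ref_high > ref_low)) stop("ref_high must exceed ref_low")
  (site_means - ref_low) / (ref_high - ref_low)
}

#' Aggregate specimens to per-site scaled trait observations
#'
#' Produces one site observation per (site, period): the mean of the chosen
#' (already normalized) character across the site's specimens, scaled to 0-1
#' via [scale_trait()], together with the specimen count and the site's
#' transect x position from the gnomonic projection. Sites with fewer than
#' `min_per_site` specimens (default 5) are dropped.
#'
#' @param specimens Normalized, filtered specimen data frame with columns
#'   `site_id`, `longitude`, `latitude`, `period` and the chosen character.
#' @param character Measurement column to aggregate (default `"CCS"`).
#' @param min_per_site Minimum specimens per (site, period) (default 5).
#' @param ref_low,ref_high Trait-scaling endpoints passed to [scale_trait()].
#' @param center Projection center for the transect axis.
#'
#' @return A site-observation data frame with columns `site_id`, `period`,
#'   `x_km`, `value`, `n`, ordered by period then x.
#' @export
aggregate_sites <- function(specimens, character = "CCS", min_per_site = 5,
                            ref_low = 0.0, ref_high = 3.1,
                            center = projection_center()) {
  needed <- c("site_id", "longitude", "latitude", "period", character)
  stopifnot(is.data.frame(specimens), all(needed %in% names(specimens)))
  key <- interaction(specimens$site_id, specimens$period, drop = TRUE)
  groups <- split(specimens, key)
  groups <- Filter(function(g) nrow(g) >= min_per_site, groups)
  if (length(groups) == 0)
    stop("no sites with at least ", min_per_site, " specimens")
  obs <- do.call(rbind, lapply(groups, function(g) {
    data.frame(site_id = g$site_id[1],
               period = g$period[1],
               x_km = transect_x_km(mean(g$longitude), mean(g$latitude), center),
               value = scale_trait(mean(g[[character]]), ref_low, ref_high),
               n = nrow(g))
  }))
  rownames(obs) <- NULL
  obs[order(obs$period, obs$x_km), , drop = FALSE]
}
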