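#' @name table_io
#' @title Delimited-text readers and writers
#'
#' @description
#' All module tables travel as tab-delimited text with a mandatory header.
#' Writers format numeric columns with 17 significant digits so that tables
#' round-trip through write/read bit-exactly.
NULL

.write_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  df
}

#' @describeIn table_io Read a specimen table (`site_id`, `period`,
#'   `longitude`, `latitude`, `sex`, measurement columns).
#' @param path File path.
#' @export
read_specimens <- function(path) {
  sp <- .read_tsv(path, c("site_id", "period", "longitude", "latitude", "sex", "SVL"))
  num_cols <- intersect(c("longitude", "latitude",
                          "CCA", "CCP", "CCS", "HW", "PGL", "PGR", "SVL"),
                        names(sp))
  for (col in num_cols) sp[[col]] <- as.numeric(sp[[col]])
  sp
}

#' @describeIn table_io Write a specimen table.
#' @param specimens Specimen data frame.
#' @export
write_specimens <- function(specimens, path) .write_tsv(specimens, path)

#' @describeIn table_io Read a site-observation table (`site_id`, `period`,
#'   `x_km`, `value`, `n`).
#' @export
read_site_observations <- function(path) {
  obs <- .read_tsv(path, c("site_id", "period", "x_km", "value", "n"))
  obs$n <- as.integer(obs$n)
  obs$x_km <- as.numeric(obs$x_km)
  obs$value <- as.numeric(obs$value)
  .check_obs(obs)
  obs
}

#' @describeIn table_io Write a site-observation table.
#' @param obs Site-observation data frame.
#' @export
write_site_observations <- function(obs, path) .write_tsv(obs, path)

#' @describeIn table_io Read a habitat quadrat table (`set_id`, `era`,
#'   `lon_deg`, `lat_deg`, `quadrat_index`, `forest_ha`, `other_ha`,
#'   `water_ha`).
#' @export
read_quadrats <- function(path) {
  q <- .read_tsv(path, c("set_id", "era", "lon_deg", "lat_deg", "quadrat_index",
                         "forest_ha", "other_ha", "water_ha"))
  for (col in c("lon_deg", "lat_deg", "forest_ha", "other_ha", "water_ha"))
    q[[col]] <- as.numeric(q[[col]])
  q
}

#' @describeIn table_io Write a habitat quadrat table.
#' @param quadrats Quadrat data frame.
#' @export
write_quadrats <- function(quadrats, path) .write_tsv(quadrats, path)

#' @describeIn table_io Write a center likelihood profile as TSV
#'   (`c_km`, `logl`).
#' @param profile A [cline_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cline_profile"))
  .write_tsv(data.frame(c_km = profile$grid, logl = profile$logl), path)
}

#' @describeIn table_io Read a center likelihood profile from TSV.
#' @export
read_profile <- function(path) {
  df <- .read_tsv(path, c("c_km", "logl"))
  cline_profile(as.numeric(df$c_km), as.numeric(df$logl))
}
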