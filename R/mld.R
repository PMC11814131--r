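#' Discrete temperature profile
#'
#' @param date calendar date of the cast.
#' @param depths depths in metres, positive downward, strictly increasing,
#'   at least 2 levels.
#' @param temperatures temperature (degrees C) per depth.
#' @param salinity optional salinity per depth (carried, unused by the MLD
#'   criterion).
#' @param quality optional per-level quality flags.
#' @return A list of class `temperature_profile`.
#' @export
temperature_profile <- function(date, depths, temperatures,
                                salinity = NULL, quality = NULL) {
  depths <- as.numeric(depths)
  temperatures <- as.numeric(temperatures)
  if (length(depths) < 2L) stop("profile needs at least 2 levels", call. = FALSE)
  if (length(depths) != length(temperatures)) {
    stop("`depths` and `temperatures` lengths differ", call. = FALSE)
  }
  if (any(diff(depths) <= 0)) {
    stop("`depths` must be strictly increasing downward", call. = FALSE)
  }
  structure(list(date = as.Date(date), depths = depths,
                 temperatures = temperatures,
                 salinity = salinity, quality = quality),
            class = "temperature_profile")
}

#' Mixed layer depth by the temperature-difference criterion
#'
#' The reference temperature is linearly interpolated at `ref_depth`
#' (default 10 m).  The MLD is the shallowest depth below the reference where
#' the temperature has dropped by at least `delta_t` (default 0.2 degrees C)
#' relative to the reference, located by linear interpolation between the
#' bracketing levels.  If the deficit is never reached the deepest level is
#' returned with flag `bottom_reached`; a profile whose shallowest level is
#' more than 5 m below `ref_depth` yields flag `no_surface_level` and a
#' missing MLD.
#'
#' @param profile a [temperature_profile()].
#' @param ref_depth reference depth in metres (default 10).
#' @param delta_t temperature deficit criterion in degrees C (default 0.2).
#' @return A list of class `mld_record`: `date`, `mld` (m, `NA` when no
#'   surface level), `method_flag` in `crossed` / `bottom_reached` /
#'   `no_surface_level`.
#' @export
compute_mld <- function(profile, ref_depth = 10, delta_t = 0.2) {
  stopifnot(inherits(profile, "temperature_profile"))
  z <- profile$depths
  temp <- profile$temperatures
  if (z[1L] > ref_depth + 5) {
    return(structure(list(date = profile$date, mld = NA_real_,
                          method_flag = "no_surface_level"),
                     class = "mld_record"))
  }
  # constant extrapolation when the cast starts slightly below ref_depth
  t_ref <- stats::approx(z, temp, xout = ref_depth, rule = 2)$y
  below <- which(z > ref_depth)
  if (length(below) == 0L) {
    return(structure(list(date = profile$date, mld = z[length(z)],
                          method_flag = "bottom_reached"),
                     class = "mld_record"))
  }
  zb <- c(ref_depth, z[below])
  deficit <- t_ref - c(t_ref, temp[below])
  hit <- which(deficit >= delta_t)
  if (length(hit) == 0L) {
    return(structure(list(date = profile$date, mld = z[length(z)],
                          method_flag = "bottom_reached"),
                     class = "mld_record"))
  }
  k <- hit[1L]
  if (deficit[k] == delta_t || k == 1L) {
    mld <- zb[k]
  } else {
    mld <- zb[k - 1L] + (delta_t - deficit[k - 1L]) *
      (zb[k] - zb[k - 1L]) / (deficit[k] - deficit[k - 1L])
  }
  structure(list(date = profile$date, mld = mld, method_flag = "crossed"),
            class = "mld_record")
}

#' @export
print.mld_record <- function(x, ...) {
  cat(sprintf("<mld: %s m on %s [%s]>\n",
              if (is.na(x$mld)) "NA" else formatC(x$mld, digits = 4),
              format(x$date), x$method_flag))
  invisible(x)
}

#' MLD anomalies against a daily baseline
#'
#' Subtracts a calendar-day baseline from a sequence of MLD records.
#' Positive anomalies mean a deeper-than-baseline mixed layer (sign
#' convention recorded on the output).
#'
#' @param mld_records either a list of [compute_mld()] records or a data
#'   frame with columns `date` and `mld`.
#' @param baseline the daily baseline: a numeric vector of length 365
#'   (one value per calendar-day slot) or a `climatology` object whose
#'   `mean` is used.
#' @return A data frame `date`, `mld`, `anomaly` with attribute
#'   `sign_convention = "positive = deeper than baseline"`.
#' @export
mld_anomaly <- function(mld_records, baseline) {
  if (is.list(mld_records) && !is.data.frame(mld_records)) {
    mld_records <- data.frame(
      date = as.Date(vapply(mld_records, function(r) as.character(r$date),
                            character(1))),
      mld = vapply(mld_records, function(r) as.numeric(r$mld), numeric(1)))
  }
  if (inherits(baseline, "climatology")) baseline <- baseline$mean
  if (length(baseline) != 365L) {
    stop("`baseline` must provide 365 calendar-day values", call. = FALSE)
  }
  s <- doy_slot(mld_records$date)
  b <- baseline[s]
  if (anyNA(b)) {
    bad <- s[is.na(b)][1L]
    stop(sprintf("baseline gap on calendar-day slot %d", bad), call. = FALSE)
  }
  out <- data.frame(date = mld_records$date, mld = mld_records$mld,
                    anomaly = mld_records$mld - b)
  attr(out, "sign_convention") <- "positive = deeper than baseline"
  out
}
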