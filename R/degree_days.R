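#' Daily degree days by the simple-average method
#'
#' The simplest growing-degree-day formula: the day contributes
#' `max(0, (tmin + tmax)/2 - base_temp)` degree-days. Days whose mean
#' temperature falls below the base temperature contribute nothing
#' (negative accumulation is biologically meaningless and would break the
#' monotonicity of cumulative GDD).
#'
#' @param tmin,tmax Daily minimum and maximum temperature in degrees C.
#'   Vectors are recycled against each other; `tmax >= tmin` is required
#'   elementwise.
#' @param base_temp Base temperature in degrees C below which thermal
#'   accumulation is considered irrelevant to development. Default 10,
#'   the customary value for olive.
#' @return Numeric vector of non-negative daily degree-days (degC day).
#' @seealso [dd_allen()] for the single-sine variant, [accumulate_gdd()]
#'   for cumulative series.
#' @examples
#' dd_tavg(8, 18, 10)   # 3
#' dd_tavg(0, 8, 10)    # 0, mean below base
#' @export
dd_tavg <- function(tmin, tmax, base_temp = 10) {
  check_tmin_tmax(tmin, tmax)
  pmax(0, (tmin + tmax) / 2 - base_temp)
}

#' Daily degree days by the Allen single-sine method
#'
#' Models the daily temperature course as a single sine wave running from
#' `tmin` to `tmax` (mean `m = (tmin + tmax)/2`, amplitude
#' `a = (tmax - tmin)/2`) and returns the day-average of degree-hours
#' above the base temperature, with no upper cutoff. Unlike the
#' simple-average method this credits hours spent above the base
#' temperature even on days whose mean is below it.
#'
#' Closed form: with `theta = asin((base - m)/a)`,
#' \deqn{dd = \frac{1}{\pi}\left[(m - b)\left(\frac{\pi}{2} - \theta\right) + a\cos\theta\right]}
#' when `tmin < base < tmax`; `m - base` when `base <= tmin`; 0 when
#' `base >= tmax`. Because the day-average of a full sine period is
#' phase-invariant, the placement of the maximum within the day does not
#' affect the result.
#'
#' @inheritParams dd_tavg
#' @return Numeric vector of non-negative daily degree-days (degC day).
#'   Always `>= dd_tavg(tmin, tmax, base_temp)` (Jensen's inequality:
#'   `max(0, .)` is convex).
#' @examples
#' dd_allen(10, 20, 10)  # 5, base = tmin reduces to the simple average
#' dd_allen(8, 18, 18)   # 0, base = tmax
#' dd_allen(8, 18, 10)   # ~3.39, exceeds dd_tavg(8, 18, 10) = 3
#' @export
dd_allen <- function(tmin, tmax, base_temp = 10) {
  check_tmin_tmax(tmin, tmax)
  n <- max(length(tmin), length(tmax), length(base_temp))
  tmin <- rep_len(tmin, n)
  tmax <- rep_len(tmax, n)
  b <- rep_len(base_temp, n)
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(n)
  below <- b <= tmin          # whole day above base
  above <- b >= tmax          # whole day below base
  mid <- !below & !above      # implies a > 0
  out[below] <- m[below] - b[below]
  if (any(mid)) {
    theta <- asin(pmin(1, pmax(-1, (b[mid] - m[mid]) / a[mid])))
    out[mid] <- ((m[mid] - b[mid]) * (pi / 2 - theta) +
                   a[mid] * cos(theta)) / pi
  }
  out
}

check_tmin_tmax <- function(tmin, tmax) {
  if (any(!is.finite(tmin)) || any(!is.finite(tmax))) {
    thermophen_stop("tmin/tmax must be finite", class = "thermophen_invalid_record")
  }
  bad <- which(rep_len(tmax, max(length(tmin), length(tmax))) <
                 rep_len(tmin, max(length(tmin), length(tmax))))
  if (length(bad)) {
    thermophen_stop("tmax < tmin at position(s) %s",
                    paste(utils::head(bad, 5), collapse = ", "),
                    class = "thermophen_invalid_record")
  }
  invisible(TRUE)
}

#' Validate a daily weather table
#'
#' Checks the contract every downstream computation relies on: required
#' columns, `tmax >= tmin` per record, uniqueness of
#' (location_id, date, source), and gap-free daily coverage from January 1
#' through the last date present within each (location, source, year)
#' group (cumulative accumulation starts on January 1, so any gap would
#' silently corrupt the running sum).
#'
#' @param weather Data frame with columns `location_id`, `date` (Date or
#'   ISO-8601 string), `tmin`, `tmax`, `source` (`"station"` or `"era5"`).
#' @return The weather data frame, invisibly, with `date` coerced to Date.
#' @export
validate_weather <- function(weather) {
  need <- c("location_id", "date", "tmin", "tmax", "source")
  miss <- setdiff(need, names(weather))
  if (length(miss)) {
    thermophen_stop("weather table is missing column(s): %s",
                    paste(miss, collapse = ", "), class = "thermophen_schema_error")
  }
  if (!inherits(weather$date, "Date")) {
    weather$date <- as.Date(as.character(weather$date), format = "%Y-%m-%d")
  }
  if (anyNA(weather$date)) {
    thermophen_stop("weather table has unparseable dates (rows %s)",
                    paste(utils::head(which(is.na(weather$date)), 5), collapse = ", "),
                    class = "thermophen_schema_error")
  }
  bad_src <- setdiff(unique(weather$source), c("station", "era5"))
  if (length(bad_src)) {
    thermophen_stop("unknown weather source(s): %s",
                    paste(bad_src, collapse = ", "), class = "thermophen_schema_error")
  }
  bad <- which(weather$tmax < weather$tmin)
  if (length(bad)) {
    b <- bad[1]
    thermophen_stop("tmax < tmin for location '%s' on %s (%d offending record(s))",
                    weather$location_id[b], format(weather$date[b]), length(bad),
                    class = "thermophen_invalid_record")
  }
  key <- paste(weather$location_id, weather$date, weather$source)
  if (anyDuplicated(key)) {
    thermophen_stop("duplicate (location_id, date, source) records, e.g. %s",
                    key[anyDuplicated(key)], class = "thermophen_invalid_record")
  }
  yr <- year_of(weather$date)
  grp <- split(weather$date, paste(weather$location_id, weather$source, yr, sep = "|"))
  for (g in names(grp)) {
    d <- sort(grp[[g]])
    jan1 <- as.Date(paste0(year_of(d[1]), "-01-01"))
    expected <- seq(jan1, max(d), by = "day")
    gap <- setdiff(as.character(expected), as.character(d))
    if (length(gap)) {
      thermophen_stop(
        "weather coverage gap in group (%s): missing %d day(s) starting %s",
        gsub("\\|", ", ", g), length(gap), gap[1],
        class = "thermophen_missing_coverage")
    }
  }
  invisible(weather)
}

#' Cumulative growing degree days from January 1
#'
#' Computes daily degree-days for every record by the chosen method and
#' accumulates them from January 1 within each (location, source, year)
#' group. Accumulation always restarts on January 1; the start date is a
#' fixed convention of the model, not a tuning knob.
#'
#' @param weather Daily weather table (see [validate_weather()]).
#' @param base_temp Base temperature in degrees C, in `[0, 45]`.
#' @param method `"tavg"` (simple average) or `"allen"` (single sine).
#' @return A data frame of class `cum_gdd` with columns `location_id`,
#'   `date`, `doy` (Jan 1 = 1; Dec 31 = 366 in leap years), `daily_dd`,
#'   `cum_gdd`, `method`, `base_temp`, `source`, sorted by location,
#'   source, date. `cum_gdd` is non-decreasing within each
#'   (location, source, year).
#' @examples
#' w <- data.frame(location_id = "a",
#'                 date = as.Date("2020-01-01") + 0:2,
#'                 tmin = 8, tmax = 18, source = "station")
#' accumulate_gdd(w, base_temp = 10, method = "tavg")$cum_gdd  # 3 6 9
#' @export
accumulate_gdd <- function(weather, base_temp = 10, method = c("tavg", "allen")) {
  method <- match.arg(method)
  if (!is.numeric(base_temp) || length(base_temp) != 1L ||
      base_temp < 0 || base_temp > 45) {
    thermophen_stop("base_temp must be a single value in [0, 45] degC")
  }
  weather <- validate_weather(weather)
  ord <- order(weather$location_id, weather$source, weather$date)
  weather <- weather[ord, , drop = FALSE]
  daily <- switch(method,
                  tavg = dd_tavg(weather$tmin, weather$tmax, base_temp),
                  allen = dd_allen(weather$tmin, weather$tmax, base_temp))
  yr <- year_of(weather$date)
  grp <- paste(weather$location_id, weather$source, yr, sep = "|")
  cum <- stats::ave(daily, grp, FUN = cumsum)
  out <- data.frame(location_id = weather$location_id,
                    date = weather$date,
                    doy = doy_of(weather$date),
                    daily_dd = daily,
                    cum_gdd = cum,
                    method = method,
                    base_temp = base_temp,
                    source = weather$source,
                    stringsAsFactors = FALSE)
  class(out) <- c("cum_gdd", "data.frame")
  out
}

#' Look up cumulative GDD for given locations and dates
#'
#' Exact lookup used when attaching GDD features to dated phenology
#' observations. Every requested (location, date) must be covered.
#'
#' @param series A `cum_gdd` data frame from [accumulate_gdd()]
#'   containing a single source.
#' @param location_id,date Vectors (recycled) of locations and dates.
#' @return Numeric vector of cumulative GDD values.
#' @export
gdd_at <- function(series, location_id, date) {
  if (length(unique(series$source)) > 1L) {
    thermophen_stop("gdd_at() requires a single-source series; subset first")
  }
  n <- max(length(location_id), length(date))
  location_id <- rep_len(location_id, n)
  date <- rep_len(as.Date(date), n)
  idx <- match(paste(location_id, date), paste(series$location_id, series$date))
  if (anyNA(idx)) {
    b <- which(is.na(idx))[1]
    thermophen_stop("no GDD coverage for location '%s' on %s (%d uncovered lookup(s))",
                    location_id[b], format(date[b]), sum(is.na(idx)),
                    class = "thermophen_missing_coverage")
  }
  series$cum_gdd[idx]
}
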