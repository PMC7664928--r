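#' Configure a synthetic phenology world
#'
#' Builds the full ground-truth configuration for a simulated
#' multi-location, multi-year olive phenology study: per-location
#' climatologies (annual mean, seasonal amplitude, diurnal range, AR(1)
#' day-to-day noise), a reanalysis-like temperature source with a
#' systematic per-location bias, and a latent phase process in which the
#' true phase rank at any date is set by ordered thresholds on
#' cumulative single-sine GDD at a known true base temperature.
#' Observed ranks are the true ranks, shifted by one stage with
#' probability `p_noise` (one-stage misreading being the plausible field
#' error).
#'
#' The defaults emulate the shape of a Tuscan olive phenology campaign:
#' 22 locations, 3 years, roughly a dozen orchard visits per
#' location-year between early March and late October (~790
#' observations), Mediterranean seasonal cycles, and sub-2-degree
#' reanalysis biases. When `thresholds` is not supplied, the K
#' thresholds are taken from the noise-free reference climatology
#' (the midpoint of the per-location parameter ranges) as the cumulative
#' GDD reached at K dates evenly spaced across the visit season, so all
#' K stages occur in the simulated data.
#'
#' @param n_locations,years Number of locations and calendar years.
#' @param annual_mean_range,amplitude_range,diurnal_range_range Ranges
#'   (degC) from which per-location annual mean temperature, seasonal
#'   amplitude, and diurnal range are drawn uniformly.
#' @param peak_lag Day-of-year phase so the seasonal maximum falls near
#'   `peak_lag + 91` (default 110: peak around late July).
#' @param ar1_coef,noise_sd AR(1) coefficient and marginal sd (degC) of
#'   the daily temperature anomaly.
#' @param era5_offset_range Range (degC) of the per-location additive
#'   bias of the reanalysis-like series.
#' @param base_temp_true True base temperature (degC) driving the latent
#'   phase process.
#' @param K Number of phase ranks.
#' @param rank_map BBCH rank map used to label observations.
#' @param thresholds Optional strictly increasing vector of K cumulative
#'   GDD thresholds (degC day).
#' @param p_noise Probability that an observation is misrecorded by one
#'   stage (must be `< 0.5`).
#' @param visit_doys Nominal day-of-year visit schedule per
#'   location-year.
#' @param visit_jitter Uniform jitter (days) applied to each visit.
#' @param seed Seed for all world randomness.
#' @return Object of class `synthetic_world_config`, including the
#'   per-location parameter table `locations`.
#' @export
synthetic_world_config <- function(n_locations = 22, years = 2008:2010,
                                   annual_mean_range = c(12, 18),
                                   amplitude_range = c(7, 11),
                                   diurnal_range_range = c(8, 12),
                                   peak_lag = 110,
                                   ar1_coef = 0.6, noise_sd = 2,
                                   era5_offset_range = c(-1.5, 1.5),
                                   base_temp_true = 10,
                                   K = 20,
                                   rank_map = default_rank_map(K),
                                   thresholds = NULL,
                                   p_noise = 0.15,
                                   visit_doys = round(seq(60, 300, length.out = 12)),
                                   visit_jitter = 3,
                                   seed = 42) {
  if (p_noise < 0 || p_noise >= 0.5) thermophen_stop("p_noise must be in [0, 0.5)")
  if (diurnal_range_range[1] <= 0) thermophen_stop("diurnal range must be positive")
  if (nrow(rank_map) != K) thermophen_stop("rank_map must have exactly K = %d codes", K)
  loc <- with_local_seed(seed, data.frame(
    location_id = sprintf("loc%02d", seq_len(n_locations)),
    annual_mean = stats::runif(n_locations, annual_mean_range[1], annual_mean_range[2]),
    amplitude = stats::runif(n_locations, amplitude_range[1], amplitude_range[2]),
    diurnal_range = stats::runif(n_locations, diurnal_range_range[1],
                                 diurnal_range_range[2]),
    era5_offset = stats::runif(n_locations, era5_offset_range[1],
                               era5_offset_range[2]),
    stringsAsFactors = FALSE))
  cfg <- structure(list(
    n_locations = n_locations, years = as.integer(years), locations = loc,
    peak_lag = peak_lag, ar1_coef = ar1_coef, noise_sd = noise_sd,
    base_temp_true = base_temp_true, K = as.integer(K), rank_map = rank_map,
    thresholds = thresholds, p_noise = p_noise,
    visit_doys = as.integer(visit_doys), visit_jitter = visit_jitter,
    seed = as.integer(seed)), class = "synthetic_world_config")
  if (is.null(cfg$thresholds)) {
    cfg$thresholds <- reference_thresholds(cfg)
  }
  if (is.unsorted(cfg$thresholds, strictly = TRUE) ||
      length(cfg$thresholds) != K) {
    thermophen_stop("thresholds must be %d strictly increasing values", K)
  }
  cfg
}

# K thresholds from the noise-free mid-range climatology: the cumulative
# Allen GDD (at the true base temperature) reached at K dates evenly
# spanning the visit season.
reference_thresholds <- function(cfg) {
  doy <- 1:365
  mean_t <- mean(cfg$locations$annual_mean) +
    mean(cfg$locations$amplitude) * sin(2 * pi * (doy - cfg$peak_lag) / 365)
  dr <- mean(cfg$locations$diurnal_range)
  cum <- cumsum(dd_allen(mean_t - dr / 2, mean_t + dr / 2, cfg$base_temp_true))
  at <- round(seq(min(cfg$visit_doys) + 10, max(cfg$visit_doys) - 10,
                  length.out = cfg$K))
  th <- cum[at]
  # guarantee strict increase even for very low-GDD shoulder days
  cummax(th) + seq_along(th) * 1e-6
}

#' Simulate daily station weather
#'
#' Daily mean temperature per location is the seasonal sine (annual mean
#' plus amplitude) plus an AR(1) anomaly; `tmin`/`tmax` sit half the
#' diurnal range below/above the mean. The series is gap-free from
#' January 1 of the first year through December 31 of the last (leap
#' days included), as cumulative accumulation requires.
#'
#' @param cfg A [synthetic_world_config()].
#' @return A daily weather data frame (`source = "station"`),
#'   reproducible byte-for-byte from `cfg$seed`.
#' @export
generate_weather <- function(cfg) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(cfg$years))),
               as.Date(sprintf("%d-12-31", max(cfg$years))), by = "day")
  doy <- doy_of(dates)
  n <- length(dates)
  seeds <- spawn_seeds(cfg$seed, cfg$n_locations + 2L)
  out <- vector("list", cfg$n_locations)
  for (i in seq_len(cfg$n_locations)) {
    p <- cfg$locations[i, ]
    anomaly <- with_local_seed(seeds[i], {
      e <- numeric(n)
      innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1_coef^2)
      e[1] <- stats::rnorm(1, 0, cfg$noise_sd)
      z <- stats::rnorm(n - 1, 0, innov_sd)
      for (t in 2:n) e[t] <- cfg$ar1_coef * e[t - 1] + z[t - 1]
      e
    })
    mean_t <- p$annual_mean +
      p$amplitude * sin(2 * pi * (doy - cfg$peak_lag) / 365) + anomaly
    out[[i]] <- data.frame(location_id = p$location_id, date = dates,
                           tmin = mean_t - p$diurnal_range / 2,
                           tmax = mean_t + p$diurnal_range / 2,
                           source = "station", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Derive a reanalysis-like weather series with per-location bias
#'
#' Applies each location's systematic additive temperature offset to the
#' station series. Because a constant offset biases every day's
#' degree-day contribution in the same direction, the cumulative-GDD
#' relative error of the biased series against the station reference
#' converges to a roughly constant per-location percentage as the
#' season accumulates — the signature reanalysis products show against
#' ground stations.
#'
#' @param station Station weather from [generate_weather()].
#' @param cfg The world configuration (holds `era5_offset` per location).
#' @return Weather data frame with `source = "era5"`.
#' @export
generate_era5_like <- function(station, cfg) {
  off <- cfg$locations$era5_offset[match(station$location_id,
                                         cfg$locations$location_id)]
  if (anyNA(off)) thermophen_stop("station series has locations absent from cfg")
  out <- station
  out$tmin <- station$tmin + off
  out$tmax <- station$tmax + off
  out$source <- "era5"
  out
}

#' Simulate phenology observations from the latent GDD process
#'
#' At each scheduled (jittered) visit the true rank is the largest k
#' whose threshold does not exceed the location's cumulative single-sine
#' GDD at the true base temperature on that date (rank 1 below the
#' first threshold). With probability `p_noise` the recorded rank is
#' shifted one stage up or down (clamped to `[1, K]`).
#'
#' @param weather Station weather covering all visit dates.
#' @param cfg The world configuration.
#' @return Data frame of observations: `location_id`, `date`,
#'   `bbch_code`, `rank` (the recorded, possibly noisy rank), and
#'   `true_rank`.
#' @export
generate_phenology <- function(weather, cfg) {
  gdd <- accumulate_gdd(weather[weather$source == "station", , drop = FALSE],
                        base_temp = cfg$base_temp_true, method = "allen")
  seeds <- spawn_seeds(cfg$seed, cfg$n_locations + 2L)
  obs <- with_local_seed(seeds[cfg$n_locations + 1L], {
    rows <- list()
    for (loc in cfg$locations$location_id) {
      for (yr in cfg$years) {
        jit <- if (cfg$visit_jitter > 0) {
          sample(seq(-cfg$visit_jitter, cfg$visit_jitter),
                 length(cfg$visit_doys), replace = TRUE)
        } else 0L
        d <- cfg$visit_doys + jit
        d <- sort(unique(pmin(365L, pmax(1L, d))))
        rows[[length(rows) + 1L]] <- data.frame(
          location_id = loc,
          date = as.Date(d - 1, origin = sprintf("%d-01-01", yr)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  g <- gdd_at(gdd, obs$location_id, obs$date)
  true_rank <- pmax(1L, findInterval(g, cfg$thresholds))
  observed <- with_local_seed(seeds[cfg$n_locations + 2L], {
    flip <- stats::runif(length(true_rank)) < cfg$p_noise
    shift <- ifelse(flip, sample(c(-1L, 1L), length(true_rank), replace = TRUE), 0L)
    pmin(cfg$K, pmax(1L, true_rank + shift))
  })
  data.frame(location_id = obs$location_id, date = obs$date,
             bbch_code = cfg$rank_map$bbch_code[observed],
             rank = as.integer(observed), true_rank = as.integer(true_rank),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic world
#'
#' Convenience wrapper: station weather, the biased reanalysis-like
#' series, and the phenology observations, together with the ground
#' truth needed for validation.
#'
#' @param cfg A [synthetic_world_config()].
#' @return List of class `synthetic_world`: `weather` (both sources,
#'   row-bound), `station`, `era5`, `phenology`, and `truth`
#'   (`base_temp_true`, `thresholds`, `p_noise`, per-location
#'   `era5_offset`).
#' @export
simulate_world <- function(cfg = synthetic_world_config()) {
  station <- generate_weather(cfg)
  era5 <- generate_era5_like(station, cfg)
  phen <- generate_phenology(station, cfg)
  structure(list(weather = rbind(station, era5),
                 station = station, era5 = era5, phenology = phen,
                 truth = list(base_temp_true = cfg$base_temp_true,
                              thresholds = cfg$thresholds,
                              p_noise = cfg$p_noise,
                              era5_offset = stats::setNames(
                                cfg$locations$era5_offset,
                                cfg$locations$location_id)),
                 config = cfg),
            class = "synthetic_world")
}
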