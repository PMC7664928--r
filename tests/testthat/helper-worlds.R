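# Shared fixtures and independent oracles, all built in code.

# Numeric oracle for the single-sine degree-day value: midpoint-rule
# average over one full sine period of max(0, m + a*sin(t) - base).
# Independent of the closed form under test.
allen_numeric <- function(tmin, tmax, base, n = 5e4) {
  t <- (seq_len(n) - 0.5) / n * 2 * pi
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  mean(pmax(0, m + a * sin(t) - base))
}

# Brute-force interval-search oracle for the threshold baseline: tries
# every rank's interval [theta_k, theta_{k+1}) explicitly.
baseline_oracle <- function(ranks, thetas, gdd) {
  thetas <- cummax(thetas)  # same monotonisation contract as the model
  vapply(gdd, function(g) {
    hit <- NA_integer_
    for (k in seq_along(ranks)) {
      upper <- if (k < length(ranks)) thetas[k + 1] else Inf
      if (g >= thetas[k] && g < upper) hit <- ranks[k]
    }
    if (is.na(hit)) hit <- if (g < thetas[1]) ranks[1] else ranks[length(ranks)]
    hit
  }, integer(1))
}

# Small fast world for unit tests.
tiny_world_config <- function(seed = 11, ...) {
  synthetic_world_config(n_locations = 4, years = 2008:2009, seed = seed, ...)
}

# Noiseless world whose per-rank GDD values are point masses: identical
# climatology at every location, no weather noise, no visit jitter, and
# one threshold placed just below the (shared) cumulative GDD of each
# visit day, so each visit maps to exactly one rank and every rank is
# observed at a single GDD value. The mean-GDD baseline then separates
# the ranks perfectly.
pointband_world <- function(n_locations = 4, years = 2009:2010,
                            base_temp_true = 10, n_visits = 12, seed = 5) {
  visit_doys <- round(seq(60, 300, length.out = n_visits))
  probe <- synthetic_world_config(
    n_locations = 1, years = years[1],
    annual_mean_range = c(15, 15), amplitude_range = c(9, 9),
    diurnal_range_range = c(10, 10), noise_sd = 0,
    base_temp_true = base_temp_true, K = n_visits,
    visit_doys = visit_doys, visit_jitter = 0, p_noise = 0, seed = seed)
  st1 <- generate_weather(probe)
  g1 <- accumulate_gdd(st1, base_temp_true, "allen")
  th <- g1$cum_gdd[match(visit_doys, g1$doy)] - 0.5
  cfg <- synthetic_world_config(
    n_locations = n_locations, years = years,
    annual_mean_range = c(15, 15), amplitude_range = c(9, 9),
    diurnal_range_range = c(10, 10), noise_sd = 0,
    base_temp_true = base_temp_true, K = n_visits,
    thresholds = th, visit_doys = visit_doys, visit_jitter = 0,
    p_noise = 0, seed = seed)
  simulate_world(cfg)
}

# Feature table holding a single GDD feature for a world.
world_gdd_table <- function(world, base_temp = world$truth$base_temp_true,
                            method = "allen", use_doy = FALSE) {
  g <- accumulate_gdd(world$station, base_temp, method)
  build_feature_table(world$phenology, list(gdd_allen = g),
                      use_doy = use_doy, K = world$config$K)
}
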