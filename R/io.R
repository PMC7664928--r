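# CSV/YAML readers and writers. All outputs are plain CSV with a
# commented metadata header (seed, config hash, package version) so any
# result file names the run that produced it; readers skip '#' lines.

#' Read a daily weather CSV
#'
#' Expected header: `location_id,date,tmin,tmax,source` with ISO-8601
#' dates and `source` in `{station, era5}`. Schema problems are
#' reported with row numbers.
#'
#' @param path CSV path.
#' @return Validated weather data frame (see [validate_weather()]).
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) thermophen_stop("weather file not found: %s", path)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("location_id", "date", "tmin", "tmax", "source")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    thermophen_stop("weather CSV %s is missing column(s): %s", path,
                    paste(miss, collapse = ", "), class = "thermophen_schema_error")
  }
  d <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  if (anyNA(d)) {
    thermophen_stop("weather CSV %s: unparseable date(s) at row(s) %s", path,
                    paste(utils::head(which(is.na(d)), 5), collapse = ", "),
                    class = "thermophen_schema_error")
  }
  raw$date <- d
  for (col in c("tmin", "tmax")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      thermophen_stop("weather CSV %s: non-numeric %s at row(s) %s", path, col,
                      paste(utils::head(which(is.na(v)), 5), collapse = ", "),
                      class = "thermophen_schema_error")
    }
    raw[[col]] <- v
  }
  bad <- which(raw$tmax < raw$tmin)
  if (length(bad)) {
    thermophen_stop("weather CSV %s: tmax < tmin at row(s) %s", path,
                    paste(utils::head(bad, 5), collapse = ", "),
                    class = "thermophen_invalid_record")
  }
  validate_weather(raw)
  raw
}

#' Read a phenology observation CSV
#'
#' Expected header: `location_id,date,bbch_code`. Observations are rank
#' encoded against the supplied map; unknown codes are an error.
#'
#' @param path CSV path.
#' @param rank_map A [bbch_rank_map()].
#' @return Rank-encoded observation data frame (possibly 0 rows, with a
#'   warning).
#' @export
read_phenology <- function(path, rank_map) {
  if (!file.exists(path)) thermophen_stop("phenology file not found: %s", path)
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning(sprintf("phenology file %s has no observations", path), call. = FALSE)
    return(data.frame(location_id = character(), date = as.Date(character()),
                      bbch_code = character(), rank = integer()))
  }
  encode_ranks(raw, rank_map)
}

#' Read a BBCH rank map from YAML or CSV
#'
#' YAML: a list of codes in developmental order (or a mapping with a
#' `codes` entry). CSV: a `bbch_code` column in order (a `rank` column,
#' if present, must equal the dense 1..K order).
#'
#' @param path `.yaml`/`.yml` or `.csv` file.
#' @return A [bbch_rank_map()].
#' @export
read_rank_map <- function(path) {
  if (!file.exists(path)) thermophen_stop("rank map file not found: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    codes <- if (is.list(y) && !is.null(y$codes)) y$codes else y
    return(bbch_rank_map(unlist(codes)))
  }
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character", stringsAsFactors = FALSE)
  if (!"bbch_code" %in% names(raw)) {
    thermophen_stop("rank map CSV needs a bbch_code column",
                    class = "thermophen_schema_error")
  }
  map <- bbch_rank_map(raw$bbch_code)
  if ("rank" %in% names(raw) &&
      !identical(as.integer(raw$rank), map$rank)) {
    thermophen_stop("rank map CSV rank column is not the dense order 1..K",
                    class = "thermophen_schema_error")
  }
  map
}

#' Write a data frame as CSV with a metadata comment header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list written as `# key: value` header lines
#'   (typically seed and config hash).
#' @export
write_csv_meta <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("thermophen ",
                                  as.character(utils::packageVersion("thermophen"))),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_meta()]
#' @param path CSV path.
#' @return Data frame (header comments skipped).
#' @export
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Serialise / load a fitted threshold baseline
#'
#' The model is a per-rank threshold table, so CSV round-trips it
#' exactly.
#'
#' @param model A `threshold_model`.
#' @param path CSV path (`rank,threshold`).
#' @param meta Metadata header entries.
#' @export
write_baseline <- function(model, path, meta = list()) {
  write_csv_meta(model$thresholds, path, meta)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  d <- read_csv_meta(path)
  m <- structure(list(thresholds = data.frame(rank = as.integer(d$rank),
                                              threshold = as.numeric(d$threshold)),
                      effective = cummax(as.numeric(d$threshold)),
                      ranks = as.integer(d$rank)),
                 class = "threshold_model")
  m
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate-or-load, GDD computation, feature construction,
#' resampled evaluation of the scenario model, optional model
#' comparison, optional base-temperature grid search, and writes every
#' result as CSV (plus a YAML run manifest naming the inputs, seed,
#' package version, and config hash).
#'
#' @param config Either a list or a path to a YAML file with entries:
#'   `weather` (path) or `simulate: true`, `phenology` (path),
#'   `rank_map` (path, optional; defaults to [default_rank_map()]),
#'   `out_dir`, `seed`, `scenario` (`features`, `model`, optional
#'   `polynomial`), `split` (`train_fraction`, `n_repeats`), optional
#'   `base_temp` (default 10), and optional `grid` (`from`, `to`, `by`)
#'   to run the optimiser.
#' @return Invisibly, a list with the evaluation (and optionally grid)
#'   objects and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% thermophen_stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  cfg_hash <- substr(rlang_free_hash(config), 1, 12)
  meta <- list(seed = seed, config_hash = cfg_hash)

  rank_map <- if (!is.null(config$rank_map)) read_rank_map(config$rank_map) else
    default_rank_map(config$K %||% 20)

  if (isTRUE(config$simulate)) {
    world <- simulate_world(synthetic_world_config(seed = seed,
                                                   K = nrow(rank_map),
                                                   rank_map = rank_map))
    weather <- world$weather
    obs <- world$phenology
  } else {
    weather <- read_weather(config$weather %||%
                              thermophen_stop("config needs weather path or simulate: true"))
    obs <- read_phenology(config$phenology %||%
                            thermophen_stop("config needs phenology path"),
                          rank_map)
  }

  sc <- config$scenario %||% list(features = c("doy", "gdd_allen"),
                                  model = "random_forest")
  model <- if (identical(sc$model, "baseline")) "baseline" else
    model_spec(sc$model, polynomial = isTRUE(sc$polynomial))
  scen <- scenario(unlist(sc$features), model)

  sp <- config$split %||% list()
  spec <- split_spec(train_fraction = sp$train_fraction %||% 0.7,
                     n_repeats = sp$n_repeats %||% 100, seed = seed)

  base_temp <- config$base_temp %||% 10
  message(sprintf("[thermophen] evaluating %s at base temp %.1f degC", scen$label,
                  base_temp))
  tab <- scenario_feature_table(weather, obs, scen, base_temp)
  dist <- resample_evaluate(tab, model_fit_fun(scen$model,
                                               baseline_feature = scen$gdd_features[1]),
                            spec)
  paths <- character(0)
  p <- file.path(out_dir, "metrics_per_repeat.csv")
  write_csv_meta(dist$reports, p, meta); paths <- c(paths, p)
  p <- file.path(out_dir, "metrics_summary.csv")
  write_csv_meta(dist$summary, p, meta); paths <- c(paths, p)

  grid_res <- NULL
  if (!is.null(config$grid)) {
    g <- config$grid
    grid <- seq(g$from %||% 0, g$to %||% 10, by = g$by %||% 0.5)
    message(sprintf("[thermophen] base-temperature grid search over %d point(s)",
                    length(grid)))
    grid_res <- optimize_base_temp(weather, obs, scen, grid = grid, spec = spec)
    p <- file.path(out_dir, "base_temp_grid.csv")
    write_csv_meta(grid_res$results, p, meta); paths <- c(paths, p)
    p <- file.path(out_dir, "base_temp_optima.csv")
    write_csv_meta(grid_res$optima, p, meta); paths <- c(paths, p)
  }

  manifest <- list(seed = seed, config_hash = cfg_hash,
                   package = as.character(utils::packageVersion("thermophen")),
                   scenario = scen$label, n_observations = nrow(obs),
                   outputs = basename(paths))
  mp <- file.path(out_dir, "run_manifest.yaml")
  yaml::write_yaml(manifest, mp)
  paths <- c(paths, mp)
  invisible(list(evaluation = dist, grid = grid_res, paths = paths))
}

# Stable content hash of a config without extra dependencies: md5 of the
# canonical YAML serialisation.
rlang_free_hash <- function(x) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}
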