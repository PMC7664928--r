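#' Describe an evaluation scenario
#'
#' A scenario names the feature set and the model used in evaluation and
#' base-temperature optimisation. Feature names combine the temperature
#' source with the degree-day method: `doy`, `gdd_tavg`, `gdd_allen`
#' (station), `era5_gdd_tavg`, `era5_gdd_allen` (reanalysis-like).
#'
#' @param features Character vector drawn from the vocabulary above. The
#'   threshold baseline consumes exactly one GDD feature (no DOY).
#' @param model A [model_spec()] or `"baseline"`.
#' @return Object of class `pheno_scenario`.
#' @examples
#' scenario(c("doy", "gdd_allen"), model_spec("random_forest"))
#' scenario("gdd_allen", "baseline")
#' @export
scenario <- function(features, model) {
  vocab <- c("doy", "gdd_tavg", "gdd_allen", "era5_gdd_tavg", "era5_gdd_allen")
  bad <- setdiff(features, vocab)
  if (length(bad)) {
    thermophen_stop("unknown feature(s): %s (choose from %s)",
                    paste(bad, collapse = ", "), paste(vocab, collapse = ", "))
  }
  gdd_feats <- setdiff(features, "doy")
  if (identical(model, "baseline")) {
    if (length(gdd_feats) != 1L || "doy" %in% features) {
      thermophen_stop("the baseline model uses exactly one GDD feature and no DOY")
    }
  } else if (!inherits(model, "model_spec")) {
    thermophen_stop("model must be a model_spec or \"baseline\"")
  }
  label <- paste0(paste(features, collapse = "+"), " / ",
                  if (identical(model, "baseline")) "baseline" else model$label)
  structure(list(features = features, gdd_features = gdd_feats,
                 model = model, label = label),
            class = "pheno_scenario")
}

# (source, method) pair encoded in a feature name like "era5_gdd_tavg"
feature_recipe <- function(feature) {
  src <- if (startsWith(feature, "era5_")) "era5" else "station"
  method <- if (endsWith(feature, "allen")) "allen" else "tavg"
  list(source = src, method = method)
}

# Compute the scenario's GDD series at one base temperature and build
# the feature table for the given observations.
scenario_feature_table <- function(weather, observations, scen, base_temp,
                                   poly_degree = 1, K = max(observations$rank)) {
  gdd_list <- lapply(stats::setNames(scen$gdd_features, scen$gdd_features),
                     function(f) {
    r <- feature_recipe(f)
    w <- weather[weather$source == r$source, , drop = FALSE]
    if (nrow(w) == 0L) {
      thermophen_stop("no weather records with source '%s' for feature '%s'",
                      r$source, f, class = "thermophen_missing_coverage")
    }
    accumulate_gdd(w, base_temp = base_temp, method = r$method)
  })
  build_feature_table(observations, gdd_series = gdd_list,
                      use_doy = "doy" %in% scen$features,
                      poly_degree = poly_degree, K = K)
}

#' Optimise the GDD base temperature by grid search
#'
#' For every candidate base temperature the scenario's cumulative-GDD
#' features are recomputed from the raw weather, the model is refitted
#' on repeated stratified 70/30 splits, and the resampled accuracy,
#' RMSE, and combined-metric distributions are recorded with confidence
#' intervals for their means. The per-metric optimum is the grid member
#' with maximum mean accuracy, minimum mean RMSE, or minimum mean
#' combined metric. The identical split sequence is reused at every
#' grid point (paired resampling), so the metric-versus-temperature
#' curves are not blurred by split noise.
#'
#' @param weather Daily weather table covering the observations.
#' @param observations Rank-encoded phenology observations.
#' @param scen A [scenario()].
#' @param grid Candidate base temperatures in degrees C, strictly
#'   increasing; default 0 to 10 by 0.5 (21 values). Temperatures above
#'   10 are rarely useful for olive but the grid is configurable for
#'   other crops.
#' @param spec A [split_spec()].
#' @param ci_level Confidence level for the mean CIs.
#' @return Object of class `base_temp_grid`: long-format `results`
#'   (base_temp, metric, mean, se, ci_lo, ci_hi), the per-temperature
#'   `distributions`, and `optima` (metric, base_temp). Metric ties
#'   resolve to the lowest temperature, with a message.
#' @export
optimize_base_temp <- function(weather, observations, scen,
                               grid = seq(0, 10, by = 0.5),
                               spec = split_spec(), ci_level = 0.95) {
  if (length(grid) == 0L) thermophen_stop("empty base-temperature grid")
  if (is.unsorted(grid, strictly = TRUE)) {
    thermophen_stop("base-temperature grid must be strictly increasing")
  }
  weather <- validate_weather(weather)
  K <- max(observations$rank)
  dists <- vector("list", length(grid))
  names(dists) <- format(grid)
  failed <- logical(length(grid))
  for (i in seq_along(grid)) {
    dists[[i]] <- tryCatch({
      tab <- scenario_feature_table(weather, observations, scen, grid[i], K = K)
      fit_fun <- model_fit_fun(scen$model, baseline_feature = scen$gdd_features[1])
      resample_evaluate(tab, fit_fun, spec, ci_level)
    }, error = function(e) {
      warning(sprintf("base temp %.1f excluded: %s", grid[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    failed[i] <- is.null(dists[[i]])
  }
  if (all(failed)) thermophen_stop("every base temperature failed")
  results <- do.call(rbind, lapply(which(!failed), function(i) {
    s <- dists[[i]]$summary
    s$base_temp <- grid[i]
    s[c("base_temp", setdiff(names(s), "base_temp"))]
  }))
  row.names(results) <- NULL
  pick <- function(metric, best = c("min", "max")) {
    best <- match.arg(best)
    sub <- results[results$metric == metric, ]
    target <- if (best == "max") max(sub$mean) else min(sub$mean)
    cand <- sub$base_temp[sub$mean == target]
    if (length(cand) > 1L) {
      message(sprintf("%s optimum tied at %s degC; reporting the lowest",
                      metric, paste(cand, collapse = ", ")))
    }
    min(cand)
  }
  optima <- data.frame(
    metric = c("accuracy", "rmse", "combined"),
    base_temp = c(pick("accuracy", "max"), pick("rmse", "min"),
                  pick("combined", "min")))
  structure(list(results = results, optima = optima,
                 distributions = dists[!failed], grid = grid,
                 scenario = scen$label, ci_level = ci_level),
            class = "base_temp_grid")
}

#' @export
print.base_temp_grid <- function(x, ...) {
  cat(sprintf("Base-temperature grid search (%s), %d grid point(s):\n",
              x$scenario, length(x$grid)))
  print(x$optima, row.names = FALSE)
  invisible(x)
}
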