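#' Specification of the repeated stratified splitting scheme
#'
#' Evaluation repeatedly partitions the observations into disjoint
#' training and test sets, stratified jointly by year and location so
#' every split sees every site and season in both roles. One
#' `split_spec` shared across model candidates (or base-temperature grid
#' points) pairs the comparisons: every candidate sees the exact same
#' partitions.
#'
#' @param train_fraction Fraction of each stratum assigned to training
#'   (default 0.70).
#' @param n_repeats Number of independent splits (default 100).
#' @param seed Root seed; per-repeat seeds are spawned from it
#'   deterministically.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, n_repeats = 100, seed = 1) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    thermophen_stop("train_fraction must be in (0, 1)")
  }
  if (n_repeats < 1) thermophen_stop("n_repeats must be >= 1")
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' One stratified train/test split
#'
#' Partitions the rows of a feature table into training and test sets,
#' stratified by (year, location). Within every stratum of size `n_s`
#' the training share is `round(train_fraction * n_s)` (half rounded
#' up); singleton strata go entirely to training, so they can never leak
#' into the test set. Deterministic given (`spec$seed`, `repeat_index`).
#'
#' @param table A feature table with `year` and `location_id` columns.
#' @param spec A [split_spec()].
#' @param repeat_index Which repeat (1..`spec$n_repeats`).
#' @param warn_singletons Warn about strata of size 1 (default TRUE;
#'   resampling loops disable it after the first repeat).
#' @return List with integer row indices `train` and `test`; together
#'   they partition the table exactly.
#' @export
stratified_split <- function(table, spec, repeat_index = 1L,
                             warn_singletons = TRUE) {
  if (repeat_index < 1L || repeat_index > spec$n_repeats) {
    thermophen_stop("repeat_index out of range 1..%d", spec$n_repeats)
  }
  strata <- paste(table$year, table$location_id, sep = "|")
  seed_r <- spawn_seeds(spec$seed, spec$n_repeats)[repeat_index]
  groups <- split(seq_len(nrow(table)), strata)
  singletons <- names(groups)[lengths(groups) == 1L]
  if (warn_singletons && length(singletons)) {
    warning(sprintf("%d stratum/strata of size 1 assigned wholly to training (e.g. %s)",
                    length(singletons), singletons[1]), call. = FALSE)
  }
  train <- integer(0)
  with_local_seed(seed_r, {
    for (g in groups) {
      n_s <- length(g)
      if (n_s == 1L) {
        train <- c(train, g)
      } else {
        n_train <- round_half_up(spec$train_fraction * n_s)
        n_train <- max(1L, min(n_s - 1L, n_train))
        train <- c(train, sample(g, n_train))
      }
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

#' Score predicted against observed phase ranks
#'
#' Accuracy (exact-match fraction), RMSE on the integer ranks, and the
#' combined selection metric `(1 - Accuracy) * RMSE`, which is zero when
#' either every case is classified correctly or the error magnitude
#' vanishes, and otherwise weights the typical error size by the error
#' rate.
#'
#' @param predictions,truth Integer rank vectors of equal positive
#'   length.
#' @return One-row data frame of class `metric_report`: `accuracy`,
#'   `rmse`, `combined`, `n_test`.
#' @examples
#' score(c(1, 1, 3, 3), c(1, 2, 3, 4))  # accuracy 0.5, rmse ~0.707
#' @export
score <- function(predictions, truth) {
  if (length(predictions) == 0L) thermophen_stop("cannot score an empty prediction set")
  if (length(predictions) != length(truth)) {
    thermophen_stop("predictions and truth lengths differ (%d vs %d)",
                    length(predictions), length(truth))
  }
  acc <- mean(predictions == truth)
  rmse <- sqrt(mean((as.numeric(predictions) - as.numeric(truth))^2))
  out <- data.frame(accuracy = acc, rmse = rmse,
                    combined = (1 - acc) * rmse,
                    n_test = length(truth))
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Resampled evaluation of one model
#'
#' Fits the model on the training side of each repeated stratified split
#' and scores it on the held-out side, yielding a distribution of
#' accuracy, RMSE, and combined-metric values, plus Student-t confidence
#' intervals for each metric's mean.
#'
#' @param table Feature table.
#' @param fit_fun `function(train, test)` returning integer rank
#'   predictions for the test rows. See [model_fit_fun()] and
#'   `fit_baseline()`-based closures.
#' @param spec A [split_spec()]; reusing one spec across calls pairs the
#'   splits exactly.
#' @param ci_level Confidence level for the mean (default 0.95).
#' @return Object of class `resample_distribution`: per-repeat reports
#'   and a per-metric summary (mean, se, ci_lo, ci_hi).
#' @export
resample_evaluate <- function(table, fit_fun, spec = split_spec(),
                              ci_level = 0.95) {
  reports <- vector("list", spec$n_repeats)
  for (r in seq_len(spec$n_repeats)) {
    idx <- stratified_split(table, spec, r, warn_singletons = (r == 1L))
    if (length(idx$test) == 0L) {
      warning(sprintf("repeat %d has an empty test set; skipped", r),
              call. = FALSE)
      next
    }
    train <- ft_rows(table, idx$train)
    test <- ft_rows(table, idx$test)
    preds <- fit_fun(train, test)
    if (length(preds) != nrow(test)) {
      thermophen_stop("fit_fun returned %d predictions for %d test rows",
                      length(preds), nrow(test))
    }
    rep_report <- score(preds, test$rank)
    rep_report$repeat_index <- r
    reports[[r]] <- rep_report
  }
  reports <- do.call(rbind, reports)
  if (is.null(reports) || nrow(reports) == 0L) {
    thermophen_stop("all resampling repeats were skipped")
  }
  summ <- do.call(rbind, lapply(c("accuracy", "rmse", "combined"), function(m) {
    x <- reports[[m]]
    n <- length(x)
    mu <- mean(x)
    if (n > 1L) {
      se <- stats::sd(x) / sqrt(n)
      half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1) * se
      data.frame(metric = m, mean = mu, se = se,
                 ci_lo = mu - half, ci_hi = mu + half)
    } else {
      data.frame(metric = m, mean = mu, se = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_)
    }
  }))
  if (nrow(reports) == 1L) {
    message("single repeat: confidence intervals undefined (reported as NA)")
  }
  structure(list(reports = reports, summary = summ, ci_level = ci_level,
                 n_repeats = spec$n_repeats,
                 n_effective = nrow(reports)),
            class = "resample_distribution")
}

#' @export
print.resample_distribution <- function(x, ...) {
  cat(sprintf("Resampled evaluation over %d repeat(s) (%.0f%% CIs):\n",
              x$n_effective, 100 * x$ci_level))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Residual diagnostics for rank predictions
#'
#' Breaks prediction residuals (`predicted - observed` rank) down the
#' ways model failure tends to show up in phenology: by error magnitude,
#' by day-of-year window, by target phase, and by location.
#'
#' @param predictions,truth Integer rank vectors.
#' @param doy Optional day-of-year per observation.
#' @param location Optional location label per observation.
#' @param doy_bin_width Width of DOY bins in days (default 30).
#' @return List of class `residual_diagnostics` with data frames
#'   `magnitude` (histogram of |residual|), `by_rank`, and, when the
#'   covariates are supplied, `by_doy` and `by_location`.
#' @export
residual_diagnostics <- function(predictions, truth, doy = NULL,
                                 location = NULL, doy_bin_width = 30) {
  if (length(predictions) != length(truth)) {
    thermophen_stop("predictions and truth lengths differ")
  }
  resid <- as.numeric(predictions) - as.numeric(truth)
  out <- list()
  mag <- table(factor(abs(resid), levels = 0:max(abs(resid))))
  out$magnitude <- data.frame(magnitude = as.integer(names(mag)),
                              count = as.integer(mag))
  grp_stats <- function(f) {
    agg <- split(resid, f)
    data.frame(group = names(agg),
               n = lengths(agg),
               mean_residual = vapply(agg, mean, 0),
               mean_abs_residual = vapply(agg, function(r) mean(abs(r)), 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  br <- grp_stats(truth)
  names(br)[1] <- "rank"
  br$rank <- as.integer(br$rank)
  out$by_rank <- br
  if (!is.null(doy)) {
    bins <- cut(doy, breaks = seq(0, 366 + doy_bin_width, by = doy_bin_width),
                include.lowest = TRUE)
    bd <- grp_stats(droplevels(bins))
    names(bd)[1] <- "doy_bin"
    out$by_doy <- bd
  }
  if (!is.null(location)) {
    bl <- grp_stats(location)
    names(bl)[1] <- "location_id"
    out$by_location <- bl
  }
  class(out) <- c("residual_diagnostics", class(out))
  out
}

#' Compare cumulative GDD from two temperature sources
#'
#' Tabulates, per location and day of year, the error and relative error
#' of one cumulative-GDD series (e.g. computed from reanalysis
#' temperatures) against a reference (e.g. station measurements). When
#' the alternative source carries a systematic per-location temperature
#' bias, the relative error settles to a roughly constant per-location
#' percentage as the season accumulates, which is the diagnostic this
#' function exposes.
#'
#' @param reference,alternative `cum_gdd` data frames with identical
#'   (location, date) coverage (sources may differ).
#' @param tail_doy_range DOY window over which convergence is summarised
#'   (default 180..366, i.e. the second half of the year).
#' @return List of class `gdd_comparison`: `trajectory` (location, date,
#'   doy, reference and alternative cum_gdd, error, rel_error) and
#'   `summary` (per-location mean/sd of the tail relative error and
#'   their ratio `sd_over_mean`).
#' @export
gdd_source_comparison <- function(reference, alternative,
                                  tail_doy_range = c(180, 366)) {
  key_a <- paste(reference$location_id, reference$date)
  key_b <- paste(alternative$location_id, alternative$date)
  if (nrow(reference) != nrow(alternative) || !setequal(key_a, key_b)) {
    thermophen_stop("reference and alternative series do not cover the same (location, date) set",
                    class = "thermophen_missing_coverage")
  }
  idx <- match(key_a, key_b)
  err <- alternative$cum_gdd[idx] - reference$cum_gdd
  rel <- ifelse(reference$cum_gdd > 0, err / reference$cum_gdd, NA_real_)
  traj <- data.frame(location_id = reference$location_id,
                     date = reference$date,
                     doy = reference$doy,
                     cum_gdd_ref = reference$cum_gdd,
                     cum_gdd_alt = alternative$cum_gdd[idx],
                     error = err,
                     rel_error = rel,
                     stringsAsFactors = FALSE)
  tail_rows <- traj[traj$doy >= tail_doy_range[1] &
                      traj$doy <= tail_doy_range[2] &
                      is.finite(traj$rel_error), ]
  summ <- do.call(rbind, lapply(split(tail_rows, tail_rows$location_id), function(d) {
    mu <- mean(d$rel_error)
    s <- stats::sd(d$rel_error)
    data.frame(location_id = d$location_id[1], n = nrow(d),
               mean_rel_error = mu, sd_rel_error = s,
               sd_over_mean = ifelse(abs(mu) > 0, s / abs(mu), NA_real_),
               stringsAsFactors = FALSE)
  }))
  row.names(summ) <- NULL
  structure(list(trajectory = traj, summary = summ,
                 tail_doy_range = tail_doy_range),
            class = "gdd_comparison")
}
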