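# Registry of model families. Each entry supplies fit(X, y, params, K)
# returning an opaque fitted object and predict(fit, X) returning
# continuous rank predictions. The learners themselves come from
# established libraries; the bespoke parts are the uniform contract,
# split pairing, rank discretisation, inner tuning, and selection.

.model_registry <- new.env(parent = emptyenv())

#' Register a model family
#'
#' Adds (or replaces) a family in the pluggable model registry. Built-in
#' families: `linear_regression` (stats), `cart` (rpart),
#' `random_forest` (randomForest), `neural_net` (nnet), `gbm`
#' (stochastic gradient boosting via xgboost with row subsampling),
#' `xgboost_linear` and `xgboost_tree` (xgboost).
#'
#' @param family Family name.
#' @param fit `function(X, y, params, K)` -> fitted object; `X` is a
#'   numeric matrix of features, `y` the numeric rank target.
#' @param predict_fun `function(fit, X)` -> numeric predictions.
#' @param packages Character vector of packages the family needs; a
#'   missing package turns fitting into an explicit capability error.
#' @param default_grid Data frame of hyperparameter candidates; a single
#'   row means no inner tuning is needed.
#' @export
register_model <- function(family, fit, predict_fun, packages = character(),
                           default_grid = data.frame(row.names = 1)) {
  assign(family, list(fit = fit, predict = predict_fun, packages = packages,
                      default_grid = default_grid),
         envir = .model_registry)
  invisible(family)
}

#' List registered model families
#' @return Character vector of family names.
#' @export
model_families <- function() sort(ls(.model_registry))

get_family <- function(family) {
  if (!exists(family, envir = .model_registry, inherits = FALSE)) {
    thermophen_stop("unknown model family '%s'; registered: %s",
                    family, paste(model_families(), collapse = ", "),
                    class = "thermophen_capability_error")
  }
  entry <- get(family, envir = .model_registry, inherits = FALSE)
  missing_pkg <- entry$packages[!vapply(entry$packages, requireNamespace, TRUE,
                                        quietly = TRUE)]
  if (length(missing_pkg)) {
    thermophen_stop("model family '%s' requires unavailable package(s): %s",
                    family, paste(missing_pkg, collapse = ", "),
                    class = "thermophen_capability_error")
  }
  entry
}

#' Describe one model candidate
#'
#' A model spec pairs a registered family with the feature treatment
#' (linear features or all monomials up to degree 4), the
#' discretisation mode used to turn continuous outputs into ranks, the
#' hyperparameter grid, and the inner cross-validation scheme used when
#' that grid has more than one candidate.
#'
#' @param family A registered family name (see [model_families()]).
#' @param polynomial Use degree-4 polynomial feature expansion (default
#'   FALSE). Each family is meaningful in both settings.
#' @param discretise `"round"`, `"floor"`, or `"ceiling"`.
#' @param grid Optional hyperparameter data frame; defaults to the
#'   family's registered grid. With more than one row, the best row is
#'   chosen by inner repeated k-fold CV (minimum RMSE) on the training
#'   split only.
#' @param tune_folds,tune_repeats Inner CV scheme (default 10 folds,
#'   3 repeats).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family, polynomial = FALSE,
                       discretise = c("round", "floor", "ceiling"),
                       grid = NULL, tune_folds = 10, tune_repeats = 3) {
  discretise <- match.arg(discretise)
  structure(list(family = family, polynomial = isTRUE(polynomial),
                 discretise = discretise, grid = grid,
                 tune_folds = as.integer(tune_folds),
                 tune_repeats = as.integer(tune_repeats),
                 label = paste0(family, if (isTRUE(polynomial)) "+poly4")),
            class = "model_spec")
}

#' Fit a model spec on training rows and predict test ranks
#'
#' Applies the spec's feature treatment, tunes on the training split
#' only if the grid has several candidates (inner repeated k-fold CV
#' minimising RMSE), fits the family's learner, and discretises the
#' continuous output to integer ranks clamped to `[1, K]`. The test
#' rows contribute nothing to tuning or fitting.
#'
#' @param spec A [model_spec()].
#' @param train,test Feature tables (see [build_feature_table()]).
#' @param tune_seed Seed for the inner CV fold assignment.
#' @return Integer rank predictions for the test rows.
#' @export
fit_predict <- function(spec, train, test, tune_seed = 1L) {
  entry <- get_family(spec$family)
  fc <- feature_cols(train)
  K <- attr(train, "K") %||% max(train$rank)
  X_train <- as.matrix(train[fc])
  X_test <- as.matrix(test[fc])
  if (spec$polynomial) {
    X_train <- poly_expand(X_train, 4)
    X_test <- poly_expand(X_test, 4)
  }
  y <- as.numeric(train$rank)
  grid <- spec$grid %||% entry$default_grid
  # local seed: stochastic learners (forests, boosting) stay
  # deterministic for a given training split without disturbing the
  # caller's RNG stream
  with_local_seed(tune_seed, {
    params <- if (nrow(grid) > 1L) {
      grid[tune_grid(entry, grid, X_train, y, K, spec$tune_folds,
                     spec$tune_repeats, tune_seed), , drop = FALSE]
    } else {
      grid
    }
    fit <- entry$fit(X_train, y, as.list(params), K)
    discretise_output(entry$predict(fit, X_test), K, spec$discretise)
  })
}

# Inner repeated k-fold CV over a hyperparameter grid; returns the row
# index with minimum mean RMSE of the continuous predictions.
tune_grid <- function(entry, grid, X, y, K, folds, repeats, seed) {
  n <- length(y)
  folds <- min(folds, n)
  rmse <- matrix(NA_real_, nrow(grid), repeats * folds)
  fold_ids <- with_local_seed(seed, {
    replicate(repeats, sample(rep_len(seq_len(folds), n)), simplify = FALSE)
  })
  col <- 0L
  for (rep_ids in fold_ids) {
    for (f in seq_len(folds)) {
      col <- col + 1L
      hold <- which(rep_ids == f)
      if (length(hold) == 0L || length(hold) == n) next
      for (g in seq_len(nrow(grid))) {
        fit <- entry$fit(X[-hold, , drop = FALSE], y[-hold],
                         as.list(grid[g, , drop = FALSE]), K)
        pred <- entry$predict(fit, X[hold, , drop = FALSE])
        rmse[g, col] <- sqrt(mean((pred - y[hold])^2))
      }
    }
  }
  which.min(rowMeans(rmse, na.rm = TRUE))
}

#' Wrap a model spec as a fit/predict closure
#'
#' @param spec A [model_spec()] or the string `"baseline"` together with
#'   `baseline_feature` naming the single GDD column the threshold
#'   baseline consumes.
#' @param baseline_feature GDD feature column for the baseline model.
#' @return `function(train, test)` suitable for [resample_evaluate()].
#' @export
model_fit_fun <- function(spec, baseline_feature = NULL) {
  if (identical(spec, "baseline")) {
    if (is.null(baseline_feature)) {
      thermophen_stop("the baseline model needs baseline_feature (one GDD column)")
    }
    return(baseline_fit_fun(baseline_feature))
  }
  if (!inherits(spec, "model_spec")) thermophen_stop("not a model_spec")
  force(spec)
  function(train, test) fit_predict(spec, train, test)
}

#' Compare model candidates on paired resampled splits
#'
#' Runs [resample_evaluate()] for every candidate on the *same* split
#' sequence (the shared `split_spec` seed pairs the partitions, so split
#' noise cancels out of the comparison) and selects the candidate with
#' the minimum mean combined metric. Ties are broken by candidate
#' order, with a message.
#'
#' @param table Feature table.
#' @param specs List of [model_spec()] objects (or `"baseline"`; see
#'   [model_fit_fun()]).
#' @param spec_split A [split_spec()].
#' @param baseline_feature Passed to [model_fit_fun()] for `"baseline"`
#'   candidates.
#' @param ci_level Confidence level for per-candidate CIs.
#' @return Object of class `model_selection`: per-candidate summary
#'   table (mean accuracy, RMSE, combined), full distributions, and the
#'   selected candidate.
#' @export
select_model <- function(table, specs, spec_split = split_spec(),
                         baseline_feature = NULL, ci_level = 0.95) {
  if (length(specs) == 0L) thermophen_stop("no model candidates supplied")
  labels <- vapply(specs, function(s)
    if (identical(s, "baseline")) "baseline" else s$label, "")
  dists <- vector("list", length(specs))
  ok <- logical(length(specs))
  for (i in seq_along(specs)) {
    dists[[i]] <- tryCatch(
      resample_evaluate(table, model_fit_fun(specs[[i]], baseline_feature),
                        spec_split, ci_level),
      error = function(e) {
        warning(sprintf("candidate '%s' failed: %s", labels[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    ok[i] <- !is.null(dists[[i]])
  }
  if (!any(ok)) thermophen_stop("all model candidates failed")
  mean_of <- function(d, m) d$summary$mean[d$summary$metric == m]
  results <- data.frame(
    label = labels[ok],
    mean_accuracy = vapply(dists[ok], mean_of, 0, m = "accuracy"),
    mean_rmse = vapply(dists[ok], mean_of, 0, m = "rmse"),
    mean_combined = vapply(dists[ok], mean_of, 0, m = "combined"),
    stringsAsFactors = FALSE)
  best <- which.min(results$mean_combined)
  if (sum(results$mean_combined == results$mean_combined[best]) > 1L) {
    message("combined-metric tie; keeping the earliest candidate in registry order")
  }
  structure(list(results = results, selected = results$label[best],
                 selected_index = which(ok)[best],
                 distributions = stats::setNames(dists[ok], labels[ok])),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by minimum mean combined metric:\n")
  print(x$results, row.names = FALSE, digits = 4)
  cat(sprintf("Selected: %s\n", x$selected))
  invisible(x)
}

# ---- built-in families -----------------------------------------------------

register_builtin_models <- function() {
  register_model("linear_regression",
    fit = function(X, y, params, K) {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0  # aliased / zero-variance columns drop out
      cf
    },
    predict_fun = function(fit, X) drop(cbind(1, X) %*% fit))

  register_model("cart",
    fit = function(X, y, params, K) {
      d <- data.frame(y = y, X, check.names = TRUE)
      rpart::rpart(y ~ ., data = d, method = "anova",
                   cp = params$cp %||% 0.01,
                   minsplit = params$minsplit %||% 20)
    },
    predict_fun = function(fit, X)
      unname(predict(fit, data.frame(X, check.names = TRUE))),
    packages = "rpart",
    default_grid = data.frame(cp = 0.01))

  register_model("random_forest",
    fit = function(X, y, params, K) {
      randomForest::randomForest(
        x = X, y = y,
        ntree = params$ntree %||% 300,
        mtry = params$mtry %||% max(1L, floor(ncol(X) / 3)))
    },
    predict_fun = function(fit, X) unname(predict(fit, X)),
    packages = "randomForest",
    default_grid = data.frame(ntree = 300))

  register_model("neural_net",
    fit = function(X, y, params, K) {
      mu <- colMeans(X)
      sdev <- apply(X, 2, stats::sd)
      sdev[sdev == 0] <- 1
      Xs <- scale(X, mu, sdev)
      net <- nnet::nnet(Xs, (y - 1) / (K - 1),
                        size = params$size %||% 5,
                        decay = params$decay %||% 0.1,
                        maxit = params$maxit %||% 300,
                        linout = FALSE, trace = FALSE)
      list(net = net, mu = mu, sd = sdev, K = K)
    },
    predict_fun = function(fit, X) {
      Xs <- scale(X, fit$mu, fit$sd)
      drop(predict(fit$net, Xs)) * (fit$K - 1) + 1
    },
    packages = "nnet",
    default_grid = data.frame(size = 5, decay = 0.1))

  xgb_fit <- function(booster, subsample) {
    function(X, y, params, K) {
      p <- list(objective = "reg:squarederror", booster = booster,
                nthread = 1)
      if (booster == "gbtree") {
        p$eta <- params$eta %||% 0.1
        p$max_depth <- params$max_depth %||% 3
        p$subsample <- subsample
      }
      xgboost::xgb.train(params = p,
                         data = xgboost::xgb.DMatrix(X, label = y),
                         nrounds = params$nrounds %||% 150, verbose = 0)
    }
  }
  xgb_predict <- function(fit, X) predict(fit, xgboost::xgb.DMatrix(X))

  # stochastic gradient boosting: boosted trees with random row
  # subsampling (without replacement) at each iteration
  register_model("gbm", fit = xgb_fit("gbtree", 0.5),
                 predict_fun = xgb_predict, packages = "xgboost",
                 default_grid = data.frame(nrounds = 150))
  register_model("xgboost_tree", fit = xgb_fit("gbtree", 1),
                 predict_fun = xgb_predict, packages = "xgboost",
                 default_grid = data.frame(nrounds = 150))
  register_model("xgboost_linear",
                 fit = xgb_fit("gblinear", 1),
                 predict_fun = xgb_predict, packages = "xgboost",
                 default_grid = data.frame(nrounds = 50))
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_models()
}
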