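make_perfect_table <- function(n_per_rank = 6, K = 8) {
  tab <- data.frame(year = 2008, location_id = "a",
                    rank = rep(seq_len(K), each = n_per_rank))
  tab$x <- as.numeric(tab$rank)
  attr(tab, "feature_cols") <- "x"
  attr(tab, "K") <- as.integer(K)
  tab
}

test_that("every built-in family fits and predicts on a learnable table", {
  tab <- make_perfect_table()
  for (fam in model_families()) {
    spec <- model_spec(fam)
    preds <- fit_predict(spec, tab, tab)
    expect_type(preds, "integer")
    expect_length(preds, nrow(tab))
    expect_true(all(preds >= 1 & preds <= 8), label = fam)
  }
})

test_that("random forest reproduces an exactly encoded target in-sample", {
  tab <- make_perfect_table(n_per_rank = 10)
  preds <- fit_predict(model_spec("random_forest"), tab, tab)
  expect_equal(mean(preds == tab$rank), 1.0)
})

test_that("linear regression on zero-variance features predicts the rounded mean rank", {
  tab <- make_perfect_table(K = 7)  # integer mean rank, no rounding ambiguity
  tab$x <- 1  # no signal left
  preds <- fit_predict(model_spec("linear_regression"), tab, tab)
  expect_true(all(preds == round(mean(tab$rank))))
})

test_that("unknown or unavailable families raise capability errors", {
  tab <- make_perfect_table()
  expect_error(fit_predict(model_spec("deep_transformer"), tab, tab),
               class = "thermophen_capability_error")
  register_model("needs_missing_pkg",
                 fit = function(X, y, params, K) NULL,
                 predict_fun = function(fit, X) NULL,
                 packages = "definitely_not_installed_pkg")
  expect_error(fit_predict(model_spec("needs_missing_pkg"), tab, tab),
               "unavailable package",
               class = "thermophen_capability_error")
  rm("needs_missing_pkg", envir = thermophen:::.model_registry)
})

test_that("polynomial variants expand features before fitting", {
  tab <- make_perfect_table()
  preds <- fit_predict(model_spec("linear_regression", polynomial = TRUE),
                       tab, tab)
  expect_length(preds, nrow(tab))
  expect_true(all(abs(preds - tab$rank) <= 1))
})

test_that("inner tuning picks the better grid row on the training split only", {
  set.seed(8)
  tab <- make_perfect_table(n_per_rank = 8)
  tab$rank <- tab$rank + rbinom(nrow(tab), 1, 0.2)
  # cp = 1 forbids any split (intercept tree); cp small allows the fit
  spec <- model_spec("cart", grid = data.frame(cp = c(1, 1e-4), minsplit = 5),
                     tune_folds = 5, tune_repeats = 2)
  preds <- fit_predict(spec, tab, tab)
  expect_gt(mean(preds == tab$rank), 0.5)  # intercept tree would be ~1/K
})

test_that("model selection pairs splits and picks the minimum mean combined metric", {
  set.seed(21)
  world <- pointband_world(n_locations = 3, years = 2009:2010)
  tab <- world_gdd_table(world)
  oracle_spec <- model_spec("cart", grid = data.frame(cp = 1e-4, minsplit = 2))
  sel <- select_model(tab, list(oracle_spec, "baseline"),
                      split_spec(n_repeats = 5, seed = 3),
                      baseline_feature = "gdd_allen")
  expect_s3_class(sel, "model_selection")
  expect_equal(nrow(sel$results), 2)
  # noiseless point-band world: both are exact; selection must still be
  # consistent with the stored means
  expect_equal(sel$results$mean_combined[match(sel$selected, sel$results$label)],
               min(sel$results$mean_combined))
  # identical candidates see identical split sequences
  sel2 <- select_model(tab, list(oracle_spec, oracle_spec),
                       split_spec(n_repeats = 5, seed = 3))
  expect_equal(sel2$distributions[[1]]$reports$accuracy,
               sel2$distributions[[2]]$reports$accuracy)
})

test_that("a constant predictor loses to an informative model on multi-class data", {
  set.seed(5)
  world <- pointband_world(n_locations = 3, years = 2009:2010)
  tab <- world_gdd_table(world)
  register_model("constant_rank",
                 fit = function(X, y, params, K) mean(y),
                 predict_fun = function(fit, X) rep(fit, nrow(X)))
  sel <- select_model(tab, list(model_spec("cart",
                                           grid = data.frame(cp = 1e-4, minsplit = 2)),
                                model_spec("constant_rank")),
                      split_spec(n_repeats = 5, seed = 7))
  expect_equal(sel$selected, "cart")
  rm("constant_rank", envir = thermophen:::.model_registry)
})

test_that("predictions are identical when test rows are hidden from training", {
  set.seed(31)
  world <- pointband_world(n_locations = 3, years = 2009:2010)
  tab <- world_gdd_table(world)
  idx <- stratified_split(tab, split_spec(n_repeats = 1, seed = 2))
  train <- thermophen:::ft_rows(tab, idx$train)
  test <- thermophen:::ft_rows(tab, idx$test)
  p1 <- fit_predict(model_spec("random_forest"), train, test)
  p2 <- fit_predict(model_spec("random_forest"), train, test)
  expect_identical(p1, p2)  # deterministic under the internal fit seed
})
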