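test_that("metric report follows the combined-metric algebra", {
  r <- score(c(1, 1, 3, 3), c(1, 2, 3, 4))
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$rmse, sqrt(0.5))
  expect_equal(r$combined, 0.5 * sqrt(0.5))
  p <- sample(1:20, 50, TRUE)
  expect_equal(score(p, p)$combined, 0)
  expect_equal(score(p, p)$accuracy, 1)
  r1 <- score(2, 5)
  expect_equal(unlist(r1[c("accuracy", "rmse", "combined")]),
               c(accuracy = 0, rmse = 3, combined = 3))
  expect_error(score(integer(0), integer(0)), "empty")
  expect_error(score(1:3, 1:4), "lengths differ")
})

make_table <- function(n_per_stratum, years = 2008:2009, locs = c("a", "b")) {
  grid <- expand.grid(year = years, location_id = locs,
                      stringsAsFactors = FALSE)
  rows <- grid[rep(seq_len(nrow(grid)), each = n_per_stratum), ]
  rows$rank <- sample(1:5, nrow(rows), TRUE)
  rows$gdd <- runif(nrow(rows), 0, 100)
  attr(rows, "feature_cols") <- "gdd"
  attr(rows, "K") <- 5L
  rows
}

test_that("stratified splits partition exactly with per-stratum 70/30 shares", {
  set.seed(1)
  tab <- make_table(10)
  sp <- split_spec(n_repeats = 5, seed = 42)
  for (r in 1:5) {
    idx <- stratified_split(tab, sp, r)
    expect_setequal(c(idx$train, idx$test), seq_len(nrow(tab)))
    expect_length(intersect(idx$train, idx$test), 0)
    for (s in split(seq_len(nrow(tab)), paste(tab$year, tab$location_id))) {
      expect_equal(sum(s %in% idx$train), 7)  # round(0.7 * 10)
    }
  }
})

test_that("per-stratum train fraction is within 1/n_s of the target", {
  set.seed(2)
  for (trial in 1:10) {
    sizes <- sample(2:15, 4, TRUE)
    tab <- do.call(rbind, lapply(seq_along(sizes), function(i) {
      data.frame(year = 2008, location_id = letters[i],
                 rank = 1, gdd = 0)[rep(1, sizes[i]), ]
    }))
    idx <- stratified_split(tab, split_spec(n_repeats = 1, seed = trial))
    for (i in seq_along(sizes)) {
      s <- which(tab$location_id == letters[i])
      frac <- sum(s %in% idx$train) / length(s)
      expect_lte(abs(frac - 0.7), 1 / length(s) + 1e-9)
    }
  }
})

test_that("singleton strata go to training with a warning and splits are deterministic", {
  tab <- make_table(1)
  sp <- split_spec(n_repeats = 2, seed = 9)
  expect_warning(idx <- stratified_split(tab, sp, 1), "size 1")
  expect_length(idx$test, 0)
  expect_equal(sort(idx$train), seq_len(nrow(tab)))

  tab2 <- make_table(8)
  a <- stratified_split(tab2, sp, 2, warn_singletons = FALSE)
  b <- stratified_split(tab2, sp, 2, warn_singletons = FALSE)
  expect_identical(a, b)
  c2 <- stratified_split(tab2, sp, 1, warn_singletons = FALSE)
  expect_false(identical(a$train, c2$train))
})

test_that("resampled evaluation aggregates per-repeat metric reports", {
  world <- pointband_world()
  tab <- world_gdd_table(world)
  fit <- thermophen:::baseline_fit_fun("gdd_allen")
  d <- resample_evaluate(tab, fit, split_spec(n_repeats = 10, seed = 4))
  expect_equal(nrow(d$reports), 10)
  expect_s3_class(d, "resample_distribution")
  # noiseless point-band world: the baseline is exact on held-out data
  expect_equal(d$summary$mean[d$summary$metric == "accuracy"], 1.0)
  expect_equal(d$summary$mean[d$summary$metric == "combined"], 0.0)
  # CI contains the mean
  ok <- with(d$summary, ci_lo <= mean & mean <= ci_hi)
  expect_true(all(ok))
})

test_that("a constant-prediction model on single-class data has zero-width CIs", {
  tab <- make_table(6)
  tab$rank <- 3L
  fit <- function(train, test) rep(3L, nrow(test))
  d <- resample_evaluate(tab, fit, split_spec(n_repeats = 8, seed = 1))
  expect_true(all(d$reports$accuracy == 1))
  expect_equal(max(d$summary$ci_hi - d$summary$ci_lo), 0)
})

test_that("a single repeat yields NA confidence intervals with a message", {
  tab <- make_table(6)
  fit <- function(train, test) rep(1L, nrow(test))
  expect_message(d <- resample_evaluate(tab, fit, split_spec(n_repeats = 1, seed = 1)),
                 "single repeat")
  expect_true(all(is.na(d$summary$ci_lo)))
  expect_equal(d$summary$mean, unlist(d$reports[1, c("accuracy", "rmse", "combined")],
                                      use.names = FALSE))
})

test_that("confidence intervals shrink as repeats grow", {
  world <- pointband_world()
  tab <- world_gdd_table(world)
  tab$rank <- pmin(attr(tab, "K"), tab$rank +
                     rbinom(nrow(tab), 1, 0.3))  # inject noise so metrics vary
  fit <- thermophen:::baseline_fit_fun("gdd_allen")
  widths <- sapply(1:5, function(s) {
    w10 <- resample_evaluate(tab, fit, split_spec(n_repeats = 10, seed = s))
    w40 <- resample_evaluate(tab, fit, split_spec(n_repeats = 40, seed = s))
    cw <- function(d) diff(unlist(d$summary[d$summary$metric == "combined",
                                            c("ci_lo", "ci_hi")]))
    c(cw(w10), cw(w40))
  })
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("residual diagnostics partition residuals exhaustively", {
  d <- residual_diagnostics(c(1, 3), c(2, 1), doy = c(100, 200),
                            location = c("a", "b"))
  expect_equal(d$magnitude$count[d$magnitude$magnitude %in% 1:2], c(1L, 1L))
  expect_equal(sum(d$by_location$n), 2)
  expect_equal(sum(d$by_doy$n), 2)
  perfect <- residual_diagnostics(1:5, 1:5)
  expect_equal(perfect$magnitude,
               data.frame(magnitude = 0L, count = 5L))
})

test_that("GDD source comparison recovers algebraic error structure", {
  w <- generate_weather(tiny_world_config())
  a <- accumulate_gdd(w, 10, "tavg")
  cmp0 <- gdd_source_comparison(a, a)
  expect_true(all(cmp0$trajectory$error == 0))

  b <- a
  b$cum_gdd <- 1.1 * a$cum_gdd   # increments scaled by 1.10
  cmp <- gdd_source_comparison(a, b)
  rel <- cmp$trajectory$rel_error[is.finite(cmp$trajectory$rel_error)]
  expect_equal(unique(round(rel, 10)), 0.1)

  expect_error(gdd_source_comparison(a, a[-1, ]),
               class = "thermophen_missing_coverage")
})
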