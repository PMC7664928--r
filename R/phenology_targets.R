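#' Build a BBCH rank map
#'
#' The BBCH scale labels developmental stages with codes whose numeric
#' values carry no metric meaning, so models never see the codes
#' directly. Instead an ordered code list is mapped to a dense integer
#' rank 1..K, and the rank is the modelling target.
#'
#' @param codes Character vector of BBCH code labels in developmental
#'   order (earliest first). Must be unique, length >= 2.
#' @return Data frame of class `bbch_rank_map` with columns `bbch_code`
#'   and `rank` (1..K in list order).
#' @seealso [default_rank_map()] for a synthetic 20-stage stand-in.
#' @export
bbch_rank_map <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) < 2L) thermophen_stop("a rank map needs at least 2 codes")
  if (anyDuplicated(codes)) {
    thermophen_stop("duplicate BBCH codes in rank map: %s",
                    paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  out <- data.frame(bbch_code = codes, rank = seq_along(codes),
                    stringsAsFactors = FALSE)
  class(out) <- c("bbch_rank_map", "data.frame")
  out
}

#' Default synthetic 20-stage rank map
#'
#' A stand-in simplified olive BBCH scale with K = 20 ordered stages,
#' spanning bud development through fruit ripening. Real studies should
#' supply their own ordered code list via [bbch_rank_map()]; this default
#' exists so the synthetic-world generator and examples have a concrete
#' scale to work with.
#'
#' @param K Number of stages (default 20).
#' @return A `bbch_rank_map` with `K` synthetic codes.
#' @export
default_rank_map <- function(K = 20) {
  olive_like <- c("00", "01", "03", "07", "09", "11", "15", "19", "31", "33",
                  "37", "51", "54", "57", "60", "65", "68", "69", "71", "75",
                  "79", "80", "81", "85", "89")
  codes <- if (K <= length(olive_like)) olive_like[seq_len(K)] else
    sprintf("S%02d", seq_len(K))
  bbch_rank_map(codes)
}

#' Attach integer ranks to BBCH observations
#'
#' @param observations Data frame with at least `location_id`, `date`,
#'   `bbch_code`.
#' @param rank_map A [bbch_rank_map()].
#' @return The observations with a `rank` column appended and `date`
#'   coerced to Date; the original code is retained.
#' @export
encode_ranks <- function(observations, rank_map) {
  need <- c("location_id", "date", "bbch_code")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    thermophen_stop("observations missing column(s): %s",
                    paste(miss, collapse = ", "), class = "thermophen_schema_error")
  }
  observations$date <- as.Date(observations$date)
  idx <- match(as.character(observations$bbch_code), rank_map$bbch_code)
  if (anyNA(idx)) {
    unknown <- unique(observations$bbch_code[is.na(idx)])
    thermophen_stop("BBCH code(s) not in rank map: %s",
                    paste(unknown, collapse = ", "),
                    class = "thermophen_unknown_code")
  }
  observations$rank <- rank_map$rank[idx]
  observations
}

#' Discretise a continuous model output to an integer rank
#'
#' Regression learners emit real-valued predictions of the rank; these
#' are snapped to an integer stage and clamped to the valid range 1..K.
#'
#' @param y Numeric predictions (finite).
#' @param K Number of ranks (>= 2).
#' @param mode `"round"` (default), `"floor"`, or `"ceiling"`.
#' @return Integer ranks in `[1, K]`. Idempotent on integer inputs
#'   already in range.
#' @export
discretise_output <- function(y, K, mode = c("round", "floor", "ceiling")) {
  mode <- match.arg(mode)
  if (!is.numeric(K) || length(K) != 1L || K < 2) {
    thermophen_stop("K must be a single integer >= 2")
  }
  if (any(!is.finite(y))) thermophen_stop("non-finite prediction cannot be discretised")
  v <- switch(mode, round = round(y), floor = floor(y), ceiling = ceiling(y))
  as.integer(pmin(K, pmax(1, v)))
}

#' Assemble the model feature table
#'
#' One row per phenology observation: the requested day-of-year and
#' cumulative-GDD features, the integer rank target, and the year and
#' location columns used for stratified splitting. Optionally expands
#' the features into all monomials of total degree 1..`poly_degree`
#' (degree 4 gives the "polynomial features" model variants).
#'
#' @param observations Rank-encoded observations (see [encode_ranks()]).
#' @param gdd_series Named list of single-source `cum_gdd` data frames;
#'   each name becomes a feature column (e.g.
#'   `list(gdd_allen = ..., era5_gdd_tavg = ...)`).
#' @param use_doy Include day-of-year as a feature (default TRUE).
#' @param poly_degree 1 for linear features; d > 1 appends all monomials
#'   of total degree 2..d in the base features (no constant term).
#' @param K Number of ranks; defaults to the maximum observed rank.
#' @return Data frame of class `pheno_features` with metadata attributes
#'   `feature_cols` and `K`. Row count always equals the observation
#'   count; uncovered observations raise an error rather than being
#'   dropped.
#' @export
build_feature_table <- function(observations, gdd_series = list(),
                                use_doy = TRUE, poly_degree = 1,
                                K = max(observations$rank)) {
  if (!"rank" %in% names(observations)) {
    thermophen_stop("observations must be rank-encoded first (see encode_ranks())")
  }
  if (!use_doy && length(gdd_series) == 0L) {
    thermophen_stop("at least one feature (DOY or a GDD series) is required")
  }
  if (length(gdd_series) && is.null(names(gdd_series))) {
    thermophen_stop("gdd_series must be a named list")
  }
  observations$date <- as.Date(observations$date)
  out <- data.frame(location_id = observations$location_id,
                    date = observations$date,
                    year = year_of(observations$date),
                    rank = as.integer(observations$rank),
                    stringsAsFactors = FALSE)
  if ("bbch_code" %in% names(observations)) out$bbch_code <- observations$bbch_code
  feats <- character(0)
  if (use_doy) {
    out$doy <- doy_of(observations$date)
    feats <- "doy"
  }
  for (nm in names(gdd_series)) {
    out[[nm]] <- gdd_at(gdd_series[[nm]], observations$location_id,
                        observations$date)
    feats <- c(feats, nm)
  }
  if (poly_degree > 1) {
    X <- poly_expand(as.matrix(out[feats]), poly_degree)
    extra <- setdiff(colnames(X), feats)
    out[extra] <- as.data.frame(X[, extra, drop = FALSE])
    feats <- colnames(X)
  }
  attr(out, "feature_cols") <- feats
  attr(out, "K") <- as.integer(K)
  class(out) <- c("pheno_features", "data.frame")
  out
}

# All monomials of total degree 1..degree in the columns of X, no
# constant term. Degree-1 monomials keep the original column names;
# higher-order terms are named like "doy2" or "doy.gdd_allen2".
poly_expand <- function(X, degree) {
  vars <- colnames(X)
  p <- length(vars)
  exps <- as.matrix(expand.grid(rep(list(0:degree), p)))
  exps <- exps[rowSums(exps) >= 1 & rowSums(exps) <= degree, , drop = FALSE]
  colnames(exps) <- vars
  exps <- exps[order(rowSums(exps)), , drop = FALSE]
  out <- matrix(NA_real_, nrow(X), nrow(exps))
  nms <- character(nrow(exps))
  for (j in seq_len(nrow(exps))) {
    e <- exps[j, ]
    out[, j] <- apply(sweep(X, 2, e, function(x, k) x^k), 1, prod)
    used <- which(e > 0)
    nms[j] <- if (length(used) == 1L && e[used] == 1) vars[used] else
      paste0(vars[used], ifelse(e[used] == 1, "", e[used]), collapse = ".")
  }
  colnames(out) <- nms
  out
}

# Row subset that preserves the feature-table metadata attributes.
ft_rows <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  attr(out, "feature_cols") <- attr(table, "feature_cols")
  attr(out, "K") <- attr(table, "K")
  class(out) <- class(table)
  out
}

feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc)) thermophen_stop("not a feature table: missing feature_cols attribute")
  fc
}
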