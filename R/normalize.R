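#' Normalization configuration
#'
#' Linear dimensionless normalization maps each raw indicator series into
#' (0, 1]. Large-value (positive-polarity) indicators always use
#' `x / max(x)`, so the best year scores exactly 1. For small-value
#' (negative-polarity) indicators two orientations are offered:
#'
#' * `"ratio_to_max"` (default) - also `x / max(x)`. The published
#'   normalized panel uses this for its declared small-value columns (their
#'   printed values reproduce the raw percentage changes), so it is the
#'   default.
#' * `"inverse_min_over_x"` - `min(x) / x`, flipping the orientation so the
#'   minimum (optimal) year maps to 1.
#'
#' @param positive_mode Only `"ratio_to_max"`.
#' @param negative_mode `"ratio_to_max"` or `"inverse_min_over_x"`.
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(positive_mode = "ratio_to_max",
                                 negative_mode = c("ratio_to_max",
                                                   "inverse_min_over_x")) {
  positive_mode <- match.arg(positive_mode, "ratio_to_max")
  negative_mode <- match.arg(negative_mode)
  structure(list(positive_mode = positive_mode,
                 negative_mode = negative_mode),
            class = "normalization_config")
}

check_series <- function(x) {
  if (length(x) == 0L) les_stop_value("empty series")
  if (anyNA(x) || !is.numeric(x)) les_stop_value("series must be numeric and non-missing")
  if (any(x <= 0)) les_stop_value("series values must be strictly positive")
  invisible(x)
}

#' Normalize one indicator series
#'
#' `normalize_positive()` rescales a large-value series by its maximum;
#' `normalize_negative()` rescales a small-value series according to the
#' chosen mode (see [normalization_config()]). Both are scale invariant
#' (`c * x` normalizes identically to `x` for any `c > 0`) and map at least
#' one year to exactly 1.
#'
#' @param x Strictly positive numeric vector (one value per year).
#' @param mode Negative-indicator mode.
#' @return Numeric vector in (0, 1], same names as `x`.
#' @export
normalize_positive <- function(x) {
  check_series(x)
  x / max(x)
}

#' @rdname normalize_positive
#' @export
normalize_negative <- function(x, mode = c("ratio_to_max",
                                           "inverse_min_over_x")) {
  mode <- match.arg(mode)
  check_series(x)
  switch(mode,
         ratio_to_max = x / max(x),
         inverse_min_over_x = min(x) / x)
}

#' Normalize a raw indicator panel
#'
#' Applies [normalize_positive()] / [normalize_negative()] column-wise
#' according to each indicator's registry polarity.
#'
#' @param panel An [indicator_panel()] of raw values.
#' @param registry An [indicator_registry()] covering the panel columns.
#' @param config A [normalization_config()].
#' @return A `normalized_panel` of the same shape.
#' @export
#' @examples
#' reg <- default_registry()
#' pan <- generate_panel(default_panel_spec(seed = 1), reg)
#' rng <- range(normalize_panel(pan, reg))
normalize_panel <- function(panel, registry = default_registry(),
                            config = normalization_config()) {
  if (!identical(colnames(panel), registry$id)) {
    les_stop_schema("panel columns do not match the registry ids")
  }
  out <- unclass(panel)
  for (j in seq_len(ncol(out))) {
    id <- registry$id[j]
    out[, j] <- tryCatch(
      if (registry$polarity[j] == "positive") normalize_positive(out[, j])
      else normalize_negative(out[, j], config$negative_mode),
      les_error = function(e) {
        les_stop(sprintf("indicator %s: %s", id, conditionMessage(e)),
                 class(e)[1L], indicator = id)
      })
  }
  indicator_panel(panel_years(panel), out, normalized = TRUE)
}

#' Signed percent change between two years
#'
#' Returns `(x[year_b] / x[year_a] - 1) * 100`. The statistic is invariant
#' under any common positive rescaling of the series, so it gives identical
#' answers on raw and ratio-to-max-normalized series.
#'
#' @param x Numeric series named by year (or an [indicator_panel()] column).
#' @param year_a,year_b Base and comparison years (must be present in
#'   `names(x)`).
#' @return A single signed percentage.
#' @export
#' @examples
#' s21 <- load_fixture("table1_normalized")[, "S21"]
#' percent_change(s21, 2004, 2017)   # +25.20
percent_change <- function(x, year_a, year_b) {
  x <- drop(x)
  if (is.null(names(x))) les_stop_schema("series must be named by year")
  a <- as.character(year_a)
  b <- as.character(year_b)
  for (y in c(a, b)) {
    if (!y %in% names(x)) {
      les_stop_lookup(sprintf("year %s not present in series", y), year = y)
    }
  }
  if (x[[a]] == 0) les_stop_value(sprintf("zero base value at year %s", a))
  unname((x[[b]] / x[[a]] - 1) * 100)
}
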