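#' Indicator panels
#'
#' An indicator panel holds raw indicator magnitudes as a years-by-indicators
#' matrix: one row per year (strictly increasing, no duplicates), one column
#' per registry indicator, all values strictly positive (ratio normalization
#' is undefined otherwise). A normalized panel has the same shape with
#' dimensionless values in (0, 1].
#'
#' @param years Integer vector of years, strictly increasing.
#' @param values Numeric matrix, `length(years)` rows.
#' @param normalized Logical; mark the panel as already dimensionless.
#' @return An object of class `indicator_panel` (additionally
#'   `normalized_panel` when `normalized = TRUE`): the values matrix with
#'   years as row names and indicator ids as column names.
#' @export
indicator_panel <- function(years, values, normalized = FALSE) {
  years <- as.integer(years)
  values <- as.matrix(values)
  if (anyNA(years) || is.unsorted(years, strictly = TRUE)) {
    les_stop_schema("years must be strictly increasing with no duplicates")
  }
  if (nrow(values) != length(years)) {
    les_stop_schema("values must have one row per year")
  }
  if (anyNA(values) || !is.numeric(values)) {
    les_stop_value("panel values must be numeric and non-missing")
  }
  if (any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    les_stop_value(sprintf(
      "non-positive value at year %d, indicator %s",
      years[bad[["row"]]], colnames(values)[bad[["col"]]]),
      row = bad[["row"]], col = bad[["col"]])
  }
  if (normalized && any(values > 1 + 1e-12)) {
    les_stop_value("normalized panel values must lie in (0, 1]")
  }
  rownames(values) <- years
  class(values) <- c(if (normalized) "normalized_panel", "indicator_panel",
                     class(values))
  values
}

panel_years <- function(panel) as.integer(rownames(panel))

#' Read an indicator panel from CSV
#'
#' The CSV must have a `year` column plus exactly one column per registry
#' indicator id (any order; columns are reordered to registry order).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal, header row).
#' @param registry An [indicator_registry()]; defaults to the 17-indicator
#'   land ecological security registry.
#' @param interpolate If `TRUE`, interior missing cells are filled by linear
#'   interpolation between the neighboring years (statistical yearbooks have
#'   gaps); by default missing cells are an error.
#' @param normalized Read as an already-normalized panel.
#' @return An [indicator_panel()].
#' @export
read_panel <- function(path, registry = default_registry(),
                       interpolate = FALSE, normalized = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"year" %in% names(df)) {
    les_stop_schema(sprintf("panel CSV '%s' has no 'year' column", path))
  }
  missing <- setdiff(registry$id, names(df))
  if (length(missing)) {
    les_stop_schema(sprintf("panel CSV is missing indicator column(s): %s",
                            paste(missing, collapse = ", ")),
                    missing = missing)
  }
  unknown <- setdiff(names(df), c("year", registry$id))
  if (length(unknown)) {
    les_stop_schema(sprintf("panel CSV has unknown column(s): %s",
                            paste(unknown, collapse = ", ")),
                    unknown = unknown)
  }
  if (anyDuplicated(df$year)) {
    les_stop_schema(sprintf("duplicate year(s): %s",
                            paste(unique(df$year[duplicated(df$year)]),
                                  collapse = ", ")))
  }
  df <- df[order(df$year), , drop = FALSE]
  vals <- as.matrix(df[registry$id])
  if (!is.numeric(vals)) {
    les_stop_value("panel CSV contains non-numeric cells")
  }
  if (anyNA(vals)) {
    if (interpolate) {
      vals <- apply(vals, 2L, function(col) {
        if (anyNA(col[c(1L, length(col))])) {
          les_stop_value("cannot interpolate missing values at the panel edges")
        }
        if (anyNA(col)) {
          col <- stats::approx(df$year[!is.na(col)], col[!is.na(col)],
                               xout = df$year)$y
        }
        col
      })
    } else {
      bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      les_stop_value(sprintf("missing value at year %d, indicator %s",
                             df$year[bad[["row"]]],
                             registry$id[bad[["col"]]]))
    }
  }
  indicator_panel(df$year, vals, normalized = normalized)
}

#' Write an indicator panel to CSV
#'
#' @param panel An [indicator_panel()].
#' @param path Output CSV path.
#' @param digits Decimal places written (default 4, the conventional
#'   reporting precision for normalized panels); use `NA` for full precision.
#' @export
write_panel <- function(panel, path, digits = 4) {
  vals <- unclass(panel)
  if (!is.na(digits)) vals <- round(vals, digits)
  df <- data.frame(year = panel_years(panel), vals, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.indicator_panel <- function(x, ...) {
  yrs <- panel_years(x)
  cat(sprintf("<%s> %d years (%d-%d) x %d indicators\n",
              if (inherits(x, "normalized_panel")) "normalized_panel"
              else "indicator_panel",
              nrow(x), yrs[1L], yrs[length(yrs)], ncol(x)))
  print(round(unclass(x), 4), ...)
  invisible(x)
}
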