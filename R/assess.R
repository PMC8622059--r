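#' Pipeline configuration
#'
#' Bundles every tunable of the evaluation pipeline: normalization modes,
#' assessment set (levels, anchors, level scores), where the weights come
#' from, the reporting score mode, and the scalar classification
#' thresholds.
#'
#' Score modes: `"scalar"` (default) reports the weighted sum of normalized
#' values - the form in which published comprehensive security values are
#' printed - with levels cut at `scalar_thresholds`; `"fuzzy"` reports
#' triangular-membership synthesis per group with max-membership levels.
#' In both modes the comprehensive value is exactly the sum of the three
#' group values.
#'
#' Default scalar thresholds (S >= 0.75 > RS >= 0.60 > RU >= 0.45 > U)
#' classify the published 0.297-0.347 range as "U" (unsafe), matching the
#' study's uniform level labels; the actual cutoffs used there are not
#' disclosed, so they are configuration.
#'
#' @param normalization A [normalization_config()].
#' @param assessment An [assessment_set()].
#' @param weights_source `"fixture_table2"` or `"ahp_from_matrices"`.
#' @param score_mode `"scalar"` or `"fuzzy"`.
#' @param scalar_thresholds Named strictly decreasing cutoffs, one per
#'   level except the least safe.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(normalization = normalization_config(),
                            assessment = assessment_set(),
                            weights_source = c("fixture_table2",
                                               "ahp_from_matrices"),
                            score_mode = c("scalar", "fuzzy"),
                            scalar_thresholds = c(S = 0.75, RS = 0.60,
                                                  RU = 0.45)) {
  weights_source <- match.arg(weights_source)
  score_mode <- match.arg(score_mode)
  if (length(scalar_thresholds) != length(assessment$levels) - 1L ||
      any(diff(scalar_thresholds) >= 0)) {
    les_stop_value(
      "scalar_thresholds must be strictly decreasing, one per level but the last")
  }
  structure(list(normalization = normalization, assessment = assessment,
                 weights_source = weights_source, score_mode = score_mode,
                 scalar_thresholds = scalar_thresholds),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(
    normalization = unclass(config$normalization),
    assessment = unclass(config$assessment),
    weights_source = config$weights_source,
    score_mode = config$score_mode,
    scalar_thresholds = as.list(config$scalar_thresholds)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    normalization = do.call(normalization_config, y$normalization),
    assessment = assessment_set(unlist(y$assessment$levels),
                                unlist(y$assessment$anchors),
                                unlist(y$assessment$level_scores)),
    weights_source = y$weights_source,
    score_mode = y$score_mode,
    scalar_thresholds = unlist(y$scalar_thresholds))
}

# scalar-mode level: safest level whose threshold the value meets
classify_scalar <- function(value, thresholds, set) {
  safe_order <- order(set$anchors, decreasing = TRUE)
  lev <- set$levels[safe_order]
  for (l in lev[-length(lev)]) {
    if (value >= thresholds[[l]]) return(l)
  }
  lev[length(lev)]
}

#' Evaluate one year of normalized indicators
#'
#' Scalar mode: the group value of g is `sum(w[i] * x[i], i in g)` using the
#' global weights directly (not renormalized within group), so the
#' comprehensive value `sum(w * x)` is exactly the sum of the group values.
#' Fuzzy mode: each group's membership matrix is synthesized with its
#' within-group renormalized weights, group memberships are combined with
#' the groups' weight mass, and the group value is that mass times the
#' group's scalar score - additivity again holds exactly.
#'
#' @param normalized_row Named 17-vector (or registry-length vector) of
#'   normalized values in [0, 1], names matching registry ids.
#' @param global_weights A [weight_vector()] labelled by registry ids.
#' @param registry An [indicator_registry()].
#' @param config A [pipeline_config()].
#' @param year Optional year tag carried into the result.
#' @return A list of class `evaluation_result`: `year`, `group_values`,
#'   `comprehensive_value`, `membership` (comprehensive and per group),
#'   `level`.
#' @export
evaluate_year <- function(normalized_row, global_weights,
                          registry = default_registry(),
                          config = pipeline_config(), year = NA_integer_) {
  normalized_row <- drop(normalized_row)
  if (!identical(names(normalized_row), registry$id) ||
      !identical(names(global_weights), registry$id)) {
    les_stop_schema("row and weight labels must match the registry ids")
  }
  set <- config$assessment
  groups <- registry_groups(registry)
  w <- as.numeric(global_weights)
  x <- as.numeric(normalized_row)
  names(w) <- names(x) <- registry$id

  group_values <- numeric(0)
  group_membership <- list()
  if (config$score_mode == "scalar") {
    for (g in groups) {
      ids <- registry_group_ids(registry, g)
      mass <- sum(w[ids])
      group_values[g] <- sum(w[ids] * x[ids])
      # membership of the group's weighted mean value, for reporting;
      # a zero-mass group has no defined mean -> maximal-ignorance uniform
      group_membership[[g]] <- if (mass > 0) {
        triangular_membership(group_values[g] / mass, set)
      } else {
        stats::setNames(rep(1 / length(set$levels), length(set$levels)),
                        set$levels)
      }
    }
    comprehensive <- sum(group_values)
    membership <- triangular_membership(comprehensive, set)
    level <- classify_scalar(comprehensive, config$scalar_thresholds, set)
  } else {
    comp_membership <- stats::setNames(numeric(length(set$levels)),
                                       set$levels)
    for (g in groups) {
      ids <- registry_group_ids(registry, g)
      mass <- sum(w[ids])
      if (mass == 0) {  # degenerate zero-mass group contributes nothing
        group_values[g] <- 0
        group_membership[[g]] <- stats::setNames(
          rep(1 / length(set$levels), length(set$levels)), set$levels)
        next
      }
      local <- weight_vector(w[ids] / mass)
      r_g <- build_membership_matrix(x[ids], set)
      syn <- synthesize(local, r_g, set)
      group_membership[[g]] <- syn$membership
      group_values[g] <- mass * syn$scalar_score
      comp_membership <- comp_membership + mass * syn$membership
    }
    comprehensive <- sum(group_values)
    membership <- comp_membership
    level <- classify(membership, set)
  }
  stopifnot(near(comprehensive, sum(group_values)),
            near(sum(membership), 1))
  structure(list(year = as.integer(year), group_values = group_values,
                 comprehensive_value = comprehensive,
                 membership = list(comprehensive = membership,
                                   groups = group_membership),
                 level = level),
            class = "evaluation_result")
}

#' Evaluate a normalized panel year by year
#'
#' @param panel A `normalized_panel`.
#' @param global_weights A [weight_vector()] over the registry ids; default
#'   the shipped published weight table, renormalized
#'   (see [fixture_weights()]).
#' @param registry An [indicator_registry()].
#' @param config A [pipeline_config()].
#' @return A data frame of class `les_results` with columns `year`, one per
#'   group, `comprehensive`, `level`, ordered by year; the full
#'   `evaluation_result` objects are in attribute `"evaluations"`.
#' @export
#' @examples
#' res <- evaluate_panel(load_fixture("table1_normalized"))
#' res[res$year %in% c(2004, 2017), ]
evaluate_panel <- function(panel, global_weights = fixture_weights(),
                           registry = default_registry(),
                           config = pipeline_config()) {
  years <- panel_years(panel)
  evals <- lapply(seq_along(years), function(i) {
    evaluate_year(panel[i, ], global_weights, registry, config,
                  year = years[i])
  })
  groups <- registry_groups(registry)
  df <- data.frame(year = years,
                   sapply(groups, function(g)
                     vapply(evals, function(e) e$group_values[[g]], 0)),
                   comprehensive = vapply(evals, `[[`, 0,
                                          "comprehensive_value"),
                   level = vapply(evals, `[[`, "", "level"),
                   check.names = FALSE)
  attr(df, "evaluations") <- evals
  class(df) <- c("les_results", "data.frame")
  df
}

#' Write / read evaluation results
#'
#' The results CSV mirrors the published layout: year, comprehensive value,
#' the three group values, and the level label, values rounded to 4
#' decimals.
#'
#' @param results A `les_results` data frame (or list of
#'   `evaluation_result`).
#' @param path CSV path.
#' @return `read_results` returns a `les_results` data frame.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "les_results")) {
    df <- as.data.frame(results)
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, TRUE, "evaluation_result"))) {
    df <- data.frame(
      year = vapply(results, `[[`, 0L, "year"),
      t(vapply(results, `[[`, results[[1L]]$group_values, "group_values")),
      comprehensive = vapply(results, `[[`, 0, "comprehensive_value"),
      level = vapply(results, `[[`, "", "level"), check.names = FALSE)
  } else {
    les_stop_value("results must be non-empty evaluation results")
  }
  if (nrow(df) == 0L) les_stop_value("results must be non-empty")
  if (anyDuplicated(df$year)) les_stop_schema("duplicate years in results")
  num <- vapply(df, is.numeric, TRUE) & names(df) != "year"
  df[num] <- lapply(df[num], round, 4)
  df <- df[c("year", "comprehensive",
             setdiff(names(df), c("year", "comprehensive", "level")),
             "level")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("year", "comprehensive", "level")
  if (!all(needed %in% names(df))) {
    les_stop_schema(sprintf("results CSV must have columns: %s",
                            paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(df$year)) les_stop_schema("duplicate years in results")
  df <- df[order(df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("les_results", "data.frame")
  df
}

#' Land-use structural change report
#'
#' Signed percent change of each category between two years, sorted by
#' magnitude. Because [percent_change()] is scale invariant the report is
#' identical on raw and ratio-to-max-normalized panels.
#'
#' @param panel An [indicator_panel()] (raw or normalized).
#' @param categories Indicator ids to report on.
#' @param year_a,year_b Base and comparison years.
#' @return A data frame `id`, `percent_change`, sorted by `|change|`
#'   descending.
#' @export
#' @examples
#' land_use_change_report(load_fixture("table1_normalized"),
#'                        c("S21", "S22", "S12", "S15", "S16"), 2004, 2017)
land_use_change_report <- function(panel, categories, year_a, year_b) {
  absent <- setdiff(categories, colnames(panel))
  if (length(absent)) {
    les_stop_lookup(sprintf("unknown categor%s: %s",
                            if (length(absent) > 1) "ies" else "y",
                            paste(absent, collapse = ", ")))
  }
  pc <- vapply(categories, function(id)
    percent_change(panel[, id], year_a, year_b), 0)
  out <- data.frame(id = categories, percent_change = pc,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-abs(out$percent_change)), , drop = FALSE]
}

#' Trend summary of evaluation results
#'
#' For the comprehensive series and each group series: year-over-year
#' deltas, the peak (argmax) year, a decomposition into maximal monotone
#' segments (rising / flat / falling runs), and a flag for series whose
#' value falls after their peak - the signature of a dimension that has
#' started to restrain overall security.
#'
#' @param results A `les_results` data frame with at least two years.
#' @return A list of class `les_trend`, one entry per series.
#' @export
trend_report <- function(results) {
  if (nrow(results) < 2L) {
    les_stop_value("trend analysis needs at least two years")
  }
  series_names <- setdiff(names(results), c("year", "level"))
  years <- results$year
  out <- lapply(stats::setNames(nm = series_names), function(s) {
    v <- results[[s]]
    d <- diff(v)
    peak_i <- which.max(v)
    runs <- rle(sign(d))
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    segments <- data.frame(
      start_year = years[starts], end_year = years[ends + 1L],
      direction = c("falling", "flat", "rising")[runs$values + 2L],
      stringsAsFactors = FALSE)
    list(series = s,
         deltas = stats::setNames(d, years[-1L]),
         peak_year = years[peak_i], peak_value = v[peak_i],
         segments = segments,
         falls_after_peak = peak_i < length(v) && any(d[peak_i:length(d)] < 0))
  })
  structure(out, class = "les_trend")
}

#' @export
print.les_trend <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%s: peak %.4f in %d, %d segment(s)%s\n",
                s$series, s$peak_value, s$peak_year, nrow(s$segments),
                if (s$falls_after_peak) " [falls after peak]" else ""))
  }
  invisible(x)
}
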