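#' Indicator registries
#'
#' An indicator registry describes the evaluation factor set: one row per
#' sub-factor with its short id, human-readable name, measurement unit,
#' polarity, and parent group. Polarity `"positive"` marks large-value
#' indicators (the maximum over the study period is optimal, e.g. forest
#' area); `"negative"` marks small-value indicators (the minimum is optimal,
#' e.g. wastewater discharge).
#'
#' @param id Character vector of unique short codes (e.g. `"S21"`).
#' @param name Character vector of indicator names.
#' @param unit Character vector of measurement units.
#' @param polarity Character vector, each `"positive"` or `"negative"`.
#' @param group Character vector of parent group ids (`"S1"`, `"S2"`, `"S3"`).
#' @param group_labels Named character vector mapping group ids to names.
#' @return A data frame of class `indicator_registry`.
#' @seealso [default_registry()]
#' @export
indicator_registry <- function(id, name, unit, polarity, group,
                               group_labels = NULL) {
  if (anyDuplicated(id)) {
    les_stop_schema(sprintf("duplicate indicator id(s): %s",
                            paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (!all(polarity %in% c("positive", "negative")) || anyNA(polarity)) {
    les_stop_value("every indicator needs polarity 'positive' or 'negative'")
  }
  if (!all(group %in% c("S1", "S2", "S3"))) {
    les_stop_value("group must be one of 'S1', 'S2', 'S3'")
  }
  reg <- data.frame(id = as.character(id), name = as.character(name),
                    unit = as.character(unit), polarity = as.character(polarity),
                    group = as.character(group), stringsAsFactors = FALSE)
  if (is.null(group_labels)) {
    group_labels <- stats::setNames(unique(reg$group), unique(reg$group))
  }
  attr(reg, "group_labels") <- group_labels
  class(reg) <- c("indicator_registry", "data.frame")
  reg
}

#' The default 17-indicator land ecological security registry
#'
#' Three main factors: S1, sustainable development of resources and the
#' environment (6 sub-factors); S2, economic sustainable development
#' (6 sub-factors); S3, social sustainable development (5 sub-factors).
#' Polarities follow the security-trend orientation of each indicator:
#' e.g. growing construction land (S21) erodes security (negative), a larger
#' forest area (S14) improves it (positive).
#'
#' @return An [indicator_registry()] with 17 rows.
#' @export
#' @examples
#' reg <- default_registry()
#' table(reg$group)
default_registry <- function() {
  indicator_registry(
    id = c("S11", "S12", "S13", "S14", "S15", "S16",
           "S21", "S22", "S23", "S24", "S25", "S26",
           "S31", "S32", "S33", "S34", "S35"),
    name = c("Area of agricultural land", "Area of cultivated land",
             "Area of orchard", "Area of forest", "Area of pastureland",
             "Area of land for other agricultural use",
             "Construction land",
             "Residential site and independent mining land",
             "Land for transportation", "Land for irrigation facility",
             "Total investment in environmental pollution abatement",
             "Waste water discharge",
             "National territorial land area", "Per capita GDP",
             "Urbanization rate", "Food supply per capita",
             "Natural population growth rate"),
    unit = c(rep("thousand hectares", 6),
             rep("thousand hectares", 4), "hundred million yuan",
             "hundred million ton",
             "ten thousand hectares", "yuan", "%", "kg/person", "%"),
    polarity = c("negative", "negative", "positive", "positive", "positive",
                 "negative",
                 "negative", "negative", "positive", "positive", "positive",
                 "negative",
                 "positive", "positive", "positive", "positive", "negative"),
    group = c(rep("S1", 6), rep("S2", 6), rep("S3", 5)),
    group_labels = c(
      S1 = "Sustainable development of resources and environment",
      S2 = "Economic sustainable development",
      S3 = "Social sustainable development")
  )
}

#' @export
print.indicator_registry <- function(x, ...) {
  cat(sprintf("<indicator_registry> %d indicators in %d groups\n",
              nrow(x), length(unique(x$group))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# ids belonging to one group, in registry order
registry_group_ids <- function(registry, group) {
  registry$id[registry$group == group]
}

registry_groups <- function(registry) unique(registry$group)
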