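#' Load a shipped reference fixture
#'
#' Three small reference tables from the published China 2004-2017 study are
#' shipped with the package, stored exactly at their 4-decimal printed
#' precision (they are never re-derived at build time):
#'
#' * `"table1_normalized"` - the normalized 14-year x 17-indicator panel,
#'   returned as a `normalized_panel`.
#' * `"table2_weights"` - the AHP sub-factor weight table (id, group,
#'   polarity, weight, rank), with the three main-factor weights
#'   (S1 = 0.3341, S2 = 0.3780, S3 = 0.2879) in attribute `"main_weights"`.
#' * `"table3_results"` - the published per-year group and comprehensive
#'   security values with their level labels, as read by [read_results()].
#'
#' Note the published weight table is internally tense: the per-group
#' sub-weight sums are each 0.3333 while the main-factor weights are
#' 0.3341/0.3780/0.2879. Both are stored verbatim; no consistency is forced.
#'
#' @param name One of `"table1_normalized"`, `"table2_weights"`,
#'   `"table3_results"`.
#' @return See above.
#' @export
#' @examples
#' w <- load_fixture("table2_weights")
#' w$weight[w$id == "S31"]    # 0.1836
load_fixture <- function(name) {
  known <- c("table1_normalized", "table2_weights", "table3_results")
  if (length(name) != 1L || !name %in% known) {
    les_stop_lookup(sprintf("unknown fixture '%s'; expected one of: %s",
                            paste(name, collapse = ", "),
                            paste(known, collapse = ", ")))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "landsec",
                      mustWork = TRUE)
  switch(name,
    table1_normalized = read_panel(path, normalized = TRUE),
    table2_weights = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      main <- df[!duplicated(df$group), c("group", "main_weight")]
      attr(df, "main_weights") <- stats::setNames(main$main_weight, main$group)
      df
    },
    table3_results = read_results(path)
  )
}

#' Table 2 weights as a weight vector
#'
#' Convenience accessor: the 17 printed sub-factor weights in registry order
#' as a [weight_vector()]. The printed values sum to 0.9999 (4-decimal
#' rounding); `renormalize = TRUE` (default) rescales them to sum exactly
#' to 1, `FALSE` returns them verbatim (then the sum-to-1 check is relaxed
#' to the printed rounding tolerance).
#'
#' @param renormalize Logical.
#' @return A [weight_vector()] of length 17.
#' @export
fixture_weights <- function(renormalize = TRUE) {
  df <- load_fixture("table2_weights")
  w <- stats::setNames(df$weight, df$id)
  if (renormalize) w <- w / sum(w)
  weight_vector(w, tol = if (renormalize) 1e-9 else 5e-4)
}
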