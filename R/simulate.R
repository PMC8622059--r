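#' Synthetic panel specification
#'
#' Describes a ground-truth generating process for a raw indicator panel:
#' per indicator an initial level (in the indicator's unit), a signed
#' annual compound growth rate, and a log-scale noise sd. Values follow
#' `value(t) = initial * (1 + growth)^t * exp(eps_t)`,
#' `eps_t ~ N(0, sd^2)`, `t = 0, 1, ...` - multiplicative log-normal noise
#' keeps every value positive, so ratio normalization is always defined.
#'
#' @param years Integer years (at least two).
#' @param indicators Data frame with columns `id`, `initial`, `growth`,
#'   `sd`.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(years, indicators, seed = 1L) {
  if (length(years) < 2L) les_stop_value("need at least two years")
  if (!all(c("id", "initial", "growth", "sd") %in% names(indicators))) {
    les_stop_schema("indicators needs columns id, initial, growth, sd")
  }
  if (any(indicators$initial <= 0)) les_stop_value("initial levels must be > 0")
  if (any(indicators$sd < 0)) les_stop_value("noise sd must be >= 0")
  if (any(indicators$growth <= -1)) les_stop_value("growth must exceed -1")
  structure(list(years = as.integer(years), indicators = indicators,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Default study-like panel specification
#'
#' A 14-year (2004-2017) specification for the 17-indicator registry whose
#' trend directions emulate the published China panel: construction and
#' mining land growing fastest among land uses, pastureland and other
#' agricultural land declining, a constant national territory area (growth
#' and noise both 0), rapid growth in per capita GDP and pollution-abatement
#' investment. Magnitudes are order-of-magnitude realistic for the units
#' involved; noise is a ~1% (log-scale) multiplicative wobble except where
#' the underlying series is administratively fixed (S31) or volatile
#' (orchard area, abatement investment).
#'
#' @param seed Integer seed.
#' @return A [panel_spec()].
#' @export
default_panel_spec <- function(seed = 1L) {
  ind <- data.frame(
    id = c("S11", "S12", "S13", "S14", "S15", "S16",
           "S21", "S22", "S23", "S24", "S25", "S26",
           "S31", "S32", "S33", "S34", "S35"),
    initial = c(657000, 130000, 11500, 236000, 262000, 25500,
                26000, 16000, 2300, 3500, 1910, 482,
                96000, 12400, 41.8, 362, 5.87),
    growth = c(-0.002, 0.0075, 0.005, 0.006, -0.0138, -0.006,
               0.0175, 0.0172, 0.042, 0.001, 0.132, 0.030,
               0, 0.127, 0.026, 0.016, -0.007),
    sd = c(0.002, 0.003, 0.02, 0.002, 0.003, 0.003,
           0.002, 0.002, 0.005, 0.003, 0.05, 0.02,
           0, 0.01, 0.003, 0.005, 0.02),
    stringsAsFactors = FALSE)
  panel_spec(2004:2017, ind, seed = seed)
}

#' Generate a raw indicator panel from a specification
#'
#' Deterministic given the spec's seed; an indicator with growth 0 and
#' sd 0 is exactly constant (and normalizes to all ones).
#'
#' @param spec A [panel_spec()].
#' @param registry An [indicator_registry()]; the spec must cover exactly
#'   its ids.
#' @return An [indicator_panel()].
#' @export
generate_panel <- function(spec, registry = default_registry()) {
  if (!setequal(spec$indicators$id, registry$id)) {
    les_stop_schema("panel spec ids must match the registry ids")
  }
  ind <- spec$indicators[match(registry$id, spec$indicators$id), ]
  t <- seq_along(spec$years) - 1L
  vals <- with_seed(spec$seed, {
    sapply(seq_len(nrow(ind)), function(j) {
      eps <- if (ind$sd[j] > 0) stats::rnorm(length(t), sd = ind$sd[j])
             else numeric(length(t))
      ind$initial[j] * (1 + ind$growth[j])^t * exp(eps)
    })
  })
  colnames(vals) <- registry$id
  indicator_panel(spec$years, vals)
}

#' Generate a perturbed judgment matrix with known ground truth
#'
#' Thin wrapper over [judgment_from_weights()], kept as the synthetic-data
#' entry point for weight-recovery experiments.
#'
#' @inheritParams judgment_from_weights
#' @return A [judgment_matrix()].
#' @export
generate_judgments <- function(weights, perturbation = 0, seed = 1L) {
  judgment_from_weights(weights, perturbation = perturbation, seed = seed)
}

#' Generate a complete study-like input bundle
#'
#' One call produces everything the pipeline needs, shaped like the
#' published study: a 14-year x 17-indicator raw panel with the published
#' trend directions (non-agricultural growth outpacing agricultural
#' decline), perfectly consistent judgment matrices reconstructed from the
#' published weight table (top-level 3 x 3 from the main-factor weights,
#' one per group from the within-group renormalized sub-weights), and a
#' default [pipeline_config()].
#'
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param perturbation Log-scale noise applied to the judgment matrices
#'   (0 = perfectly consistent).
#' @return A list with `panel`, `judgments` (list: `top`, `S1`, `S2`,
#'   `S3`), and `config`.
#' @export
#' @examples
#' b <- generate_study_like_bundle(seed = 7)
#' w <- hierarchical_weights(b$judgments$top, b$judgments[c("S1","S2","S3")])
#' res <- evaluate_panel(normalize_panel(b$panel), w$global)
generate_study_like_bundle <- function(seed = 1L, perturbation = 0) {
  registry <- default_registry()
  tab2 <- load_fixture("table2_weights")
  main <- attr(tab2, "main_weights")
  judgments <- list(
    top = judgment_from_weights(weight_vector(main / sum(main)),
                                perturbation, seed = seed))
  for (g in registry_groups(registry)) {
    wg <- tab2$weight[tab2$group == g]
    judgments[[g]] <- judgment_from_weights(
      weight_vector(stats::setNames(wg / sum(wg), tab2$id[tab2$group == g])),
      perturbation, seed = seed + match(g, registry_groups(registry)))
  }
  list(panel = generate_panel(default_panel_spec(seed = seed), registry),
       judgments = judgments,
       config = pipeline_config())
}
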