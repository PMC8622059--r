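---
title: "Methods: AHP-FCE evaluation of land ecological security"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AHP-FCE evaluation of land ecological security}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsec)
```

## The model

Land ecological security is scored as a weighted composite over a
three-level hierarchy. The factor set

$$S = \{S_1, S_2, S_3\}$$

splits into 17 sub-factors: six resource-and-environment indicators
($S_{11}$-$S_{16}$: agricultural, cultivated, orchard, forest, pasture,
other agricultural land), six economic indicators ($S_{21}$-$S_{26}$:
construction land, residential/mining land, transportation and irrigation
land, pollution-abatement investment, wastewater discharge), and five
social indicators ($S_{31}$-$S_{35}$: territory area, per-capita GDP,
urbanization rate, per-capita food supply, natural population growth
rate). Each indicator carries a polarity: for *large-value* (positive)
indicators the maximum over the study window is optimal; for
*small-value* (negative) indicators the minimum is.

The pipeline has four stages, each an exported function family:

1. **Normalization** (`normalize_panel`). Linear dimensionless scaling
   into $(0, 1]$, column by column.
2. **Weighting** (`hierarchical_weights`). AHP: pairwise judgment
   matrices on the Saaty 1-9 scale, principal-eigenvector weights,
   CI/CR consistency control, and product-rule aggregation of the
   top-level and within-group weights into 17 global weights summing
   to 1.
3. **Fuzzy mapping** (`build_membership_matrix`). Triangular membership
   degrees of each normalized value against a 4-level assessment set
   $V = \{S, RS, RU, U\}$ (safe, relatively safe, relatively unsafe,
   unsafe).
4. **Synthesis** (`synthesize`, `evaluate_year`). The weighted-average
   operator $X = W R$ (ordinary matrix-vector product, *not* max-min
   composition), scalar collapse against level scores, and per-year
   group plus comprehensive values.

## Normalization: why ratio-to-max on both polarities

For a positive indicator the scaling is forced: $x_t / \max_t x_t$. For
negative indicators two conventions exist, and the package implements
both:

* `ratio_to_max` — also $x / \max(x)$, preserving year ordering;
* `inverse_min_over_x` — $\min(x) / x$, flipping orientation so the
  optimal (minimum) year scores 1.

`ratio_to_max` is the default because it is what the shipped reference
panel demonstrably uses: the printed normalized columns of the declared
small-value indicators reproduce the independently printed land-use
percentage changes (e.g. construction land $1.0000 / 0.7987 - 1 =
+25.20\%$) only under $x/\max$. The verbal definition of small-value
indicators suggests the flipped orientation, so it is offered behind the
`negative_mode` config key, but evidence beats prose for the default.
Two consequences are load-bearing and tested as properties: ratio
normalization is scale invariant and idempotent, and `percent_change` is
identical on raw and ratio-normalized series. No min-max (range)
normalization is offered — no printed value supports it. Non-positive
raw values are an error, never shifted: ratio normalization would be
meaningless, and the one indicator that could in principle go negative
(natural population growth rate) never does in the panels emulated here.

## AHP: extraction, consistency, reconstruction

`principal_eigen` uses power iteration from the uniform vector,
normalizing to sum 1 each step, with `tol = 1e-12` on the sup-norm
change and `max_iter = 10000`; $\lambda_{\max}$ is the mean componentwise
Rayleigh ratio at convergence. For positive matrices the iteration is
globally convergent; non-convergence raises a numeric error carrying the
residual rather than returning silently. A geometric-mean-of-rows
extractor (`method = "geometric"`) is available because the literature
rarely states which variant was used; both agree exactly on consistent
matrices, and a dense `eigen()` decomposition serves as an independent
oracle in the test suite (agreement to 1e-8 on all orders up to 10).

Consistency uses $CI = (\lambda_{\max} - n)/(n - 1)$ and
$CR = CI / RI(n)$ with Saaty's random-index table
$RI(1..10) = 0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49$;
orders above 10 require the caller to supply an extended table. The
acceptance bound $CR < 0.1$ is the conventional one. Orders $n \le 2$
are consistent by definition ($CI = CR = 0$).

The expert-elicited judgment matrices behind the reference weight table
were never published; what is published is the weight table itself. The
package therefore reconstructs perfectly consistent matrices as ratio
matrices $a_{ij} = w_i / w_j$ (`judgment_from_weights`), which have
$\lambda_{\max} = n$ and $CR = 0$ exactly — matching the reported zero
consistency coefficient — and whose principal eigenvector recovers the
generating weights to machine precision. With `perturbation` $> 0$ the
same constructor multiplies antisymmetric log-normal noise onto the
upper triangle (reciprocity always exact), which is the ground-truth
mechanism for the weight-recovery experiments: recovery error is 0 at
zero perturbation and grows statistically with it. Reconstructed
matrices may leave the $[1/9, 9]$ scale (the most extreme published
weight ratio is $0.1233/0.0090 \approx 13.7$); that is a warning, not an
error, since the scale bound applies to elicited judgments, not derived
ratios.

A caveat the tests encode: the published weight table is internally
tense — its per-group sub-weight sums are each 0.3333 while its
main-factor weights are 0.3341/0.3780/0.2879. Composing main and
renormalized local weights therefore preserves each group's internal
rank order and the global extremes (territory area first, wastewater
discharge last) but *not* the full printed global ranking. Both printed
sets are stored verbatim in the fixture; no consistency is forced.

## Fuzzy evaluation: anchors, boundaries, ties

The assessment set pairs each level with an anchor on the normalized
scale. The reference study derived its memberships from an undisclosed
Delphi elicitation, so anchors are required, documented configuration,
not constants. The default is equally spaced anchors
$(1.0, 0.75, 0.5, 0.25)$ for $(S, RS, RU, U)$: with values living in
$(0, 1]$ and 1 meaning "best observed", equal spacing is the natural
uninformative choice. Membership of $x$ in an interior level with anchor
$r_i$ and neighbors $(r_{\min}, r_{\max})$ rises as
$(x - r_{\min})/(r_i - r_{\min})$, falls as
$(r_{\max} - x)/(r_{\max} - r_i)$, and is 0 outside. Terminal levels use
half-triangles clamped at the scale ends, so $x = 1$ is fully safe and
any $x$ at or below the lowest anchor is fully unsafe; every vector is
renormalized to sum 1 (for interior $x$ adjacent triangles already sum
to 1, so this only matters at the clamps). The Delphi vote route is also
implemented (`membership_from_votes`: row proportions of a vote-count
matrix) for when expert votes exist.

Scalar collapse uses level scores defaulting to the anchors themselves.
Classification follows maximum membership with ties broken toward the
level with the *lower* anchor — conservative for a security assessment —
and is orientation-independent (safety is defined by anchor value, not
declaration order).

## Scalar vs. fuzzy reporting, and what is verifiable

`evaluate_year` supports both modes; both make the comprehensive value
the exact sum of the three group values, because group values are built
from global weights directly (scalar: $\sum_{i \in g} w_i x_i$; fuzzy:
group weight mass times the group's synthesized scalar score). That
additivity is deliberately the *only* contract checked against the
published per-year results: the published component magnitudes
(0.10-0.12 per group) are not reproducible as any weighted combination
of the published normalized panel and weight table — recomputing with
this package's defaults gives comprehensive values of 0.83-0.98 —
because the anchors and level scores actually used were never printed.
The printed rows do, however, sum exactly, and the reference series'
qualitative structure (comprehensive value rising through 2016; the
resources-and-environment component peaking in 2009 and declining after)
is reproduced by `trend_report` on the shipped results fixture.

Scalar-mode level thresholds default to
$S \ge 0.75 > RS \ge 0.60 > RU \ge 0.45 > U$, chosen so the published
0.297-0.347 range classifies as unsafe, consistent with the uniformly
"U" published labels; they are configuration because the study never
prints its cutoffs.

## The synthetic-data generator

`generate_panel` draws
$x_t = x_0 (1+g)^t e^{\varepsilon_t}$, $\varepsilon_t \sim N(0,
\sigma^2)$, per indicator. Noise is multiplicative log-normal so
positivity — a precondition of ratio normalization — holds by
construction. The default specification (`default_panel_spec`) encodes a
14-year, 17-indicator panel with the reference study's qualitative trend
directions: construction and mining land growing ~1.7%/yr (+25% over the
span), cultivated land +0.75%/yr, pastureland −1.4%/yr, other
agricultural land −0.6%/yr, a constant territory area (growth and noise
exactly 0), fast-growing per-capita GDP (+12.7%/yr) and abatement
investment (+13%/yr). Initial levels are order-of-magnitude realistic in
each indicator's unit (e.g. 26,000 thousand hectares of construction
land, 96,000 ten-thousand hectares of territory); noise defaults to a
~1% log-scale wobble, larger for historically volatile series (orchard
area, abatement investment). Magnitudes are parameters, not claims: a
green end-to-end test establishes that the pipeline's algebraic
contracts hold on data *shaped like* the study panel, not that the
generator reproduces China's yearbooks. Cross-indicator correlation and
spatial structure are deliberately not modeled.

All randomness flows through one integer seed; the global RNG state is
saved and restored, and the same seed reproduces panels, judgment
matrices, and bundles bit-identically.

## Numerical choices and degenerate inputs

* Power iteration: `tol = 1e-12`, `max_iter = 10000`; CR reported to
  full precision, 1e-9 used as the "exactly consistent" band in tests.
* Weight vectors must sum to 1 within 1e-9; the shipped printed weights
  sum to 0.9999 and are renormalized by default (`fixture_weights`).
* Ties at a column maximum all map to 1 (no jitter); ties in
  classification go to the less safe level.
* Fixtures store the printed 4-decimal values verbatim and are never
  re-derived (anti-drift); computation is full precision, printing is
  4 decimals.
* A group with zero total weight mass has no defined weighted-mean
  value; it contributes 0 to the comprehensive value and reports a
  uniform membership vector.
* Missing panel cells are rejected by default; interior gaps can be
  linearly interpolated behind `read_panel(..., interpolate = TRUE)`,
  mirroring how yearbook gaps are filled in practice. Edge gaps are
  always an error.

## Known limitations

* The published per-year component magnitudes cannot be independently
  verified (see above); anyone re-scoring real data should treat
  anchors, level scores, and thresholds as elicitation inputs.
* The RI table covers orders up to 10; larger judgment matrices need a
  user-supplied table.
* No group-AHP fusion of multiple experts, no fuzzy-interval AHP, no
  incomplete-matrix completion beyond reciprocal auto-fill, and no
  spatial disaggregation or forecasting.
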