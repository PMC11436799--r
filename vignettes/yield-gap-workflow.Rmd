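---
title: "Diagnosing and targeting rice yield gaps from survey data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and targeting rice yield gaps from survey data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

paddygap implements an analytics-led diagnosis of crop yield gaps from
field-level survey tables, built around five statistical ideas: an empirical
attainable-yield benchmark, a random-forest yield model, sequential ICE-based
gap attribution, interventional Shapley attribution with sign-based
co-limitation clustering, and local spatial statistics plus counterfactual
scenario accounting. This vignette explains each piece, the assumptions
behind it, the tunable parameters, and the numerical choices made where the
design was genuinely open. It states no empirical results beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The attainable-yield benchmark

For a region (a state, in the intended use), the *attainable yield*
$Y_{att}$ is the mean observed yield of the top decile of surveyed fields:
all fields at or above the empirical 90th percentile of the yield
distribution (linear-interpolation quantile, ties at the cutoff included in
the top set). Every other field's *attainable yield gap* is
$Y_{g,a} = Y_{att} - y_i > 0$. This is a pragmatic benchmark: it reflects
management already practiced by the best local fields rather than a
biophysical potential, so "closing the gap" never requires technology absent
from the region. The decile is configurable (`attainable_yield(table,
decile)`); 0.10 is the conventional default.

## The yield model

`fit_yield_model()` fits a `ranger` regression forest of observed yield
(t ha^-1^, untransformed) on the encoded predictors. Defaults: 500 trees,
`mtry = ceiling(p/3)`, and a **minimum terminal-node size of 50** — the key
regularisation on noisy survey data, where deep trees would memorise
field-level noise. Keeping the target untransformed means every downstream
attribution (ICE increments, Shapley values) is in t ha^-1^.

Survey studies are often ambiguous about which $R^2$ they quote, so the
model reports three: out-of-bag, training (optimistic), and optionally
k-fold cross-validated. Categorical predictors are ordinally coded by the
schema's level order; min–max scaled copies are stored for display only
(attribution colour ramps), never for fitting. A constant column min–max
scales to 0 — the degenerate case is mapped to "low" rather than 0/0.

Permutation importance is the mean increase in mean-squared prediction
error over `n_repeats` permutations of a feature column, with its
permutation SD. Groups of collinear features can be permuted jointly
(same row permutation for all columns in the group), which is the honest
way to score duplicated signal — single-column permutation dilutes it.
Ranking ties break by feature name so the constraint selection is
reproducible.

## Sequential ICE decomposition (Yg1, Yg2)

The top two *management* features by permutation importance are the
candidate constraints. For each field:

1. Sweep variable 1 over its observed-range grid with everything else at
   the field's reported values (an individual conditional expectation
   curve). $Y_{step1}$ is the curve maximum; $Y_{g1} = Y_{step1} -
   \hat y(\text{reported})$.
2. Substitute variable 1's optimal level into the field, then sweep
   variable 2. $Y_{g2} = Y_{step2} - Y_{step1}$.

Both increments are non-negative by construction because the reported value
always competes in the maximum. Grid steps are set at measurement
granularity: 10 kg ha^-1^ for N, 1 event for irrigation, 5/10/2 kg ha^-1^
for P/K/Zn, 5 days for sowing date; categorical variables sweep their
observed levels. Grids never extrapolate beyond the observed data range.

**Argmax tie-break.** When several levels achieve the curve maximum within
1e-9 t ha^-1^, the reported level wins if it is among them (no change is
recommended when change buys nothing), otherwise the smallest such level
wins (the resource-minimising recommendation). The two rules compose: "don't
move" dominates "move as little as possible".

The decomposition stops at two variables deliberately: sequential
substitution further down the ranking compounds model extrapolation error,
and two constraints are what the targeting scenarios act on.

## Interventional Shapley attribution

`shap_values()` attributes each field's prediction to its features with
Shapley values under the *interventional* value function: the payoff of a
coalition $S$ is the mean prediction when features in $S$ take the field's
values and the rest take values from a background sample. This makes
$\phi_j$ literally "the yield deviation from the population mean prediction
attributable to feature j", and makes additivity
$base + \sum_j \phi_j = \hat y$ exact. A path-dependent formulation (using
tree cover weights) was considered and rejected: its baseline is not the
population mean and it attributes to correlated-but-unused features.

The computation is exact for the ensemble and background — coalitions are
never sampled. Each leaf's path is flattened to per-feature interval
constraints; for a foreground/background pair the leaf's Shapley
contribution has a closed form in the counts of features forced to either
side, so the cost is linear in (records x background x leaves). The
independent test oracle, `exact_shapley()`, instead enumerates all $2^p$
coalitions through the model's own `predict` method and refuses $p > 12$.

**Background size.** The background is a fixed-seed simple random sample of
`bg_size = 100` rows (all rows when fewer). Run time is linear in the
background; 100 rows keep the base value within a few hundredths of a
t ha^-1^ of the full-data mean prediction while keeping landscape-scale
attribution affordable. The attribution itself is exact *given* the
background; only the base value's match to the full-data mean depends on
this size. Pass `background =` explicitly to use the full table.

**Clusters.** Fields are classified by the sign of $\phi$ for the number of
irrigations (I) and the N rate (N): `I+N+`, `I-N+`, `I+N-`, `I-N-`
(co-limited). $\phi = 0$ exactly counts as `+`: zero marginal contribution
implies no expected gain from change. Negative $\phi$ marks the input level
as suppressing predicted yield — the actionable, targetable state.

## Spatial hotspots (Getis–Ord Gi*)

`gi_star()` computes the standard self-inclusive Gi* z-score with binary
weights inside a fixed 10 km great-circle band (haversine distance, mean
Earth radius 6371.0088 km — no projection is assumed). Cold spots of
$\phi_N$ (z at or below the two-sided 5% normal threshold) are zones where
insufficient N consistently suppresses yields across neighbouring fields —
the actionable map. No multiplicity correction is applied by default, as is
conventional for these maps; `fdr = TRUE` applies Benjamini–Hochberg across
fields. Degenerate cases are defined, not errors: a band covering the whole
landscape gives 0/0, reported as z = 0 (no local deviation); isolated
fields keep their self-only neighbourhood and are identifiable via
`n_neighbors = 1`.

## Scenario engine

Four canonical counterfactuals (`scenario_spec()`): blanket 125 kg N ha^-1^
(a typical state recommendation), blanket 180 kg N ha^-1^ (the
analytics-derived population plateau; `derive_blanket_rate()` reads it off
the partial-dependence argmax with the smallest-rate tie-break), targeted N
(only fields with $\phi_N < 0$), and targeted co-limitation (only `I-N-`
fields, N to 180 and irrigations to 5).

Blanket scenarios set N *down* as well as up — a uniform recommendation
replaces current practice, which is how a low blanket rate can reduce total
N use. Targeted scenarios only raise inputs; a targeted field already at or
above the rate is left unchanged.

Accounting: per-field deltas come from model predictions on the modified
versus baseline table, with untargeted fields contributing exactly zero.
District aggregates scale the mean per-field delta (over *all* surveyed
fields in the district, non-adopters included as zeros) by the district
rice area, treating the surveyed fields as the district's area-weighted
sample. Irrigation counts are aggregated per hectare under the same rule —
the survey records events per field-season, and scaling them like N keeps
all three input aggregates on one convention. Partial net returns per
hectare are `dyield x paddy_price - dN x n_cost - dirr x irrigation_cost`
(defaults: USD 20 per irrigation, USD 0.14 per kg subsidised N, USD 250
per t paddy — roughly a 2018 minimum support price; all configurable, and
nothing in the package's tests depends on the paddy price). The marginal
nitrogen-use efficiency is `sum(additional grain kg) / sum(additional N
kg)` over fields that add N, NA when none do.

## The synthetic landscape generator

`generate_survey()` exists so every stage is testable end to end with known
truth. It emulates an eastern Indo-Gangetic rice survey at desk scale:

* **Response surface** (`true_response()`): additive Mitscherlich-type
  saturating responses for N (half-saturation 60 kg ha^-1^, hard plateau at
  180 kg ha^-1^) and irrigation (half-saturation 3 events, plateau at 5),
  small saturating P/K/Zn terms, linear weather and sowing-date terms, a
  small ordinal variety effect, intercept 2 t ha^-1^. The form is
  analytically differentiable (tests compare finite differences against the
  closed-form derivative) and the hard plateaus make "non-limiting" exact.
* **Co-limitation strata**: each field draws a class — 35% `I+N+`, 35%
  `I-N+`, 20% `I-N-`, 10% `I+N-` — which routes its N rate to a limited
  (0–60 kg ha^-1^) or non-limited (140–240) range and its irrigation count
  to a low (0–2) or high (5–8) pool. The ranges are separated so the class
  boundaries sit far from the response's decision thresholds and recovery
  tests measure method error, not boundary noise.
* **Space**: district centroids on a grid over a 2° x 2° extent, fields
  uniform within their district cell, weather drawn per district with
  field-level jitter. At the default 5,000 fields this gives a few dozen
  neighbours within the 10 km Gi* band. Planted hotspot circles (an
  N-depleted and an irrigation-depleted 15 km disc by default) override the
  stratum draw inside them, creating spatial constraint clusters by
  construction.
* **Noise**: a single additive Gaussian term, 0.4 t ha^-1^ by default,
  floored so yields stay positive. Ground-truth labels call a field
  N-limited (irrigation-limited) when raising that input to its plateau
  raises true expected yield by more than `noise_sd / 2`. The landscape's
  true attainable yield is the top-decile mean of the true expected yields
  of the generated sample (the sample quantity, not a population constant,
  so the zero-noise check is exact).

What the generator does **not** emulate: the joint correlation structure of
real management practices (fertiliser rates are independent given the
stratum), measurement error distinct from process noise (real surveys mix
farmer recall with crop cuts), missing data, multi-year dynamics, and any
confounding between management and unobserved soil quality. Passing
recovery tests therefore shows the machinery is correct and well
calibrated under a favourable but honest data-generating process — not that
a real survey will be as kind.

## Problem sizes and run-time choices

The reference testing condition is 5,000 fields over 12 districts with
noise 0.4 t ha^-1^ — large enough for stable top-decile benchmarks, Gi*
neighbourhoods, and cluster-share recovery, while a full pipeline run
(including exact interventional attribution for all fields against a
100-row background) completes in a few minutes on one core. The Gi* null
calibration uses 2,000 fields and 20 value replicates on a fixed point set.
The exhaustive Shapley oracle is exercised on a 6-feature, 50-record model,
where $2^6$ coalitions are cheap and the comparison tolerance (1e-4
t ha^-1^) is far below any agronomic signal.

## Known limitations

* ICE substitution extrapolates management combinations the forest may
  never have seen; grids are clamped to observed ranges to bound this.
* Shapley signs near zero are sensitive to model noise; cluster shares are
  stable long before individual borderline fields are.
* District aggregation assumes surveyed fields are representative of the
  district's rice area; no survey weights are implemented.
* The scenario engine prices only N and irrigation (partial net returns);
  labour, seed, and risk are out of scope.
* Gi* assumes the z-scores are comparable across fields with different
  neighbour counts; very sparse areas are flagged, not corrected.
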