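# paddygap

Yield-gap decomposition and intervention targeting for field-level rice
survey data.

Large-n farm surveys (thousands of field-year records of management
practices, weather, and measured yields) make it possible to ask not just
*how large* a region's yield gap is, but *which practices cause it, on which
fields, and where*. paddygap implements that analytics-led workflow for
agronomists and agricultural economists working with such surveys:

1. **Attainable yield benchmark** — the mean yield of the top decile of
   fields, `Y_att`; every other field's attainable yield gap is
   `Yg_a = Y_att − y_i`.
2. **Yield model** — a random-forest regression of yield on management and
   biophysical predictors (≥ 50 observations per terminal node), with
   permutation feature importance.
3. **Sequential ICE decomposition** — for each field, sweep the most
   important management variable over its observed range with all else at
   reported values (an individual conditional expectation curve); the gain
   to the curve maximum is `Yg1`. Substitute the optimal level, sweep the
   second variable: `Yg2`. `Yg1 + Yg2` is the expected gap closure from
   fixing the top two constraints.
4. **Shapley attribution and co-limitation clusters** — exact interventional
   Shapley values `φ_j` (t/ha) for the tree ensemble, so
   `base + Σ_j φ_j = prediction` per field; fields are classified by
   `sign(φ_irrigation)` and `sign(φ_N)` into `I±N±` clusters (`I-N-` =
   co-limited).
5. **Spatial hotspots** — the Getis–Ord Gi* statistic on per-field `φ`
   within a fixed 10 km haversine band; cold spots of `φ_N` are zones where
   insufficient N consistently suppresses yield.
6. **Scenario engine** — blanket versus targeted changes to N rate and
   irrigation, scored on production, input use, partial net returns, and
   marginal nitrogen-use efficiency, aggregated by district rice area.

A synthetic landscape generator with recorded ground truth (true response
surface, limitation labels, planted spatial constraint clusters) makes the
whole pipeline testable without any survey download.

## Worked example

```r
library(paddygap)

land  <- generate_survey(generator_config(n_fields = 1000, n_districts = 5,
                                          seed = 21))
gs    <- attainable_yield(land$survey)
fm    <- encode_features(land$survey)
model <- fit_yield_model(fm, land$survey$yield_obs, seed = 22)
model
#> <yield_model> ranger regression forest
#>   records: 1000, features: 9
#>   trees: 500, mtry: 3, min node size: 50
#>   R2  oob: 0.773  training: 0.841

imp <- permutation_importance(model, fm, land$survey$yield_obs, seed = 23,
                              features = survey_schema()$management)
dec <- decompose_sequential(model, fm, ranking = imp, table = land$survey)
summarise_decomposition(dec, gs)
#> # A tibble: 3 × 6
#>   component         mean     q25 median   q75 share_of_attainable
#> 1 n_rate           0.428 0.00472 0.0143 1.10               0.0702
#> 2 irrigation_count 0.331 0.00693 0.358  0.587              0.0543
#> 3 combined         0.759 0.0276  0.538  1.33               0.124
```

N rate and irrigation emerge as the top two constraints; fixing both for
every field would close an average 0.76 t/ha — about 12% of the attainable
yield — but the quartiles show the gains concentrate in a responsive
minority of fields. Clustering by attribution signs finds that minority:

```r
sh <- shap_values(model, fm, seed = 24)
cl <- assign_clusters(sh, districts = land$survey$district)
cl
#> <cluster_assignment> 1000 fields
#>   I+N+: 34.8%
#>   I-N+: 33.5%
#>   I+N-: 10.9%
#>   I-N-: 20.8%

spec <- scenario_spec(3)              # raise N to 180 kg/ha where phi_N < 0
ap   <- apply_scenario(land$survey, spec, cl)
evaluate_scenario(model, land$survey, ap$modified, land$district_areas,
                  spec, ap$mask)
#> <scenario_result> scenario 3 (n_negative)
#>   fields changed: 31.7%
#>   additional production: 162146 t;  additional N: 18456 t
#>   per adopting field: +1.32 t/ha, +308.6 USD/ha
#>   NUE of additional N: 8.8 kg grain/kg N
```

Targeting the N-limited third of fields delivers a per-adopter yield gain
several times the blanket-scenario average (compare `scenario_spec(2)`),
which is the case for analytics-based targeting in one sentence.

`run_pipeline(pipeline_config(...))` chains all stages, writes each stage's
CSV plus a `manifest.json` with the seed and config hash, and reproduces
its outputs bitwise under a fixed seed. Small example input files are in
`inst/extdata/`.

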