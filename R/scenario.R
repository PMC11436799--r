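# Ex-ante intensification scenarios: blanket versus targeted changes to N
# rate and irrigation, evaluated with the fitted yield model and aggregated
# to district and region level by rice area.

#' Specify an intensification scenario
#'
#' Four canonical scenarios:
#' * **1** — blanket state recommendation: every field set to 125 kg N/ha;
#' * **2** — blanket analytics-derived rate: every field set to 180 kg N/ha;
#' * **3** — targeted N: only fields with a negative Shapley value for N
#'   (clusters `I+N-` and `I-N-`) raised to 180 kg N/ha;
#' * **4** — targeted co-limitation: only `I-N-` fields, N raised to
#'   180 kg N/ha and irrigations raised to 5.
#'
#' Blanket scenarios set N to the blanket rate in every field, downward as
#' well as upward (a uniform recommendation replaces current practice, which
#' is why a low blanket rate can reduce total N use). Targeted scenarios
#' only ever raise inputs: a targeted field already at or above the scenario
#' rate is left unchanged.
#'
#' @param id scenario id in 1..4.
#' @param n_rate_new kg N/ha; defaults 125 (id 1) or 180 (ids 2-4).
#' @param irrigation_new irrigation count target (id 4 only; default 5).
#' @param prices list: `irrigation_cost` (USD per irrigation event, default
#'   20), `n_cost` (USD per kg subsidized N, default 0.14), `paddy_price`
#'   (USD per t of paddy; default 250, approximately the 2018 minimum
#'   support price — configure to taste).
#' @return a `scenario_spec` list with a `targeting` tag (`all`,
#'   `n_negative`, or `co_limited`).
#' @export
scenario_spec <- function(id, n_rate_new = NULL, irrigation_new = NULL,
                          prices = list()) {
  if (!id %in% 1:4) abort("scenario id must be 1, 2, 3 or 4")
  prices <- utils::modifyList(
    list(irrigation_cost = 20, n_cost = 0.14, paddy_price = 250), prices)
  if (any(unlist(prices) < 0)) abort("prices must be non-negative")
  n_rate_new <- n_rate_new %||% if (id == 1) 125 else 180
  if (n_rate_new < 0) abort("n_rate_new must be non-negative")
  irrigation_new <- if (id == 4) irrigation_new %||% 5 else NULL
  targeting <- switch(id, "all", "all", "n_negative", "co_limited")
  structure(list(id = id, n_rate_new = n_rate_new,
                 irrigation_new = irrigation_new,
                 targeting = targeting, prices = prices),
            class = "scenario_spec")
}

#' Apply a scenario to a survey table
#'
#' Produces the counterfactual table and the change mask. Targeted scenarios
#' (ids 3 and 4) require the cluster assignment computed on the same table.
#'
#' @param table a `survey_table`.
#' @param spec a [scenario_spec()].
#' @param clusters a [assign_clusters()] result (ids 3-4 only).
#' @return list: `modified` (table with new inputs), `mask` (logical, TRUE
#'   where any input changed), `targeted` (logical, TRUE where the
#'   targeting rule selected the field).
#' @export
apply_scenario <- function(table, spec, clusters = NULL) {
  n <- nrow(table)
  targeted <- switch(
    spec$targeting,
    all = rep(TRUE, n),
    n_negative = {
      if (is.null(clusters)) abort("scenario needs cluster labels")
      stopifnot(length(clusters$labels) == n)
      clusters$phi_n < 0
    },
    co_limited = {
      if (is.null(clusters)) abort("scenario needs cluster labels")
      stopifnot(length(clusters$labels) == n)
      clusters$labels == "I-N-"
    })
  modified <- table
  if (spec$targeting == "all") {
    modified$n_rate <- rep(spec$n_rate_new, n)  # blanket: down as well as up
  } else {
    modified$n_rate[targeted] <- pmax(table$n_rate[targeted], spec$n_rate_new)
  }
  if (!is.null(spec$irrigation_new)) {
    modified$irrigation_count[targeted] <-
      pmax(table$irrigation_count[targeted], spec$irrigation_new)
  }
  mask <- modified$n_rate != table$n_rate |
    modified$irrigation_count != table$irrigation_count
  list(modified = modified, mask = mask, targeted = targeted)
}

#' Evaluate a scenario against baseline practice
#'
#' Predicts counterfactual yields with the fitted model and aggregates the
#' deltas. Per field: `dyield` (t/ha), `dn` (kg N/ha), `dirr` (events), and
#' the partial net return `dprofit = dyield * paddy_price - dn * n_cost -
#' dirr * irrigation_cost` (USD/ha). District aggregates scale the mean
#' per-field delta across all surveyed fields of the district (non-adopters
#' contributing zero) by the district rice area, so the surveyed fields act
#' as the district's area-weighted sample; irrigation counts are treated as
#' per-hectare events under the same scaling. The nitrogen-use efficiency of
#' the additional N is `sum(additional grain kg) / sum(additional N kg)`
#' over fields with `dn > 0`, reported as NA when no field adds N.
#'
#' @param model a `yield_model`.
#' @param baseline the original `survey_table`.
#' @param modified the counterfactual table from [apply_scenario()].
#' @param district_areas tibble (district, rice_area_ha) covering every
#'   district in the table.
#' @param spec the [scenario_spec()].
#' @param mask change mask from [apply_scenario()]; recomputed if omitted.
#' @return A `scenario_result`: list with `district` (per-district deltas),
#'   `total` (region totals), `per_adopter` (mean dyield, dprofit over
#'   changed fields), `nue`, `fraction_changed`, `spec`, and the per-field
#'   delta tibble `fields`.
#' @export
evaluate_scenario <- function(model, baseline, modified, district_areas,
                              spec, mask = NULL) {
  stopifnot(nrow(baseline) == nrow(modified),
            all(baseline$field_id == modified$field_id))
  missing_d <- setdiff(unique(baseline$district), district_areas$district)
  if (length(missing_d) > 0) {
    abort(paste0("district(s) missing a rice area: ",
                 paste(missing_d, collapse = ", ")))
  }
  schema <- attr(baseline, "schema") %||% survey_schema()
  dyield <- predict(model, encode_features(modified, schema)) -
    predict(model, encode_features(baseline, schema))
  dn <- modified$n_rate - baseline$n_rate
  dirr <- modified$irrigation_count - baseline$irrigation_count
  if (is.null(mask)) mask <- dn != 0 | dirr != 0
  dyield[!mask] <- 0  # untargeted fields contribute exactly zero
  pr <- spec$prices
  dprofit <- dyield * pr$paddy_price - dn * pr$n_cost -
    dirr * pr$irrigation_cost

  fields <- tibble(field_id = as.character(baseline$field_id),
                   district = baseline$district,
                   changed = mask, dyield = dyield, dn = dn, dirr = dirr,
                   dprofit = dprofit)
  district <- fields |>
    left_join(district_areas, by = "district") |>
    group_by(.data$district) |>
    summarise(
      rice_area_ha = .data$rice_area_ha[1],
      fraction_changed = mean(.data$changed),
      dproduction_t = mean(.data$dyield) * .data$rice_area_ha[1],
      dn_use_t = mean(.data$dn) * .data$rice_area_ha[1] / 1000,
      dirrigation_events = mean(.data$dirr) * .data$rice_area_ha[1],
      dprofit_usd = mean(.data$dprofit) * .data$rice_area_ha[1],
      .groups = "drop")
  total <- summarise(district,
                     rice_area_ha = sum(.data$rice_area_ha),
                     fraction_changed = mean(fields$changed),
                     dproduction_t = sum(.data$dproduction_t),
                     dn_use_t = sum(.data$dn_use_t),
                     dirrigation_events = sum(.data$dirrigation_events),
                     dprofit_usd = sum(.data$dprofit_usd))
  adds_n <- dn > 0
  nue <- if (any(adds_n)) {
    sum(dyield[adds_n]) * 1000 / sum(dn[adds_n])  # kg grain per kg N
  } else NA_real_
  per_adopter <- if (any(mask)) {
    tibble(n = sum(mask),
           mean_dyield = mean(dyield[mask]),
           mean_dn = mean(dn[mask]),
           mean_dirr = mean(dirr[mask]),
           mean_dprofit = mean(dprofit[mask]))
  } else {
    tibble(n = 0L, mean_dyield = 0, mean_dn = 0, mean_dirr = 0,
           mean_dprofit = 0)
  }
  structure(list(district = district, total = total,
                 per_adopter = per_adopter, nue = nue,
                 fraction_changed = mean(mask), spec = spec,
                 fields = fields),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> scenario ", x$spec$id,
      " (", x$spec$targeting, ")\n",
      "  fields changed: ", sprintf("%.1f%%", 100 * x$fraction_changed), "\n",
      "  additional production: ", round(x$total$dproduction_t), " t",
      ";  additional N: ", round(x$total$dn_use_t), " t\n",
      "  per adopting field: +", round(x$per_adopter$mean_dyield, 2),
      " t/ha, +", round(x$per_adopter$mean_dprofit, 1), " USD/ha\n",
      "  NUE of additional N: ",
      if (is.na(x$nue)) "n/a" else paste0(round(x$nue, 1), " kg grain/kg N"),
      "\n", sep = "")
  invisible(x)
}

#' Derive a population-level blanket N rate from partial dependence
#'
#' The analytics-based blanket rate is read off the model's partial
#' dependence for N: mean prediction over all fields with every field's N
#' set to each grid rate in turn; the recommended rate is the smallest rate
#' achieving the maximum (within 1e-9 t/ha). This interprets the
#' "population-level non-limiting rate" as the partial-dependence argmax
#' with a resource-minimizing tie-break.
#'
#' @param model a `yield_model`.
#' @param fm training `feature_matrix`.
#' @param variable variable to optimise (default `n_rate`).
#' @param grid_step grid step (default the variable's ICE step).
#' @return list: `rate`, `curve` (tibble level, mean_prediction).
#' @export
derive_blanket_rate <- function(model, fm, variable = "n_rate",
                                grid_step = NULL) {
  grid <- ice_grid(fm, variable, grid_step)
  n <- nrow(fm$x)
  big <- fm$x[rep(seq_len(n), times = length(grid)), , drop = FALSE]
  big[, variable] <- rep(grid, each = n)
  pd <- colMeans(matrix(predict(model, big), nrow = n))
  rate <- grid[which(pd >= max(pd) - 1e-9)[1]]
  list(rate = rate, curve = tibble(level = grid, mean_prediction = pd))
}
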