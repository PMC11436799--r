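# Per-field Shapley attribution of yield predictions, its exhaustive oracle,
# importance ranking by mean |phi|, and N/irrigation co-limitation clusters.

# Flatten the fitted ranger ensemble into plain arrays for the C++ core.
extract_forest <- function(model) {
  cached <- attr(model, "forest_arrays")
  if (!is.null(cached)) return(cached)
  nt <- model$forest$num.trees %||% model$hyper$num_trees
  lapply(seq_len(nt), function(t) {
    ti <- ranger::treeInfo(model$forest, t)
    list(left = as.integer(ifelse(is.na(ti$leftChild), -1L, ti$leftChild)),
         right = as.integer(ifelse(is.na(ti$rightChild), -1L, ti$rightChild)),
         var = as.integer(ifelse(ti$terminal, -1L,
                                 match(ti$splitvarName, model$features) - 1L)),
         split = ifelse(is.na(ti$splitval), 0, ti$splitval),
         pred = ifelse(is.na(ti$prediction), 0, ti$prediction))
  })
}

#' Interventional Shapley values for a fitted yield model
#'
#' Computes the per-field, per-feature Shapley attribution phi_j (t/ha) of
#' the model's yield prediction, under the interventional value function:
#' the payoff of a feature coalition is the mean prediction when the
#' coalition's features take the field's values and all others take values
#' from a background sample of the data. phi_j is then the yield deviation
#' from the mean prediction attributable to feature j — negative values mean
#' the field's current level of that input suppresses its predicted yield.
#'
#' The computation is exact for the tree ensemble and the given background
#' (no sampling of coalitions): leaf contributions are enumerated per
#' foreground/background pair with closed-form Shapley weights, so the
#' additivity identity `base + sum_j phi_j = prediction` holds to floating
#' point for every record.
#'
#' @param model a `yield_model`.
#' @param fm `feature_matrix` (or numeric matrix) of the records to explain;
#'   must match the training schema.
#' @param background optional explicit background matrix; by default a
#'   simple random sample of `bg_size` rows of `fm` (all rows when
#'   `nrow <= bg_size`), drawn with `seed`.
#' @param bg_size background sample size (trade-off between run time, which
#'   is linear in it, and how exactly the base value equals the full-data
#'   mean prediction).
#' @param seed seed for the background draw.
#' @return A `shap_matrix`: list with `phi` (records x features, t/ha),
#'   `base` (mean prediction over the background), `prediction` (per-record
#'   model prediction), `features`, `background`.
#' @export
shap_values <- function(model, fm, background = NULL, bg_size = 100,
                        seed = 1L) {
  x <- feature_x(fm)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss) > 0) {
    abort(paste0("feature schema mismatch; missing: ",
                 paste(miss, collapse = ", ")))
  }
  x <- x[, model$features, drop = FALSE]
  if (is.null(background)) {
    if (nrow(x) <= bg_size) {
      background <- x
    } else {
      set.seed(seed)
      background <- x[sample.int(nrow(x), bg_size), , drop = FALSE]
    }
  } else {
    background <- feature_x(background)[, model$features, drop = FALSE]
  }
  trees <- extract_forest(model)
  phi <- shap_interventional_cpp(trees, x, background)
  colnames(phi) <- model$features
  pred <- forest_predict_cpp(trees, x)
  base <- mean(forest_predict_cpp(trees, background))
  structure(list(phi = phi, base = base, prediction = pred,
                 features = model$features, background = background),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat("<shap_matrix> ", nrow(x$phi), " records x ", ncol(x$phi),
      " features, base value ", round(x$base, 3), " t/ha\n", sep = "")
  invisible(x)
}

#' Exact Shapley values by exhaustive coalition enumeration
#'
#' Independent oracle for [shap_values()]: enumerates all 2^p feature
#' coalitions and computes
#' `phi_j = sum_{S not containing j} |S|! (p-|S|-1)! / p! * (v(S+j) - v(S))`
#' with the interventional payoff `v(S)` = mean prediction over the
#' background with the features outside S replaced by background values.
#' Predictions go through the model's own `predict` method (or an arbitrary
#' `predict_fun`), not the tree-traversal code, so the two routes are
#' independent. Refuses more than 12 features.
#'
#' @param model object with a `predict` method (e.g. a `yield_model`), or
#'   anything if `predict_fun` is given.
#' @param record named numeric vector (or 1-row matrix) of feature values.
#' @param background numeric matrix of background rows (same columns).
#' @param predict_fun optional `function(matrix) -> numeric`.
#' @return named numeric vector phi, one entry per feature; satisfies
#'   `sum(phi) = f(record) - mean(f(background))` exactly.
#' @export
exact_shapley <- function(model, record, background, predict_fun = NULL) {
  if (is.matrix(record)) record <- record[1, ]
  background <- feature_x(background)
  p <- length(record)
  if (p > 12) abort("exact_shapley refuses more than 12 features")
  stopifnot(ncol(background) == p)
  if (is.null(predict_fun)) predict_fun <- function(m) predict(model, m)
  B <- nrow(background)

  # one batched prediction for all 2^p coalitions
  n_sub <- bitwShiftL(1L, p)
  big <- background[rep(seq_len(B), times = n_sub), , drop = FALSE]
  for (s in seq_len(n_sub) - 1L) {
    rows <- s * B + seq_len(B)
    in_s <- bitwAnd(bitwShiftR(s, seq_len(p) - 1L), 1L) == 1L
    if (any(in_s)) {
      big[rows, in_s] <- matrix(record[in_s], nrow = B, ncol = sum(in_s),
                                byrow = TRUE)
    }
  }
  v <- colMeans(matrix(predict_fun(big), nrow = B))  # v[s+1] = v(S)

  fact <- factorial(0:p)
  phi <- numeric(p)
  sizes <- vapply(seq_len(n_sub) - 1L,
                  function(s) sum(bitwAnd(bitwShiftR(s, seq_len(p) - 1L), 1L)),
                  numeric(1))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in seq_len(n_sub) - 1L) {
      if (bitwAnd(s, bit) != 0L) next
      w <- fact[sizes[s + 1] + 1] * fact[p - sizes[s + 1]] / fact[p + 1]
      phi[j] <- phi[j] + w * (v[bitwOr(s, bit) + 1] - v[s + 1])
    }
  }
  setNames(phi, names(record) %||% colnames(background))
}

#' Rank features by mean absolute Shapley value
#'
#' The summary-plot importance: mean over records of |phi_j|, descending,
#' ties broken alphabetically. `group` restricts the ranking to the
#' management or biophysical predictors of the schema, matching the usual
#' two-panel attribution summary.
#'
#' @param shap a `shap_matrix`.
#' @param group `NULL`, `"management"`, or `"biophysical"`.
#' @param schema a [survey_schema()] (used when `group` is given).
#' @return tibble (feature, mean_abs_shap, rank), descending.
#' @export
rank_importance <- function(shap, group = NULL, schema = survey_schema()) {
  if (nrow(shap$phi) == 0) abort("empty shap matrix")
  score <- colMeans(abs(shap$phi))
  if (!is.null(group)) {
    group <- match.arg(group, c("management", "biophysical"))
    score <- score[names(score) %in% schema[[group]]]
  }
  out <- tibble(feature = names(score), mean_abs_shap = unname(score))
  out <- out[order(-out$mean_abs_shap, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Assign fields to irrigation/nitrogen co-limitation clusters
#'
#' Classifies every field by the sign of its Shapley value for the number of
#' irrigations (I) and the N fertilizer rate (N): `I+N+` (neither limiting),
#' `I-N+` (irrigation limiting), `I+N-` (N limiting), `I-N-` (co-limited).
#' A phi of exactly 0 counts as `+` (no expected gain from changing the
#' input). Shares are reported overall and, when `districts` is supplied,
#' per district.
#'
#' @param shap a `shap_matrix`.
#' @param var_irrigation,var_n feature names of the two practices.
#' @param districts optional per-record district labels.
#' @return A `cluster_assignment`: list with `labels` (per-record factor),
#'   `shares` (tibble label, share), `district_shares` (or NULL), and the
#'   two phi vectors.
#' @export
assign_clusters <- function(shap, var_irrigation = "irrigation_count",
                            var_n = "n_rate", districts = NULL) {
  for (v in c(var_irrigation, var_n)) {
    if (!v %in% colnames(shap$phi)) abort(paste0("no such feature: ", v))
  }
  phi_i <- shap$phi[, var_irrigation]
  phi_n <- shap$phi[, var_n]
  lab <- paste0("I", ifelse(phi_i >= 0, "+", "-"),
                "N", ifelse(phi_n >= 0, "+", "-"))
  levels <- c("I+N+", "I-N+", "I+N-", "I-N-")
  labels <- factor(lab, levels = levels)
  shares <- tibble(label = levels,
                   share = as.numeric(table(labels)[levels]) / length(labels))
  district_shares <- NULL
  if (!is.null(districts)) {
    district_shares <- tibble(district = districts, label = labels) |>
      group_by(.data$district, .data$label, .drop = FALSE) |>
      summarise(n = n(), .groups = "drop_last") |>
      mutate(share = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  structure(list(labels = labels, shares = shares,
                 district_shares = district_shares,
                 phi_irrigation = phi_i, phi_n = phi_n),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " fields\n", sep = "")
  s <- x$shares
  for (i in seq_len(nrow(s))) {
    cat("  ", s$label[i], ": ", sprintf("%.1f%%", 100 * s$share[i]), "\n",
        sep = "")
  }
  invisible(x)
}

#' Long-format data for an attribution summary plot
#'
#' One row per record x feature: the Shapley value and the record's min-max
#' scaled feature value (the colour dimension of the usual beeswarm summary
#' plot), with features ordered by mean absolute attribution.
#'
#' @param shap a `shap_matrix`.
#' @param fm the `feature_matrix` the attributions were computed on
#'   (supplies the scaled values).
#' @param group optional restriction passed to [rank_importance()].
#' @param schema schema for the group split.
#' @return tibble (feature, scaled_value, phi), feature as a factor in
#'   importance order.
#' @export
shap_summary_data <- function(shap, fm, group = NULL,
                              schema = survey_schema()) {
  stopifnot(nrow(fm$scaled) == nrow(shap$phi))
  rk <- rank_importance(shap, group = group, schema = schema)
  out <- bind_rows(lapply(rk$feature, function(f) {
    tibble(feature = f,
           scaled_value = fm$scaled[, f],
           phi = shap$phi[, f])
  }))
  out$feature <- factor(out$feature, levels = rk$feature)
  out
}
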