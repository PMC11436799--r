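#' Attainable yield and attainable yield gaps
#'
#' The attainable yield is the mean observed yield of the top decile of
#' fields: all fields whose yield is at or above the empirical 90th
#' percentile (linear-interpolation quantile; ties at the cutoff are in the
#' top set). The attainable yield gap of every remaining field is the
#' attainable yield minus its observed yield — strictly positive, since any
#' field below the cutoff is below the mean of the fields above it.
#'
#' @param table a `survey_table` (or data frame with `yield_obs`).
#' @param decile top fraction used as the benchmark (default 0.10).
#' @return A `gap_summary`: list with `y_att` (t/ha), `cutoff`, `decile`,
#'   `n_top`, `state`, and `gaps` — tibble (field_id, year, yield_obs, yg_a)
#'   for the non-top-decile fields.
#' @export
attainable_yield <- function(table, decile = 0.10) {
  y <- table$yield_obs
  if (length(y) == 0) abort("empty table")
  if (length(y) < 10) abort("need at least 10 records")
  stopifnot(decile > 0, decile < 1)
  cutoff <- quantile(y, 1 - decile, names = FALSE, type = 7)
  top <- y >= cutoff
  y_att <- mean(y[top])
  gaps <- tibble(field_id = as.character(table$field_id),
                 year = table$year,
                 yield_obs = y,
                 yg_a = y_att - y)[!top, ]
  structure(list(y_att = y_att, cutoff = cutoff, decile = decile,
                 n_top = sum(top), state = attr(table, "state"),
                 gaps = gaps),
            class = "gap_summary")
}

#' @export
print.gap_summary <- function(x, ...) {
  cat("<gap_summary> state: ", x$state %||% "?", "\n",
      "  attainable yield (top ", 100 * x$decile, "% mean): ",
      round(x$y_att, 2), " t/ha over ", x$n_top, " fields\n",
      "  mean gap of remaining fields: ",
      round(mean(x$gaps$yg_a), 2), " t/ha\n", sep = "")
  invisible(x)
}

grid_steps_default <- function() {
  c(n_rate = 10, irrigation_count = 1, p_rate = 5, k_rate = 10,
    zn_rate = 2, sowing_doy = 5)
}

#' Build the ICE grid for one variable
#'
#' Numeric variables: the observed min..max in the table, in the variable's
#' step (10 kg/ha for N, 1 event for irrigation, 5/10/2 kg/ha for P/K/Zn,
#' 5 days for sowing date), never extrapolating beyond the data. Categorical
#' variables: the set of observed levels (as ordinal codes). The field's own
#' reported value is always evaluated in addition to the grid.
#'
#' @param fm training `feature_matrix` (supplies the observed ranges).
#' @param variable feature name.
#' @param grid_step step override for numeric variables.
#' @return numeric vector of grid levels (codes for categorical variables).
#' @export
ice_grid <- function(fm, variable, grid_step = NULL) {
  if (!variable %in% colnames(fm$x)) {
    abort(paste0("variable not in schema: ", variable))
  }
  v <- fm$x[, variable]
  if (variable %in% names(fm$encoding)) return(sort(unique(v)))
  if (!is.null(grid_step) && grid_step <= 0) abort("grid_step must be > 0")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])  # constant in the data: trivial grid
  step <- grid_step %||% unname(grid_steps_default()[variable])
  if (is.null(step) || is.na(step)) step <- diff(rng) / 24
  seq(rng[1], rng[2], by = step)
}

#' Individual conditional expectation sweep for one field
#'
#' Predicts yield for a single field as one input variable is swept over its
#' observed-range grid, all other inputs held at the field's reported
#' values. The argmax is resource-minimizing: if the reported level already
#' achieves the curve maximum (within 1e-9 t/ha) it is kept, otherwise the
#' smallest level achieving the maximum is chosen.
#'
#' @param model a `yield_model`.
#' @param record one row of a `feature_matrix` (named numeric vector or
#'   1-row matrix of encoded predictors).
#' @param variable feature to sweep.
#' @param fm training feature matrix (for the observed range).
#' @param grid_step optional numeric step override.
#' @return An `ice_curve`: list with `variable`, `curve` (tibble level,
#'   prediction), `reported_level`, `reported_prediction`, `argmax_level`,
#'   `max_prediction`.
#' @export
ice_sweep <- function(model, record, variable, fm, grid_step = NULL) {
  if (is.matrix(record)) record <- record[1, ]
  grid <- ice_grid(fm, variable, grid_step)
  x <- matrix(rep(record, each = length(grid)), nrow = length(grid),
              dimnames = list(NULL, names(record)))
  x[, variable] <- grid
  pred <- predict(model, x)
  rep_level <- unname(record[variable])
  rep_pred <- predict(model, matrix(record, nrow = 1,
                                    dimnames = list(NULL, names(record))))
  pick <- pick_argmax(grid, pred, rep_level, rep_pred)
  structure(list(variable = variable,
                 curve = tibble(level = grid, prediction = pred),
                 reported_level = rep_level,
                 reported_prediction = rep_pred,
                 argmax_level = pick$level,
                 max_prediction = pick$value),
            class = "ice_curve")
}

# Shared argmax rule: max over grid and reported value; keep the reported
# level when it ties the max, else the smallest grid level achieving it.
pick_argmax <- function(grid, pred, rep_level, rep_pred, tol = 1e-9) {
  m <- max(pred, rep_pred)
  if (rep_pred >= m - tol) {
    list(level = rep_level, value = max(rep_pred, m))
  } else {
    list(level = grid[which(pred >= m - tol)[1]], value = m)
  }
}

#' Sequential ICE decomposition of the yield gap
#'
#' Attributes each field's yield gap to the two leading management
#' constraints. For every field: (1) sweep the most important management
#' variable over its ICE grid; `Y_step1` is the curve maximum and
#' `Yg1 = Y_step1 - prediction at reported values`; (2) substitute the
#' variable's optimal level (e.g. the N rate of maximum yield), then sweep
#' the second variable; `Y_step2` is that maximum and `Yg2 = Y_step2 -
#' Y_step1`. Both increments are non-negative by construction because the
#' reported value always competes in the max. `Yg1 + Yg2` is the expected
#' gap closure from fixing both constraints.
#'
#' @param model a `yield_model` fitted on `fm`'s schema.
#' @param fm the `feature_matrix` of the table being decomposed.
#' @param ranking an `importance_ranking`; its top two management features
#'   are the decomposition variables (override with `variables`).
#' @param schema schema giving the management group.
#' @param variables optional explicit character pair, bypassing the ranking.
#' @param table optional `survey_table` supplying field ids for the output.
#' @return A `decomposition_result` tibble: field_id, y_base, y_step1,
#'   y_step2, yg1, yg2, combined, var1/var2 reported and optimal levels;
#'   attributes `var1`, `var2`.
#' @export
decompose_sequential <- function(model, fm, ranking = NULL,
                                 schema = fm$schema %||% survey_schema(),
                                 variables = NULL, table = NULL) {
  if (is.null(variables)) {
    if (is.null(ranking)) abort("supply either a ranking or two variables")
    variables <- top_management(ranking, schema, k = 2)
  }
  if (length(variables) < 2) abort("need two management variables")
  v1 <- variables[1]; v2 <- variables[2]
  x <- fm$x
  n <- nrow(x)
  y_base <- predict(model, x)

  sweep_max <- function(x_now, variable, base_pred) {
    grid <- ice_grid(fm, variable)
    g <- length(grid)
    # stack: one block of n rows per grid level, single batched prediction
    big <- x_now[rep(seq_len(n), times = g), , drop = FALSE]
    big[, variable] <- rep(grid, each = n)
    pm <- matrix(predict(model, big), nrow = n)  # n x g
    row_max <- do.call(pmax, c(as.data.frame(pm), list(base_pred)))
    tol <- 1e-9
    opt <- numeric(n)
    reported <- x_now[, variable]
    at_reported <- base_pred >= row_max - tol
    opt[at_reported] <- reported[at_reported]
    if (any(!at_reported)) {
      idx <- apply(pm[!at_reported, , drop = FALSE] >=
                     row_max[!at_reported] - tol, 1, which.max)
      opt[!at_reported] <- grid[idx]
    }
    list(y_max = row_max, opt = opt)
  }

  s1 <- sweep_max(x, v1, y_base)
  x_sub <- x
  x_sub[, v1] <- s1$opt
  y_step1 <- s1$y_max
  s2 <- sweep_max(x_sub, v2, y_step1)
  y_step2 <- s2$y_max

  out <- tibble(field_id = if (!is.null(table)) as.character(table$field_id)
                           else sprintf("R%05d", seq_len(n)),
                y_base = y_base, y_step1 = y_step1, y_step2 = y_step2,
                yg1 = y_step1 - y_base, yg2 = y_step2 - y_step1,
                combined = y_step2 - y_base,
                var1_reported = x[, v1], var1_opt = s1$opt,
                var2_reported = x[, v2], var2_opt = s2$opt)
  structure(out, var1 = v1, var2 = v2,
            class = c("decomposition_result", class(out)))
}

#' Summarise a decomposition across fields
#'
#' Quartile summaries of Yg1, Yg2 and their sum, optionally expressed
#' relative to the attainable yield of the state (`gap_summary`).
#'
#' @param decomposition a `decomposition_result`.
#' @param gap_summary optional [attainable_yield()] result; when given, the
#'   summary adds each statistic as a fraction of the attainable yield.
#' @return tibble with one row per component (yg1, yg2, combined).
#' @export
summarise_decomposition <- function(decomposition, gap_summary = NULL) {
  comp <- function(v, name) {
    q <- quantile(decomposition[[v]], c(0.25, 0.5, 0.75), names = FALSE)
    tibble(component = name, mean = mean(decomposition[[v]]),
           q25 = q[1], median = q[2], q75 = q[3])
  }
  out <- bind_rows(comp("yg1", attr(decomposition, "var1")),
                   comp("yg2", attr(decomposition, "var2")),
                   comp("combined", "combined"))
  if (!is.null(gap_summary)) {
    out$share_of_attainable <- out$mean / gap_summary$y_att
  }
  out
}
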