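#' Survey data schema
#'
#' Defines the canonical column set of a field-year survey table, the
#' partition of predictors into management and biophysical groups, the
#' ordinal levels of the variety-class factor, and the validation bounds
#' applied by [read_survey()] / [validate_survey()].
#'
#' Management variables are those a farmer controls within a season
#' (fertilizer rates, irrigation, sowing date, variety class); biophysical
#' variables are seasonal weather aggregates attached to each field. Every
#' predictor belongs to exactly one group — the partition is asserted at
#' load time because the gap decomposition and the attribution summaries
#' are reported per group.
#'
#' @param extra_management,extra_biophysical optional additional numeric
#'   predictor columns, extending the canonical core.
#' @return A list of class `survey_schema` with elements `columns`,
#'   `management`, `biophysical`, `predictors`, `categorical` (named list of
#'   ordered level sets), and `bounds`.
#' @export
#' @examples
#' sch <- survey_schema()
#' sch$management
survey_schema <- function(extra_management = character(),
                          extra_biophysical = character()) {
  management <- c("n_rate", "p_rate", "k_rate", "zn_rate",
                  "irrigation_count", "sowing_doy", "variety_class",
                  extra_management)
  biophysical <- c("weather_srad", "weather_tmax", extra_biophysical)
  both <- intersect(management, biophysical)
  if (length(both) > 0) {
    abort(paste0("predictors assigned to both groups: ",
                 paste(both, collapse = ", ")))
  }
  structure(list(
    columns = c("field_id", "lat", "lon", "state", "district", "year",
                "yield_obs", management, biophysical),
    management = management,
    biophysical = biophysical,
    predictors = c(management, biophysical),
    categorical = list(variety_class = c("short", "medium", "long")),
    bounds = list(
      yield_obs = c(0, 15),          # open interval: 0 < yield < 15 t/ha
      n_rate = c(0, Inf),
      p_rate = c(0, Inf),
      k_rate = c(0, Inf),
      zn_rate = c(0, Inf),
      irrigation_count = c(0, Inf),  # integer-valued
      sowing_doy = c(1, 366),
      lat = c(-90, 90),
      lon = c(-180, 180)
    )
  ), class = "survey_schema")
}

#' Validate a raw survey data frame
#'
#' Applies row-level validation: numeric parseability, bounds (yield strictly
#' inside (0, 15) t/ha, non-negative rates, Julian day in 1..366, integer
#' irrigation counts), known variety-class levels, finite coordinates, and no
#' missing values. Rows failing any check are rejected with a diagnostic;
#' duplicated `field_id` x `year` combinations are an error for the whole
#' table. Rejection rather than imputation keeps the per-field substitution
#' steps downstream well defined.
#'
#' @param df data frame with at least the columns of `schema$columns`.
#' @param schema a [survey_schema()].
#' @param state optional state label to attach; defaults to the modal value
#'   of the `state` column.
#' @return A `survey_table`: a tibble of valid records carrying the schema,
#'   with attributes `rejected` (tibble of row, field_id, reason) and `state`.
#' @export
validate_survey <- function(df, schema = survey_schema(), state = NULL) {
  missing_cols <- setdiff(schema$columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)[schema$columns]

  reasons <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }

  num_cols <- setdiff(schema$columns,
                      c("field_id", "state", "district",
                        names(schema$categorical)))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    flag(is.na(v) | !is.finite(v), paste0("unparseable or missing ", cl))
    df[[cl]] <- v
  }
  b <- schema$bounds
  flag(df$yield_obs <= b$yield_obs[1] | df$yield_obs >= b$yield_obs[2],
       "yield_obs outside (0, 15) t/ha")
  for (cl in c("n_rate", "p_rate", "k_rate", "zn_rate")) {
    flag(df[[cl]] < 0, paste0("negative ", cl))
  }
  flag(df$irrigation_count < 0 |
         df$irrigation_count != round(df$irrigation_count),
       "irrigation_count not a non-negative integer")
  flag(df$sowing_doy < 1 | df$sowing_doy > 366, "sowing_doy outside 1..366")
  flag(abs(df$lat) > 90 | abs(df$lon) > 180, "coordinate out of range")
  for (cl in names(schema$categorical)) {
    lev <- schema$categorical[[cl]]
    df[[cl]] <- as.character(df[[cl]])
    flag(!(df[[cl]] %in% lev), paste0("unknown ", cl, " level"))
  }
  flag(is.na(df$field_id) | df$field_id == "", "empty field_id")

  keep <- is.na(reasons)
  rejected <- tibble(row = which(!keep),
                     field_id = as.character(df$field_id[!keep]),
                     reason = reasons[!keep])
  out <- df[keep, ]

  key <- paste(out$field_id, out$year, sep = "/")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort(paste0("duplicated field_id/year: ",
                 paste(head(dups, 10), collapse = ", ")))
  }
  if (is.null(state)) {
    tab <- table(out$state)
    state <- if (length(tab) > 0) names(tab)[which.max(tab)] else NA_character_
  }
  new_survey_table(out, schema, state, rejected)
}

new_survey_table <- function(tbl, schema, state, rejected = NULL) {
  structure(tbl,
            schema = schema, state = state, rejected = rejected,
            class = c("survey_table", class(tibble())))
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table> ", nrow(x), " field-year records, state: ",
      attr(x, "state"), "\n", sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0) {
    cat("  (", nrow(rej), " rows rejected at validation)\n", sep = "")
  }
  NextMethod()
}

#' Read a survey CSV
#'
#' Reads a UTF-8 CSV whose header matches the schema columns and validates it
#' with [validate_survey()]. Invalid rows are dropped and reported via the
#' `rejected` attribute; per-state/district record counts are available from
#' [survey_counts()].
#'
#' @inheritParams validate_survey
#' @param path path to the CSV file.
#' @return A `survey_table`.
#' @export
read_survey <- function(path, schema = survey_schema(), state = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_survey(df, schema, state)
}

#' Write a survey table as CSV
#'
#' One header row, UTF-8, columns exactly in schema order. Reading the file
#' back reproduces the table (validation is idempotent).
#'
#' @param table a `survey_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Record counts per state and district
#' @param table a `survey_table`.
#' @return tibble with state, district, n.
#' @export
survey_counts <- function(table) {
  as_tibble(table) |>
    group_by(.data$state, .data$district) |>
    summarise(n = n(), .groups = "drop")
}

#' Read the district rice-area table
#'
#' @param path CSV with columns `district`, `rice_area_ha`.
#' @return tibble with positive areas.
#' @export
read_district_areas <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("district", "rice_area_ha") %in% names(df))) {
    abort("district areas CSV must have columns: district, rice_area_ha")
  }
  if (any(!is.finite(df$rice_area_ha)) || any(df$rice_area_ha <= 0)) {
    abort("rice_area_ha must be positive and finite")
  }
  df
}

#' Encode survey predictors as a numeric feature matrix
#'
#' Categorical predictors are ordinally coded (first level = 0) using the
#' schema's level order; numeric predictors are passed through unchanged. The
#' raw (unscaled) values are what the yield model consumes, so Shapley
#' attributions stay in t/ha. Per-feature min/max and a min-max scaled copy
#' are stored for display (the scaled value drives the colour ramp on
#' attribution summary plots); a constant column scales to 0.
#'
#' @param table a `survey_table` (or data frame with predictor columns).
#' @param schema the schema used to select and group predictors.
#' @return A `feature_matrix`: list with `x` (numeric matrix records x
#'   features), `scaled` (min-max scaled copy), `encoding` (named list of
#'   level vectors), `ranges` (feature, min, max), `schema`.
#' @export
encode_features <- function(table, schema = attr(table, "schema") %||% survey_schema()) {
  x <- matrix(NA_real_, nrow = nrow(table), ncol = length(schema$predictors),
              dimnames = list(NULL, schema$predictors))
  for (cl in schema$predictors) {
    if (cl %in% names(schema$categorical)) {
      lev <- schema$categorical[[cl]]
      v <- as.character(table[[cl]])
      unseen <- setdiff(unique(v), lev)
      if (length(unseen) > 0) {
        abort(paste0("unseen level(s) in ", cl, ": ",
                     paste(unseen, collapse = ", ")))
      }
      x[, cl] <- match(v, lev) - 1
    } else {
      x[, cl] <- as.numeric(table[[cl]])
    }
  }
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  scaled <- sweep(x, 2, rng[1, ], "-")
  scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), "/")
  scaled[, span == 0] <- 0  # constant column -> 0, not 0/0
  structure(list(x = x, scaled = scaled,
                 encoding = schema$categorical,
                 ranges = tibble(feature = colnames(x),
                                 min = rng[1, ], max = rng[2, ]),
                 schema = schema),
            class = "feature_matrix")
}

#' Decode a feature matrix back to predictor columns
#'
#' Inverse of [encode_features()] for the predictor columns: ordinal codes
#' are mapped back to their levels, numeric columns returned as-is.
#'
#' @param fm a `feature_matrix`.
#' @return tibble of predictor columns.
#' @export
decode_features <- function(fm) {
  out <- as_tibble(as.data.frame(fm$x))
  for (cl in names(fm$encoding)) {
    out[[cl]] <- fm$encoding[[cl]][out[[cl]] + 1]
  }
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " records x ", ncol(x$x),
      " features\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
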