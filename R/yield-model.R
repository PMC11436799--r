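#' Fit the random-forest yield model
#'
#' Fits a regression random forest of observed yield on the encoded
#' predictors, with a minimum terminal-node size of 50 observations (the
#' guard against over-fitting on survey data of this size). The target is
#' the raw observed yield in t/ha, untransformed, so that downstream Shapley
#' attributions are directly interpretable as yield deviations.
#'
#' Variance explained is reported three ways, because survey studies are
#' often ambiguous about which is quoted: out-of-bag R^2, training R^2
#' (optimistic), and optionally k-fold cross-validated R^2.
#'
#' @param fm a `feature_matrix` from [encode_features()] (or numeric matrix).
#' @param y numeric vector of observed yields (t/ha).
#' @param num_trees,mtry,min_node_size forest hyperparameters; `mtry`
#'   defaults to `ceiling(p / 3)`, `min_node_size` to 50.
#' @param seed integer seed; fit, prediction and importance are reproducible
#'   under a fixed seed.
#' @param cv_folds if > 0, also estimate R^2 by k-fold cross-validation
#'   (refitting the forest per fold).
#' @return A `yield_model`: the fitted ranger handle plus feature schema,
#'   hyperparameters, seed, training-data fingerprint, and the R^2 report.
#' @export
fit_yield_model <- function(fm, y, num_trees = 500, mtry = NULL,
                            min_node_size = 50, seed = 1L, cv_folds = 0) {
  x <- feature_x(fm)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < min_node_size) {
    abort(paste0("cannot fit: ", nrow(x), " records < minimum node size ",
                 min_node_size))
  }
  if (nrow(x) < 200) {
    warn(paste0("only ", nrow(x), " records; yield model will be unstable"))
  }
  p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(p / 3)
  dat <- data.frame(.y = y, x, check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    seed = seed, respect.unordered.factors = FALSE,
    num.threads = 1)
  train_pred <- stats::predict(rf, data.frame(x, check.names = FALSE),
                               num.threads = 1)$predictions
  r2 <- list(oob = rf$r.squared,
             training = 1 - mean((y - train_pred)^2) / stats::var(y),
             cv = NA_real_)
  if (cv_folds > 0) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
    pred_cv <- numeric(nrow(x))
    for (k in seq_len(cv_folds)) {
      rf_k <- ranger::ranger(
        dependent.variable.name = ".y", data = dat[fold != k, , drop = FALSE],
        num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
        seed = seed + k, num.threads = 1)
      pred_cv[fold == k] <- stats::predict(
        rf_k, data.frame(x[fold == k, , drop = FALSE], check.names = FALSE),
        num.threads = 1)$predictions
    }
    r2$cv <- 1 - mean((y - pred_cv)^2) / stats::var(y)
  }
  structure(list(forest = rf,
                 features = colnames(x),
                 hyper = list(num_trees = num_trees, mtry = mtry,
                              min_node_size = min_node_size),
                 seed = seed,
                 n_train = nrow(x),
                 yield_range = range(y),
                 fingerprint = rlang::hash(list(x, y)),
                 r2 = r2),
            class = "yield_model")
}

feature_x <- function(fm) {
  if (inherits(fm, "feature_matrix")) return(fm$x)
  if (is.data.frame(fm)) return(as.matrix(fm))
  if (is.matrix(fm)) return(fm)
  abort("expected a feature_matrix, matrix, or data frame")
}

#' @export
print.yield_model <- function(x, ...) {
  cat("<yield_model> ranger regression forest\n",
      "  records: ", x$n_train, ", features: ", length(x$features), "\n",
      "  trees: ", x$hyper$num_trees, ", mtry: ", x$hyper$mtry,
      ", min node size: ", x$hyper$min_node_size, "\n",
      "  R2  oob: ", round(x$r2$oob, 3),
      "  training: ", round(x$r2$training, 3),
      if (!is.na(x$r2$cv)) paste0("  cv: ", round(x$r2$cv, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Predict yields from a fitted model
#'
#' Columns are aligned to the training schema by name, so column order in
#' the input does not matter; missing or extra predictor columns are an
#' error naming the offending columns.
#'
#' @param object a `yield_model`.
#' @param fm a `feature_matrix`, numeric matrix, or data frame of predictors.
#' @param ... unused.
#' @return numeric vector of predicted yields (t/ha).
#' @export
predict.yield_model <- function(object, fm, ...) {
  x <- feature_x(fm)
  miss <- setdiff(object$features, colnames(x))
  extra <- setdiff(colnames(x), object$features)
  if (length(miss) > 0 || length(extra) > 0) {
    abort(paste0("feature schema mismatch;",
                 if (length(miss)) paste0(" missing: ",
                                          paste(miss, collapse = ", ")),
                 if (length(extra)) paste0(" unexpected: ",
                                           paste(extra, collapse = ", "))))
  }
  x <- x[, object$features, drop = FALSE]
  stats::predict(object$forest, data.frame(x, check.names = FALSE),
                 num.threads = 1)$predictions
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean increase in mean-squared prediction
#' error when that feature's column is permuted, averaged over `n_repeats`
#' independent permutations; the permutation standard deviation is reported
#' alongside. Features can be permuted jointly in groups (a duplicated or
#' collinear pair shares its signal, so single-feature permutation dilutes
#' both scores while a joint permutation recovers the combined one — pass
#' the pair as a group to measure that). Restricting `features` to the
#' management group is how the top yield-gap constraint candidates are
#' selected.
#'
#' @param model a `yield_model`.
#' @param fm feature matrix the importance is evaluated on.
#' @param y observed yields matching `fm`.
#' @param n_repeats number of permutations per feature (>= 1).
#' @param seed RNG seed for the permutations.
#' @param features character vector restricting which features are scored
#'   (default: all). Ranked among themselves.
#' @param groups optional named list of character vectors; each group's
#'   columns are permuted jointly (with the same row permutation) and scored
#'   as one unit, in addition to entries of `features`.
#' @return An `importance_ranking` tibble (feature, importance, sd, rank),
#'   descending by importance, ties broken by feature name.
#' @export
permutation_importance <- function(model, fm, y, n_repeats = 5, seed = 1L,
                                   features = NULL, groups = NULL) {
  stopifnot(n_repeats >= 1)
  x <- feature_x(fm)
  base_pred <- predict(model, x)
  base_mse <- mean((y - base_pred)^2)
  units <- as.list(features %||% model$features)
  names(units) <- unlist(lapply(units, paste, collapse = "+"))
  if (!is.null(groups)) units <- c(units, groups)

  set.seed(seed)
  perms <- replicate(n_repeats, sample.int(nrow(x)), simplify = FALSE)
  score <- function(cols) {
    d <- vapply(perms, function(pr) {
      xp <- x
      xp[, cols] <- x[pr, cols, drop = FALSE]  # joint permutation
      mean((y - predict(model, xp))^2) - base_mse
    }, numeric(1))
    c(mean(d), sd(d))
  }
  res <- vapply(units, score, numeric(2))
  out <- tibble(feature = names(units),
                importance = res[1, ],
                sd = if (n_repeats > 1) res[2, ] else NA_real_)
  out <- out[order(-out$importance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  structure(out, method = "permutation",
            class = c("importance_ranking", class(out)))
}

#' Top management constraints from an importance ranking
#'
#' Convenience selector: the `k` highest-ranked features among the schema's
#' management group.
#' @param ranking an `importance_ranking`.
#' @param schema a [survey_schema()].
#' @param k how many to return.
#' @return character vector of feature names, most important first.
#' @export
top_management <- function(ranking, schema = survey_schema(), k = 2) {
  mg <- ranking$feature[ranking$feature %in% schema$management]
  if (length(mg) < k) {
    abort(paste0("need at least ", k, " management features in the ranking"))
  }
  mg[seq_len(k)]
}

#' Save / load a fitted yield model
#'
#' Persists the model with its feature schema, hyperparameters, seed,
#' training fingerprint and the package version that wrote it; loading
#' refuses files that lack those fields.
#'
#' @param model a `yield_model`.
#' @param path file path (conventionally `.rds`).
#' @return `save_yield_model()` returns `path` invisibly;
#'   `load_yield_model()` returns the `yield_model`.
#' @export
save_yield_model <- function(model, path) {
  stopifnot(inherits(model, "yield_model"))
  model$package_version <- as.character(utils::packageVersion("paddygap"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_yield_model
#' @export
load_yield_model <- function(path) {
  model <- readRDS(path)
  need <- c("forest", "features", "hyper", "seed", "fingerprint",
            "package_version")
  if (!inherits(model, "yield_model") || !all(need %in% names(model))) {
    abort("not a saved yield_model (missing schema/seed metadata)")
  }
  model
}
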