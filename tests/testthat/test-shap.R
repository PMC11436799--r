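test_that("exact Shapley of a single-feature model is f(x) minus the base", {
  f <- function(m) 2 * m[, 1]^2
  bg <- matrix(runif(20), ncol = 1, dimnames = list(NULL, "a"))
  x <- c(a = 0.7)
  phi <- exact_shapley(NULL, x, bg, predict_fun = f)
  expect_equal(unname(phi["a"]), 2 * 0.49 - mean(2 * bg[, 1]^2),
               tolerance = 1e-12)
})

test_that("exact Shapley of a linear model is coef times deviation from the background mean", {
  set.seed(11)
  coefs <- c(a = 1.5, b = -2, c = 0.5)
  f <- function(m) m %*% coefs
  bg <- matrix(runif(60), ncol = 3, dimnames = list(NULL, names(coefs)))
  x <- c(a = 0.9, b = 0.1, c = 0.5)
  phi <- exact_shapley(NULL, x, bg, predict_fun = f)
  expect_equal(phi, coefs * (x - colMeans(bg)), tolerance = 1e-12)
})

test_that("exact Shapley is symmetric for exchangeable features", {
  f <- function(m) m[, 1] + m[, 2] + m[, 1] * m[, 2]
  set.seed(12)
  bg <- matrix(runif(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  bg[, 2] <- bg[, 1]  # symmetric background
  phi <- exact_shapley(NULL, c(a = 0.8, b = 0.8), bg, predict_fun = f)
  expect_equal(unname(phi["a"]), unname(phi["b"]), tolerance = 1e-12)
})

test_that("exact Shapley refuses more than 12 features", {
  bg <- matrix(runif(26), ncol = 13)
  expect_error(exact_shapley(NULL, runif(13), bg, predict_fun = rowSums),
               "12 features")
})

test_that("a constant model attributes nothing", {
  set.seed(13)
  x <- matrix(runif(200 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- suppressWarnings(tiny_model(x, rep(3.3, 200)))
  sh <- shap_values(m, x, bg_size = 50, seed = 1)
  expect_true(all(sh$phi == 0))
  expect_equal(sh$base, 3.3, tolerance = 1e-12)
})

test_that("a stump splitting on one feature attributes everything to it", {
  set.seed(14)
  n <- 300
  x <- cbind(n_rate = runif(n, 0, 200), other = runif(n))
  y <- ifelse(x[, "n_rate"] > 100, 6, 3)
  m <- fit_yield_model(x, y, num_trees = 1, min_node_size = 50, seed = 2)
  sh <- shap_values(m, x, bg_size = 100, seed = 1)
  expect_true(all(abs(sh$phi[, "other"]) < 1e-12))
  expect_equal(sh$phi[, "n_rate"], sh$prediction - sh$base, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("fast attribution matches the exhaustive-subset oracle on a 6-feature model", {
  set.seed(15)
  n <- 50
  x <- matrix(runif(n * 6), ncol = 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * x[, 1] + x[, 2] * x[, 3] - x[, 4] + rnorm(n, 0, 0.1)
  m <- suppressWarnings(
    fit_yield_model(x, y, num_trees = 100, min_node_size = 5, seed = 3))
  sh <- shap_values(m, x, background = x)
  for (i in c(1, 17, 42)) {
    phi_oracle <- exact_shapley(m, x[i, ], x)
    expect_equal(sh$phi[i, ], phi_oracle, tolerance = 1e-4)
  }
  # additivity against the mean prediction, every record
  expect_lt(max(abs(sh$base + rowSums(sh$phi) - sh$prediction)), 1e-6)
})

test_that("attributions satisfy additivity on the full landscape", {
  sh <- big_shap()
  expect_lt(max(abs(sh$base + rowSums(sh$phi) - sh$prediction)), 1e-6)
})

test_that("mean-absolute ranking matches the direct formula and orders groups", {
  sh <- big_shap()
  r_all <- rank_importance(sh)
  expect_equal(r_all$mean_abs_shap,
               unname(sort(colMeans(abs(sh$phi)), decreasing = TRUE)))
  r_mgmt <- rank_importance(sh, group = "management")
  expect_true(all(r_mgmt$feature %in% survey_schema()$management))
  expect_setequal(r_mgmt$feature[1:2], c("n_rate", "irrigation_count"))
})

test_that("an all-zero attribution column ranks last with score zero", {
  sh <- fake_shap(phi_i = c(0.5, -0.2, 0.1), phi_n = c(0, 0, 0))
  r <- rank_importance(sh)
  expect_identical(r$feature[2], "n_rate")
  expect_identical(r$mean_abs_shap[2], 0)
})

test_that("cluster labels follow the sign rule with zero counted as non-limiting", {
  cl <- assign_clusters(fake_shap(phi_i = c(0.2, -0.3, 0, -0.1),
                                  phi_n = c(-0.1, 0.4, 0, -0.2)))
  expect_identical(as.character(cl$labels), c("I+N-", "I-N+", "I+N+", "I-N-"))
  cl_pos <- assign_clusters(fake_shap(phi_i = rep(0.1, 5), phi_n = rep(0.2, 5)))
  expect_identical(cl_pos$shares$share[cl_pos$shares$label == "I+N+"], 1)
  expect_equal(sum(cl_pos$shares$share), 1)
})

test_that("cluster shares are invariant to record and feature order", {
  sh <- big_shap()
  cl <- big_clusters()
  perm <- sample(nrow(sh$phi))
  sh_perm <- sh
  sh_perm$phi <- sh$phi[perm, c("weather_tmax", setdiff(colnames(sh$phi),
                                                        "weather_tmax"))]
  cl_perm <- assign_clusters(sh_perm)
  expect_identical(cl$shares$share, cl_perm$shares$share)
})

test_that("explaining records with a permuted feature order gives identical attributions", {
  set.seed(16)
  x <- matrix(runif(120 * 4), ncol = 4, dimnames = list(NULL, letters[1:4]))
  y <- x[, 1] + 2 * x[, 2] + rnorm(120, 0, 0.1)
  m <- suppressWarnings(tiny_model(x, y, min_node_size = 10))
  sh1 <- shap_values(m, x, background = x[1:30, ])
  sh2 <- shap_values(m, x[, c(3, 1, 4, 2)], background = x[1:30, c(2, 3, 4, 1)])
  expect_identical(sh1$phi, sh2$phi)
})

test_that("summary-plot data pairs each attribution with its scaled value", {
  sh <- big_shap()
  fm <- big_fm()
  d <- shap_summary_data(sh, fm, group = "management")
  expect_identical(levels(d$feature),
                   rank_importance(sh, "management")$feature)
  expect_equal(nrow(d), nrow(fm$x) * length(levels(d$feature)))
  one <- d[d$feature == "n_rate", ]
  expect_identical(one$phi, unname(sh$phi[, "n_rate"]))
  expect_true(all(one$scaled_value >= 0 & one$scaled_value <= 1))
})
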