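test_that("a constant target is predicted exactly everywhere", {
  set.seed(1)
  x <- matrix(runif(300 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m <- suppressWarnings(tiny_model(x, rep(4.2, 300)))
  p <- predict(m, x)
  expect_equal(p, rep(4.2, 300), tolerance = 1e-12)
  expect_length(unique(p), 1)
})

test_that("fit, predict and importance are deterministic under a fixed seed", {
  set.seed(2)
  x <- matrix(runif(400 * 4), ncol = 4,
              dimnames = list(NULL, letters[1:4]))
  y <- 2 * x[, 1] + x[, 2] + rnorm(400, 0, 0.2)
  m1 <- tiny_model(x, y, seed = 99)
  m2 <- tiny_model(x, y, seed = 99)
  probe <- matrix(runif(50 * 4), ncol = 4, dimnames = list(NULL, letters[1:4]))
  expect_identical(predict(m1, probe), predict(m2, probe))
  i1 <- permutation_importance(m1, x, y, seed = 5)
  i2 <- permutation_importance(m2, x, y, seed = 5)
  expect_identical(i1$importance, i2$importance)
})

test_that("prediction aligns columns by name and rejects schema mismatches", {
  set.seed(3)
  x <- matrix(runif(300 * 3), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- x[, 1] + rnorm(300, 0, 0.1)
  m <- tiny_model(x, y)
  shuffled <- x[, c("c", "a", "b")]
  expect_identical(predict(m, x), predict(m, shuffled))
  expect_error(predict(m, x[, 1:2]), "missing: c")
  bad <- cbind(x, d = 1)
  expect_error(predict(m, bad), "unexpected: d")
  # single record vs batch containing it
  expect_identical(predict(m, x[7, , drop = FALSE]), predict(m, x)[7])
})

test_that("fitting fails below the node-size floor and warns on small samples", {
  x <- matrix(runif(30 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_yield_model(x, runif(30), min_node_size = 50), "node size")
  expect_warning(fit_yield_model(x, runif(30), min_node_size = 5,
                                 num_trees = 50), "unstable")
})

test_that("a null feature scores near zero permutation importance", {
  # scored on held-out data: the forest inevitably fits some noise through
  # the null feature, which inflates its training-set importance
  set.seed(4)
  n <- 1000
  x <- cbind(signal = runif(n), null = runif(n))
  y <- 3 * x[, "signal"] + rnorm(n, 0, 0.3)
  tr <- 1:700
  m <- fit_yield_model(x[tr, ], y[tr], num_trees = 200, min_node_size = 50,
                       seed = 1)
  imp <- permutation_importance(m, x[-tr, ], y[-tr], n_repeats = 20, seed = 6)
  null_row <- imp[imp$feature == "null", ]
  signal_score <- imp$importance[imp$feature == "signal"]
  # indistinguishable from zero, or negligible against the real signal
  expect_lt(abs(null_row$importance),
            max(2 * null_row$sd, 0.02 * signal_score))
  expect_identical(imp$feature[1], "signal")
})

test_that("duplicated features dilute single scores but a joint permutation recovers them", {
  set.seed(5)
  n <- 200
  s <- runif(n)
  x_dup <- cbind(s1 = s, s2 = s, other = runif(n))
  y <- 3 * s + rnorm(n, 0, 0.2)
  m_dup <- tiny_model(x_dup, y, min_node_size = 10)
  imp <- permutation_importance(m_dup, x_dup, y, n_repeats = 5, seed = 7,
                                groups = list(pair = c("s1", "s2")))
  joint <- imp$importance[imp$feature == "pair"]
  single <- imp$importance[imp$feature %in% c("s1", "s2")]
  expect_gte(joint, max(single))
  # against an unduplicated fit, each single score is diluted
  x_one <- cbind(s1 = s, other = x_dup[, "other"])
  m_one <- tiny_model(x_one, y, min_node_size = 10)
  imp_one <- permutation_importance(m_one, x_one, y, n_repeats = 5, seed = 7)
  expect_lt(max(single), imp_one$importance[imp_one$feature == "s1"])
})

test_that("held-out R2 is close to the oracle R2 of the true response", {
  land <- big_landscape()
  fm <- big_fm()
  hold <- 4001:5000
  m <- fit_yield_model(fm$x[-hold, ], land$survey$yield_obs[-hold], seed = 7)
  pred <- predict(m, fm$x[hold, ])
  y <- land$survey$yield_obs[hold]
  r2 <- 1 - mean((y - pred)^2) / stats::var(y)
  mu <- land$ground_truth$true_yield[hold]
  r2_oracle <- 1 - mean((y - mu)^2) / stats::var(y)
  expect_lt(abs(r2 - r2_oracle), 0.1)
})

test_that("on zero-noise data the model explains at least 90% of variance held out", {
  land <- noiseless_landscape()
  fm <- encode_features(land$survey)
  hold <- 4001:5000
  m <- fit_yield_model(fm$x[-hold, ], land$survey$yield_obs[-hold], seed = 7)
  pred <- predict(m, fm$x[hold, ])
  y <- land$survey$yield_obs[hold]
  expect_gte(1 - mean((y - pred)^2) / stats::var(y), 0.9)
})

test_that("the planted dominant constraint ranks first among management features", {
  imp <- big_importance()
  expect_identical(imp$feature[1], "n_rate")
  expect_identical(top_management(imp), c("n_rate", "irrigation_count"))
})

test_that("models persist with schema and seed metadata", {
  f <- withr::local_tempfile(fileext = ".rds")
  m <- big_model()
  save_yield_model(m, f)
  m2 <- load_yield_model(f)
  expect_identical(m2$features, m$features)
  expect_identical(m2$seed, m$seed)
  expect_identical(m2$fingerprint, m$fingerprint)
  probe <- big_fm()$x[1:20, ]
  expect_identical(predict(m2, probe), predict(m, probe))
  saveRDS(list(a = 1), f)
  expect_error(load_yield_model(f), "saved yield_model")
})
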