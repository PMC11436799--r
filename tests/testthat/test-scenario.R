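test_that("scenario specs carry the canonical defaults and validate inputs", {
  expect_identical(scenario_spec(1)$n_rate_new, 125)
  expect_identical(scenario_spec(2)$n_rate_new, 180)
  expect_identical(scenario_spec(3)$targeting, "n_negative")
  s4 <- scenario_spec(4)
  expect_identical(s4$irrigation_new, 5)
  expect_identical(s4$targeting, "co_limited")
  expect_identical(s4$prices$irrigation_cost, 20)
  expect_identical(s4$prices$n_cost, 0.14)
  expect_error(scenario_spec(5), "id")
  expect_error(scenario_spec(2, prices = list(n_cost = -1)), "prices")
  expect_error(scenario_spec(2, n_rate_new = -10), "n_rate_new")
})

test_that("a blanket scenario sets every field to the blanket rate, downward included", {
  land <- generate_survey(generator_config(n_fields = 300, n_districts = 3,
                                           seed = 6))
  ap <- apply_scenario(land$survey, scenario_spec(2))
  expect_true(all(ap$modified$n_rate == 180))
  expect_true(any(land$survey$n_rate > 180))  # some fields were adjusted down
  expect_identical(ap$mask, land$survey$n_rate != 180)
})

test_that("targeted scenarios change exactly the fields selected by the sign rule", {
  land <- generate_survey(generator_config(n_fields = 300, n_districts = 3,
                                           seed = 6))
  set.seed(1)
  phi_n <- rnorm(300)
  phi_i <- rnorm(300)
  cl <- assign_clusters(fake_shap(phi_i, phi_n))
  ap3 <- apply_scenario(land$survey, scenario_spec(3), cl)
  expect_identical(ap3$targeted, phi_n < 0)
  # targeted fields below 180 are raised to exactly 180; others untouched
  expect_true(all(ap3$modified$n_rate[ap3$targeted] >= 180 |
                    ap3$modified$n_rate[ap3$targeted] ==
                      land$survey$n_rate[ap3$targeted]))
  expect_identical(ap3$modified$n_rate[!ap3$targeted],
                   land$survey$n_rate[!ap3$targeted])
  expect_identical(ap3$mask, phi_n < 0 & land$survey$n_rate < 180)
  # scenario 4 targets a subset of scenario 3's fields
  ap4 <- apply_scenario(land$survey, scenario_spec(4), cl)
  expect_true(all(ap4$targeted <= ap3$targeted))
  expect_true(all(ap4$modified$irrigation_count[ap4$targeted] >= 5))
  # targeted scenarios need clusters
  expect_error(apply_scenario(land$survey, scenario_spec(4)), "cluster")
})

test_that("a co-limitation scenario with no co-limited fields changes nothing", {
  land <- generate_survey(generator_config(n_fields = 200, n_districts = 2,
                                           seed = 7))
  cl <- assign_clusters(fake_shap(rep(0.1, 200), rep(0.1, 200)))
  spec <- scenario_spec(4)
  ap <- apply_scenario(land$survey, spec, cl)
  expect_false(any(ap$mask))
  m <- big_model()
  res <- evaluate_scenario(m, land$survey, ap$modified, land$district_areas,
                           spec, ap$mask)
  expect_identical(res$total$dproduction_t, 0)
  expect_identical(res$total$dn_use_t, 0)
  expect_true(is.na(res$nue))
  expect_identical(res$per_adopter$n, 0L)
})

test_that("profit deltas satisfy the partial-net-return identity", {
  # hand arithmetic: 0.5 t/ha x 250 - 60 kg x 0.14 - 2 irr x 20 = 76.6 USD/ha
  expect_equal(0.5 * 250 - 60 * 0.14 - 2 * 20, 76.6)
  land <- big_landscape()
  cl <- big_clusters()
  spec <- scenario_spec(4)
  ap <- apply_scenario(land$survey, spec, cl)
  res <- evaluate_scenario(big_model(), land$survey, ap$modified,
                           land$district_areas, spec, ap$mask)
  f <- res$fields
  pr <- spec$prices
  expect_equal(f$dprofit,
               f$dyield * pr$paddy_price - f$dn * pr$n_cost -
                 f$dirr * pr$irrigation_cost,
               tolerance = 1e-12)
  # accounting identity: totals are the sum of district aggregates
  expect_equal(res$total$dproduction_t, sum(res$district$dproduction_t))
  expect_equal(res$total$dprofit_usd, sum(res$district$dprofit_usd))
  expect_equal(res$total$dn_use_t, sum(res$district$dn_use_t))
  # district production = mean per-field delta (non-adopters zero) x area
  d1 <- res$district[1, ]
  in_d <- f$district == d1$district
  expect_equal(d1$dproduction_t, mean(f$dyield[in_d]) * d1$rice_area_ha)
})

test_that("a missing district area is an error naming the district", {
  land <- generate_survey(generator_config(n_fields = 200, n_districts = 2,
                                           seed = 8))
  areas <- land$district_areas[-1, ]
  spec <- scenario_spec(2)
  ap <- apply_scenario(land$survey, spec)
  expect_error(evaluate_scenario(big_model(), land$survey, ap$modified,
                                 areas, spec, ap$mask),
               "D01")
})

test_that("targeting yields at least the blanket per-adopter gain", {
  land <- big_landscape()
  m <- big_model()
  cl <- big_clusters()
  gains <- vapply(2:4, function(id) {
    spec <- scenario_spec(id)
    ap <- apply_scenario(land$survey, spec, cl)
    evaluate_scenario(m, land$survey, ap$modified, land$district_areas,
                      spec, ap$mask)$per_adopter$mean_dyield
  }, numeric(1))
  expect_gte(gains[2], gains[1])  # targeted N beats blanket per adopter
  expect_gte(gains[3], gains[2])  # co-limitation targeting beats both
})

test_that("the derived blanket rate sits at the population response plateau", {
  br <- derive_blanket_rate(big_model(), big_fm())
  expect_true(br$rate >= 120 && br$rate <= 240)
  expect_equal(max(br$curve$mean_prediction),
               br$curve$mean_prediction[br$curve$level == br$rate],
               tolerance = 1e-9)
  # smallest-rate tie-break: no smaller grid rate achieves the maximum
  smaller <- br$curve$mean_prediction[br$curve$level < br$rate]
  if (length(smaller) > 0) {
    expect_true(all(smaller < max(br$curve$mean_prediction) - 1e-9))
  }
})
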