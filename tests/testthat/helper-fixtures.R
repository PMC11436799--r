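# Shared fixtures, computed lazily and cached for the whole test run.
# The "big" landscape is the reference study condition: 5,000 fields over
# 12 districts, yield noise 0.4 t/ha, planted N-depleted and
# irrigation-depleted circles, seed 42.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

big_landscape <- function() {
  fixture("big_landscape", function() generate_survey(generator_config(seed = 42)))
}

big_fm <- function() {
  fixture("big_fm", function() encode_features(big_landscape()$survey))
}

big_model <- function() {
  fixture("big_model", function() {
    fit_yield_model(big_fm(), big_landscape()$survey$yield_obs, seed = 7)
  })
}

big_shap <- function() {
  fixture("big_shap", function() {
    shap_values(big_model(), big_fm(), bg_size = 100, seed = 3)
  })
}

big_importance <- function() {
  fixture("big_importance", function() {
    permutation_importance(big_model(), big_fm(),
                           big_landscape()$survey$yield_obs,
                           seed = 5, features = survey_schema()$management)
  })
}

big_decomposition <- function() {
  fixture("big_decomposition", function() {
    decompose_sequential(big_model(), big_fm(), ranking = big_importance(),
                         table = big_landscape()$survey)
  })
}

big_clusters <- function() {
  fixture("big_clusters", function() {
    assign_clusters(big_shap(), districts = big_landscape()$survey$district)
  })
}

# Zero-noise twin of the big landscape (same seed and structure).
noiseless_landscape <- function() {
  fixture("noiseless_landscape", function() {
    generate_survey(generator_config(seed = 42, noise_sd = 0))
  })
}

noiseless_model <- function() {
  fixture("noiseless_model", function() {
    fit_yield_model(encode_features(noiseless_landscape()$survey),
                    noiseless_landscape()$survey$yield_obs, seed = 7)
  })
}

# Small ad-hoc regression forest on an arbitrary numeric matrix; returns the
# same yield_model structure the package functions expect.
tiny_model <- function(x, y, num_trees = 100, min_node_size = 5, seed = 1) {
  fit_yield_model(x, y, num_trees = num_trees,
                  min_node_size = min_node_size, seed = seed)
}

# Minimal hand-built shap_matrix for tests of the sign rules.
fake_shap <- function(phi_i, phi_n) {
  phi <- cbind(irrigation_count = phi_i, n_rate = phi_n)
  structure(list(phi = phi, base = 4, prediction = 4 + rowSums(phi),
                 features = colnames(phi), background = NULL),
            class = "shap_matrix")
}

# Haversine used by test oracles, written out (not the package helper).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371.0088) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Dense-matrix Gi* oracle: direct evaluation of the published formula.
oracle_gi_star <- function(lat, lon, x, band_km) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    w <- as.numeric(oracle_haversine_km(lat[i], lon[i], lat, lon) <= band_km)
    sw <- sum(w)
    z[i] <- (sum(w * x) - xbar * sw) /
      (s * sqrt((n * sw - sw^2) / (n - 1)))
  }
  z
}

true_n_gain <- function(n_rate, config = generator_config(seed = 42)) {
  p <- config$response_params
  cn <- log(2) / p$n_half
  p$n_max * (exp(-cn * pmin(n_rate, p$n_plateau)) - exp(-cn * p$n_plateau))
}

true_irr_gain <- function(irr, config = generator_config(seed = 42)) {
  p <- config$response_params
  ci <- log(2) / p$irr_half
  p$irr_max * (exp(-ci * pmin(irr, p$irr_plateau)) - exp(-ci * p$irr_plateau))
}

fields_in_circle <- function(survey, center) {
  oracle_haversine_km(survey$lat, survey$lon, center$lat, center$lon) <=
    center$radius_km
}
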