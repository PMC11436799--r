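#' Configuration for the synthetic survey-landscape generator
#'
#' Bundles every knob of [generate_survey()]: landscape size and spatial
#' extent, the true yield-response parameters, management-practice
#' distributions (including the nitrogen/irrigation co-limitation strata),
#' planted spatial constraint hotspots, the yield noise level, and the seed.
#'
#' The default landscape emulates an eastern Indo-Gangetic rice survey at
#' desk scale: 5,000 fields over 12 districts on a 2 x 2 degree extent,
#' yields of roughly 2-7 t/ha, a saturating nitrogen response that plateaus
#' at 180 kg N/ha, an irrigation response that plateaus at 5 events, and four
#' co-limitation strata (35% neither limited, 35% irrigation-limited, 20%
#' co-limited, 10% nitrogen-limited) with yield noise of 0.4 t/ha.
#'
#' @param n_fields number of field-year records (>= 10 x `n_districts`).
#' @param n_districts number of districts, laid out on a grid.
#' @param spatial_extent named numeric: `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` (decimal degrees WGS84).
#' @param response_params named list of true-response coefficients; see
#'   [true_response()] for meaning of each.
#' @param noise_sd standard deviation (t/ha) of additive Gaussian yield noise.
#' @param management_distributions named list: `strata` (probabilities of the
#'   `I+N+`, `I-N+`, `I-N-`, `I+N-` classes), `n_low`/`n_high` (kg N/ha ranges
#'   for limited/non-limited fields), `irr_low`/`irr_high` (irrigation count
#'   pools), ranges for P/K/Zn rates and sowing day, and weather moments.
#' @param hotspot_centers data frame of planted spatial constraint clusters:
#'   `lat`, `lon`, `radius_km`, `variable` (`"n_rate"` or
#'   `"irrigation_count"`), `sign` (`"-"` depletes the input inside the
#'   circle, `"+"` enriches it).
#' @param seed integer RNG seed; identical configs give bitwise-identical
#'   landscapes.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_fields = 5000,
                             n_districts = 12,
                             spatial_extent = c(lat_min = 25, lat_max = 27,
                                                lon_min = 84, lon_max = 86),
                             response_params = default_response_params(),
                             noise_sd = 0.4,
                             management_distributions = default_management_distributions(),
                             hotspot_centers = default_hotspot_centers(),
                             seed = 1L) {
  cfg <- list(n_fields = as.integer(n_fields),
              n_districts = as.integer(n_districts),
              spatial_extent = spatial_extent,
              response_params = utils::modifyList(default_response_params(),
                                                  as.list(response_params)),
              noise_sd = noise_sd,
              management_distributions = utils::modifyList(
                default_management_distributions(),
                as.list(management_distributions)),
              hotspot_centers = hotspot_centers,
              seed = as.integer(seed))
  cfg_err <- function(field, why) {
    abort(paste0("invalid generator config field '", field, "': ", why))
  }
  if (is.na(cfg$n_fields) || cfg$n_fields < 10 * cfg$n_districts) {
    cfg_err("n_fields", "need n_fields >= 10 * n_districts")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0) {
    cfg_err("noise_sd", "must be a non-negative number")
  }
  ext <- cfg$spatial_extent
  need <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(ext)) ||
      ext["lat_min"] >= ext["lat_max"] || ext["lon_min"] >= ext["lon_max"]) {
    cfg_err("spatial_extent", "need lat_min < lat_max and lon_min < lon_max")
  }
  md <- cfg$management_distributions
  if (abs(sum(md$strata) - 1) > 1e-8 || any(md$strata < 0)) {
    cfg_err("management_distributions$strata", "probabilities must sum to 1")
  }
  for (r in c("n_low", "n_high", "p_range", "k_range", "zn_range")) {
    if (any(md[[r]] < 0)) cfg_err(paste0("management_distributions$", r),
                                  "rates must be non-negative")
  }
  if (any(md$irr_low < 0) || any(md$irr_high < 0)) {
    cfg_err("management_distributions$irr_low/irr_high",
            "irrigation counts must be non-negative integers")
  }
  hs <- cfg$hotspot_centers
  if (!is.null(hs) && nrow(hs) > 0) {
    need_hs <- c("lat", "lon", "radius_km", "variable", "sign")
    if (!all(need_hs %in% names(hs))) {
      cfg_err("hotspot_centers", paste0("need columns ",
                                        paste(need_hs, collapse = ", ")))
    }
    if (!all(hs$variable %in% c("n_rate", "irrigation_count"))) {
      cfg_err("hotspot_centers$variable",
              "must be n_rate or irrigation_count")
    }
    if (!all(hs$sign %in% c("-", "+"))) {
      cfg_err("hotspot_centers$sign", "must be '-' or '+'")
    }
  }
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
default_response_params <- function() {
  list(intercept = 2.0,
       n_max = 2.5, n_half = 60, n_plateau = 180,     # kg N/ha
       irr_max = 1.5, irr_half = 3, irr_plateau = 5,  # events
       p_max = 0.3, p_half = 20,
       k_max = 0.2, k_half = 25,
       zn_max = 0.1, zn_half = 8,
       sowing_slope = -0.008, sowing_ref = 152,       # t/ha per day past ref
       srad_slope = 0.0012, srad_ref = 2000,          # t/ha per MJ m^-2
       tmax_slope = 0.06, tmax_ref = 33,              # t/ha per deg C
       variety_effect = 0.15)                         # t/ha per ordinal level
}

#' @rdname generator_config
#' @export
default_management_distributions <- function() {
  list(strata = c("I+N+" = 0.35, "I-N+" = 0.35, "I-N-" = 0.20, "I+N-" = 0.10),
       n_low = c(0, 60), n_high = c(140, 240),
       irr_low = 0:2, irr_high = 5:8,
       p_range = c(0, 60), k_range = c(0, 60), zn_range = c(0, 25),
       sowing_range = c(152, 213),
       srad = c(mean = 2000, sd = 120),
       tmax = c(mean = 33, sd = 1.2),
       variety_probs = c(short = 0.30, medium = 0.45, long = 0.25))
}

#' @rdname generator_config
#' @export
default_hotspot_centers <- function() {
  tibble(lat = c(25.45, 26.55), lon = c(84.45, 85.55),
         radius_km = c(15, 15),
         variable = c("n_rate", "irrigation_count"),
         sign = c("-", "-"))
}

saturating <- function(v, vmax, vhalf, vplateau = Inf) {
  vmax * (1 - exp(-log(2) / vhalf * pmin(v, vplateau)))
}

#' True expected yield of the synthetic response surface
#'
#' The generating model is additive: Mitscherlich-type saturating responses
#' to N, irrigation, P, K and Zn (half-saturation constants `*_half`, with
#' hard plateaus for N and irrigation beyond which extra input has exactly
#' zero effect), linear terms in the seasonal weather aggregates and sowing
#' day, and a small additive ordinal variety effect. The form is chosen to be
#' analytically differentiable so recovery tests can compare model-based
#' response estimates against closed-form truth.
#'
#' @param record data frame (one or more rows) with the predictor columns of
#'   [survey_schema()].
#' @param config a [generator_config()].
#' @return numeric vector of expected yields (t/ha), deterministic in the
#'   inputs.
#' @export
true_response <- function(record, config) {
  p <- config$response_params
  vcode <- match(as.character(record$variety_class),
                 c("short", "medium", "long")) - 1
  p$intercept +
    saturating(record$n_rate, p$n_max, p$n_half, p$n_plateau) +
    saturating(record$irrigation_count, p$irr_max, p$irr_half, p$irr_plateau) +
    saturating(record$p_rate, p$p_max, p$p_half) +
    saturating(record$k_rate, p$k_max, p$k_half) +
    saturating(record$zn_rate, p$zn_max, p$zn_half) +
    p$sowing_slope * (record$sowing_doy - p$sowing_ref) +
    p$srad_slope * (record$weather_srad - p$srad_ref) +
    p$tmax_slope * (record$weather_tmax - p$tmax_ref) +
    p$variety_effect * vcode
}

#' Analytic derivative of the true N response
#'
#' d(yield)/d(N) of [true_response()] at rate `n` (0 beyond the plateau);
#' used as the closed-form oracle in derivative-recovery tests.
#' @inheritParams true_response
#' @param n N rate (kg/ha).
#' @export
true_response_dN <- function(n, config) {
  p <- config$response_params
  c_n <- log(2) / p$n_half
  ifelse(n < p$n_plateau, p$n_max * c_n * exp(-c_n * n), 0)
}

#' Generate a synthetic survey landscape with ground truth
#'
#' Lays district centroids on a grid over the spatial extent, scatters fields
#' uniformly within their district cell, assigns each field to a
#' co-limitation stratum (which sets its N rate and irrigation count to a
#' "limited" or "non-limited" pool), overrides management inside planted
#' hotspot circles, draws weather per district with field-level jitter, and
#' produces observed yields as `true_response + N(0, noise_sd)` (floored at
#' 0.3 t/ha so every record passes validation).
#'
#' Ground truth records, per field: the true expected yield, whether the
#' field is N-limited and/or irrigation-limited (raising the input to its
#' plateau raises true expected yield by more than `noise_sd / 2`), and the
#' landscape's true attainable yield (top-decile mean of true expected
#' yields, same decile convention as [attainable_yield()]).
#'
#' @param config a [generator_config()].
#' @return list with `survey` (a validated `survey_table`), `ground_truth`
#'   (tibble: field_id, true_yield, n_limited, irrigation_limited, stratum,
#'   with attribute `attainable`), and `district_areas` (tibble: district,
#'   rice_area_ha).
#' @export
generate_survey <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  set.seed(config$seed)
  n <- config$n_fields
  md <- config$management_distributions
  ext <- config$spatial_extent

  # district grid: as-square-as-possible layout over the extent
  ncol_d <- ceiling(sqrt(config$n_districts))
  nrow_d <- ceiling(config$n_districts / ncol_d)
  d_idx <- sample(rep_len(seq_len(config$n_districts), n))
  d_col <- (d_idx - 1) %% ncol_d
  d_row <- (d_idx - 1) %/% ncol_d
  lon_w <- (ext["lon_max"] - ext["lon_min"]) / ncol_d
  lat_h <- (ext["lat_max"] - ext["lat_min"]) / nrow_d
  lon <- ext["lon_min"] + (d_col + runif(n)) * lon_w
  lat <- ext["lat_min"] + (d_row + runif(n)) * lat_h
  district <- sprintf("D%02d", d_idx)

  stratum <- sample(names(md$strata), n, replace = TRUE, prob = md$strata)
  n_lim_draw <- stratum %in% c("I-N-", "I+N-")
  i_lim_draw <- stratum %in% c("I-N-", "I-N+")
  n_rate <- ifelse(n_lim_draw,
                   runif(n, md$n_low[1], md$n_low[2]),
                   runif(n, md$n_high[1], md$n_high[2]))
  irrigation_count <- ifelse(i_lim_draw,
                             sample(md$irr_low, n, replace = TRUE),
                             sample(md$irr_high, n, replace = TRUE))

  # planted spatial clusters override the stratum draw inside each circle
  hs <- config$hotspot_centers
  if (!is.null(hs) && nrow(hs) > 0) {
    for (i in seq_len(nrow(hs))) {
      d_km <- haversine_km(lat, lon, hs$lat[i], hs$lon[i])
      inside <- d_km <= hs$radius_km[i]
      if (!any(inside)) next
      m <- sum(inside)
      if (hs$variable[i] == "n_rate") {
        rng <- if (hs$sign[i] == "-") md$n_low else md$n_high
        n_rate[inside] <- runif(m, rng[1], rng[2])
      } else {
        pool <- if (hs$sign[i] == "-") md$irr_low else md$irr_high
        irrigation_count[inside] <- sample(pool, m, replace = TRUE)
      }
    }
  }

  p_rate <- runif(n, md$p_range[1], md$p_range[2])
  k_rate <- runif(n, md$k_range[1], md$k_range[2])
  zn_rate <- runif(n, md$zn_range[1], md$zn_range[2])
  sowing_doy <- sample(seq(md$sowing_range[1], md$sowing_range[2]), n,
                       replace = TRUE)
  variety_class <- sample(names(md$variety_probs), n, replace = TRUE,
                          prob = md$variety_probs)

  # weather: district-level base + field jitter (spatially clustered)
  srad_base <- rnorm(config$n_districts, md$srad["mean"], md$srad["sd"])
  tmax_base <- rnorm(config$n_districts, md$tmax["mean"], md$tmax["sd"])
  weather_srad <- srad_base[d_idx] + rnorm(n, 0, md$srad["sd"] / 3)
  weather_tmax <- tmax_base[d_idx] + rnorm(n, 0, md$tmax["sd"] / 3)

  rec <- tibble(field_id = sprintf("F%05d", seq_len(n)),
                lat = as.numeric(lat), lon = as.numeric(lon),
                state = "State-1", district = district,
                year = sample(2017:2019, n, replace = TRUE),
                yield_obs = NA_real_,
                n_rate = n_rate, p_rate = p_rate, k_rate = k_rate,
                zn_rate = zn_rate, irrigation_count = irrigation_count,
                sowing_doy = sowing_doy, variety_class = variety_class,
                weather_srad = weather_srad, weather_tmax = weather_tmax)

  mu <- true_response(rec, config)
  noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
  rec$yield_obs <- pmax(mu + noise, 0.3)

  # limitation labels from the generating rule, on realised management
  rp <- config$response_params
  gain_n <- saturating(rp$n_plateau, rp$n_max, rp$n_half, rp$n_plateau) -
    saturating(rec$n_rate, rp$n_max, rp$n_half, rp$n_plateau)
  gain_i <- saturating(rp$irr_plateau, rp$irr_max, rp$irr_half, rp$irr_plateau) -
    saturating(rec$irrigation_count, rp$irr_max, rp$irr_half, rp$irr_plateau)
  gt <- tibble(field_id = rec$field_id,
               true_yield = mu,
               n_limited = gain_n > config$noise_sd / 2,
               irrigation_limited = gain_i > config$noise_sd / 2,
               stratum = stratum)
  cutoff <- quantile(mu, 0.9, names = FALSE)
  attr(gt, "attainable") <- mean(mu[mu >= cutoff])

  areas <- tibble(district = sprintf("D%02d", seq_len(config$n_districts)),
                  rice_area_ha = round(runif(config$n_districts, 5e4, 1.5e5)))

  survey <- validate_survey(rec, survey_schema(), state = "State-1")
  list(survey = survey, ground_truth = gt, district_areas = areas)
}

#' Write a generated landscape to CSV files
#'
#' Emits the survey table, the ground-truth table, and the district areas in
#' the CSV dialects the rest of the pipeline reads.
#'
#' @param landscape result of [generate_survey()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(survey = file.path(dir, "survey.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"),
             district_areas = file.path(dir, "district_areas.csv"))
  write_survey(landscape$survey, paths["survey"])
  write.csv(as.data.frame(landscape$ground_truth), paths["ground_truth"],
            row.names = FALSE)
  write.csv(as.data.frame(landscape$district_areas), paths["district_areas"],
            row.names = FALSE)
  invisible(paths)
}
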