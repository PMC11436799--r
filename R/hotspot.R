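# Getis-Ord Gi* hotspot statistic on per-field values (typically Shapley
# attributions), with a fixed great-circle distance band.

EARTH_RADIUS_M <- 6371008.8  # mean Earth radius, metres

haversine_km <- function(lat, lon, lat0, lon0) {
  geosphere::distHaversine(cbind(lon, lat), cbind(lon0, lat0),
                           r = EARTH_RADIUS_M) / 1000
}

#' Getis-Ord Gi* statistic with a fixed distance band
#'
#' For each field i, with binary self-inclusive weights `w_ij = 1` iff the
#' haversine distance between fields i and j is at most `band_km`:
#'
#' `z_i = (sum_j w_ij x_j - xbar * W_i) /
#'        (S * sqrt((n * W_i - W_i^2) / (n - 1)))`
#'
#' where `W_i = sum_j w_ij`, `xbar` and `S` are the mean and population
#' standard deviation of all n values. Large positive z marks a hot spot
#' (locally high values), large negative a cold spot. A field whose band
#' covers the whole landscape has a zero-over-zero statistic; it is
#' reported as z = 0 (no local deviation from the global mean). Isolated
#' fields (only themselves in the band) are retained and flagged via
#' `n_neighbors = 1`.
#'
#' @param lat,lon field coordinates, decimal degrees WGS84.
#' @param values per-field scalar (e.g. phi for N rate); must have positive
#'   variance.
#' @param band_km fixed distance band radius in km (default 10).
#' @return A `hotspot_result` tibble: lat, lon, value, z, n_neighbors; with
#'   attribute `band_km`.
#' @export
gi_star <- function(lat, lon, values, band_km = 10) {
  n <- length(values)
  stopifnot(length(lat) == n, length(lon) == n)
  if (n < 2) abort("need at least 2 fields")
  xbar <- mean(values)
  s2 <- mean(values^2) - xbar^2
  if (s2 <= 0) abort("degenerate field: values have zero variance")
  s <- sqrt(s2)
  z <- numeric(n)
  wn <- integer(n)
  pts <- cbind(lon, lat)
  for (i in seq_len(n)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                  r = EARTH_RADIUS_M) / 1000
    w <- d <= band_km            # binary, self-inclusive (d[i] = 0)
    W <- sum(w)
    wn[i] <- W
    denom <- s * sqrt((n * W - W^2) / (n - 1))
    z[i] <- if (denom == 0) 0 else (sum(values[w]) - xbar * W) / denom
  }
  structure(tibble(lat = lat, lon = lon, value = values, z = z,
                   n_neighbors = wn),
            band_km = band_km,
            class = c("hotspot_result", class(tibble())))
}

#' Classify Gi* z-scores into hot, cold, and not-significant
#'
#' Two-sided normal threshold: hot if `z >= z_(1-alpha/2)`, cold if
#' `z <= -z_(1-alpha/2)`, otherwise not significant (at alpha = 0.05 the
#' threshold is 1.96). Optionally applies a Benjamini-Hochberg correction
#' across fields before thresholding; the default is the raw classification
#' used on constraint maps.
#'
#' @param result a `hotspot_result`.
#' @param alpha significance level.
#' @param fdr apply Benjamini-Hochberg FDR correction across fields.
#' @return the input tibble with a `category` factor
#'   (`hot`/`cold`/`not significant`) added.
#' @export
classify_hotspots <- function(result, alpha = 0.05, fdr = FALSE) {
  z <- result$z
  if (fdr) {
    pv <- 2 * stats::pnorm(-abs(z))
    sig <- p.adjust(pv, method = "BH") <= alpha
  } else {
    zc <- qnorm(1 - alpha / 2)
    sig <- abs(z) >= zc
  }
  result$category <- factor(
    ifelse(sig & z > 0, "hot", ifelse(sig & z < 0, "cold", "not significant")),
    levels = c("hot", "cold", "not significant"))
  result
}
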