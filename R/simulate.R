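#' Default generating conditions per season and zone
#'
#' Stratum-level means used by the synthetic station-grid generator:
#' upper-50-m temperature (mean, SD and plausible range), salinity,
#' chlorophyll, copepod and chaetognath densities, mean gut fullness (NPC)
#' and seasonal mean wind speed, for a subtropical shelf/open-ocean system
#' sampled in summer, fall and winter. Temperatures peak in summer and
#' fall (> 24 degC) and drop in winter, neritic copepod densities exceed
#' oceanic ones in every season with a summer maximum, salinity is lowest
#' on the winter shelf (river influence) where chlorophyll peaks, and the
#' wind strengthens from summer to winter.
#'
#' @return A data frame with one row per season x zone stratum.
#' @export
stratum_defaults <- function() {
  data.frame(
    season = rep(c("summer", "fall", "winter"), each = 2L),
    zone = rep(c("neritic", "oceanic"), 3L),
    T_mean = c(26.6, 26.4, 27.3, 27.9, 20.5, 22.2),
    T_sd   = c(0.98, 0.98, 0.46, 0.46, 1.10, 0.70),
    T_min  = c(24.38, 24.38, 26.27, 26.27, 18.7, 21.7),
    T_max  = c(29.12, 29.12, 28.20, 28.20, 22.0, 23.1),
    S_mean = c(36.1, 36.3, 36.4, 36.5, 35.5, 36.2),
    S_sd   = c(0.15, 0.10, 0.10, 0.08, 0.45, 0.15),
    chl_mean = c(0.45, 0.25, 0.40, 0.20, 1.00, 0.30),
    copepod_mean = c(205.2, 45.3, 68.6, 30.6, 151.6, 51.6),
    chaetognath_mean = c(12, 4, 6, 3, 8, 4),
    npc = c(0.04, 0.04, 0.04, 0.04, 0.03, 0.03),
    wind = c(2.64, 2.64, 2.81, 2.81, 3.87, 3.87),
    bottom_min = c(20, 1000, 20, 1000, 20, 1000),
    bottom_max = c(200, 3500, 200, 3500, 200, 3500),
    stringsAsFactors = FALSE)
}

#' Scenario configuration for the synthetic generators
#'
#' Assembles the generating conditions for one season x zone stratum,
#' starting from [stratum_defaults()] and applying any overrides. Copepod
#' and chaetognath densities are drawn log-normally (plankton counts are
#' strictly positive and right-skewed) with the configured arithmetic mean
#' and coefficient of variation.
#'
#' @param season,zone Stratum selectors.
#' @param n_stations Number of stations to generate, >= 1.
#' @param seed Integer seed (mandatory: every generated dataset must be
#'   reproducible).
#' @param density_cv Coefficient of variation of the log-normal density
#'   draws (default 0.6).
#' @param ... Named overrides of any [stratum_defaults()] column.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(season = c("summer", "fall", "winter"),
                            zone = c("neritic", "oceanic"),
                            n_stations = 12, seed, density_cv = 0.6, ...) {
  season <- match.arg(season)
  zone <- match.arg(zone)
  if (missing(seed)) stop("a seed is mandatory for reproducible generation")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!is.numeric(n_stations) || n_stations < 1)
    stop("n_stations must be >= 1")
  if (density_cv <= 0) stop("density_cv must be > 0")
  base <- stratum_defaults()
  row <- base[base$season == season & base$zone == zone, ]
  cfg <- as.list(row)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) stop("unknown override(s): ", paste(bad, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (cfg$T_sd <= 0 || cfg$S_sd <= 0 || cfg$copepod_mean <= 0 ||
      cfg$chaetognath_mean <= 0 || cfg$chl_mean <= 0)
    stop("scale parameters must be > 0")
  cfg$n_stations <- as.integer(n_stations)
  cfg$seed <- as.integer(seed)
  cfg$density_cv <- density_cv
  structure(cfg, class = "scenario_config")
}

rlnorm_mean <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

# Linear-gradient + noise profile whose 0-50 m trapezoidal mean hits
# `target` exactly (a constant offset fixes it, since the mean is linear
# in the values).
make_profile <- function(depths, target, gradient, noise_sd, z_ref = 50) {
  v <- -gradient * depths + stats::rnorm(length(depths), 0, noise_sd)
  v + (target - integrate_upper_layer(depths, v, z_max = z_ref))
}

#' Generate a synthetic station grid with CTD profiles
#'
#' Draws `n_stations` stations for one stratum: integrated temperature,
#' salinity and chlorophyll from truncated normal distributions around the
#' configured stratum means, copepod and chaetognath densities from
#' log-normal distributions with the configured arithmetic means, and a
#' CTD cast per station built as a linear vertical gradient plus noise,
#' shifted so its upper-50-m trapezoidal mean equals the station's drawn
#' value exactly. Fully deterministic given the config's seed.
#'
#' @param config A [scenario_config()].
#' @param depth_step CTD sampling interval, m (default 5).
#' @return A list with `stations` (data frame, one row per station) and
#'   `ctd` (data frame of profiles: `station_id`, `depth_m`, `temp_c`,
#'   `sal_psu`, `chl_mg_m3`).
#' @examples
#' g <- generate_station_grid(scenario_config("summer", "neritic",
#'                                            n_stations = 4, seed = 7))
#' head(g$stations)
#' @export
generate_station_grid <- function(config, depth_step = 5) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_stations
  ids <- sprintf("%s-%s-%02d", substr(config$season, 1, 2),
                 substr(config$zone, 1, 3), seq_len(n))
  T_c <- rnorm_trunc(n, config$T_mean, config$T_sd, config$T_min, config$T_max)
  S <- rnorm_trunc(n, config$S_mean, config$S_sd,
                   config$S_mean - 4 * config$S_sd,
                   config$S_mean + 4 * config$S_sd)
  chl <- rlnorm_mean(n, config$chl_mean, 0.4)
  cop <- rlnorm_mean(n, config$copepod_mean, config$density_cv)
  cha <- rlnorm_mean(n, config$chaetognath_mean, config$density_cv)
  bottom <- stats::runif(n, config$bottom_min, config$bottom_max)
  dist_coast <- if (config$zone == "neritic") stats::runif(n, 5, 60)
                else stats::runif(n, 80, 300)
  stations <- data.frame(
    station_id = ids, season = config$season, zone = config$zone,
    temp_c = T_c, sal_psu = S, chl_mg_m3 = chl,
    bottom_depth_m = bottom, dist_coast_km = dist_coast,
    copepod_density_ind_m3 = cop, chaetognath_density_ind_m3 = cha,
    wind_speed_m_s = config$wind, stringsAsFactors = FALSE)

  ctd <- do.call(rbind, lapply(seq_len(n), function(i) {
    zmax <- max(60, min(200, floor(bottom[i])))
    z <- seq(0, zmax, by = depth_step)
    data.frame(station_id = ids[i], depth_m = z,
               temp_c = make_profile(z, T_c[i], gradient = 0.08, noise_sd = 0.05),
               sal_psu = make_profile(z, S[i], gradient = -0.002, noise_sd = 0.01),
               chl_mg_m3 = pmax(0.01, make_profile(z, chl[i], gradient = 0.002,
                                                   noise_sd = 0.02)),
               stringsAsFactors = FALSE)
  }))
  list(stations = stations, ctd = ctd)
}

#' Generate a synthetic gut survey
#'
#' Per-predator ingested-prey counts drawn Bernoulli(`true_NPC`) by default
#' (chaetognath guts typically hold at most one prey item), or Poisson for
#' mean gut fullness above one.
#'
#' @param n_predators Number of predators examined, >= 1.
#' @param true_NPC Generating mean prey count per gut, >= 0; must be <= 1
#'   in Bernoulli mode.
#' @param seed Integer seed.
#' @param mode `"bernoulli"` (default) or `"poisson"`.
#' @return A [gut_survey()].
#' @export
generate_gut_survey <- function(n_predators, true_NPC, seed,
                                mode = c("bernoulli", "poisson")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_predators) || n_predators < 1)
    stop("n_predators must be >= 1")
  if (!is.numeric(true_NPC) || !is.finite(true_NPC) || true_NPC < 0)
    stop("true_NPC must be finite and >= 0")
  if (mode == "bernoulli" && true_NPC > 1)
    stop("true_NPC > 1 requires mode = \"poisson\"")
  set.seed(seed)
  counts <- switch(mode,
    bernoulli = stats::rbinom(n_predators, 1L, true_NPC),
    poisson   = stats::rpois(n_predators, true_NPC))
  gut_survey(counts)
}

#' Generate a paired gut/habitat composition with known selection
#'
#' Habitat counts are multinomial with the supplied taxon probabilities;
#' gut counts are multinomial with those probabilities tilted by per-taxon
#' selection odds, \eqn{g_i \propto a_i \cdot o_i}. With all odds equal to
#' one the generating gut and habitat compositions coincide and the
#' expected electivity index of every taxon is 0.5.
#'
#' @param taxa Character vector of taxon names.
#' @param habitat_probs Habitat composition probabilities (sum to 1).
#' @param selection_odds Per-taxon selection odds, > 0 (scalar recycled).
#' @param N_G,N_A Totals for the gut and habitat samples.
#' @param seed Integer seed.
#' @return A list of two [composition_table()]s, `gut` and `habitat`.
#' @export
generate_diet_pair <- function(taxa, habitat_probs, selection_odds = 1,
                               N_G, N_A, seed) {
  stopifnot(is.character(taxa), is.numeric(habitat_probs))
  if (length(taxa) != length(habitat_probs))
    stop("taxa and habitat_probs lengths differ")
  if (abs(sum(habitat_probs) - 1) > 1e-8)
    stop("habitat_probs must sum to 1")
  selection_odds <- rep_len(selection_odds, length(taxa))
  if (any(selection_odds <= 0)) stop("selection odds must be > 0")
  if (N_G < 1 || N_A < 1) stop("sample totals must be >= 1")
  set.seed(seed)
  gut_probs <- habitat_probs * selection_odds
  gut_probs <- gut_probs / sum(gut_probs)
  A <- as.integer(stats::rmultinom(1L, N_A, habitat_probs))
  G <- as.integer(stats::rmultinom(1L, N_G, gut_probs))
  list(gut = composition_table(taxa, G), habitat = composition_table(taxa, A))
}
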