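#' Standardize a plankton count to individuals per cubic meter
#'
#' @param count Number of organisms in the sample, >= 0.
#' @param volume Volume of water filtered, m^3, > 0.
#' @return Density, ind/m^3.
#' @examples
#' standardize_density(1026, 5)   # 205.2 ind/m^3
#' @export
standardize_density <- function(count, volume) {
  stopifnot(is.numeric(count), is.numeric(volume))
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("filtered volume must be finite and > 0")
  if (any(!is.finite(count)) || any(count < 0))
    stop("count must be finite and >= 0")
  count / volume
}

#' Temperature-dependent digestion-time model
#'
#' Digestion time of one prey item decays exponentially with ambient
#' temperature: \eqn{DT(T) = a e^{-bT}} hours. The defaults (`a = 10.48` h,
#' `b = 0.086` per degC) describe copepod digestion by an epipelagic
#' chaetognath; at tropical temperatures they give digestion times of
#' roughly 0.9-2.1 h.
#'
#' @param a Pre-factor, hours (digestion time extrapolated to 0 degC), > 0.
#' @param b Temperature coefficient, 1/degC, > 0.
#' @return An object of class `digestion_model`.
#' @export
digestion_model <- function(a = 10.48, b = 0.086) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (!is.finite(a) || a <= 0) stop("pre-factor a must be > 0")
  if (!is.finite(b) || b <= 0) stop("temperature coefficient b must be > 0")
  structure(list(a = a, b = b), class = "digestion_model")
}

#' Digestion time at a given temperature
#'
#' @param model A [digestion_model()].
#' @param T_c Water temperature, degC. Vectorised; values must lie in a
#'   plausible oceanographic window (-2 to 40 degC).
#' @return Digestion time(s), hours; strictly decreasing in `T_c`.
#' @examples
#' digestion_time(digestion_model(), 29.12)   # ~0.86 h
#' digestion_time(digestion_model(), 18.72)   # ~2.09 h
#' @export
digestion_time <- function(model, T_c) {
  stopifnot(inherits(model, "digestion_model"), is.numeric(T_c))
  if (any(!is.finite(T_c))) stop("temperature must be finite")
  if (any(T_c < -2) || any(T_c > 40))
    stop("temperature outside the plausible window [-2, 40] degC")
  model$a * exp(-model$b * T_c)
}

#' Daily feeding rate from gut fullness and digestion time
#'
#' The classical gut-content estimator: if a predator holds on average `NPC`
#' prey in its gut and digests one prey in `DT` hours, it ingests
#' \eqn{FR = (NPC / DT) \times 24} prey per day at steady state.
#'
#' @param NPC Mean number of prey per predator gut, >= 0. Vectorised.
#' @param DT Digestion time, hours, > 0. Scalar or same length as `NPC`.
#' @return Feeding rate(s), prey/predator/day.
#' @examples
#' feeding_rate(NPC = 0.04, DT = 1.09)
#' @export
feeding_rate <- function(NPC, DT) {
  stopifnot(is.numeric(NPC), is.numeric(DT))
  if (any(!is.finite(DT)) || any(DT <= 0)) stop("digestion time DT must be > 0")
  if (any(!is.finite(NPC)) || any(NPC < 0)) stop("NPC must be finite and >= 0")
  (NPC / DT) * 24
}

#' Gut survey: per-predator ingested-prey counts
#'
#' Holds the individual gut counts of a sample of predators (prey found
#' near the mouth are excluded upstream, as possible cod-end feeding), so
#' that the mean gut fullness NPC and its standard error are computable.
#'
#' @param counts Non-negative integer vector, one element per predator.
#' @return An object of class `gut_survey` with elements `counts`,
#'   `n_predators`, `NPC`, `se_NPC`.
#' @examples
#' gut_survey(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
#' @export
gut_survey <- function(counts) {
  stopifnot(is.numeric(counts))
  if (length(counts) < 1L) stop("gut survey must contain at least one predator")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("gut counts must be non-negative integers")
  n <- length(counts)
  structure(list(counts = as.integer(counts), n_predators = n,
                 NPC = mean(counts),
                 se_NPC = if (n > 1L) stats::sd(counts) / sqrt(n) else NA_real_),
            class = "gut_survey")
}

#' @export
print.gut_survey <- function(x, ...) {
  cat(sprintf("Gut survey: %d predators, NPC = %.4f (SE %.4f)\n",
              x$n_predators, x$NPC, x$se_NPC))
  invisible(x)
}

#' One sampling station's environmental and density record
#'
#' @param season One of `"summer"`, `"fall"`, `"winter"`.
#' @param zone One of `"neritic"`, `"oceanic"`.
#' @param T_c Upper-50-m integrated mean temperature, degC.
#' @param S Salinity, psu.
#' @param chl Chlorophyll concentration, mg/m^3.
#' @param bottom_depth Bottom depth, m.
#' @param dist_coast Distance from the coast, km.
#' @param copepod_density Prey density, ind/m^3, >= 0.
#' @param chaetognath_density Predator density, ind/m^3, >= 0.
#' @param wind Mean wind speed, m/s, >= 0.
#' @param station_id Optional station identifier.
#' @return An object of class `station_record`.
#' @export
station_record <- function(season, zone, T_c, S = NA_real_, chl = NA_real_,
                           bottom_depth = NA_real_, dist_coast = NA_real_,
                           copepod_density = NA_real_,
                           chaetognath_density = NA_real_,
                           wind = NA_real_, station_id = NA_character_) {
  season <- match.arg(season, c("summer", "fall", "winter"))
  zone <- match.arg(zone, c("neritic", "oceanic"))
  if (!is.finite(T_c)) stop("station temperature must be finite")
  dens <- c(copepod_density, chaetognath_density, wind)
  if (any(dens < 0, na.rm = TRUE)) stop("densities and wind must be >= 0")
  structure(list(season = season, zone = zone, T_c = T_c, S = S, chl = chl,
                 bottom_depth = bottom_depth, dist_coast = dist_coast,
                 copepod_density = copepod_density,
                 chaetognath_density = chaetognath_density,
                 wind = wind, station_id = station_id),
            class = "station_record")
}

#' Station-level feeding rate with auditable intermediates
#'
#' Composes the gut-content estimator at one station: NPC from the gut
#' survey, digestion time from the station's integrated temperature, and
#' the daily feeding rate from both. The intermediates are returned so each
#' reported rate is traceable.
#'
#' @param station A [station_record()].
#' @param gut A [gut_survey()].
#' @param model A [digestion_model()].
#' @return A list with `NPC`, `DT_h`, `FR_per_day`, `n_predators`.
#' @export
station_feeding_rate <- function(station, gut, model = digestion_model()) {
  stopifnot(inherits(station, "station_record"), inherits(gut, "gut_survey"))
  DT <- digestion_time(model, station$T_c)
  list(NPC = gut$NPC, DT_h = DT, FR_per_day = feeding_rate(gut$NPC, DT),
       n_predators = gut$n_predators)
}

#' Depth-integrated mean of a CTD profile over the upper layer
#'
#' Trapezoidal mean \eqn{\int_0^{z_{max}} v(z)\,dz / z_{max}} of a profiled
#' variable over the upper `z_max` meters, the standard way station-level
#' environmental covariates are condensed from CTD casts. The profile is
#' linearly interpolated at `z_max` if no sample falls exactly there; a
#' profile shallower than `z_max` is averaged over its available span with
#' a warning.
#'
#' @param depth Depths of the profile samples, m, strictly increasing.
#' @param value Profiled variable at those depths.
#' @param z_max Integration depth, m (default 50).
#' @return The layer-mean value.
#' @examples
#' z <- seq(0, 100, by = 5)
#' integrate_upper_layer(z, 30 - 0.1 * z)   # exact for linear profiles: 27.5
#' @export
integrate_upper_layer <- function(depth, value, z_max = 50) {
  stopifnot(is.numeric(depth), is.numeric(value), length(depth) == length(value))
  if (length(depth) < 2L) stop("profile needs at least two points")
  if (any(!is.finite(depth)) || any(!is.finite(value)))
    stop("profile contains non-finite values")
  if (is.unsorted(depth, strictly = TRUE))
    stop("profile depths must be strictly increasing")
  top <- min(z_max, max(depth))
  if (top < z_max)
    warning(sprintf("profile reaches only %.1f m; averaging over [0, %.1f]",
                    max(depth), top))
  keep <- depth <= top
  z <- depth[keep]
  v <- value[keep]
  if (max(z) < top) {  # interpolate the cut point
    vi <- stats::approx(depth, value, xout = top)$y
    z <- c(z, top)
    v <- c(v, vi)
  }
  if (min(z) > 0) {  # extend the shallowest sample to the surface
    z <- c(0, z)
    v <- c(v[1L], v)
  }
  area <- sum(diff(z) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2)
  area / (max(z) - min(z))
}
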