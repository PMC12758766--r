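#' Encounter-kernel parameters for a planktonic predator-prey pair
#'
#' Bundles the geometric and kinematic parameters of the analytical
#' encounter kernels: the predator's perception (encounter) radius and the
#' swimming speeds of prey and predator. Defaults describe an ambush-feeding
#' chaetognath (motionless, 3 mm prey-detection radius) and an escaping
#' copepod (150 mm/s escape jump).
#'
#' @param R Perception radius of the predator, m. Must be > 0.
#' @param x Prey swimming speed, m/s. Must be >= 0.
#' @param y Predator swimming speed, m/s. Must be >= 0. Zero for an ambush
#'   predator.
#' @return An object of class `encounter_params`.
#' @examples
#' encounter_params()                  # ambush chaetognath vs copepod
#' encounter_params(R = 0.001, x = 0.05, y = 0.02)
#' @export
encounter_params <- function(R = 0.003, x = 0.150, y = 0) {
  stopifnot(is.numeric(R), length(R) == 1L, is.numeric(x), length(x) == 1L,
            is.numeric(y), length(y) == 1L)
  if (!is.finite(R) || R <= 0) stop("perception radius R must be finite and > 0")
  if (!is.finite(x) || x < 0) stop("prey speed x must be finite and >= 0")
  if (!is.finite(y) || y < 0) stop("predator speed y must be finite and >= 0")
  structure(list(R = R, x = x, y = y), class = "encounter_params")
}

#' @export
print.encounter_params <- function(x, ...) {
  cat("Encounter kernel parameters\n")
  cat(sprintf("  perception radius R: %g m\n", x$R))
  cat(sprintf("  prey speed x:        %g m/s\n", x$x))
  cat(sprintf("  predator speed y:    %g m/s\n", x$y))
  invisible(x)
}

# Bracketed speed term of the calm-water kernel, [(x+y)^3 - |x-y|^3]/(6xy),
# with its algebraic limit max(x, y) when one speed is zero. The expression
# is continuous there; only the literal division breaks down.
gs_speed_term <- function(x, y) {
  if (x == 0 && y == 0)
    stop("no relative motion: encounter rate undefined when both speeds are zero")
  if (x == 0 || y == 0) return(max(x, y))
  ((x + y)^3 - abs(x - y)^3) / (6 * x * y)
}

SECONDS_PER_DAY <- 86400

#' Calm-water (Gerritsen-Strickler) encounter rate
#'
#' Expected number of prey entering the predator's perception sphere per day
#' in still water, for two populations moving at constant speeds:
#' \deqn{C = 86\,400 \cdot \frac{\pi R^2 N}{6} \cdot
#'       \frac{(x+y)^3 - |x-y|^3}{x\,y}}
#' evaluated in SI units (m, m/s, ind/m^3) and converted to encounters per
#' day. When one speed is zero the algebraic limit is used, giving
#' \eqn{C = 86\,400\,\pi R^2 N \max(x, y)}; for an ambush predator
#' (\eqn{y = 0}) this is the flux of ballistic prey through the perception
#' sphere's cross-section.
#'
#' @param params An [encounter_params()] object.
#' @param N Prey density, ind/m^3. Vectorised; each element must be >= 0.
#' @return Encounter rate(s), prey/predator/day, same length as `N`.
#' @examples
#' p <- encounter_params()          # R = 3 mm, x = 150 mm/s, y = 0
#' gs_rate(p, 205.2)                # ~75 copepods/chaetognath/day
#' @seealso [ro_rate()] for the turbulence-augmented version.
#' @export
gs_rate <- function(params, N) {
  stopifnot(inherits(params, "encounter_params"), is.numeric(N))
  if (any(!is.finite(N)) || any(N < 0)) stop("prey density N must be finite and >= 0")
  SECONDS_PER_DAY * pi * params$R^2 * N * gs_speed_term(params$x, params$y)
}

#' Turbulent (Rothschild-Osborn) encounter rate
#'
#' Extends the calm-water kernel to wind-induced small-scale turbulence by
#' replacing each organism's speed \eqn{v} with \eqn{\sqrt{v^2 + w^2}},
#' where \eqn{w} is the root-mean-square turbulent velocity. For an ambush
#' predator (\eqn{y = 0}) the rate has the closed form
#' \deqn{C = 86\,400\,\pi R^2 N \, \frac{3x^2 + 4w^2}{3\sqrt{x^2 + w^2}}.}
#' At \eqn{w = 0} it reduces exactly to [gs_rate()].
#'
#' @inheritParams gs_rate
#' @param w Root-mean-square turbulent velocity, m/s, >= 0. Scalar or the
#'   same length as `N`.
#' @return Encounter rate(s), prey/predator/day.
#' @examples
#' p <- encounter_params()
#' ro_rate(p, 205.2, w = 0)       # identical to gs_rate(p, 205.2)
#' ro_rate(p, 205.2, w = 0.132)   # ~1.5x enhancement at the surface
#' @export
ro_rate <- function(params, N, w) {
  stopifnot(inherits(params, "encounter_params"), is.numeric(N), is.numeric(w))
  if (any(!is.finite(w)) || any(w < 0)) stop("turbulent velocity w must be finite and >= 0")
  if (any(!is.finite(N)) || any(N < 0)) stop("prey density N must be finite and >= 0")
  if (length(w) != 1L && length(w) != length(N))
    stop("w must be scalar or match length(N)")
  xs <- sqrt(params$x^2 + w^2)
  ys <- sqrt(params$y^2 + w^2)
  term <- mapply(gs_speed_term, xs, ys)
  SECONDS_PER_DAY * pi * params$R^2 * N * term
}

#' Turbulence enhancement factor for an ambush predator
#'
#' Ratio of the turbulent to the calm-water encounter rate for a motionless
#' predator (\eqn{y = 0}) and prey speed `x`:
#' \deqn{f(w) = \frac{3x^2 + 4w^2}{3x\sqrt{x^2 + w^2}}.}
#' `f(0) = 1` and `f` is strictly increasing in `w`; the prey density cancels.
#'
#' @param x Prey speed, m/s, > 0.
#' @param w Root-mean-square turbulent velocity, m/s, >= 0. Vectorised.
#' @return Dimensionless enhancement ratio(s) >= 1.
#' @examples
#' enhancement_factor(0.150, 0.150)   # 1.65
#' @export
enhancement_factor <- function(x, w) {
  stopifnot(is.numeric(x), length(x) == 1L, is.numeric(w))
  if (!is.finite(x) || x <= 0)
    stop("prey speed x must be > 0 (ratio undefined for a motionless pair)")
  if (any(!is.finite(w)) || any(w < 0)) stop("w must be finite and >= 0")
  (3 * x^2 + 4 * w^2) / (3 * x * sqrt(x^2 + w^2))
}

#' Calibrate the surface turbulent velocity from an observed enhancement
#'
#' Closed-form inverse of [enhancement_factor()]: given an observed ratio
#' `f` of turbulent to calm surface encounter rates for an ambush predator,
#' returns the root-mean-square turbulent velocity `w` that produces it.
#' Writing \eqn{q = \sqrt{1 + (w/x)^2}}, the enhancement is
#' \eqn{f = (4q^2 - 1)/(3q)}, whose admissible root is
#' \eqn{q = (3f + \sqrt{9f^2 + 16})/8}, so \eqn{w = x\sqrt{q^2 - 1}}.
#'
#' This is a calibration device: field studies typically report the
#' enhancement (or paired calm/turbulent rates) rather than `w` itself, and
#' the wind-to-`w` transfer function is site- and reference-dependent.
#'
#' @param f Observed enhancement ratio, >= 1. Vectorised.
#' @param x Prey speed, m/s, > 0.
#' @return Turbulent velocity `w`, m/s, such that
#'   `enhancement_factor(x, w) == f` to machine precision.
#' @examples
#' calibrate_surface_w(115.1 / 75.4, x = 0.150)   # ~0.132 m/s
#' @export
calibrate_surface_w <- function(f, x) {
  stopifnot(is.numeric(f), is.numeric(x), length(x) == 1L)
  if (!is.finite(x) || x <= 0) stop("prey speed x must be > 0")
  if (any(!is.finite(f)) || any(f < 1))
    stop("enhancement ratio f must be >= 1 (turbulence cannot reduce encounters)")
  q <- (3 * f + sqrt(9 * f^2 + 16)) / 8
  x * sqrt(pmax(q^2 - 1, 0))
}

#' Vertical turbulence specification
#'
#' Describes how the wind-driven root-mean-square turbulent velocity decays
#' with depth. The surface value `w0` is the physically meaningful input
#' (obtained e.g. from [calibrate_surface_w()]); the mean wind speed `W`
#' and turbulent kinetic energy `k` are carried as provenance metadata.
#'
#' @param w0 Surface rms turbulent velocity, m/s, >= 0.
#' @param decay_depth Depth scale of the decay, m, > 0: the e-folding depth
#'   for `"exponential"`, the extinction depth for `"linear_cutoff"`.
#' @param profile_mode One of `"exponential"` (default), `"linear_cutoff"`,
#'   `"constant"`.
#' @param W Mean wind speed, m/s (metadata).
#' @param k Turbulent kinetic energy, m^2/s^2 (metadata).
#' @return An object of class `turbulence_spec`.
#' @examples
#' turbulence_spec(w0 = 0.132, decay_depth = 12)
#' @export
turbulence_spec <- function(w0, decay_depth = 12,
                            profile_mode = c("exponential", "linear_cutoff",
                                             "constant"),
                            W = NA_real_, k = NA_real_) {
  profile_mode <- match.arg(profile_mode)
  stopifnot(is.numeric(w0), length(w0) == 1L,
            is.numeric(decay_depth), length(decay_depth) == 1L)
  if (!is.finite(w0) || w0 < 0) stop("w0 must be finite and >= 0")
  if (!is.finite(decay_depth) || decay_depth <= 0) stop("decay_depth must be > 0")
  structure(list(w0 = w0, decay_depth = decay_depth,
                 profile_mode = profile_mode, W = W, k = k),
            class = "turbulence_spec")
}

#' Turbulent velocity as a function of depth
#'
#' Evaluates the vertical profile `w(z)` implied by a [turbulence_spec()]:
#' `w0 * exp(-z / decay_depth)` (exponential), `w0 * max(0, 1 - z /
#' decay_depth)` (linear cutoff), or a depth-constant `w0`. All modes
#' satisfy `w(0) = w0` and are monotone non-increasing in depth.
#'
#' @param spec A [turbulence_spec()].
#' @param depths Depth grid, m, >= 0.
#' @return Numeric vector of turbulent velocities, m/s.
#' @export
turbulence_profile <- function(spec, depths) {
  stopifnot(inherits(spec, "turbulence_spec"), is.numeric(depths))
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depths must be finite and >= 0")
  switch(spec$profile_mode,
    exponential   = spec$w0 * exp(-depths / spec$decay_depth),
    linear_cutoff = spec$w0 * pmax(0, 1 - depths / spec$decay_depth),
    constant      = rep(spec$w0, length(depths)),
    stop("unknown profile_mode: ", spec$profile_mode)
  )
}

#' Vertical profile of calm and turbulent encounter rates
#'
#' Composes the two kernels over a depth grid: the calm-water rate is
#' depth-constant for a fixed prey density, while the turbulent rate decays
#' toward it as `w(z)` vanishes with depth.
#'
#' @inheritParams gs_rate
#' @param N Prey density, ind/m^3 (single value applied at all depths).
#' @param spec A [turbulence_spec()].
#' @param depths Depth grid, m.
#' @return A data frame with columns `depth`, `w`, `c_gs`, `c_ro` (rates in
#'   prey/predator/day).
#' @examples
#' p <- encounter_params()
#' ts <- turbulence_spec(w0 = calibrate_surface_w(1.53, 0.150), decay_depth = 12)
#' encounter_profile(p, N = 205.2, spec = ts, depths = seq(0, 60, by = 10))
#' @export
encounter_profile <- function(params, N, spec, depths) {
  stopifnot(is.numeric(N), length(N) == 1L)
  w <- turbulence_profile(spec, depths)
  c_gs <- rep(gs_rate(params, N), length(depths))
  c_ro <- ro_rate(params, rep(N, length(depths)), w)
  data.frame(depth = depths, w = w, c_gs = c_gs, c_ro = c_ro)
}
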