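#' Tapered-fiber specification
#'
#' Collects the optical parameters of the tapered fiber bundle in one
#' validated object. Angles are radians; lengths are micrometres. The
#' refractive-index pair `(n_core, n_clad)` feeds every formula that needs
#' core/cladding indices; `n_ext` (defaulting to `n_clad`) is the external
#' index in the normalized-frequency formula. Defaults are the device values
#' (core radius 0.6 um at the small end, 550 nm illumination, indices
#' 1.52 / 1.50).
#'
#' @param core_radius_um Fiber core radius (um).
#' @param wavelength_um Incident wavelength (um).
#' @param n_core,n_clad Core and cladding refractive indices (> 1).
#' @param n_ext External index for the V-number radicand; defaults to
#'   `n_clad`.
#' @param theta_s Entry angle (rad); kept as the arcsine argument as in the
#'   design formula, so `|theta_s| <= 1` is required where used.
#' @param delta Taper cone angle for the reflection-angle recursion (rad).
#' @param alpha Cone angle for the mode feature-angle recursion (rad).
#' @param theta Incidence angle at the core/cladding interface (rad), used
#'   by the penetration-depth formula.
#' @return A `foa_fiber_spec` list.
#' @export
tapered_fiber_spec <- function(core_radius_um = 0.6, wavelength_um = 0.55,
                               n_core = 1.52, n_clad = 1.50, n_ext = n_clad,
                               theta_s = 0.3, delta = 0.02, alpha = 0.02,
                               theta = 85 * pi / 180) {
  check_number(core_radius_um, "core_radius_um", lower = 0, strict_lower = TRUE)
  check_number(wavelength_um, "wavelength_um", lower = 0, strict_lower = TRUE)
  check_number(n_core, "n_core", lower = 1, strict_lower = TRUE)
  check_number(n_clad, "n_clad", lower = 1, strict_lower = TRUE)
  check_number(n_ext, "n_ext", lower = 1, strict_lower = TRUE)
  check_number(theta_s, "theta_s")
  check_number(delta, "delta", lower = 0)
  check_number(alpha, "alpha", lower = 0)
  check_number(theta, "theta", lower = 0, upper = pi / 2)
  structure(
    list(core_radius_um = core_radius_um, wavelength_um = wavelength_um,
         n_core = n_core, n_clad = n_clad, n_ext = n_ext, theta_s = theta_s,
         delta = delta, alpha = alpha, theta = theta),
    class = "foa_fiber_spec"
  )
}

#' Normalized frequency (V number) of the tapered fiber
#'
#' `V = 2 pi r / lambda * sqrt(n_core^2 - n_ext^2)`. A fiber with `V <
#' 2.405` carries only the fundamental mode, which minimizes modal
#' dispersion and hence image distortion.
#'
#' @param spec A [tapered_fiber_spec()].
#' @return The dimensionless V number.
#' @export
v_number <- function(spec = tapered_fiber_spec()) {
  if (spec$n_core < spec$n_ext) {
    stop_parameter("`n_core` must be at least `n_ext` for guided propagation.")
  }
  2 * pi * spec$core_radius_um / spec$wavelength_um *
    sqrt(spec$n_core^2 - spec$n_ext^2)
}

#' @describeIn v_number `TRUE` when `v_number(spec) < 2.405` (single-mode
#'   criterion).
#' @export
is_single_mode <- function(spec = tapered_fiber_spec()) {
  v_number(spec) < 2.405
}

#' Incidence angle after n reflections in the taper
#'
#' `phi_n = pi/2 - (n0/n1) * arcsin(theta_s) + (2n - 1) * delta / 2`, with
#' `n0/n1 = n_core/n_clad`: each reflection in the widening taper tilts the
#' ray by the cone angle, so the incidence angle at the core/cladding
#' interface grows with the reflection count and total internal reflection
#' is preserved.
#'
#' @param n Reflection count (integer >= 1; may be a vector).
#' @param spec A [tapered_fiber_spec()].
#' @return Angle(s) in radians.
#' @export
incident_angle <- function(n, spec = tapered_fiber_spec()) {
  if (any(n < 1) || any(n != round(n))) {
    stop_parameter("`n` must be positive integers.")
  }
  if (abs(spec$theta_s) > 1) {
    stop_parameter("`theta_s` must lie in [-1, 1] (arcsine argument).")
  }
  pi / 2 - (spec$n_core / spec$n_clad) * asin(spec$theta_s) +
    (2 * n - 1) * spec$delta / 2
}

#' Mode feature angle after n reflections
#'
#' `theta_n = (n0/n1) * arcsin(theta_s) - (n - 1) * alpha`: the propagating
#' mode's feature angle shrinks by the cone angle at every reflection, i.e.
#' the mode order drops as light travels from the small to the large end.
#'
#' @inheritParams incident_angle
#' @return Angle(s) in radians.
#' @export
mode_feature_angle <- function(n, spec = tapered_fiber_spec()) {
  if (any(n < 1) || any(n != round(n))) {
    stop_parameter("`n` must be positive integers.")
  }
  if (abs(spec$theta_s) > 1) {
    stop_parameter("`theta_s` must lie in [-1, 1] (arcsine argument).")
  }
  (spec$n_core / spec$n_clad) * asin(spec$theta_s) - (n - 1) * spec$alpha
}

#' Evanescent penetration depth
#'
#' `dp = lambda / (2 pi sqrt(n_core^2 sin^2(theta) - n_clad^2))`, valid in
#' the total-internal-reflection regime `n_core * sin(theta) > n_clad`;
#' strictly decreasing in the incidence angle, so steeper reflections leak
#' less near-field detail into the cladding.
#'
#' @param spec A [tapered_fiber_spec()].
#' @param theta Optional incidence angle (rad) overriding `spec$theta`.
#' @return Penetration depth in micrometres.
#' @export
penetration_depth <- function(spec = tapered_fiber_spec(), theta = NULL) {
  th <- theta %||% spec$theta
  radicand <- spec$n_core^2 * sin(th)^2 - spec$n_clad^2
  if (any(radicand <= 0)) {
    abort("Not in the total-internal-reflection regime: need n_core * sin(theta) > n_clad.",
          class = "foa_evanescent_error")
  }
  spec$wavelength_um / (2 * pi * sqrt(radicand))
}

#' Effective light-transmission area fraction of the hexagonal lattice
#'
#' `(pi / 3.464) * (d / D)^2` where `d` is the core radius and `D` the fiber
#' radius; at `d = D` this is the hexagonal disk-packing density
#' `pi / (2 sqrt(3)) ~ 0.9069`.
#'
#' @param d Core radius (um), `0 < d <= D`.
#' @param D Fiber radius (um).
#' @return Dimensionless area fraction.
#' @export
transmission_area_fraction <- function(d, D) {
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  if (d > D) stop_parameter("`d` (core radius) cannot exceed `D` (fiber radius).")
  (pi / 3.464) * (d / D)^2
}

#' Sampling period of a fiber-core lattice
#'
#' The spatial sampling period set by the core arrangement: `sqrt(3) * d`
#' for hexagonal packing and `2 * d` for a square grid (the corresponding
#' spatial frequencies are `1/(sqrt(3) d)` and `1/(2 d)`).
#'
#' @param d Core radius (um).
#' @param arrangement `"hexagonal"` or `"square"`.
#' @return Period in micrometres.
#' @export
resolution_period <- function(d, arrangement = c("hexagonal", "square")) {
  arrangement <- match.arg(arrangement)
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  if (arrangement == "hexagonal") sqrt(3) * d else 2 * d
}

#' Resolution gain of hexagonal over square packing
#'
#' Ratio of the square to the hexagonal sampling period, `2 / sqrt(3) ~
#' 1.1547`: hexagonal packing samples about 1.15x more finely at the same
#' core radius.
#'
#' @return Dimensionless gain.
#' @export
hex_over_square_gain <- function() {
  2 / sqrt(3)
}

#' Field-of-view area ratio
#'
#' Area of FOV `a` over area of FOV `b`, each given as `(width, height)`.
#'
#' @param a,b Length-2 positive numerics (width, height), any common length
#'   unit.
#' @return Dimensionless area ratio.
#' @export
fov_area_ratio <- function(a, b) {
  for (nm in c("a", "b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(v <= 0)) {
      stop_parameter(sprintf("`%s` must be two positive numbers (width, height).", nm))
    }
  }
  (a[1] * a[2]) / (b[1] * b[2])
}
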