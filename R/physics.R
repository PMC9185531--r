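# Electromagnetic groundwork for the echo simulator: the dielectric law
# linking glucose concentration to complex permittivity, Snell refraction,
# the s-polarized Fresnel reflection magnitude, and plane-wave propagation
# constants in a lossy medium.

# Vacuum constants (SI).
.eps0 <- 8.8541878128e-12
.mu0 <- 4e-7 * pi
.c0 <- 299792458

#' Dielectric properties of a glucose solution
#'
#' Container for the complex permittivity of a medium: relative permittivity
#' `eps_real` (the real part, dimensionless), loss part `eps_imag`
#' (dimensionless, equal to sigma / (eps0 * omega)), conductivity `sigma`
#' (S/m), relative permeability `mu` and the loss tangent
#' `tan(delta) = |eps_imag| / eps_real`.
#'
#' @param eps_real Relative permittivity, > 0.
#' @param loss_tangent Loss tangent, >= 0.
#' @param carrier_hz Frequency at which `sigma` is evaluated (Hz).
#' @param mu Relative permeability (default 1, non-magnetic media).
#' @return An object of class `medium_properties` (a named list).
#' @examples
#' medium_properties(7.8, 0.17)
#' @export
medium_properties <- function(eps_real, loss_tangent, carrier_hz = 77e9, mu = 1) {
  stopifnot_scalar_number(eps_real, "eps_real", lower = 1e-12)
  stopifnot_scalar_number(loss_tangent, "loss_tangent", lower = 0)
  stopifnot_scalar_number(carrier_hz, "carrier_hz", lower = 1e-12)
  omega <- 2 * pi * carrier_hz
  eps_imag <- loss_tangent * eps_real
  structure(
    list(
      eps_real = eps_real,
      eps_imag = eps_imag,
      sigma = eps_imag * .eps0 * omega,
      mu = mu,
      loss_tangent = loss_tangent,
      carrier_hz = carrier_hz
    ),
    class = "medium_properties"
  )
}

#' @export
print.medium_properties <- function(x, ...) {
  cat(sprintf(
    "<medium_properties> eps' = %.4g, eps'' = %.4g, tan(delta) = %.4g, sigma = %.4g S/m\n",
    x$eps_real, x$eps_imag, x$loss_tangent, x$sigma
  ))
  invisible(x)
}

#' Dielectric law: glucose concentration to permittivity coefficients
#'
#' Published millimetre-wave measurements report that over roughly
#' 0.7--1.2 mg/mL the relative permittivity of a glucose solution increases
#' and its loss tangent decreases with concentration. The simulator encodes
#' this with the simplest law reproducing both trends: affine in
#' concentration, `eps'(c) = a0 + a1 c` with `a1 > 0` and
#' `tan(delta)(c) = b0 - b1 c` with `b1 > 0`.
#'
#' The default coefficients are phenomenological: they are chosen so that, in
#' the default scene (thin solution cell in front of a metal plate at 77 GHz),
#' both the front-interface reflection and the attenuated back-plate return
#' contribute to the echo. They are not literal water-glucose permittivities.
#'
#' @param a0,a1 Intercept and slope of the relative permittivity law.
#' @param b0,b1 Intercept and (negated) slope of the loss-tangent law.
#' @param range Validity range of the law in mg/mL.
#' @return A `dielectric_law` object.
#' @export
dielectric_law <- function(a0 = 6, a1 = 2, b0 = 0.35, b1 = 0.16,
                           range = c(0.5, 1.5)) {
  stopifnot(a1 > 0, b1 > 0, length(range) == 2L, range[1] < range[2])
  if (b0 - b1 * range[2] < 0) {
    abort("loss tangent would be negative at the top of the validity range")
  }
  structure(list(a0 = a0, a1 = a1, b0 = b0, b1 = b1, range = range),
            class = "dielectric_law")
}

#' Map a glucose concentration to medium properties
#'
#' Evaluates the dielectric law at concentration `conc`: permittivity strictly
#' increasing and loss tangent strictly decreasing in concentration.
#'
#' @param conc Glucose concentration in mg/mL, inside `law$range`.
#' @param law A [dielectric_law()].
#' @param carrier_hz Carrier frequency in Hz (default 77 GHz).
#' @return A [medium_properties()] object.
#' @export
concentration_to_medium <- function(conc, law = dielectric_law(),
                                    carrier_hz = 77e9) {
  stopifnot_scalar_number(conc, "conc")
  if (conc < law$range[1] || conc > law$range[2]) {
    abort(sprintf(
      "concentration %.3g mg/mL outside the dielectric law's validity range [%g, %g]",
      conc, law$range[1], law$range[2]
    ))
  }
  medium_properties(
    eps_real = law$a0 + law$a1 * conc,
    loss_tangent = law$b0 - law$b1 * conc,
    carrier_hz = carrier_hz
  )
}

#' Refraction angle from Snell's law
#'
#' For non-magnetic media the ratio of the sines of the incidence and
#' transmission angles equals `sqrt(eps2 / eps1)`.
#'
#' @param theta_i Incidence angle in radians, in `[0, pi/2)`.
#' @param eps1,eps2 Relative permittivities of the incident and transmitting
#'   media.
#' @return Transmission angle in radians.
#' @export
snell_angle <- function(theta_i, eps1, eps2) {
  stopifnot_scalar_number(theta_i, "theta_i", lower = 0, upper = pi / 2 - 1e-12)
  stopifnot_scalar_number(eps1, "eps1", lower = 1e-12)
  stopifnot_scalar_number(eps2, "eps2", lower = 1e-12)
  s <- sin(theta_i) * sqrt(eps1 / eps2)
  if (s > 1) {
    abort("total internal reflection: sin(theta_i) * sqrt(eps1/eps2) > 1")
  }
  asin(s)
}

#' s-polarized Fresnel reflection magnitude
#'
#' Amplitude ratio `|E_R| / |E_0|` of the reflected perpendicular-polarized
#' (s) wave, `|sin(theta_i - theta_t) / sin(theta_i + theta_t)|`. The
#' equivalent admittance form
#' `|n1 cos(theta_i) - n2 cos(theta_t)| / (n1 cos(theta_i) + n2 cos(theta_t))`
#' with `n = sqrt(eps mu)` is used because it stays regular at normal
#' incidence, where the sine quotient degenerates to 0/0.
#'
#' @param theta_i,theta_t Incidence and transmission angles (radians).
#' @param m1,m2 [medium_properties()] of the two media.
#' @return Reflection magnitude in `[0, 1]`.
#' @export
reflection_coeff_s <- function(theta_i, theta_t, m1, m2) {
  n1 <- sqrt(m1$eps_real * m1$mu)
  n2 <- sqrt(m2$eps_real * m2$mu)
  num <- n1 * cos(theta_i) - n2 * cos(theta_t)
  den <- n1 * cos(theta_i) + n2 * cos(theta_t)
  if (abs(den) < 1e-300) abort("singular interface: zero admittance sum")
  abs(num) / den
}

#' Attenuation and phase constants of a lossy medium
#'
#' Decomposes the complex wavenumber `k = beta - i alpha` of a plane wave at
#' angular frequency `omega` in a medium with conductivity `sigma`:
#' \deqn{\beta = \omega \sqrt{\mu\epsilon/2}\sqrt{\sqrt{1 + (\sigma/\epsilon\omega)^2} + 1}}
#' \deqn{\alpha = \omega \sqrt{\mu\epsilon/2}\sqrt{\sqrt{1 + (\sigma/\epsilon\omega)^2} - 1}}
#' with \eqn{\mu,\epsilon} the absolute permeability and (real) permittivity.
#' Satisfies `beta^2 - alpha^2 == omega^2 mu eps` exactly, and `alpha == 0`
#' for a lossless medium.
#'
#' @param m A [medium_properties()] object.
#' @param omega Angular frequency in rad/s.
#' @return A list with `alpha` (Np/m) and `beta` (rad/m).
#' @export
propagation_constants <- function(m, omega) {
  stopifnot_scalar_number(omega, "omega", lower = 1e-12)
  eps_abs <- .eps0 * m$eps_real
  mu_abs <- .mu0 * m$mu
  # sigma / (eps * omega) is exactly the loss tangent
  t2 <- (m$sigma / (eps_abs * omega))^2
  base <- omega * sqrt(mu_abs * eps_abs / 2)
  list(
    alpha = base * sqrt(sqrt(1 + t2) - 1),
    beta = base * sqrt(sqrt(1 + t2) + 1)
  )
}

#' Plane-wave field after propagating a lossy path
#'
#' `E(r, t) = E0 exp(-alpha r) exp(i (omega t - beta r))`: exponential
#' amplitude decay at rate `alpha` and phase advance at rate `beta`.
#'
#' @param E0 Field amplitude at `r = 0` (arbitrary units).
#' @param alpha Attenuation constant (Np/m).
#' @param beta Phase constant (rad/m).
#' @param r Path length (m), >= 0.
#' @param omega Angular frequency (rad/s).
#' @param t Time (s).
#' @return Complex field value.
#' @export
attenuated_field <- function(E0, alpha, beta, r, omega = 0, t = 0) {
  stopifnot_scalar_number(r, "r", lower = 0)
  E0 * exp(-alpha * r) * exp(1i * (omega * t - beta * r))
}

#' Scene geometry of the radar bench
#'
#' @param incidence_angle Incidence angle at the solution surface (radians),
#'   default 0 (boresight).
#' @param solution_thickness One-way path length through the solution (m).
#'   The default 1.3 mm keeps the solution translucent at 77 GHz so the
#'   back-plate return contributes amplitude and phase to the echo.
#' @param backplate_reflectivity Reflection magnitude of the metal back plate,
#'   in `[0, 1]` (default 1).
#' @param carrier_hz Radar carrier frequency (Hz), default 77 GHz.
#' @return A `scene_geometry` object.
#' @export
scene_geometry <- function(incidence_angle = 0, solution_thickness = 1.3e-3,
                           backplate_reflectivity = 1, carrier_hz = 77e9) {
  stopifnot_scalar_number(incidence_angle, "incidence_angle", 0, pi / 2 - 1e-12)
  stopifnot_scalar_number(solution_thickness, "solution_thickness", lower = 1e-12)
  stopifnot_scalar_number(backplate_reflectivity, "backplate_reflectivity", 0, 1)
  structure(
    list(
      incidence_angle = incidence_angle,
      solution_thickness = solution_thickness,
      backplate_reflectivity = backplate_reflectivity,
      carrier_hz = carrier_hz
    ),
    class = "scene_geometry"
  )
}

#' Complex echo amplitude of the solution cell
#'
#' The received echo is modelled as the sum of the signal directly reflected
#' from the front interface of the solution and the signal that penetrates the
#' solution and is reflected by the metal plate at the back:
#' \deqn{A(c) = r_f + (1 - r_f^2)\, R_b\, e^{-2\alpha \ell}\, e^{-i 2\beta \ell}}
#' where \eqn{r_f} is the front Fresnel magnitude, \eqn{R_b} the back-plate
#' reflectivity, and \eqn{\ell} the one-way path through the solution
#' (thickness divided by the cosine of the refraction angle). Under the
#' default dielectric law every term grows with concentration (larger
#' permittivity raises \eqn{r_f}; smaller loss tangent lowers \eqn{\alpha})
#' and the round-trip phase stays inside a half-turn where the interference
#' is constructive, so `Mod(echo_amplitude(c, ...))` is strictly increasing
#' in `c` over the law's validity range.
#'
#' @param conc Glucose concentration (mg/mL).
#' @param geom A [scene_geometry()].
#' @param law A [dielectric_law()].
#' @return Complex echo amplitude (arbitrary units).
#' @export
echo_amplitude <- function(conc, geom = scene_geometry(), law = dielectric_law()) {
  air <- medium_properties(1, 0, carrier_hz = geom$carrier_hz)
  sol <- concentration_to_medium(conc, law, carrier_hz = geom$carrier_hz)
  theta_t <- snell_angle(geom$incidence_angle, air$eps_real, sol$eps_real)
  r_front <- reflection_coeff_s(geom$incidence_angle, theta_t, air, sol)
  omega <- 2 * pi * geom$carrier_hz
  pc <- propagation_constants(sol, omega)
  path <- geom$solution_thickness / cos(theta_t)
  back <- (1 - r_front^2) * geom$backplate_reflectivity *
    attenuated_field(1, pc$alpha, pc$beta, 2 * path)
  r_front + back
}
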