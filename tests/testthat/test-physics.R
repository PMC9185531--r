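# Dielectric law, Snell refraction, Fresnel reflection and lossy-medium
# propagation.

test_that("medium properties hold their invariants", {
  m <- medium_properties(7.8, 0.17)
  expect_gt(m$eps_real, 0)
  expect_equal(m$loss_tangent, abs(m$eps_imag) / m$eps_real, tolerance = 1e-12)
  expect_gt(m$sigma, 0)
  expect_error(medium_properties(-1, 0.1), "eps_real")
})

test_that("dielectric law is monotone: permittivity up, loss tangent down", {
  law <- dielectric_law()
  grid <- c(0.69, 0.81, 0.91, 1.03, 1.08)
  media <- lapply(grid, concentration_to_medium, law = law)
  eps <- vapply(media, `[[`, numeric(1), "eps_real")
  tand <- vapply(media, `[[`, numeric(1), "loss_tangent")
  # brute-force sort oracle over the 5-point grid
  expect_identical(eps, sort(eps))
  expect_identical(tand, sort(tand, decreasing = TRUE))
  expect_true(all(diff(eps) > 0))
  expect_true(all(diff(tand) < 0))
  # determinism: same input, identical output
  expect_identical(concentration_to_medium(0.91), concentration_to_medium(0.91))
  expect_error(concentration_to_medium(3), "validity range")
})

test_that("snell_angle inverts the sine ratio", {
  expect_equal(snell_angle(0.4, 5, 5), 0.4)
  expect_equal(snell_angle(0, 1, 9), 0)
  # theta_i = 30 deg, eps2/eps1 = 4 -> sin(theta_t) = 0.5 / 2
  expect_equal(snell_angle(pi / 6, 1, 4), asin(0.25), tolerance = 1e-12)
  expect_error(snell_angle(pi / 3, 9, 1), "total internal reflection")
})

test_that("s-wave Fresnel magnitude matches closed forms and trends", {
  air <- medium_properties(1, 0)
  m9 <- medium_properties(9, 0)
  # normal incidence, eps 1 -> 9: |1 - 3| / (1 + 3)
  expect_equal(reflection_coeff_s(0, 0, air, m9), 0.5, tolerance = 1e-12)
  # no impedance contrast
  expect_equal(reflection_coeff_s(0.3, 0.3, air, air), 0)
  # oblique case agrees with the sine-quotient form
  ti <- 0.5
  tt <- snell_angle(ti, 1, 4)
  m4 <- medium_properties(4, 0)
  expect_equal(reflection_coeff_s(ti, tt, air, m4),
               abs(sin(ti - tt) / sin(ti + tt)), tolerance = 1e-12)
  # larger eps2 at fixed theta_i -> larger reflection
  co <- vapply(c(2, 4, 6, 8), function(e2) {
    reflection_coeff_s(ti, snell_angle(ti, 1, e2), air,
                       medium_properties(e2, 0))
  }, numeric(1))
  expect_true(all(diff(co) > 0))
})

test_that("propagation constants obey the lossy-medium closed forms", {
  eps0 <- 8.8541878128e-12
  mu0 <- 4e-7 * pi
  omega <- 2 * pi * 77e9
  # lossless limit: alpha = 0, beta = omega sqrt(mu0 eps0 eps')
  m0 <- medium_properties(7.8, 0)
  pc0 <- propagation_constants(m0, omega)
  expect_equal(pc0$alpha, 0)
  expect_equal(pc0$beta, omega * sqrt(mu0 * eps0 * 7.8), tolerance = 1e-12)
  # doubling sigma (via loss tangent) strictly increases alpha
  a <- propagation_constants(medium_properties(7.8, 0.1), omega)$alpha
  b <- propagation_constants(medium_properties(7.8, 0.2), omega)$alpha
  expect_gt(b, a)
  # algebraic identity: beta^2 - alpha^2 == omega^2 mu eps
  for (tand in c(0, 0.1, 0.5, 2)) {
    m <- medium_properties(5.5, tand)
    pc <- propagation_constants(m, omega)
    expect_equal(pc$beta^2 - pc$alpha^2, omega^2 * mu0 * eps0 * 5.5,
                 tolerance = 1e-9 * pc$beta^2)
  }
})

test_that("attenuated field follows the exponential decay law", {
  expect_equal(Mod(attenuated_field(2, 50, 1000, 0)), 2)
  r <- 0.01
  expect_equal(Mod(attenuated_field(1, log(2) / r, 1e3, r)), 0.5,
               tolerance = 1e-12)
  # semigroup: doubling the path squares the relative magnitude
  m1 <- Mod(attenuated_field(1, 80, 1e3, r))
  m2 <- Mod(attenuated_field(1, 80, 1e3, 2 * r))
  expect_equal(m2, m1^2, tolerance = 1e-12)
  # phase = omega t - beta r (mod 2pi)
  f <- attenuated_field(1, 0, 700, 0.003, omega = 2 * pi * 10, t = 0.02)
  expect_equal(Arg(f), (2 * pi * 10 * 0.02 - 700 * 0.003) %% (2 * pi) - 2 * pi,
               tolerance = 1e-9)
})

test_that("echo amplitude reduces to the front term and grows with conc", {
  geom0 <- scene_geometry(backplate_reflectivity = 0)
  air <- medium_properties(1, 0)
  sol <- concentration_to_medium(0.91)
  front <- reflection_coeff_s(0, 0, air, sol)
  expect_equal(echo_amplitude(0.91, geom0), front + 0i, tolerance = 1e-12)
  # opaque-solution limit: huge loss kills the back term
  law_opaque <- dielectric_law(b0 = 0.95, b1 = 0.2)
  thick <- scene_geometry(solution_thickness = 0.05)
  sol_o <- concentration_to_medium(0.91, law_opaque)
  front_o <- reflection_coeff_s(0, 0, air, sol_o)
  expect_equal(Mod(echo_amplitude(0.91, thick, law_opaque)), front_o,
               tolerance = 1e-6)
  # the five calibration concentrations give strictly increasing magnitude
  mods <- vapply(c(0.69, 0.81, 0.91, 1.03, 1.08),
                 function(cc) Mod(echo_amplitude(cc)), numeric(1))
  expect_true(all(diff(mods) > 0))
})
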