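# Shared helpers: relative-tolerance expectation and independent oracles.

expect_rel <- function(object, expected, tol = 1e-6) {
  expect_true(is.finite(object))
  expect_lt(abs(object - expected), tol * abs(expected))
}

# Independent quadrature oracle for the Boltzmann orientation average:
# <cos theta> = int_{-1}^{1} u e^{x u} du / int_{-1}^{1} e^{x u} du,
# computed with the integrand scaled by e^{-x} for numerical safety.
langevin_quadrature <- function(x) {
  num <- stats::integrate(function(u) u * exp(x * (u - 1)), -1, 1,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  den <- stats::integrate(function(u) exp(x * (u - 1)), -1, 1,
                          rel.tol = 1e-10, abs.tol = 1e-12)$value
  num / den
}

# Closed-form steady conduction rise on a finite spherical domain with the
# bath imposed at R_out: T(r) = Q/(4 pi kappa) (1/r - 1/R_out).
conduction_closed_form <- function(Q, conductivity, r, R_out) {
  Q / (4 * pi * conductivity) * (1 / r - 1 / R_out)
}
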