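test_that("SLP field/frequency correction follows the f*H^2 law", {
  expect_equal(round_sig(correct_slp(15, 15, 410, 25.5, 465), 2), 49)
  expect_equal(round_sig(correct_slp(37, 24.8, 700, 25.5, 465), 2), 26)
  expect_equal(correct_slp(12, 20, 300, 20, 300), 12)
  expect_identical(correct_slp(12, 20, 300, 0, 300), 0)
  expect_error(correct_slp(12, 0, 300), class = "mg_error_invalid")
})

test_that("SLP correction is exactly multiplicative across conditions", {
  set.seed(53)
  for (i in 1:50) {
    slp <- 10^runif(1, -2, 3)
    a <- c(10^runif(1, 0.5, 2), 10^runif(1, 1.5, 3))
    b <- c(10^runif(1, 0.5, 2), 10^runif(1, 1.5, 3))
    cc <- c(10^runif(1, 0.5, 2), 10^runif(1, 1.5, 3))
    via_b <- correct_slp(correct_slp(slp, a[1], a[2], b[1], b[2]), b[1], b[2], cc[1], cc[2])
    direct <- correct_slp(slp, a[1], a[2], cc[1], cc[2])
    expect_rel(via_b, direct, 1e-12)
  }
})

test_that("per-particle heat rate is SLP times metal mass", {
  Q <- particle_heat_rate(30, 2400)
  expect_rel(Q, 6.68e-18, 1e-2)
  expect_equal(round_sig(Q, 1), 7e-18)
  expect_identical(particle_heat_rate(0, 2400), 0)
  expect_rel(particle_heat_rate(30, 1200), Q / 2, 1e-12)
})

test_that("steady conduction rise follows the 1/r law, reaching 1.5e-10 K at the ferritin surface", {
  Q <- particle_heat_rate(30, 2400)
  expect_equal(round_sig(steady_temp_rise(Q, 6e-9), 2), 1.5e-10)
  expect_lt(steady_temp_rise(Q, 1), 1e-18)  # decays to bath
  expect_rel(steady_temp_rise(Q, 3e-9), 2 * steady_temp_rise(Q, 6e-9), 1e-12)
  set.seed(61)
  r <- 10^runif(50, -9, -5)
  expect_equal(steady_temp_rise(Q, r) * r, rep(Q / (4 * pi * 0.61), 50))
  expect_error(steady_temp_rise(Q, 0), class = "mg_error_invalid")
})

test_that("interfacial temperature step is Q/(4 pi R^2 G)", {
  Q <- particle_heat_rate(30, 2400)
  expect_equal(round_sig(interface_temp_step(Q, 6e-9, 2e8), 1), 7e-11)
  expect_identical(interface_temp_step(0, 6e-9, 2e8), 0)
  expect_lt(interface_temp_step(Q, 6e-9, 1e30), 1e-30)  # perfect interface
  expect_error(interface_temp_step(Q, 6e-9, 0), class = "mg_error_invalid")
})

test_that("cell-surface rise treats surface particles as a uniform spherical source", {
  Q <- particle_heat_rate(30, 2400)
  expect_equal(round_sig(cell_surface_temp_rise(Q, 1e4, 5e-6), 2), 1.7e-9)
  expect_identical(cell_surface_temp_rise(Q, 0, 5e-6), 0)
  expect_rel(cell_surface_temp_rise(Q, 1, 6e-9), steady_temp_rise(Q, 6e-9), 1e-12)
})

test_that("brain-scale heating is 1.2e-4 W/g, a 1% addition to basal metabolism", {
  Q <- particle_heat_rate(30, 2400)
  P <- brain_heating_rate(Q, 1e4, 5e-6)
  expect_equal(round_sig(P, 2), 1.2e-4)
  expect_equal(round_sig(P / basal_brain_metabolic_rate(), 1), 0.01)
  expect_identical(brain_heating_rate(0, 1e4, 5e-6), 0)
})

test_that("temperature rises are additive in the heat rate", {
  q1 <- 3e-18
  q2 <- 5e-18
  expect_rel(steady_temp_rise(q1 + q2, 6e-9),
             steady_temp_rise(q1, 6e-9) + steady_temp_rise(q2, 6e-9), 1e-12)
  expect_rel(cell_surface_temp_rise(q1 + q2, 1e4, 5e-6),
             cell_surface_temp_rise(q1, 1e4, 5e-6) +
               cell_surface_temp_rise(q2, 1e4, 5e-6), 1e-12)
})

test_that("finite-difference conduction oracle agrees with the closed form and converges", {
  Q <- 6.68e-18
  Rs <- 6e-9
  Rd <- 6e-5  # outer bath boundary 1e4 source radii away
  err_at <- function(n) {
    p <- radial_heat_oracle(Q, Rs, Rd, n_shells = n)
    keep <- seq_len(nrow(p) - 1)
    exact <- conduction_closed_form(Q, 0.61, p$radius[keep], Rd)
    max(abs(p$rise[keep] - exact) / exact)
  }
  e500 <- err_at(500)
  e1000 <- err_at(1000)
  e2000 <- err_at(2000)
  expect_lt(e1000, 0.01)
  expect_lt(e2000, e500)  # second-order convergence under refinement
  # well inside the domain the profile is the infinite-bath 1/r law
  p <- radial_heat_oracle(Q, Rs, Rd, n_shells = 1000)
  inner <- p$radius <= Rd / 200  # far from the outer bath boundary
  exact_inf <- Q / (4 * pi * 0.61 * p$radius[inner])
  expect_lt(max(abs(p$rise[inner] - exact_inf) / exact_inf), 0.01)
})

test_that("conduction oracle is linear in Q and conductivity, and validates its grid", {
  p0 <- radial_heat_oracle(0, 6e-9, 6e-7, n_shells = 50)
  expect_true(all(p0$rise == 0))
  p1 <- radial_heat_oracle(1e-18, 6e-9, 6e-7, n_shells = 50)
  p2 <- radial_heat_oracle(1e-18, 6e-9, 6e-7, n_shells = 50, conductivity = 0.305)
  expect_equal(p2$rise, 2 * p1$rise)
  expect_error(radial_heat_oracle(1e-18, 6e-9, 6e-7, radii = c(6e-9, 5e-9, 6e-7)),
               class = "mg_error_invalid")
  expect_error(radial_heat_oracle(1e-18, 6e-9, 5e-9), class = "mg_error_invalid")
})

test_that("ferritin at its measured heating bound produces an immeasurably small rise", {
  rec <- table1_records()
  ferritin <- rec[rec$slp_is_upper_bound, ]
  expect_equal(nrow(ferritin), 1)
  expect_lt(ferritin$slp_corr_computed, 0.11)
  Q <- particle_heat_rate(ferritin$slp_corr_computed, 2400)
  expect_lt(steady_temp_rise(Q, 6e-9), 1e-12)
})
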