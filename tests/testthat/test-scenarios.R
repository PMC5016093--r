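test_that("built-in scenarios carry the published parameter sets", {
  sc <- builtin_scenarios()
  expect_true(all(c("qin-compass", "wheeler-static", "stanley-heating",
                    "highfield-5T") %in% sc$id))
  qin <- sc[sc$id == "qin-compass", ]
  expect_equal(qin$n_atoms, 40)
  expect_equal(qin$unpaired_electrons, 5)
  expect_equal(qin$B_T, 5e-5)
  expect_equal(qin$claimed_alignment, 0.45)
  wheeler <- sc[sc$id == "wheeler-static", ]
  expect_equal(wheeler$radius_m, 6e-9)
  expect_equal(wheeler$B_T, 0.05)
  expect_equal(wheeler$gradient_T_per_m, 6.6)
  expect_equal(wheeler$gradient_T_per_m_printed, 7)
  stanley <- sc[sc$id == "stanley-heating", ]
  expect_equal(stanley$ac_field_kA_per_m, 25.5)
  expect_equal(stanley$ac_frequency_kHz, 465)
  expect_equal(stanley$slp_W_per_g, 30)
  expect_equal(stanley$n_particles, 1e4)
  expect_equal(stanley$cell_radius_m, 5e-6)
  expect_true(all(nchar(sc$provenance) > 0))
})

test_that("the published SLP table has seven rows with bounds and discrepancies flagged", {
  rec <- table1_records()
  expect_equal(nrow(rec), 7)
  hergt <- rec[rec$reference == "hergt2004", ]
  expect_equal(unname(unlist(hergt[, c("d_nm", "H_kA_per_m", "f_kHz", "slp_W_per_g")])),
               c(7, 15, 410, 15))
  expect_equal(sum(rec$slp_is_upper_bound), 1)
  expect_equal(rec$slp_W_per_g[rec$slp_is_upper_bound], 0.01)
  expect_equal(rec$slp_corr_printed_W_per_g[rec$slp_is_upper_bound], 0.1)
  # exactly the two rows inconsistent with f*H^2 scaling are flagged
  expect_equal(sort(rec$reference[rec$scaling_discrepant]),
               c("ferritin_cobalt", "magnetite_8nm"))
  expect_rel(rec$slp_corr_computed[rec$reference == "magnetite_8nm"], 419, 5e-3)
  expect_rel(rec$slp_corr_computed[rec$reference == "ferritin_cobalt"], 30.1, 5e-3)
  # every non-flagged row's correction reproduces the published number
  expect_true(all(rec$corr_matches_printed[!rec$scaling_discrepant]))
})

test_that("random scenarios are seed-deterministic and respect their ranges", {
  a <- random_scenarios(5, seed = 42)
  b <- random_scenarios(5, seed = 42)
  expect_identical(a, b)
  expect_false(identical(random_scenarios(5, seed = 43)$xi_J_per_T2, a$xi_J_per_T2))
  expect_true(all(a$xi_J_per_T2 >= 1e-24 & a$xi_J_per_T2 <= 1e-20))
  expect_true(all(a$radius_m >= 2e-9 & a$radius_m <= 5e-8))
  expect_true(all(a$B_T >= 1e-5 & a$B_T <= 10))
  expect_true(all(a$slp_W_per_g >= 0.01 & a$slp_W_per_g <= 1e3))
  pinned <- random_scenarios(3, seed = 1, ranges = list(B = c(0.05, 0.05)))
  expect_true(all(pinned$B_T == 0.05))
  expect_error(random_scenarios(1, seed = 1, ranges = list(B = c(-1, 1))),
               class = "mg_error_invalid")
  expect_error(random_scenarios(1, seed = 1, ranges = list(banana = c(1, 2))),
               class = "mg_error_invalid")
})

test_that("randomly generated scenarios obey the exact scaling invariants", {
  sc <- random_scenarios(300, seed = 7)
  m <- induced_moment(sc$xi_J_per_T2, sc$B_T)
  f <- dipole_pair_force(m, 2 * sc$radius_m)
  # inverse-fourth law and quadratic field dependence, exactly
  expect_equal(dipole_pair_force(m, 4 * sc$radius_m), f / 16)
  expect_equal(dipole_pair_force(induced_moment(sc$xi_J_per_T2, 2 * sc$B_T),
                                 2 * sc$radius_m), 4 * f)
  pull <- gradient_pull_force(sc$xi_J_per_T2, sc$B_T, sc$gradient_T_per_m)
  expect_equal(gradient_pull_force(sc$xi_J_per_T2, 2 * sc$B_T, sc$gradient_T_per_m),
               2 * pull)
  expect_true(all(pull >= 0 & is.finite(pull)))
  # verdict engine accepts the generated rows
  v <- evaluate_scenarios(sc[1:5, ])
  expect_s3_class(v, "mg_verdicts")
  expect_true(all(is.finite(v$log_unit_gap)))
})

test_that("packaged fixtures round-trip through their readers", {
  rec <- susceptibility_records()
  expect_equal(nrow(rec), 3)
  expect_named(rec, c("source_label", "value", "convention",
                      "fe_per_particle", "particle_molar_mass", "note"))
  expect_setequal(unique(rec$convention), c("cgs_per_mol_fe", "si_per_mass"))
  sc <- builtin_scenarios()
  raw <- readr::read_csv(system.file("extdata", "scenarios.csv",
                                     package = "magnetolimits"),
                         show_col_types = FALSE)
  expect_equal(sc$xi_J_per_T2, raw$xi_J_per_T2)
  expect_equal(sc$B_T, raw$B_T)
})
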