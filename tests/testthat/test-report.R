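test_that("log-unit gap is log10(threshold/computed) and antisymmetric", {
  expect_rel(log_unit_gap(7e-23, 2e-13), 9.456, 1e-3)
  expect_equal(floor(log_unit_gap(7e-23, 2e-13)), 9)   # "at least 9"
  expect_identical(log_unit_gap(3.5, 3.5), 0)
  expect_gt(log_unit_gap(1.45e-10, 5), 10)             # "more than 10"
  set.seed(71)
  a <- 10^runif(50, -20, 5)
  b <- 10^runif(50, -20, 5)
  expect_equal(log_unit_gap(a, b), -log_unit_gap(b, a))
  expect_error(log_unit_gap(0, 1), class = "mg_error_invalid")
  expect_error(log_unit_gap(1, -1), class = "mg_error_invalid")
})

test_that("static-force scenario yields implausible verdicts across all four mechanisms", {
  v <- evaluate_scenario("wheeler-static")
  expect_s3_class(v, "mg_verdicts")
  expect_setequal(v$quantity, c("gradient_pull_force", "membrane_stress",
                                "dipole_pair_force", "dipole_escape_energy",
                                "anisotropy_energy"))
  expect_false(any(v$plausible))
  expect_true(all(v$log_unit_gap[v$headline] >= 4))
  expect_gte(v$log_unit_gap[v$quantity == "gradient_pull_force"], 9)
  expect_equal(round(v$log_unit_gap[v$quantity == "dipole_pair_force"]), 8)
  expect_gte(v$log_unit_gap[v$quantity == "dipole_escape_energy"], 8)
  expect_gte(v$log_unit_gap[v$quantity == "membrane_stress"], 6)
  expect_error(evaluate_scenario("no-such-scenario"), class = "mg_error_lookup")
})

test_that("compass scenario verdict sits about five log units below the claim", {
  v <- evaluate_scenario("qin-compass")
  gap <- v$log_unit_gap[v$quantity == "alignment_mean_cos"]
  expect_equal(round(gap), 5)
  expect_false(any(v$plausible))
})

test_that("heating without an AC drive produces zero heat and an infinite gap", {
  sc <- builtin_scenarios()
  sc <- sc[sc$id == "stanley-heating", ]
  sc$ac_field_kA_per_m <- 0
  v <- evaluate_scenarios(sc)
  expect_true(all(v$value == 0))
  expect_true(all(is.infinite(v$log_unit_gap)))
  expect_false(any(v$plausible))
})

test_that("verdict gaps are invariant to the unit system of the susceptibility input", {
  sc <- builtin_scenarios()
  sc <- sc[sc$id == "wheeler-static", ]
  direct <- evaluate_scenarios(sc, mode = "full")
  # same scenario, magnetizability re-derived through the CGS entry point
  chi_cgs <- convert_molar_susceptibility_si_to_cgs(
    sc$xi_J_per_T2 * mg_constants()$avogadro * mg_constants()$vacuum_permeability / 2400
  )
  sc$xi_J_per_T2 <- xi_from_molar_fe_susceptibility(chi_cgs, 2400)
  via_cgs <- evaluate_scenarios(sc, mode = "full")
  expect_equal(via_cgs$log_unit_gap, direct$log_unit_gap)
})

test_that("verdict and reproduction objects support tidy, glance and autoplot", {
  v <- evaluate_scenarios()
  expect_s3_class(tidy(v), "tbl_df")
  g <- glance(v)
  expect_equal(g$n_plausible, 0)
  expect_equal(g$mode, "replicate")
  rt <- reproduction_table()
  expect_s3_class(tidy(rt), "tbl_df")
  gr <- glance(rt)
  expect_equal(gr$n_headline, 12)
  expect_s3_class(autoplot(v), "ggplot")
  expect_s3_class(autoplot(rt), "ggplot")
})

test_that("full-precision mode reproduces every value not tied to the display-rounding path", {
  rt <- reproduction_table(mode = "full")
  stable <- !grepl("rounding path", rt$note) & !rt$flagged
  expect_true(all(rt$match[stable]))
  # path-dependent rows stay within a factor ~2 of the published numbers
  path_rows <- grepl("rounding path", rt$note)
  expect_true(any(path_rows))
  ratio <- rt$computed[path_rows] / rt$printed[path_rows]
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("reports serialize to CSV and JSON", {
  v <- evaluate_scenario("stanley-heating")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(v, csv, format = "csv")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(v))
  js <- withr::local_tempfile(fileext = ".json")
  write_report(v, js, format = "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$mode, "replicate")
  expect_equal(nrow(parsed$rows), nrow(v))
})
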