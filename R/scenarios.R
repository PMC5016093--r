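#' Built-in analysis scenarios
#'
#' The named parameter sets the plausibility analysis runs on, one row per
#' scenario, shipped as packaged data:
#'
#' * `qin-compass` — the molecular-compass claim: a 40-iron-atom complex in
#'   the ~50 uT geomagnetic field at room temperature, claimed alignment
#'   fraction 0.45.
#' * `wheeler-static` — ferritin tethered to a mechanosensitive channel under
#'   a ~0.05 T static field with ~6.6 T/m gradient (7 T/m in the displayed
#'   arithmetic; replicate mode uses the printed value).
#' * `highfield-5T` — the same static-force mechanisms extrapolated to a 5 T
#'   field, the practical upper limit before inductive artifacts.
#' * `stanley-heating` — ferritin tethered to TRPV1 driven at 25.5 kA/m and
#'   465 kHz, granting an engineered upper-bound SLP of 30 W/g of metal.
#' * `ferritin-measured` — the same heating chain at the measured
#'   non-detection bound for magnetite-core ferritin (SLP < 0.01 W/g at
#'   12.4 kA/m, 183 kHz).
#'
#' @return tibble, one row per scenario; columns irrelevant to a scenario's
#'   kind are `NA`. The `provenance` column summarises where each parameter
#'   value comes from.
#' @examples
#' builtin_scenarios()$id
#' @export
builtin_scenarios <- function() {
  readr::read_csv(
    mg_extdata("scenarios.csv"),
    col_types = readr::cols(
      id = readr::col_character(),
      kind = readr::col_character(),
      description = readr::col_character(),
      slp_is_upper_bound = readr::col_logical(),
      provenance = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Published specific-loss-power measurements for sub-10-nm particles
#'
#' Seven published SLP records for small magnetic nanoparticles (maghemite,
#' magnetite, and ferritin reconstituted with magnetite or cobalt-doped
#' magnetite cores), together with the published corrected values rescaled to
#' 25.5 kA/m and 465 kHz. The function recomputes the correction with the
#' f*H^2 law ([correct_slp()]) and compares against the published corrected
#' number at its printed precision:
#'
#' * `slp_corr_computed` — the f*H^2 correction of the measured SLP;
#' * `slp_corr_displayed` — the same, rounded to the printed precision;
#' * `corr_matches_printed` — whether that reproduces the published value;
#' * `scaling_discrepant` — `TRUE` for the rows whose published corrections
#'   are not reproduced by the stated scaling law (the 8-nm magnetite row,
#'   printed 75 vs computed ~420, and the cobalt-doped ferritin row, printed
#'   130 vs computed ~30). These are flagged, not silently corrected.
#'
#' Rows with `slp_is_upper_bound = TRUE` are non-detection bounds ("<"
#' values); their corrected values are upper bounds too.
#'
#' @param target_field,target_frequency conditions to correct to; defaults
#'   25.5 kA/m and 465 kHz.
#' @return tibble of 7 records with measured and corrected SLP columns.
#' @examples
#' table1_records()[, c("reference", "slp_W_per_g", "slp_corr_computed")]
#' @export
table1_records <- function(target_field = 25.5, target_frequency = 465) {
  rec <- readr::read_csv(
    mg_extdata("table1.csv"),
    col_types = readr::cols(
      reference = readr::col_character(),
      material = readr::col_character(),
      slp_is_upper_bound = readr::col_logical(),
      notes = readr::col_character(),
      printed_sig_digits = readr::col_integer(),
      .default = readr::col_double()
    )
  )
  rec |>
    mutate(
      slp_corr_computed = correct_slp(
        .data$slp_W_per_g, .data$H_kA_per_m, .data$f_kHz,
        target_field, target_frequency
      ),
      slp_corr_displayed = purrr::map2_dbl(
        .data$slp_corr_computed, .data$printed_sig_digits, round_sig
      ),
      corr_matches_printed = abs(.data$slp_corr_displayed - .data$slp_corr_printed_W_per_g) <=
        1e-9 * abs(.data$slp_corr_printed_W_per_g),
      scaling_discrepant = !.data$corr_matches_printed
    )
}

#' Randomized physically valid scenarios for property testing
#'
#' Draws scenario parameters log-uniformly within physically valid bounds.
#' Log-uniform sampling is the natural choice for an order-of-magnitude
#' analysis whose quantities span many decades. Deterministic for a fixed
#' seed; each emitted id records the seed.
#'
#' @param n number of scenarios to draw (>= 1).
#' @param seed integer seed.
#' @param ranges named list of `c(min, max)` bounds overriding the defaults:
#'   `xi` in J/T^2 (1e-24 to 1e-20), `radius` in m (2e-9 to 5e-8), `B` in T
#'   (1e-5 to 10), `gradient` in T/m (0.1 to 100), `slp` in W/g (0.01 to
#'   1e3), `field_kA_m` (5 to 50), `frequency_kHz` (50 to 1000). Bounds must
#'   be positive with min <= max; a degenerate range (min == max) pins the
#'   parameter.
#' @return tibble shaped like [builtin_scenarios()] rows of kind
#'   `"random"`, with all particle, field and heating parameters populated.
#' @examples
#' random_scenarios(3, seed = 1)$id
#' @export
random_scenarios <- function(n = 1, seed, ranges = NULL) {
  if (missing(seed)) mg_stop("`seed` is required for reproducibility.")
  check_finite(seed, "seed")
  check_pos(n, "n")
  defaults <- list(
    xi = c(1e-24, 1e-20),
    radius = c(2e-9, 5e-8),
    B = c(1e-5, 10),
    gradient = c(0.1, 100),
    slp = c(0.01, 1e3),
    field_kA_m = c(5, 50),
    frequency_kHz = c(50, 1000)
  )
  if (!is.null(ranges)) {
    bad <- setdiff(names(ranges), names(defaults))
    if (length(bad)) {
      mg_stop(paste0("unknown range name(s): ", paste(bad, collapse = ", ")))
    }
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
        mg_stop(sprintf("range `%s` must be positive c(min, max) with min <= max.", nm))
      }
      defaults[[nm]] <- r
    }
  }
  draw <- function(bounds, n) {
    if (bounds[1] == bounds[2]) {
      return(rep(bounds[1], n))
    }
    exp(stats::runif(n, log(bounds[1]), log(bounds[2])))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  tibble(
    id = sprintf("random-seed%d-%d", as.integer(seed), seq_len(n)),
    kind = "random",
    description = "log-uniformly sampled property-test scenario",
    temperature_K = 298,
    xi_J_per_T2 = draw(defaults$xi, n),
    radius_m = draw(defaults$radius, n),
    B_T = draw(defaults$B, n),
    gradient_T_per_m = draw(defaults$gradient, n),
    slp_W_per_g = draw(defaults$slp, n),
    ref_field_kA_per_m = draw(defaults$field_kA_m, n),
    ref_frequency_kHz = draw(defaults$frequency_kHz, n),
    ac_field_kA_per_m = 25.5,
    ac_frequency_kHz = 465,
    fe_per_particle = 2400,
    conductivity_W_per_mK = 0.61,
    boundary_conductance_W_per_m2K = 2e8,
    cell_radius_m = 5e-6,
    n_particles = 1e4,
    tissue_density_g_per_m3 = 1.03e6
  )
}

#' Default biophysical thresholds
#'
#' The thresholds computed quantities are compared against:
#' * `channel_gating_force` — 2e-13 N, the measured gating force of
#'   hair-cell mechanotransduction channels;
#' * `trpv4_stress` — 2 Pa (~20 dyn/cm^2) membrane shear stress to gate
#'   TRPV4;
#' * `piezo1_stress` — 5 Pa (~50 dyn/cm^2) for Piezo1;
#' * `trpv1_delta_T` — 5 K temperature rise to activate TRPV1;
#' * `thermal_energy` — kT at the working temperature, the floor any
#'   mechanical signal must clear to beat thermal noise.
#'
#' @param constants list from [mg_constants()].
#' @param temperature temperature for the kT entry (K); defaults to the
#'   constants' default.
#' @return named list of thresholds (SI units).
#' @examples
#' threshold_registry()$channel_gating_force
#' @export
threshold_registry <- function(constants = mg_constants(), temperature = NULL) {
  list(
    channel_gating_force = 2e-13,
    trpv4_stress = convert_stress_cgs_to_si(20),
    piezo1_stress = convert_stress_cgs_to_si(50),
    trpv1_delta_T = 5,
    thermal_energy = thermal_energy(temperature, constants)
  )
}
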