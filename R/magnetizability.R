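#' Single-particle magnetizability from molar-iron susceptibility (CGS)
#'
#' Derives the magnetizability xi of one (super)paramagnetic particle — the
#' proportionality m = xi * B between its induced moment and the applied flux
#' density — from a bulk susceptibility chi reported in CGS units per mole of
#' iron. The bulk relation M = chi * H = chi * B / mu0 is normalized per
#' particle by dividing by the number of particles per mole of iron,
#' N_A / fe_per_particle:
#'
#'   xi = fe_per_particle * chi_SI / (N_A * mu0),
#'
#' where chi_SI = chi_cgs * 4*pi*1e-6.
#'
#' @param chi_fe molar susceptibility, CGS emu per mol Fe (> 0).
#' @param fe_per_particle iron atoms per particle (>= 1); ferritin at the
#'   maximal reported loading of 23% w/w carries about 2400 Fe.
#' @param constants list from [mg_constants()].
#' @return xi in J/T^2 per particle.
#' @examples
#' xi_from_molar_fe_susceptibility(5.9e-3, 2400)  # 2.35e-22
#' xi_from_molar_fe_susceptibility(6.05e-3, 2400) # 2.41e-22
#' @export
xi_from_molar_fe_susceptibility <- function(chi_fe, fe_per_particle = 2400,
                                            constants = mg_constants()) {
  check_pos(chi_fe, "chi_fe")
  check_pos(fe_per_particle, "fe_per_particle")
  if (any(fe_per_particle < 1)) {
    mg_stop("`fe_per_particle` must be >= 1.")
  }
  chi_si <- convert_molar_susceptibility_cgs_to_si(chi_fe)
  fe_per_particle * chi_si / (constants$avogadro * constants$vacuum_permeability)
}

#' Single-particle magnetizability from mass susceptibility (SI)
#'
#' For a susceptibility reported per unit mass in the SI convention
#' A*m^2/(g*T) — i.e. moment per gram per tesla — the particle magnetizability
#' is the mass susceptibility times the particle mass:
#'
#'   xi = chi_mass * particle_molar_mass / N_A.
#'
#' Dimensional bookkeeping: with chi_mass already expressed as moment per
#' (mass x flux density), the mu0 appearing in the volume-susceptibility
#' relation xi = chi * mu0 / rho is absorbed into the unit convention, so no
#' explicit mu0 factor appears here.
#'
#' @param chi_mass mass susceptibility in A*m^2/(g*T) (> 0).
#' @param particle_molar_mass particle molar mass in g/mol (> 0); loaded
#'   ferritin weighs about 5.8e5 g/mol.
#' @param constants list from [mg_constants()].
#' @return xi in J/T^2 per particle.
#' @examples
#' xi_from_mass_susceptibility(2.5e-4, 5.8e5) # 2.41e-22
#' @export
xi_from_mass_susceptibility <- function(chi_mass, particle_molar_mass = 5.8e5,
                                        constants = mg_constants()) {
  check_pos(chi_mass, "chi_mass")
  check_pos(particle_molar_mass, "particle_molar_mass")
  chi_mass * particle_molar_mass / constants$avogadro
}

#' Single-particle magnetizability from a Curie-law effective moment
#'
#' If the susceptibility follows the Curie law with an effective moment
#' mu_eff (in Bohr magnetons) per metal atom, the particle magnetizability is
#'
#'   xi = n_atoms * (mu_eff * mu_B)^2 / (3 k T).
#'
#' This provides an independent cross-check on the unit conversions of the
#' susceptibility routes.
#'
#' @param mu_eff effective moment per atom in units of mu_B (> 0).
#' @param n_atoms metal atoms per particle (>= 1).
#' @param temperature temperature in K (> 0).
#' @param constants list from [mg_constants()].
#' @return xi in J/T^2 per particle.
#' @examples
#' xi_from_curie_moment(3.78, 2400, 298) # 2.39e-22
#' @export
xi_from_curie_moment <- function(mu_eff, n_atoms = 2400,
                                 temperature = NULL,
                                 constants = mg_constants()) {
  check_pos(mu_eff, "mu_eff")
  check_pos(n_atoms, "n_atoms")
  if (any(n_atoms < 1)) mg_stop("`n_atoms` must be >= 1.")
  if (is.null(temperature)) temperature <- constants$default_temperature
  check_pos(temperature, "temperature")
  mu <- mu_eff * constants$bohr_magneton
  n_atoms * mu^2 / (3 * constants$boltzmann * temperature)
}

#' Consensus magnetizability across independent derivations
#'
#' Arithmetic mean of the per-record magnetizabilities; in replicate mode the
#' mean is rounded to two significant digits (the precision at which the
#' consensus value 2.4e-22 J/T^2 is carried through the force calculations).
#'
#' @param xi numeric vector of magnetizabilities in J/T^2 (non-empty, > 0).
#' @param policy an [rounding_policy()]; replicate mode rounds the mean to
#'   2 significant digits.
#' @return consensus xi in J/T^2.
#' @examples
#' consensus_xi(c(2.35e-22, 2.41e-22, 2.41e-22)) # 2.4e-22
#' @export
consensus_xi <- function(xi, policy = rounding_policy("replicate", 2L)) {
  if (length(xi) == 0L) mg_stop("`xi` must be a non-empty vector.")
  check_pos(xi, "xi")
  m <- mean(xi)
  if (inherits(policy, "mg_rounding_policy") && policy$mode == "replicate") {
    m <- round_sig(m, 2L, policy$tie_rule)
  }
  m
}

#' Published ferritin susceptibility records
#'
#' The three bulk susceptibility measurements of native (horse-spleen)
#' ferritin used to derive the particle magnetizability, shipped as packaged
#' data. Each row states the value in its original normalization convention:
#' `cgs_per_mol_fe` (CGS emu per mole of iron) or `si_per_mass`
#' (A*m^2/(g*T)).
#'
#' @return tibble with columns `source_label`, `value`, `convention`,
#'   `fe_per_particle`, `particle_molar_mass`, `note`.
#' @examples
#' susceptibility_records()
#' @export
susceptibility_records <- function() {
  readr::read_csv(
    mg_extdata("susceptibility_records.csv"),
    col_types = readr::cols(
      source_label = readr::col_character(),
      value = readr::col_double(),
      convention = readr::col_character(),
      fe_per_particle = readr::col_double(),
      particle_molar_mass = readr::col_double(),
      note = readr::col_character()
    )
  )
}

#' Derive per-particle magnetizability for a table of susceptibility records
#'
#' Data-frame-first wrapper: takes a tibble shaped like
#' [susceptibility_records()] and appends the derived `xi` column, dispatching
#' on each record's normalization convention.
#'
#' @param records data frame with columns `value`, `convention`,
#'   `fe_per_particle`, `particle_molar_mass`.
#' @param constants list from [mg_constants()].
#' @return the input tibble with an added `xi` column (J/T^2).
#' @examples
#' derive_xi(susceptibility_records())
#' @export
derive_xi <- function(records, constants = mg_constants()) {
  if (!is.data.frame(records)) mg_stop("`records` must be a data frame.")
  needed <- c("value", "convention", "fe_per_particle", "particle_molar_mass")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    mg_stop(paste0("`records` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  known <- c("cgs_per_mol_fe", "si_per_mass")
  if (!all(records$convention %in% known)) {
    mg_stop("`convention` must be 'cgs_per_mol_fe' or 'si_per_mass'.")
  }
  records |>
    as_tibble() |>
    mutate(
      xi = purrr::pmap_dbl(
        list(.data$value, .data$convention, .data$fe_per_particle, .data$particle_molar_mass),
        function(value, convention, fe, mm) {
          if (convention == "cgs_per_mol_fe") {
            xi_from_molar_fe_susceptibility(value, fe, constants)
          } else {
            xi_from_mass_susceptibility(value, mm, constants)
          }
        }
      )
    )
}
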