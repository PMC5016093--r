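#' Physical constants used throughout the package
#'
#' Returns the set of physical constants the calculations rely on, optionally
#' with individual values overridden. All internal computation is SI; CGS
#' quantities are converted at entry points only.
#'
#' Defaults are CODATA-grade: the Bohr magneton is 9.274e-24 J/T and the
#' Boltzmann constant 1.380649e-23 J/K. Single-digit display values such as
#' "9e-24 J/T" are treated as display rounding, never as inputs. The default
#' temperature is 298 K (room temperature, at which kT = 4.11e-21 J), because
#' the historical susceptibility measurements and the alignment arguments are
#' referenced to room temperature rather than body temperature.
#'
#' @param overrides named list (or named arguments via `...`) of constants to
#'   replace; unknown names are an error. Values must be strictly positive.
#' @param ... individual overrides, e.g. `default_temperature = 310`.
#' @return named list with elements `bohr_magneton` (J/T), `boltzmann` (J/K),
#'   `vacuum_permeability` (N/A^2, exactly 4*pi*1e-7), `avogadro` (1/mol),
#'   `iron_molar_mass` (g/mol), `water_thermal_conductivity` (W/(m*K)),
#'   `default_temperature` (K).
#' @examples
#' mg_constants()$bohr_magneton
#' mg_constants(default_temperature = 310)$default_temperature
#' @export
mg_constants <- function(overrides = NULL, ...) {
  const <- list(
    bohr_magneton = 9.274e-24,
    boltzmann = 1.380649e-23,
    vacuum_permeability = 4 * pi * 1e-7,
    avogadro = 6.02214076e23,
    iron_molar_mass = 55.85,
    water_thermal_conductivity = 0.61,
    default_temperature = 298
  )
  overrides <- c(overrides, list(...))
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(const))
    if (length(bad)) {
      mg_stop(paste0("unknown constant(s): ", paste(bad, collapse = ", ")))
    }
    for (nm in names(overrides)) {
      check_pos(overrides[[nm]], nm)
      const[[nm]] <- overrides[[nm]]
    }
  }
  const
}

#' Significant-figure rounding policy
#'
#' The analysis is order-of-magnitude by construction and displays most
#' quantities at single-digit precision. A policy object makes both
#' computation paths expressible: `"full_precision"` performs no intermediate
#' rounding, while `"replicate"` rounds intermediate inputs to `sig_digits`
#' significant digits so that displayed arithmetic can be reproduced step by
#' step.
#'
#' @param mode `"replicate"` or `"full_precision"`.
#' @param sig_digits positive integer; defaults to 1 in replicate mode.
#' @param tie_rule `"half_even"` (default) or `"half_up"`. Half-even is the
#'   default because it reproduces displayed single-digit arithmetic such as
#'   2.5e-5 -> 2e-5.
#' @return list of class `mg_rounding_policy`.
#' @examples
#' rounding_policy("replicate")
#' @export
rounding_policy <- function(mode = c("replicate", "full_precision"),
                            sig_digits = 1L,
                            tie_rule = c("half_even", "half_up")) {
  mode <- match.arg(mode)
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(sig_digits) || length(sig_digits) != 1L ||
      !is.finite(sig_digits) || sig_digits < 1 || sig_digits != round(sig_digits)) {
    mg_stop("`sig_digits` must be a positive integer.")
  }
  structure(
    list(mode = mode, sig_digits = as.integer(sig_digits), tie_rule = tie_rule),
    class = "mg_rounding_policy"
  )
}

#' Round to a number of significant digits with an explicit tie rule
#'
#' Unlike [signif()], the tie rule is explicit: `"half_even"` (banker's
#' rounding, the default) or `"half_up"`. Vectorized over `x`. Floating-point
#' noise in the scaled mantissa is snapped at 12 significant digits before tie
#' handling so that values that are ties in exact arithmetic are treated as
#' ties.
#'
#' @param x finite numeric vector.
#' @param sig_digits number of significant digits (positive integer).
#' @param tie_rule `"half_even"` or `"half_up"`.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_sig(2.5e-5, 1)           # 2e-5 (tie to even)
#' round_sig(2.5e-5, 1, "half_up") # 3e-5
#' round_sig(6.68e-18, 1)         # 7e-18
#' @export
round_sig <- function(x, sig_digits = 1L, tie_rule = c("half_even", "half_up")) {
  tie_rule <- match.arg(tie_rule)
  check_finite(x, "x")
  if (!is.numeric(sig_digits) || length(sig_digits) != 1L || sig_digits < 1) {
    mg_stop("`sig_digits` must be a positive integer.")
  }
  out <- x
  nz <- x != 0
  if (any(nz)) {
    ax <- abs(x[nz])
    e <- floor(log10(ax))
    k <- sig_digits - 1 - e
    m <- signif(ax * 10^k, 12)
    r <- if (tie_rule == "half_even") round(m) else floor(m + 0.5)
    out[nz] <- sign(x[nz]) * r * 10^(-k)
  }
  out
}

# Apply a rounding policy to an intermediate value: identity in
# full_precision mode, round_sig in replicate mode.
apply_policy <- function(x, policy, sig_digits = policy$sig_digits) {
  if (policy$mode == "full_precision") {
    return(x)
  }
  round_sig(x, sig_digits, policy$tie_rule)
}

#' Convert molar magnetic susceptibility from CGS to SI
#'
#' One CGS unit (emu/mol) of molar susceptibility equals 4*pi*1e-6 SI units.
#'
#' @param chi_cgs finite numeric, molar susceptibility in CGS emu/mol.
#' @return susceptibility in the SI molar convention.
#' @examples
#' convert_molar_susceptibility_cgs_to_si(1)       # 1.2566e-5
#' convert_molar_susceptibility_cgs_to_si(5.9e-3)  # 7.414e-8
#' @export
convert_molar_susceptibility_cgs_to_si <- function(chi_cgs) {
  check_finite(chi_cgs, "chi_cgs")
  chi_cgs * 4 * pi * 1e-6
}

#' @rdname convert_molar_susceptibility_cgs_to_si
#' @param chi_si susceptibility in the SI molar convention.
#' @export
convert_molar_susceptibility_si_to_cgs <- function(chi_si) {
  check_finite(chi_si, "chi_si")
  chi_si / (4 * pi * 1e-6)
}

#' Convert stress from CGS (dyn/cm^2) to SI (Pa)
#'
#' Membrane-stress thresholds for mechanosensitive channels are quoted in
#' dyn/cm^2 in the physiology literature; 1 dyn/cm^2 = 0.1 Pa.
#'
#' @param stress non-negative numeric, dyn/cm^2.
#' @return stress in Pa.
#' @examples
#' convert_stress_cgs_to_si(20) # 2 Pa
#' @export
convert_stress_cgs_to_si <- function(stress) {
  check_nonneg(stress, "stress")
  stress * 0.1
}

#' Thermal energy kT
#'
#' @param temperature temperature in K (>= 0); defaults to the constants'
#'   `default_temperature`.
#' @param constants list from [mg_constants()].
#' @return energy in J.
#' @examples
#' thermal_energy(298) # 4.11e-21 J
#' @export
thermal_energy <- function(temperature = NULL, constants = mg_constants()) {
  if (is.null(temperature)) temperature <- constants$default_temperature
  check_nonneg(temperature, "temperature")
  constants$boltzmann * temperature
}

#' Read a package configuration file
#'
#' A small YAML file can override constants, the working temperature and the
#' rounding policy, e.g.:
#' ```yaml
#' constants:
#'   iron_molar_mass: 55.85
#' temperature: 310
#' rounding:
#'   mode: replicate
#'   sig_digits: 1
#'   tie_rule: half_even
#' ```
#'
#' @param path path to a YAML file.
#' @return list with elements `constants` (see [mg_constants()]),
#'   `temperature` (K) and `rounding` (an `mg_rounding_policy`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    mg_stop(sprintf("config file '%s' not found", path), class = "mg_error_lookup")
  }
  cfg <- yaml::read_yaml(path)
  const <- mg_constants(overrides = cfg$constants)
  temperature <- cfg$temperature %||% const$default_temperature
  check_pos(temperature, "temperature")
  r <- cfg$rounding %||% list()
  policy <- rounding_policy(
    mode = r$mode %||% "replicate",
    sig_digits = r$sig_digits %||% 1L,
    tie_rule = r$tie_rule %||% "half_even"
  )
  list(constants = const, temperature = temperature, rounding = policy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
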