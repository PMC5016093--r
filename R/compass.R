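#' Spin-only effective magnetic moment of an atom
#'
#' mu_eff = sqrt(n (n + 2)) mu_B for an atom with n unpaired electrons. For
#' iron, n is at most 5 (high-spin Fe3+).
#'
#' @param n_unpaired number of unpaired electrons (integer, 0 to 7).
#' @param constants list from [mg_constants()].
#' @return moment in J/T.
#' @examples
#' atom_effective_moment(5) # 5.49e-23 J/T
#' @export
atom_effective_moment <- function(n_unpaired, constants = mg_constants()) {
  check_finite(n_unpaired, "n_unpaired")
  if (any(n_unpaired < 0) || any(n_unpaired != round(n_unpaired))) {
    mg_stop("`n_unpaired` must be a non-negative integer.")
  }
  if (any(n_unpaired > 7)) {
    mg_stop("`n_unpaired` cannot exceed 7 (half-filled f shell).")
  }
  sqrt(n_unpaired * (n_unpaired + 2)) * constants$bohr_magneton
}

#' Maximal moment of a complex of atoms with perfectly aligned spins
#'
#' The most generous estimate of a multi-atom complex's permanent moment:
#' every atomic spin-only moment perfectly co-aligned,
#' m = n_atoms * sqrt(n (n + 2)) mu_B. No known mechanism produces such
#' alignment at room temperature for a few dozen dispersed iron atoms; this is
#' an upper bound used to test the compass claim on its most favorable terms.
#'
#' @param n_atoms number of atoms in the complex (>= 0).
#' @param n_unpaired unpaired electrons per atom (default 5, the iron
#'   maximum).
#' @param constants list from [mg_constants()].
#' @return moment in J/T.
#' @examples
#' complex_max_moment(40, 5)              # 2.19e-21 J/T
#' round_sig(complex_max_moment(40, 5), 1) # 2e-21
#' @export
complex_max_moment <- function(n_atoms, n_unpaired = 5, constants = mg_constants()) {
  check_nonneg(n_atoms, "n_atoms")
  n_atoms * atom_effective_moment(n_unpaired, constants)
}

#' Interaction energy of a magnetic moment with a field
#'
#' Returns the magnitude of the field-moment interaction energy: m*B for a
#' permanent moment, and m*B/2 for an induced moment (the factor 1/2 arises
#' because the moment is itself proportional to the field). Callers needing
#' the potential energy use the negative of the returned magnitude.
#'
#' @param m moment in J/T (>= 0).
#' @param B flux density in T (>= 0).
#' @param induced logical; `TRUE` for an induced (linear-response) moment.
#' @return energy magnitude in J.
#' @examples
#' field_interaction_energy(2e-21, 5e-5)                 # 1e-25 J
#' field_interaction_energy(1.2e-23, 0.05, induced = TRUE) # 3e-25 J
#' @export
field_interaction_energy <- function(m, B, induced = FALSE) {
  check_nonneg(m, "m")
  check_nonneg(B, "B")
  if (induced) 0.5 * m * B else m * B
}

#' Thermal alignment bias of a permanent moment in a weak field
#'
#' The dimensionless ratio x = m B / (k T) between the magnetic interaction
#' energy and the thermal energy per degree of freedom. For weak fields this
#' ratio is the order-of-magnitude proxy for the degree of orientational
#' alignment one can expect; the equilibrium mean alignment is the Langevin
#' function [langevin_mean_cosine()], which equals x/3 for small x.
#'
#' @param m moment in J/T (>= 0).
#' @param B flux density in T (>= 0).
#' @param temperature bath temperature in K (> 0).
#' @param constants list from [mg_constants()].
#' @return dimensionless ratio.
#' @examples
#' alignment_bias(2e-21, 5e-5, 298) # ~2.4e-5
#' @export
alignment_bias <- function(m, B, temperature = NULL, constants = mg_constants()) {
  check_nonneg(m, "m")
  check_nonneg(B, "B")
  if (is.null(temperature)) temperature <- constants$default_temperature
  check_pos(temperature, "temperature")
  m * B / thermal_energy(temperature, constants)
}

#' Langevin function
#'
#' L(x) = coth(x) - 1/x, the equilibrium mean cosine of the angle between a
#' classical permanent moment and the field at x = m B / (k T). Numerically
#' stable at both ends: a series expansion x/3 - x^3/45 + 2 x^5/945 is used
#' for |x| < 1e-3, and the direct form elsewhere (coth saturates for large x,
#' giving the 1 - 1/x asymptote).
#'
#' @param x dimensionless field-to-thermal energy ratio (finite).
#' @return L(x), in (-1, 1); in [0, 1) for x >= 0.
#' @examples
#' langevin(1)      # 0.3130
#' langevin(1e-6)   # ~3.33e-7 (x/3 regime)
#' @export
langevin <- function(x) {
  check_finite(x, "x")
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45 + 2 * xs^5 / 945
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Equilibrium mean alignment of a permanent moment
#'
#' Langevin orientation statistics: the Boltzmann-averaged cosine of the
#' angle between a permanent moment m and the applied field B at temperature
#' T, L(m B / k T). Serves as the exact counterpart to the order-of-magnitude
#' proxy [alignment_bias()] (they agree to within x^2/15 relative for small
#' x).
#'
#' @inheritParams alignment_bias
#' @return mean cosine, in [0, 1).
#' @examples
#' langevin_mean_cosine(2e-21, 5e-5, 298) # ~8.1e-6
#' @export
langevin_mean_cosine <- function(m, B, temperature = NULL, constants = mg_constants()) {
  langevin(alignment_bias(m, B, temperature, constants))
}
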