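#' Rescale a specific loss power to other field conditions
#'
#' Over the field/frequency range relevant to small-animal heating coils,
#' SLP varies proportionally to the drive frequency and to the square of the
#' field amplitude:
#' SLP(H, f) = SLP(H0, f0) * (f / f0) * (H / H0)^2.
#' The correction is exactly multiplicative, so chaining A -> B -> C equals
#' A -> C.
#'
#' @param slp measured specific loss power, W per g of metal (>= 0).
#' @param ref_field field amplitude of the measurement, kA/m (> 0).
#' @param ref_frequency drive frequency of the measurement, kHz (> 0).
#' @param target_field field amplitude to correct to, kA/m (>= 0); default
#'   25.5 kA/m.
#' @param target_frequency frequency to correct to, kHz (> 0); default
#'   465 kHz.
#' @return corrected SLP in W/g.
#' @examples
#' correct_slp(15, 15, 410) # 49 W/g at 25.5 kA/m, 465 kHz
#' @export
correct_slp <- function(slp, ref_field, ref_frequency,
                        target_field = 25.5, target_frequency = 465) {
  check_nonneg(slp, "slp")
  check_pos(ref_field, "ref_field")
  check_pos(ref_frequency, "ref_frequency")
  check_nonneg(target_field, "target_field")
  check_pos(target_frequency, "target_frequency")
  slp * (target_frequency / ref_frequency) * (target_field / ref_field)^2
}

#' Heat output of a single particle from its specific loss power
#'
#' Q = SLP * (mass of metal in the particle)
#'   = SLP * metal_atoms * molar_mass / N_A.
#'
#' @param slp specific loss power, W per g of metal (>= 0).
#' @param metal_atoms metal atoms per particle (>= 0); 2400 Fe for loaded
#'   ferritin.
#' @param molar_mass metal molar mass in g/mol (default iron, 55.85).
#' @param constants list from [mg_constants()].
#' @return heat rate in W per particle.
#' @examples
#' particle_heat_rate(30, 2400) # 6.68e-18 W
#' @export
particle_heat_rate <- function(slp, metal_atoms = 2400,
                               molar_mass = NULL,
                               constants = mg_constants()) {
  check_nonneg(slp, "slp")
  check_nonneg(metal_atoms, "metal_atoms")
  if (is.null(molar_mass)) molar_mass <- constants$iron_molar_mass
  check_nonneg(molar_mass, "molar_mass")
  slp * metal_atoms * molar_mass / constants$avogadro
}

#' Steady-state temperature rise around a heated sphere
#'
#' Fourier conduction from a steadily heated sphere into an infinite bath
#' gives a temperature rise above bath of T(r) = Q / (4 pi kappa r) at
#' distance r from the center.
#'
#' @param Q heat rate in W (>= 0).
#' @param r distance from the center in m (> 0).
#' @param conductivity medium thermal conductivity in W/(m*K) (> 0);
#'   default water, 0.61.
#' @return temperature rise in K.
#' @examples
#' steady_temp_rise(6.68e-18, 6e-9) # ~1.5e-10 K
#' @export
steady_temp_rise <- function(Q, r, conductivity = NULL,
                             constants = mg_constants()) {
  check_nonneg(Q, "Q")
  check_pos(r, "r")
  if (is.null(conductivity)) conductivity <- constants$water_thermal_conductivity
  check_pos(conductivity, "conductivity")
  Q / (4 * pi * conductivity * r)
}

#' Temperature step across the particle-water interface
#'
#' Interfacial (Kapitza) thermal resistance makes the temperature
#' discontinuous at a material boundary: for heat rate Q leaving a sphere of
#' radius R through an interface of conductance G,
#' dT = Q / (4 pi R^2 G).
#'
#' @param Q heat rate in W (>= 0).
#' @param radius particle radius in m (> 0).
#' @param conductance interfacial thermal conductance in W/(m^2*K) (> 0);
#'   2e8 is typical of coated nanoparticles in water.
#' @return temperature step in K.
#' @examples
#' interface_temp_step(6.68e-18, 6e-9, 2e8) # ~7e-11 K
#' @export
interface_temp_step <- function(Q, radius, conductance = 2e8) {
  check_nonneg(Q, "Q")
  check_pos(radius, "radius")
  check_pos(conductance, "conductance")
  Q / (4 * pi * radius^2 * conductance)
}

#' Surface temperature rise of a cell decorated with heated particles
#'
#' N particles on the surface of a spherical cell, treated as a uniform
#' spherical heat source, give an outside-temperature profile that again
#' falls off as 1/r; at the cell surface the rise is
#' T = Q * N / (4 pi kappa r_cell).
#'
#' @param Q heat rate per particle in W (>= 0).
#' @param n_particles particles on the cell surface (>= 0).
#' @param cell_radius cell radius in m (> 0).
#' @param conductivity medium conductivity in W/(m*K) (> 0); default water.
#' @return temperature rise in K.
#' @examples
#' cell_surface_temp_rise(6.68e-18, 1e4, 5e-6) # ~1.7e-9 K
#' @export
cell_surface_temp_rise <- function(Q, n_particles, cell_radius,
                                   conductivity = NULL,
                                   constants = mg_constants()) {
  check_nonneg(Q, "Q")
  check_nonneg(n_particles, "n_particles")
  check_pos(cell_radius, "cell_radius")
  if (is.null(conductivity)) conductivity <- constants$water_thermal_conductivity
  check_pos(conductivity, "conductivity")
  Q * n_particles / (4 * pi * conductivity * cell_radius)
}

#' Tissue-scale heating rate from per-cell particle load
#'
#' If every cell of radius r_cell in a tissue of density rho carries N
#' heated particles, the specific heating rate of the tissue is
#' P = Q * N / ((4/3) pi r_cell^3 rho), in W per g of tissue. Compare with
#' the basal metabolic rate of brain tissue, ~1.2e-2 W/g.
#'
#' @param Q heat rate per particle in W (>= 0).
#' @param n_particles particles per cell (>= 0).
#' @param cell_radius cell radius in m (> 0).
#' @param tissue_density tissue density in g/m^3 (> 0); default brain,
#'   1.03e6 g/m^3 (1.03 g/cm^3).
#' @return heating rate in W per g of tissue.
#' @examples
#' brain_heating_rate(6.68e-18, 1e4, 5e-6) # ~1.2e-4 W/g
#' @export
brain_heating_rate <- function(Q, n_particles, cell_radius,
                               tissue_density = 1.03e6) {
  check_nonneg(Q, "Q")
  check_nonneg(n_particles, "n_particles")
  check_pos(cell_radius, "cell_radius")
  check_pos(tissue_density, "tissue_density")
  Q * n_particles / ((4 / 3) * pi * cell_radius^3 * tissue_density)
}

#' Basal metabolic rate of brain tissue
#'
#' @return ~1.2e-2 W per g of tissue.
#' @export
basal_brain_metabolic_rate <- function() 1.2e-2

#' Finite-difference solution of steady radial heat conduction
#'
#' Numerical oracle for the analytic 1/r profile: solves the steady-state,
#' spherically symmetric conduction problem around a sphere of radius
#' `R_source` emitting heat at rate `Q`, with the bath temperature imposed at
#' `domain_radius`, by a conservative finite-volume discretization and a
#' tridiagonal (Thomas) solve. On a finite domain the exact rise above bath
#' is Q/(4 pi kappa) (1/r - 1/domain_radius); the discrete solution converges
#' to it under grid refinement, and approaches the infinite-bath 1/r law at
#' radii well inside the outer boundary.
#'
#' @param Q heat rate in W (>= 0).
#' @param R_source source sphere radius in m (> 0).
#' @param domain_radius outer boundary radius in m (> R_source).
#' @param n_shells number of radial shells (>= 10).
#' @param conductivity medium conductivity in W/(m*K) (> 0); default water.
#' @param grid `"geometric"` (default; natural for a 1/r solution) or
#'   `"uniform"` node spacing; alternatively supply `radii` directly.
#' @param radii optional strictly increasing vector of node radii from
#'   R_source to domain_radius, overriding `grid`/`n_shells`.
#' @return tibble with columns `radius` (m) and `rise` (K above bath).
#' @examples
#' prof <- radial_heat_oracle(6.68e-18, 6e-9, 6e-7, n_shells = 100)
#' head(prof)
#' @export
radial_heat_oracle <- function(Q, R_source, domain_radius, n_shells = 1000,
                               conductivity = NULL, grid = c("geometric", "uniform"),
                               radii = NULL, constants = mg_constants()) {
  grid <- match.arg(grid)
  check_nonneg(Q, "Q")
  check_pos(R_source, "R_source")
  check_pos(domain_radius, "domain_radius")
  if (domain_radius <= R_source) {
    mg_stop("`domain_radius` must exceed `R_source`.")
  }
  if (is.null(conductivity)) conductivity <- constants$water_thermal_conductivity
  check_pos(conductivity, "conductivity")
  if (is.null(radii)) {
    if (n_shells < 10) mg_stop("`n_shells` must be >= 10.")
    radii <- if (grid == "geometric") {
      exp(seq(log(R_source), log(domain_radius), length.out = n_shells + 1))
    } else {
      seq(R_source, domain_radius, length.out = n_shells + 1)
    }
  } else {
    check_pos(radii, "radii")
    if (length(radii) < 11 || any(diff(radii) <= 0)) {
      mg_stop("`radii` must be strictly increasing with at least 11 nodes.")
    }
  }
  nN <- length(radii)
  # interface conductances between adjacent nodes (midpoint interface area)
  rmid <- (radii[-nN] + radii[-1]) / 2
  g <- 4 * pi * conductivity * rmid^2 / diff(radii)
  # unknowns T_1..T_{nN-1}; T_nN = 0 (bath). Tridiagonal system:
  #   node 1 (flux BC):        g1 (T1 - T2) = Q
  #   node i (conservation):   g_{i-1}(T_{i-1}-T_i) - g_i(T_i - T_{i+1}) = 0
  m <- nN - 1L
  lower <- c(0, -g[1:(m - 1)])
  diagv <- c(g[1], g[1:(m - 1)] + g[2:m])
  upper <- c(-g[1:(m - 1)], 0)
  rhs <- c(Q, rep(0, m - 1L))
  # Thomas algorithm
  cp <- numeric(m)
  dp <- numeric(m)
  cp[1] <- upper[1] / diagv[1]
  dp[1] <- rhs[1] / diagv[1]
  for (i in 2:m) {
    denom <- diagv[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  temp <- numeric(m)
  temp[m] <- dp[m]
  if (m > 1) {
    for (i in (m - 1):1) temp[i] <- dp[i] - cp[i] * temp[i + 1]
  }
  tibble(radius = radii, rise = c(temp, 0))
}
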