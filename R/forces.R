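#' Induced magnetic moment of a paramagnetic particle
#'
#' m = xi * B: the moment induced in a (super)paramagnetic particle of
#' magnetizability xi by a flux density B.
#'
#' @param xi magnetizability in J/T^2 (>= 0).
#' @param B flux density in T (>= 0).
#' @return moment in J/T.
#' @examples
#' induced_moment(2.4e-22, 0.05) # 1.2e-23 J/T
#' @export
induced_moment <- function(xi, B) {
  check_nonneg(xi, "xi")
  check_nonneg(B, "B")
  xi * B
}

#' Force on a paramagnetic particle in a field gradient
#'
#' The induced-moment interaction energy is U = -(1/2) xi B^2; its spatial
#' derivative gives the pull toward higher field,
#' F = xi * B * dB/dx.
#'
#' @param xi magnetizability in J/T^2 (>= 0).
#' @param B flux density in T (>= 0).
#' @param gradient field gradient dB/dx in T/m (>= 0).
#' @return force in N.
#' @examples
#' gradient_pull_force(2e-22, 0.05, 7) # 7e-23 N
#' @export
gradient_pull_force <- function(xi, B, gradient) {
  check_nonneg(xi, "xi")
  check_nonneg(B, "B")
  check_nonneg(gradient, "gradient")
  xi * B * gradient
}

#' Force between two magnetic dipoles at close range
#'
#' For two equal moments m a distance d apart: in the collinear (head-to-
#' tail, field parallel to the membrane) configuration the force is
#' attractive with magnitude F = (3 mu0 / 2 pi) m^2 / d^4. In the
#' side-by-side perpendicular configuration (field normal to the membrane)
#' the moments repel with half that magnitude. Magnitudes are returned; the
#' orientation flag records which geometry is meant.
#'
#' @param m moment of each particle in J/T (>= 0).
#' @param d center-to-center separation in m (> 0); touching ferritins have
#'   d = 2R = 12 nm.
#' @param orientation `"collinear"` (attractive, default) or
#'   `"perpendicular"` (repulsive, half magnitude).
#' @param constants list from [mg_constants()].
#' @return force magnitude in N.
#' @examples
#' dipole_pair_force(1e-23, 1.2e-8) # ~2.9e-21 N
#' @export
dipole_pair_force <- function(m, d, orientation = c("collinear", "perpendicular"),
                              constants = mg_constants()) {
  orientation <- match.arg(orientation)
  check_nonneg(m, "m")
  check_pos(d, "d")
  f <- 3 * constants$vacuum_permeability / (2 * pi) * m^2 / d^4
  if (orientation == "perpendicular") f <- f / 2
  f
}

#' Escape free energy of a dipole pair relative to thermal energy
#'
#' Because the pair force falls off as d^-4, moving two touching particles
#' one radius apart releases essentially all the interaction free energy;
#' F * R is therefore the free-energy scale of the bound configuration, and
#' F * R / (k T) measures whether the attraction can survive thermal motion.
#'
#' @param force pair force in N (>= 0).
#' @param radius particle radius in m (> 0).
#' @param temperature bath temperature in K (> 0).
#' @param constants list from [mg_constants()].
#' @return dimensionless free-energy-to-kT ratio.
#' @examples
#' dipole_escape_energy_ratio(3e-21, 6e-9, 298) # ~4.4e-9
#' @export
dipole_escape_energy_ratio <- function(force, radius, temperature = NULL,
                                       constants = mg_constants()) {
  check_nonneg(force, "force")
  check_pos(radius, "radius")
  if (is.null(temperature)) temperature <- constants$default_temperature
  check_pos(temperature, "temperature")
  force * radius / thermal_energy(temperature, constants)
}

#' Anisotropy free-energy gap of an induced moment
#'
#' Upper bound on the orientational free-energy difference available for a
#' magnetic torque: assuming infinite anisotropy (magnetizability xi along
#' the easy axis, zero orthogonal), the easy-axis-parallel configuration is
#' favored by |U| = (1/2) xi B^2 over the orthogonal one.
#'
#' @param xi magnetizability in J/T^2 (>= 0).
#' @param B flux density in T (>= 0).
#' @return energy magnitude in J.
#' @examples
#' anisotropy_energy_gap(2.4e-22, 0.05) # 3e-25 J
#' anisotropy_energy_gap(2.4e-22, 5)    # 3e-21 J, comparable with kT
#' @export
anisotropy_energy_gap <- function(xi, B) {
  check_nonneg(xi, "xi")
  check_nonneg(B, "B")
  0.5 * xi * B^2
}

#' Particle surface density required to reach a membrane stress
#'
#' How many particles per unit membrane area, each pulled with a given
#' force, are needed to produce a target stress.
#'
#' @param stress target membrane stress in Pa (> 0).
#' @param per_particle_force force per particle in N (> 0).
#' @return areal density in particles per m^2 (divide by 1e12 for per um^2).
#' @examples
#' required_surface_density(2, 7e-23) / 1e12 # ~2.9e10 per um^2
#' @export
required_surface_density <- function(stress, per_particle_force) {
  check_pos(stress, "stress")
  check_pos(per_particle_force, "per_particle_force")
  stress / per_particle_force
}

#' Close-packing areal density of spheres on a membrane
#'
#' Geometric ceiling on how many spheres of radius R fit per unit area:
#' square packing 1/(2R)^2 (the headline figure), or hexagonal packing which
#' exceeds it by 2/sqrt(3).
#'
#' @param radius sphere radius in m (> 0).
#' @param packing `"square"` (default) or `"hexagonal"`.
#' @return areal density in spheres per m^2.
#' @examples
#' max_packing_density(6e-9) / 1e12 # ~6.9e3 per um^2
#' @export
max_packing_density <- function(radius, packing = c("square", "hexagonal")) {
  packing <- match.arg(packing)
  check_pos(radius, "radius")
  d <- 1 / (2 * radius)^2
  if (packing == "hexagonal") d <- d * 2 / sqrt(3)
  d
}
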