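# Ion-matter physics: Bethe-Bloch stopping power, CSDA range bookkeeping,
# Highland multiple Coulomb scattering, Bohr energy-loss straggling, dose.
# Shell and density-effect corrections are deliberately omitted (see the
# methods vignette); the accuracy budget of the imaging model is a few percent.

K_BETHE <- 0.307075   # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
M_ELECTRON <- 0.51099895  # MeV
GY_PER_MEV_G <- 1.602e-10 # Gy * g / MeV
E_CUTOFF <- 0.5           # MeV/u, lower edge of the stopping-power validity window
E_MAX <- 500              # MeV/u, upper edge

# kinematics at a given kinetic energy per nucleon
.beta_gamma <- function(ion, energy_per_nucleon) {
  gamma <- 1 + energy_per_nucleon / ion$mass_per_nucleon
  beta2 <- 1 - 1 / gamma^2
  list(gamma = gamma, beta2 = beta2)
}

#' Mass stopping power (Bethe-Bloch)
#'
#' Electronic mass stopping power S/rho in MeV cm^2/g, evaluated at the ion's
#' velocity from the plain Bethe-Bloch formula (no shell or density-effect
#' corrections).
#'
#' @param ion An [ion_species()] or built-in name.
#' @param energy_per_nucleon Kinetic energy per nucleon in MeV/u; vectorised.
#'   Must lie in `[0.5, 500]`.
#' @param material A [material()] or built-in name.
#' @return Stopping power in MeV cm^2/g, same length as `energy_per_nucleon`.
#' @examples
#' mass_stopping_power("proton", 200, "water")  # ~4.49 MeV cm^2/g
#' @export
mass_stopping_power <- function(ion, energy_per_nucleon, material) {
  ion <- ion_species(ion); material <- material(material)
  if (any(energy_per_nucleon < E_CUTOFF | energy_per_nucleon > E_MAX)) {
    stop("energy_per_nucleon outside the [0.5, 500] MeV/u validity window",
         call. = FALSE)
  }
  kin <- .beta_gamma(ion, energy_per_nucleon)
  I_mev <- material$mean_excitation_energy * 1e-6
  arg <- 2 * M_ELECTRON * kin$beta2 * kin$gamma^2 / I_mev
  K_BETHE * ion$charge_number^2 * material$z_over_a / kin$beta2 *
    (log(arg) - kin$beta2)
}

# Range/energy tables are cached per (ion, material); the table integrates
# A dE/u / (S * rho) on a fine log grid from the 0.5 MeV/u cutoff.  The
# residual range below the cutoff (< 0.01 mm) is neglected.
.range_cache <- new.env(parent = emptyenv())

.range_table <- function(ion, material) {
  key <- paste(ion$name, ion$charge_number, ion$mass_number,
               round(ion$mass_per_nucleon, 4), material$name,
               material$density, material$mean_excitation_energy,
               material$z_over_a, sep = "|")
  tab <- .range_cache[[key]]
  if (!is.null(tab)) return(tab)
  e <- exp(seq(log(E_CUTOFF), log(E_MAX), length.out = 1200))
  integrand <- ion$mass_number /
    (mass_stopping_power(ion, e, material) * material$density)
  # cumulative trapezoid in E
  r <- c(0, cumsum(diff(e) * (utils::head(integrand, -1) + utils::tail(integrand, -1)) / 2))
  tab <- list(
    e = e, r = r,
    r_of_e = stats::splinefun(e, r, method = "hyman"),
    e_of_r = stats::splinefun(r, e, method = "hyman")
  )
  .range_cache[[key]] <- tab
  tab
}

#' CSDA range
#'
#' Continuous-slowing-down range in cm, the integral of `A dE / (S rho)` from
#' the 0.5 MeV/u cutoff up to the given energy. Strictly increasing in energy.
#'
#' @inheritParams mass_stopping_power
#' @return Range in cm.
#' @examples
#' csda_range("proton", 168.3, "water")  # ~19.7 cm
#' @export
csda_range <- function(ion, energy_per_nucleon, material) {
  ion <- ion_species(ion); material <- material(material)
  if (any(energy_per_nucleon < E_CUTOFF | energy_per_nucleon > E_MAX)) {
    stop("energy_per_nucleon outside the [0.5, 500] MeV/u validity window",
         call. = FALSE)
  }
  .range_table(ion, material)$r_of_e(energy_per_nucleon)
}

#' Residual energy after a slab
#'
#' Inverts the range table: solves `range(E_out) = range(E_in) - thickness`.
#' Returns 0 where the ion stops inside the slab.
#'
#' @inheritParams mass_stopping_power
#' @param thickness Slab thickness in cm (>= 0); vectorised with recycling.
#' @return Residual kinetic energy per nucleon in MeV/u (0 if stopped).
#' @examples
#' energy_after("helium", 168.3, "pmma", 16.1)
#' @export
energy_after <- function(ion, energy_per_nucleon, material, thickness) {
  ion <- ion_species(ion); material <- material(material)
  if (any(thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  tab <- .range_table(ion, material)
  n <- max(length(energy_per_nucleon), length(thickness))
  e_in <- rep_len(energy_per_nucleon, n)
  th <- rep_len(thickness, n)
  r_out <- tab$r_of_e(e_in) - th
  out <- numeric(n)
  ok <- r_out > 0
  out[ok] <- pmax(tab$e_of_r(r_out[ok]), 0)
  # below the integration cutoff the residual energy is treated as absorbed
  out[out < E_CUTOFF] <- 0
  out
}

#' Water-equivalent thickness
#'
#' WET of a slab at a reference energy: `thickness * (S rho)_mat / (S rho)_water`.
#' Additive over stacked slabs by construction.
#'
#' @param material A [material()] or name.
#' @param thickness Physical thickness in mm (>= 0).
#' @param reference_energy Energy per nucleon (MeV/u) at which the
#'   stopping-power ratio is taken; the relative stopping power is only weakly
#'   energy dependent.
#' @param ion Ion species used for the ratio (default helium); the ratio is
#'   nearly species independent.
#' @return Water-equivalent thickness in mm.
#' @examples
#' water_equivalent_thickness("pmma", 161, 150)  # ~186 mm
#' @export
water_equivalent_thickness <- function(material, thickness, reference_energy,
                                       ion = "helium") {
  material <- material(material); ion <- ion_species(ion)
  if (any(thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  water <- material("water")
  rsp <- mass_stopping_power(ion, reference_energy, material) * material$density /
    (mass_stopping_power(ion, reference_energy, water) * water$density)
  thickness * rsp
}

#' Highland multiple-scattering angle
#'
#' Projected scattering angle sigma from the Highland formula
#' `theta0 = 13.6 MeV/(beta c p) * z * sqrt(x/X0) * (1 + 0.038 ln(x/X0))`
#' with `p` the total momentum of the ion.
#'
#' @inheritParams mass_stopping_power
#' @param thickness Traversed thickness in cm (> 0).
#' @return Projected angle sigma in radians.
#' @export
highland_sigma <- function(ion, energy_per_nucleon, material, thickness) {
  ion <- ion_species(ion); material <- material(material)
  x_over_x0 <- thickness * material$density / material$radiation_length
  if (any(x_over_x0 <= 0)) stop("x/X0 must be > 0", call. = FALSE)
  t_mev <- energy_per_nucleon * ion$mass_number
  m_mev <- ion$mass_per_nucleon * ion$mass_number
  pc <- sqrt(t_mev * (t_mev + 2 * m_mev))
  beta <- pc / (t_mev + m_mev)
  13.6 / (beta * pc) * ion$charge_number * sqrt(x_over_x0) *
    (1 + 0.038 * log(x_over_x0))
}

#' Bohr energy-loss straggling
#'
#' Gaussian spread of the energy loss in a slab per Bohr's formula,
#' `sigma^2 = 0.1569 z^2 (Z/A) rho x` (MeV^2, x in cm).
#'
#' @inheritParams highland_sigma
#' @return Sigma of the deposited-energy distribution in MeV.
#' @export
bohr_straggling_sigma <- function(ion, material, thickness) {
  ion <- ion_species(ion); material <- material(material)
  if (any(thickness <= 0)) stop("thickness must be > 0", call. = FALSE)
  sqrt(0.1569 * ion$charge_number^2 * material$z_over_a *
         material$density * thickness)
}

#' Fluence-to-dose conversion
#'
#' `D = Phi * (S/rho) * 1.602e-10 Gy g/MeV`.
#'
#' @param fluence Particles per cm^2 (>= 0).
#' @inheritParams mass_stopping_power
#' @return Dose in Gy.
#' @examples
#' fluence_to_dose(4.64e11, "proton", 200, "water")  # ~330 Gy
#' @export
fluence_to_dose <- function(fluence, ion, energy_per_nucleon, material) {
  if (any(fluence < 0)) stop("fluence must be >= 0", call. = FALSE)
  fluence * mass_stopping_power(ion, energy_per_nucleon, material) * GY_PER_MEV_G
}

#' Mean energy deposition in a silicon layer
#'
#' CSDA energy lost by the ion in a thin silicon slab (the sensor of one
#' detector layer); equals the full residual kinetic energy if the ion stops
#' inside the slab.
#'
#' @inheritParams mass_stopping_power
#' @param thickness Sensor thickness in um (default 300).
#' @return Deposited energy in MeV (total, not per nucleon).
#' @export
deposition_in_silicon <- function(ion, energy_per_nucleon, thickness = 300) {
  ion <- ion_species(ion)
  if (any(energy_per_nucleon <= 0)) stop("energy must be > 0", call. = FALSE)
  e_out <- energy_after(ion, energy_per_nucleon, "silicon", thickness * 1e-4)
  (energy_per_nucleon - e_out) * ion$mass_number
}
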