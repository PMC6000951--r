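#' Ion species
#'
#' Construct the projectile description used by all physics routines. Built-in
#' species are `"proton"`, `"helium"` (helium-4) and `"carbon"` (carbon-12).
#'
#' @param name Built-in species name, or an arbitrary label when the remaining
#'   arguments are supplied explicitly.
#' @param charge_number Projectile charge number Z (>= 1).
#' @param mass_number Nucleon number A (>= Z).
#' @param mass_per_nucleon Rest mass per nucleon in MeV/c^2.
#' @return An object of class `ion_species`: a list with fields `name`,
#'   `charge_number`, `mass_number`, `mass_per_nucleon`.
#' @examples
#' ion_species("helium")
#' ion_species("deuteron", charge_number = 1, mass_number = 2,
#'             mass_per_nucleon = 937.8)
#' @export
ion_species <- function(name, charge_number = NULL, mass_number = NULL,
                        mass_per_nucleon = NULL) {
  if (inherits(name, "ion_species")) return(name)
  builtins <- list(
    proton = list(Z = 1L, A = 1L, m = 938.2721),
    helium = list(Z = 2L, A = 4L, m = 3727.379 / 4),
    carbon = list(Z = 6L, A = 12L, m = 11177.929 / 12)
  )
  if (is.null(charge_number)) {
    b <- builtins[[match.arg(name, names(builtins))]]
    charge_number <- b$Z; mass_number <- b$A; mass_per_nucleon <- b$m
  }
  stopifnot(charge_number >= 1, mass_number >= charge_number,
            mass_per_nucleon > 0)
  structure(list(name = name,
                 charge_number = as.integer(charge_number),
                 mass_number = as.integer(mass_number),
                 mass_per_nucleon = mass_per_nucleon),
            class = "ion_species")
}

#' Material constants
#'
#' Stopping-power and scattering constants for the materials of the imaging
#' setup. Built-ins: `"water"`, `"pmma"` (the phantom, 1.19 g/cm^3), `"air"`,
#' `"silicon"` (the 300 um sensor layers).
#'
#' @param name Built-in material name, or a label when all constants are given.
#' @param density g/cm^3.
#' @param mean_excitation_energy Mean excitation energy I in eV.
#' @param z_over_a Ratio of atomic number to mass number (mol electrons/g).
#' @param radiation_length X0 in g/cm^2.
#' @return An object of class `material`.
#' @examples
#' material("pmma")
#' @export
material <- function(name, density = NULL, mean_excitation_energy = NULL,
                     z_over_a = NULL, radiation_length = NULL) {
  if (inherits(name, "material")) return(name)
  builtins <- list(
    water   = list(rho = 1.0,      I = 75.0,  za = 0.55509, X0 = 36.08),
    pmma    = list(rho = 1.19,     I = 74.0,  za = 0.53937, X0 = 40.55),
    air     = list(rho = 1.205e-3, I = 85.7,  za = 0.49919, X0 = 36.62),
    silicon = list(rho = 2.33,     I = 173.0, za = 0.49848, X0 = 21.82)
  )
  if (is.null(density)) {
    b <- builtins[[match.arg(name, names(builtins))]]
    density <- b$rho; mean_excitation_energy <- b$I
    z_over_a <- b$za; radiation_length <- b$X0
  }
  stopifnot(density > 0, mean_excitation_energy > 0, z_over_a > 0,
            radiation_length > 0)
  structure(list(name = name, density = density,
                 mean_excitation_energy = mean_excitation_energy,
                 z_over_a = z_over_a, radiation_length = radiation_length),
            class = "material")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s  Z=%d A=%d m/u=%.3f MeV\n",
              x$name, x$charge_number, x$mass_number, x$mass_per_nucleon))
  invisible(x)
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho=%.4g g/cm3  I=%.4g eV  Z/A=%.4f  X0=%.4g g/cm2\n",
              x$name, x$density, x$mean_excitation_energy, x$z_over_a,
              x$radiation_length))
  invisible(x)
}

#' Energy grid covering the clinical window
#'
#' Strictly increasing energies per nucleon (MeV/u) spanning at least
#' 1-250 MeV/u, log-spaced; used for range tables and round-trip tests.
#'
#' @param n Number of grid points.
#' @param from,to Grid limits in MeV/u.
#' @return Numeric vector, strictly increasing.
#' @export
energy_grid <- function(n = 200, from = 1, to = 250) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}
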