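## Physical constants (CODATA 2018), SI units.
.const <- list(
  e    = 1.602176634e-19,   # elementary charge, C
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  Nav  = 6.02214076e23      # Avogadro number, 1/mol
)

#' Bjerrum length
#'
#' Distance at which two elementary charges embedded in a uniform dielectric
#' interact with thermal energy kBT: \eqn{l_B = e^2 / (4\pi \epsilon
#' \epsilon_0 k_B T)}. In water at 25 C (\eqn{\epsilon = 78.5}) this is
#' about 0.714 nm.
#'
#' @param dielectric relative dielectric constant of the medium (> 0).
#' @param temperature absolute temperature in kelvin (default 298.15).
#' @return Bjerrum length in nm.
#' @export
#' @examples
#' bjerrum_length(78.5)          # ~0.714 nm, water at 25 C
#' bjerrum_length(40) / bjerrum_length(80)  # inverse proportionality
bjerrum_length <- function(dielectric, temperature = 298.15) {
  if (any(dielectric <= 0)) stop("dielectric must be positive", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  lb_m <- .const$e^2 / (4 * pi * dielectric * .const$eps0 * .const$kB * temperature)
  lb_m * 1e9
}

#' Solution conditions for an electrolyte bath
#'
#' Bundles the bulk parameters of a symmetric monovalent electrolyte: pH,
#' salt molarity, temperature and solvent dielectric constant. Screening is
#' computed from the salt alone; protons enter the ionization chemistry but
#' are assumed negligible for screening (valid for pH roughly 3-11 at the
#' salt concentrations of interest).
#'
#' @param pH bulk pH, in [0, 14].
#' @param salt_molarity monovalent salt concentration in mol/L (> 0).
#' @param temperature kelvin (default 298.15, water at 25 C).
#' @param solvent_dielectric relative dielectric constant of the solvent
#'   (default 78.5).
#' @return An object of class `solution_conditions` with fields `pH`,
#'   `salt_molarity`, `temperature`, `solvent_dielectric`, plus the derived
#'   water-phase Bjerrum length `lB` (nm) and inverse Debye length `kappa`
#'   (1/nm).
#' @export
#' @examples
#' cond <- solution_conditions(pH = 7, salt_molarity = 0.1)
#' 1 / cond$kappa   # Debye length, ~0.96 nm at 100 mM
solution_conditions <- function(pH, salt_molarity, temperature = 298.15,
                                solvent_dielectric = 78.5) {
  stopifnot(length(pH) == 1, length(salt_molarity) == 1)
  if (!is.finite(pH) || pH < 0 || pH > 14)
    stop("pH must lie in [0, 14]", call. = FALSE)
  if (!is.finite(salt_molarity) || salt_molarity <= 0)
    stop("salt_molarity must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  if (!is.finite(solvent_dielectric) || solvent_dielectric <= 1)
    stop("solvent_dielectric must exceed 1", call. = FALSE)
  lB <- bjerrum_length(solvent_dielectric, temperature)
  ## kappa^2 = 8 pi lB n0, n0 = number density of each ion species in 1/nm^3
  n0 <- salt_molarity * .const$Nav * 1e-24   # mol/L -> 1/nm^3
  kappa <- sqrt(8 * pi * lB * n0)
  structure(list(pH = pH, salt_molarity = salt_molarity,
                 temperature = temperature,
                 solvent_dielectric = solvent_dielectric,
                 lB = lB, kappa = kappa, n0 = n0),
            class = "solution_conditions")
}

#' Debye screening length
#'
#' \eqn{\kappa^{-1} = \sqrt{\epsilon_m \epsilon_0 k_B T / (2 N_A c e^2)}}
#' for a symmetric monovalent electrolyte of molarity c. About 0.96 nm in
#' 100 mM salt and 9.6 nm in 1 mM.
#'
#' @param cond a [solution_conditions()] object.
#' @return Debye length in nm.
#' @export
debye_length <- function(cond) {
  stopifnot(inherits(cond, "solution_conditions"))
  1 / cond$kappa
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf(
    "Electrolyte: pH %.2f, %.4g M monovalent salt, T = %.2f K, eps_m = %.1f\n",
    x$pH, x$salt_molarity, x$temperature, x$solvent_dielectric))
  cat(sprintf("  Bjerrum length lB = %.4f nm, Debye length 1/kappa = %.4f nm\n",
              x$lB, 1 / x$kappa))
  invisible(x)
}
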