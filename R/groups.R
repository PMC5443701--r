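#' Define an ionizable group
#'
#' A titratable chemical species: an acid (valence -1, e.g. carboxylate,
#' phosphate) or a base (valence +1, e.g. amine). `ion_radius` is the
#' radius of the ionized form, used in the Born solvation penalty when the
#' group sits inside a low-dielectric interior.
#'
#' @param pKa negative log10 of the acid dissociation constant, in (0, 14).
#' @param valence +1 for a basic group, -1 for an acidic group.
#' @param ion_radius radius of the ionized species in nm (default 0.25,
#'   appropriate for carboxylate).
#' @param label optional name.
#' @return An `ionizable_group` object.
#' @export
#' @examples
#' glu <- ionizable_group(4.3, -1, label = "Glu")
#' lys <- ionizable_group(10.4, +1, label = "Lys")
ionizable_group <- function(pKa, valence, ion_radius = 0.25, label = "") {
  if (!valence %in% c(-1, 1)) stop("valence must be +1 or -1", call. = FALSE)
  if (!is.finite(pKa) || pKa <= 0 || pKa >= 14)
    stop("pKa must lie in (0, 14)", call. = FALSE)
  if (!is.finite(ion_radius) || ion_radius <= 0)
    stop("ion_radius must be positive", call. = FALSE)
  structure(list(pKa = pKa, valence = valence, ion_radius = ion_radius,
                 label = as.character(label)),
            class = "ionizable_group")
}

#' Inventory of ionizable groups
#'
#' A set of (group, count) pairs describing all titratable species carried
#' by a molecule.
#'
#' @param groups list of [ionizable_group()] objects.
#' @param counts numeric vector of non-negative counts, one per group.
#'   Fractional counts are allowed (convenient for smeared models).
#' @return A `group_set` object.
#' @export
group_set <- function(groups, counts) {
  if (inherits(groups, "ionizable_group")) groups <- list(groups)
  stopifnot(length(groups) == length(counts))
  if (length(groups) == 0) stop("at least one group required", call. = FALSE)
  if (any(!vapply(groups, inherits, TRUE, "ionizable_group")))
    stop("all elements must be ionizable_group objects", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) stop("at least one group must have count > 0", call. = FALSE)
  structure(list(groups = groups, counts = as.numeric(counts)),
            class = "group_set")
}

#' @export
print.group_set <- function(x, ...) {
  cat(sprintf("Ionizable group set (%d species, %.4g groups total):\n",
              length(x$groups), sum(x$counts)))
  for (k in seq_along(x$groups)) {
    g <- x$groups[[k]]
    cat(sprintf("  %-10s pKa %-5.2f z %+d  count %.4g\n",
                ifelse(nzchar(g$label), g$label, "(unnamed)"),
                g$pKa, g$valence, x$counts[k]))
  }
  invisible(x)
}

#' Fractional ionization of a group in a local environment
#'
#' Degree of ionization of an acid or base coupled to the local
#' (dimensionless) electrostatic potential and a solvation penalty:
#' \deqn{\alpha = \frac{1}{1 + 10^{z(\mathrm{pH} - \mathrm{p}K_a)}
#'   \exp(z\tilde\psi + \phi_s + \phi_0)}.}
#' With \eqn{\tilde\psi = \phi_s = \phi_0 = 0} this reduces to the ideal
#' Henderson-Hasselbalch fraction. A negative potential promotes
#' deprotonation of bases and suppresses ionization of acids; the Born term
#' \eqn{\phi_s \ge 0} always suppresses ionization.
#'
#' @param group an [ionizable_group()], or its valence/pKa supplied via
#'   `valence` and `pKa` directly.
#' @param pH bulk pH.
#' @param psi_local dimensionless local potential \eqn{e\psi/k_BT}
#'   (default 0).
#' @param phi_s dimensionless Born solvation penalty, >= 0 (default 0).
#' @param phi_0 additional non-electrostatic free energy offset in kBT
#'   (default 0).
#' @return ionized fraction in [0, 1]; vectorized over `psi_local` and `pH`.
#' @export
#' @examples
#' asp <- ionizable_group(4, -1)
#' ionization_fraction(asp, pH = 4)          # 0.5 at pH = pKa
#' ionization_fraction(asp, pH = 7, phi_s = 4.2)  # buried: suppressed
ionization_fraction <- function(group, pH, psi_local = 0, phi_s = 0, phi_0 = 0) {
  stopifnot(inherits(group, "ionizable_group"))
  if (any(phi_s < 0)) stop("phi_s must be non-negative", call. = FALSE)
  z <- group$valence
  ## log-domain evaluation: never overflows, saturates smoothly at 0 or 1
  loggamma <- z * (pH - group$pKa) * log(10) + z * psi_local + phi_s + phi_0
  1 / (1 + exp(pmin(loggamma, 700)))
}

## derivative d alpha / d psi  = -z alpha (1 - alpha); used in Newton solvers
.dalpha_dpsi <- function(alpha, valence) -valence * alpha * (1 - alpha)

#' Born solvation penalty for a buried ionized group
#'
#' Difference in Born solvation energy of an ionized group of radius
#' \eqn{r_A} between the aqueous phase (dielectric \eqn{\epsilon_m}) and a
#' low-dielectric interior (\eqn{\epsilon_p}):
#' \deqn{\phi_s / k_BT = p \, \frac{l_{B,m}}{2 r_A}
#'   \left(\frac{\epsilon_m}{\epsilon_p} - 1\right) \ge 0,}
#' where \eqn{l_{B,m}} is the Bjerrum length of the aqueous medium and
#' \eqn{p \in (0, 1]} an optional attenuation factor absorbing
#' contributions (H-bonding, local polarizability) that soften the penalty.
#' For a carboxylate (\eqn{r_A} = 0.25 nm) buried at \eqn{\epsilon_p = 40}
#' in water this gives about 1.4 kBT.
#'
#' @param interior_dielectric dielectric constant of the interior.
#' @param cond [solution_conditions()] (supplies \eqn{\epsilon_m} and T).
#' @param ion_radius radius of the ionized species in nm.
#' @param attenuation multiplicative factor p in (0, 1] (default 1).
#' @return dimensionless energy (units of kBT), never negative.
#' @export
born_term <- function(interior_dielectric, cond, ion_radius = 0.25,
                      attenuation = 1) {
  stopifnot(inherits(cond, "solution_conditions"))
  if (any(ion_radius <= 0)) stop("ion_radius must be positive", call. = FALSE)
  if (any(attenuation <= 0 | attenuation > 1))
    stop("attenuation must lie in (0, 1]", call. = FALSE)
  if (any(interior_dielectric <= 0))
    stop("interior_dielectric must be positive", call. = FALSE)
  lBm <- cond$lB  # Bjerrum length of the aqueous medium
  val <- attenuation * lBm / (2 * ion_radius) *
    (cond$solvent_dielectric / interior_dielectric - 1)
  pmax(val, 0)
}

#' Structural (Henderson-Hasselbalch) charge
#'
#' Ideal-solution net charge of a molecule from its group inventory:
#' \deqn{q_{str} = \sum_i \frac{z_i}{1 + 10^{z_i(\mathrm{pH} - pK_i)}}}
#' in units of e, ignoring all electrostatic feedback.
#'
#' @param groups a [group_set()].
#' @param pH bulk pH (may be a vector).
#' @return signed charge in elementary charges, vectorized over `pH`.
#' @export
#' @examples
#' gs <- group_set(list(ionizable_group(4, -1, label = "acid")), 10)
#' structural_charge(gs, pH = 4)   # -5: half-ionized at pH = pKa
structural_charge <- function(groups, pH) {
  stopifnot(inherits(groups, "group_set"))
  out <- numeric(length(pH))
  for (k in seq_along(groups$groups)) {
    g <- groups$groups[[k]]
    out <- out + groups$counts[k] * g$valence * ionization_fraction(g, pH)
  }
  out
}
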