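#' Dielectric sphere model of a globular macromolecule
#'
#' A globular molecule is represented as a uniform dielectric sphere of
#' radius R housing its ionizable groups as uniform volume densities. The
#' sphere is transparent to protons (groups titrate against the bulk pH)
#' but impervious to salt ions. Buried groups pay the Born penalty
#' [born_term()] computed from the interior dielectric constant.
#'
#' @param radius sphere radius R in nm.
#' @param interior_dielectric interior dielectric constant (>= 1).
#' @param groups a [group_set()] distributed uniformly over the volume.
#' @param born_attenuation attenuation p of the Born term, in (0, 1].
#' @param phi_0 non-electrostatic ionization offset in kBT (default 0).
#' @param born_on logical; set `FALSE` to drop the Born term entirely.
#' @return A `sphere_model` object.
#' @export
sphere_model <- function(radius, interior_dielectric, groups,
                         born_attenuation = 1, phi_0 = 0, born_on = TRUE) {
  stopifnot(inherits(groups, "group_set"))
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (interior_dielectric < 1)
    stop("interior_dielectric must be >= 1", call. = FALSE)
  structure(list(radius = radius, interior_dielectric = interior_dielectric,
                 groups = groups, born_attenuation = born_attenuation,
                 phi_0 = phi_0, born_on = isTRUE(born_on)),
            class = "sphere_model")
}

#' Cylinder model of a linear polyelectrolyte
#'
#' Rigid hollow cylinder carrying its ionizable groups as a uniform surface
#' density (lateral surface plus end caps for finite length). Groups are
#' solvent-exposed, so no interior dielectric or Born term enters; the
#' local surface potential alone regulates their ionization. With
#' `constant_charge` set, regulation is frozen and the cylinder carries the
#' given fixed total charge instead (used for renormalization runs).
#'
#' @param radius cylinder radius R = D/2 in nm.
#' @param length cylinder length L in nm, or `Inf` for the infinite limit.
#' @param surface_groups a [group_set()], or `NULL` when `constant_charge`
#'   is given.
#' @param constant_charge optional fixed total charge in e (signed);
#'   disables regulation.
#' @return A `cylinder_model` object.
#' @export
cylinder_model <- function(radius, length = Inf, surface_groups = NULL,
                           constant_charge = NULL) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  if (length <= 0) stop("length must be positive (or Inf)", call. = FALSE)
  if (is.null(surface_groups) && is.null(constant_charge))
    stop("supply surface_groups or constant_charge", call. = FALSE)
  if (!is.null(surface_groups)) stopifnot(inherits(surface_groups, "group_set"))
  structure(list(radius = radius, length = length,
                 surface_groups = surface_groups,
                 constant_charge = constant_charge,
                 regulation_enabled = is.null(constant_charge)),
            class = "cylinder_model")
}

#' Core-shell sphere model for buried-residue pKa prediction
#'
#' A globular protein hosting a single buried ionizable residue is modelled
#' as a concentric core-shell sphere: a small low-dielectric core of radius
#' `core_radius` containing the residue (its charge smeared over the core
#' volume), surrounded by a uniform-dielectric shell carrying the protein's
#' background formal charge, bathed in electrolyte. The residue's Born
#' penalty is computed from the core dielectric with attenuation `p`.
#'
#' @param outer_radius outer (protein) radius in nm.
#' @param core_radius core radius in nm (< outer_radius).
#' @param core_dielectric dielectric constant of the core.
#' @param shell_dielectric dielectric constant of the shell.
#' @param core_group a single [ionizable_group()] housed in the core.
#' @param shell_charge background formal charge of the shell in e (signed,
#'   held fixed across pH unless a shell composition is supplied).
#' @param shell_groups optional [group_set()]; if given, the shell charge is
#'   recomputed per pH from this composition (ideal ionization).
#' @param born_attenuation attenuation p of the core Born term.
#' @return A `core_shell_model` object.
#' @export
core_shell_model <- function(outer_radius, core_radius, core_dielectric,
                             shell_dielectric, core_group, shell_charge = 0,
                             shell_groups = NULL, born_attenuation = 1) {
  stopifnot(inherits(core_group, "ionizable_group"))
  if (!(core_radius > 0 && core_radius < outer_radius))
    stop("need 0 < core_radius < outer_radius", call. = FALSE)
  if (!is.null(shell_groups)) stopifnot(inherits(shell_groups, "group_set"))
  structure(list(outer_radius = outer_radius, core_radius = core_radius,
                 core_dielectric = core_dielectric,
                 shell_dielectric = shell_dielectric,
                 core_group = core_group, shell_charge = shell_charge,
                 shell_groups = shell_groups,
                 born_attenuation = born_attenuation),
            class = "core_shell_model")
}

#' Parallel-plate slit geometry for effective-charge extraction
#'
#' Like-charged parallel walls at z = 0 and z = 2h with the object of
#' interest centred at the mid-plane z = h. The inter-surface gap is
#' z* = h minus the object's half-extent along z. Used by
#' [effective_charge()] and [interaction_free_energy()].
#'
#' @param half_height slit half-height h in nm.
#' @param wall_surface_charge wall charge density in e/nm^2 (signed; same
#'   sign as the object for the like-charged setup).
#' @param lateral_extent radial truncation of the computational domain in
#'   nm (`NULL` = auto, 10 Debye lengths beyond the object).
#' @return A `slit_geometry` object.
#' @export
slit_geometry <- function(half_height, wall_surface_charge,
                          lateral_extent = NULL) {
  if (half_height <= 0) stop("half_height must be positive", call. = FALSE)
  structure(list(half_height = half_height,
                 wall_surface_charge = wall_surface_charge,
                 lateral_extent = lateral_extent),
            class = "slit_geometry")
}

## half-extent of an object along the slit normal (z)
.object_half_extent <- function(model) {
  switch(class(model)[1],
         sphere_model   = model$radius,
         cylinder_model = {
           if (!is.finite(model$length))
             stop("finite length required in a slit", call. = FALSE)
           model$length / 2
         },
         stop("unsupported model class", call. = FALSE))
}

## total structural charge count helpers ------------------------------------

## full-ionization (saturated) charge of a group set, signed
.full_charge <- function(groups) {
  sum(groups$counts * vapply(groups$groups, function(g) g$valence, 0))
}

## surface area of a finite cylinder (lateral + both caps), nm^2
.cylinder_area <- function(radius, length) {
  2 * pi * radius * length + 2 * pi * radius^2
}
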