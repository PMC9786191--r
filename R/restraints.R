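# Restraint families used by all protocols:
#
#  * pin          -- flat-bottom parabolic positional restraint on a C-alpha
#                    atom: penalty-free within `free_radius` (1 Angstrom) of
#                    the template position, harmonic (k = 10 kcal/mol/A^2)
#                    beyond.  Keeps the channel fold near the template while
#                    permitting local drift.
#  * plane        -- the atom is free to move within a plane normal to the
#                    pore axis but not to leave it (S4 pulling).  Enforced by
#                    projecting the axial coordinate back to the target after
#                    every perturbation plus a stiff harmonic during
#                    minimization, to a 0.05 Angstrom tolerance.
#  * axial        -- the atom (ligand para-carbon) is held at a fixed
#                    cylindrical radius from the pore axis; azimuth and the
#                    axial coordinate stay fully free (egress pulling).
#                    Enforced like planes, by rigid radial translation of the
#                    whole ligand plus a stiff harmonic.

PLANE_K <- 1000      # kcal/mol/A^2, stiff harmonic backing the projection
PLANE_TOL <- 0.05    # Angstrom, enforcement tolerance

#' Flat-bottom pin restraint
#'
#' @param atom atom index (into the combined channel+ligand coordinate set).
#' @param template numeric(3) template position, Angstrom.
#' @param free_radius penalty-free radius (default 1 Angstrom).
#' @param k force constant, kcal/mol/A^2 (default 10).
#' @return Restraint object.
#' @export
pin_restraint <- function(atom, template, free_radius = 1, k = 10) {
  stopifnot(free_radius >= 0, k >= 0, length(template) == 3)
  structure(list(kind = "pin", atom = as.integer(atom),
                 template = as.numeric(template),
                 free_radius = free_radius, k = k),
            class = "Restraint")
}

#' Plane restraint (fixed axial coordinate)
#'
#' @param atom atom index.
#' @param target_z target coordinate along the pore axis, Angstrom.
#' @return Restraint object.
#' @export
plane_restraint <- function(atom, target_z) {
  structure(list(kind = "plane", atom = as.integer(atom),
                 target_z = target_z, k = PLANE_K),
            class = "Restraint")
}

#' Axial-distance restraint (fixed cylindrical radius from the pore axis)
#'
#' Equivalent to constraining the atom to a sphere whose centre slides
#' freely along the pore axis: the constrained coordinate is the radius
#' only; azimuth and axial position remain free.
#'
#' @param atom atom index (the ligand para-carbon in egress scans).
#' @param target_rho target radius, Angstrom (>= 0).
#' @param group atom indices translated rigidly together with `atom` when
#'   the constraint is projected (the whole ligand).
#' @return Restraint object.
#' @export
axial_restraint <- function(atom, target_rho, group = atom) {
  stopifnot(target_rho >= 0)
  structure(list(kind = "axial", atom = as.integer(atom),
                 target_rho = target_rho, group = as.integer(group),
                 k = PLANE_K),
            class = "Restraint")
}

#' @export
print.Restraint <- function(x, ...) {
  cat("<Restraint ", x$kind, " on atom ", x$atom, ">\n", sep = "")
  invisible(x)
}

#' Pin restraint energy at a given deviation
#'
#' Zero for deviations within the flat bottom, `k * (d - free_radius)^2`
#' beyond; continuous with continuous derivative at the boundary.
#'
#' @param deviation distance from the template position, Angstrom (>= 0).
#' @param pin a [pin_restraint()] (only `free_radius` and `k` are used).
#' @return Energy in kcal/mol (vectorized over `deviation`).
#' @examples
#' pin_energy(2.0, pin_restraint(1, c(0, 0, 0)))  # 10 kcal/mol
#' @export
pin_energy <- function(deviation, pin = pin_restraint(1L, c(0, 0, 0))) {
  stopifnot(all(deviation >= 0))
  over <- pmax(0, deviation - pin$free_radius)
  pin$k * over^2
}

#' Plane-restraint violation of an atom
#'
#' @param xyz coordinate matrix or a [channel_structure()].
#' @param restraint a [plane_restraint()].
#' @param axis pore axis (`list(point=, dir=)`); taken from the structure if
#'   one is supplied.
#' @return Absolute axial deviation from the target plane, Angstrom.
#' @export
plane_violation <- function(xyz, restraint, axis = NULL) {
  if (inherits(xyz, "ChannelStructure")) {
    if (is.null(axis)) axis <- xyz$pore_axis
    xyz <- coords(xyz)
  }
  if (is.null(axis)) stop("pore axis undefined")
  z <- axis_coords(xyz[restraint$atom, , drop = FALSE], axis)$z
  abs(z - restraint$target_z)
}

#' Cylindrical radius of a restrained atom about the pore axis
#'
#' @param xyz coordinate matrix or a [channel_structure()].
#' @param restraint an [axial_restraint()].
#' @param axis pore axis; taken from the structure if one is supplied.
#' @return Radius rho, Angstrom.
#' @export
axial_distance <- function(xyz, restraint, axis = NULL) {
  if (inherits(xyz, "ChannelStructure")) {
    if (is.null(axis)) axis <- xyz$pore_axis
    xyz <- coords(xyz)
  }
  if (is.null(axis)) stop("pore axis undefined")
  axis_coords(xyz[restraint$atom, , drop = FALSE], axis)$rho
}

# Total restraint penalty for a coordinate set.
restraint_energy <- function(xyz, restraints, axis) {
  e <- 0
  for (r in restraints) {
    if (r$kind == "pin") {
      d <- vnorm(xyz[r$atom, ] - r$template)
      e <- e + pin_energy(d, r)
    } else if (r$kind == "plane") {
      e <- e + r$k * plane_violation(xyz, r, axis)^2
    } else if (r$kind == "axial") {
      e <- e + r$k * (axial_distance(xyz, r, axis) - r$target_rho)^2
    }
  }
  e
}

# Project constrained coordinates exactly onto their target manifolds.
# Planes: move the atom along the axis.  Axial: translate the restrained
# group rigidly in the radial direction of the restrained atom.  Other
# degrees of freedom are untouched.
project_restraints <- function(xyz, restraints, axis) {
  u <- unitize(axis$dir)
  for (r in restraints) {
    if (r$kind == "plane") {
      z <- axis_coords(xyz[r$atom, , drop = FALSE], axis)$z
      xyz[r$atom, ] <- xyz[r$atom, ] + (r$target_z - z) * u
    } else if (r$kind == "axial") {
      ac <- axis_coords(xyz[r$atom, , drop = FALSE], axis)
      if (ac$rho < 1e-9) {
        # atom on the axis: pick a deterministic radial direction
        rad <- if (abs(u[1]) < 0.9) unitize(c(1, 0, 0) - u[1] * u)
               else unitize(c(0, 1, 0) - u[2] * u)
      } else {
        rad <- as.numeric(ac$radial[1, ]) / ac$rho
      }
      shift <- (r$target_rho - ac$rho) * rad
      xyz[r$group, ] <- sweep(xyz[r$group, , drop = FALSE], 2, shift, "+")
    }
  }
  xyz
}
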