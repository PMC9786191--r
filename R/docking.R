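# Random-start ligand docking.
#
# Pipeline: hundreds of random ligand positions/orientations/conformations
# generated with the mass centre inside a sphere at the focus of the P1
# helices -> a fixed-count coarse MC-minimization of every start (no
# ligand-channel restraints) -> ranking by total energy -> full
# patience-terminated MCM refinement of the energetically best complexes ->
# a merged pose stack.  Reporting windows use the ligand-channel
# interaction energy.

#' Docking configuration
#'
#' @param center sphere centre; `NULL` = centroid of P1-helix C-alpha atoms
#'   (the focus of the P1 helices).
#' @param radius sphere radius, Angstrom (default 8).
#' @param n_starts number of random starts (default 400).
#' @param coarse_steps MC-minimizations per start in the coarse stage
#'   (default 100).
#' @param n_refine starts promoted to full MCM refinement (default 100).
#' @param refine_patience patience of the refinement MCM (default 1000).
#' @param report_window interaction-energy window for reporting, kcal/mol
#'   (default 10).
#' @param seed RNG seed.
#' @param mcm an [mcm_config()] template for engine amplitudes; its
#'   seed/patience fields are overridden per stage.
#' @return Object of class `DockingConfig`.
#' @export
docking_config <- function(center = NULL, radius = 8, n_starts = 400,
                           coarse_steps = 100, n_refine = 100,
                           refine_patience = 1000, report_window = 10,
                           seed = 1, mcm = mcm_config()) {
  stopifnot(radius > 0, n_refine <= n_starts || n_starts == 0)
  structure(as.list(environment()), class = "DockingConfig")
}

#' Centroid of the P1-helix C-alpha atoms
#'
#' @param structure an annotated [channel_structure()].
#' @return numeric(3): the focus of the P1 helices, the default docking
#'   sphere centre.
#' @export
p1_focus <- function(structure) {
  ann <- structure$annotations
  if (is.null(ann)) stop("structure has no segment annotations")
  p_res <- ann$resnum[ann$segment == "p"]
  at <- structure$atoms
  sel <- at$resnum %in% p_res & at$name == "CA"
  if (!any(sel)) stop("no P1-helix CA atoms found")
  colMeans(as.matrix(at[sel, c("x", "y", "z")]))
}

#' Generate random docking starts
#'
#' Mass centres uniform in the sphere, orientations uniform over rotation
#' space (Shoemake quaternions), rotatable torsions uniform in (-pi, pi].
#'
#' @param config a [docking_config()].
#' @param ligand a [ligand_model()].
#' @param structure an annotated [channel_structure()] (used when the
#'   sphere centre defaults to the P1 focus).
#' @param seed RNG seed (default from config).
#' @return list of starts; each has `xyz` (ligand coordinates), `center`
#'   (mass-centre position), `quat` and `torsions`.
#' @export
generate_starts <- function(config, ligand, structure = NULL,
                            seed = config$seed) {
  set.seed(seed)
  center <- config$center
  if (is.null(center)) center <- p1_focus(structure)
  base_xyz <- ligand_coords(ligand)
  nt <- if (!is.null(ligand$torsions)) nrow(ligand$torsions) else 0
  starts <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    # uniform point in the sphere by radius inversion
    u <- unitize(rnorm(3))
    pt <- center + u * config$radius * runif(1)^(1 / 3)
    tor <- if (nt > 0) runif(nt, -pi, pi) else numeric(0)
    xyz <- base_xyz
    if (nt > 0)
      for (k in seq_len(nt))
        xyz <- rotate_about_bond(xyz, ligand$torsions$a1[k],
                                 ligand$torsions$a2[k],
                                 ligand$torsions$moving[[k]], tor[k])
    q <- random_quat()
    R <- quat_to_matrix(q)
    lig <- set_ligand_coords(ligand, xyz)
    mc <- ligand_mass_center(lig)
    xyz <- sweep(sweep(xyz, 2, mc) %*% t(R), 2, pt, "+")
    starts[[s]] <- list(xyz = xyz, center = pt, quat = q, torsions = tor)
  }
  starts
}

#' Dock a ligand into a channel
#'
#' @param structure an annotated [channel_structure()] with types/charges.
#' @param ligand a [ligand_model()].
#' @param config a [docking_config()].
#' @param params an [energy_params()].
#' @param flexible passed to [mcm_state()] (default `"auto"`).
#' @return list with `stack` (a [pose_stack()] of refined complexes; its
#'   records carry total and interaction energies), `coarse` (data.frame of
#'   per-start coarse energies) and `config`.
#' @export
dock <- function(structure, ligand, config = docking_config(),
                 params = energy_params(), flexible = "auto") {
  starts <- generate_starts(config, ligand, structure)
  if (length(starts) == 0)
    return(list(stack = pose_stack(), coarse = NULL, config = config))
  mc <- config$mcm
  coarse <- vector("list", length(starts))
  stack <- pose_stack(window = mc$stack_window,
                      capacity = mc$stack_capacity,
                      sim_threshold = mc$stack_threshold)
  lig0 <- ligand
  for (s in seq_along(starts)) {
    lig0 <- set_ligand_coords(lig0, starts[[s]]$xyz)
    st <- mcm_state(structure, lig0, params, flexible = flexible)
    cfg <- mc
    cfg$n_steps <- config$coarse_steps
    cfg$seed <- config$seed + 13 * s
    run <- mcm_run(st, cfg)
    coarse[[s]] <- list(start = s, energy = run$best$objective,
                        state = run$best)
  }
  energies <- vapply(coarse, `[[`, numeric(1), "energy")
  top <- order(energies)[seq_len(min(config$n_refine, length(starts)))]
  for (s in top) {
    cfg <- mc
    cfg$n_steps <- NULL
    cfg$patience <- config$refine_patience
    cfg$seed <- config$seed + 97 * s
    run <- mcm_run(coarse[[s]]$state, cfg, stack = stack)
    stack <- run$stack
  }
  list(stack = stack,
       coarse = data.frame(start = seq_along(starts), energy = energies,
                           refined = seq_along(starts) %in% top),
       config = config)
}

#' Ranked pose table from a stack
#'
#' Filters records to an interaction-energy window above the best record,
#' ranks them, classifies each pose and lists contact residues (any heavy
#' atom within 4 Angstrom), labelled through the anchor table when segment
#' annotations are available.
#'
#' @param stack a [pose_stack()] whose records carry ligand coordinates.
#' @param structure the docked [channel_structure()].
#' @param window interaction-energy window, kcal/mol (default 10).
#' @param anchors optional [anchor_table()] for labelling contacts.
#' @param boundary radial TB/UDB classification boundary, Angstrom.
#' @param contact_cutoff contact distance, Angstrom (default 4).
#' @return data.frame: rank, energy, interaction, class, contacts.
#' @export
report_poses <- function(stack, structure, window = 10, anchors = NULL,
                         boundary = 8, contact_cutoff = 4) {
  if (length(stack$records) == 0) {
    warning("empty pose stack")
    return(data.frame(rank = integer(), energy = numeric(),
                      interaction = numeric(), class = character(),
                      contacts = character()))
  }
  inter <- vapply(stack$records, function(r)
    if (is.null(r$interaction)) r$energy else r$interaction, numeric(1))
  keep <- which(inter <= min(inter) + window)
  keep <- keep[order(inter[keep])]
  rows <- lapply(seq_along(keep), function(i) {
    r <- stack$records[[keep[i]]]
    cls <- classify_pose(structure, r$coords, boundary = boundary)
    cont <- contact_residues(structure, r$coords, cutoff = contact_cutoff,
                             anchors = anchors)
    data.frame(rank = i,
               energy = r$energy,
               interaction = inter[keep[i]],
               class = cls,
               contacts = paste(cont$label, collapse = " "))
  })
  do.call(rbind, rows)
}

#' Classify a ligand pose as fenestration (TB-like) or inner-pore (UDB-like)
#'
#' Geometric rule: the radial distance of the aromatic-ring centroid from
#' the pore axis against a boundary.  Ring atoms are taken as the ligand
#' atoms named C2..C6/CP when coordinates come with names, else the last
#' six atoms.
#'
#' @param structure a [channel_structure()] (for the pore axis).
#' @param lig_xyz ligand coordinate matrix.
#' @param boundary radial boundary, Angstrom (default 8).
#' @return `"TB"` (ring in the fenestration, beyond the boundary) or
#'   `"UDB"` (ring toward the inner pore).
#' @export
classify_pose <- function(structure, lig_xyz, boundary = 8) {
  n <- nrow(lig_xyz)
  ring <- lig_xyz[max(1, n - 5):n, , drop = FALSE]
  rho <- axis_coords(matrix(colMeans(ring), 1), structure$pore_axis)$rho
  if (rho > boundary) "TB" else "UDB"
}

#' Contact residues of a ligand pose
#'
#' @param structure a [channel_structure()].
#' @param lig_xyz ligand coordinates.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4).
#' @param anchors optional [anchor_table()]; with annotations present,
#'   contacts are reported as universal labels, else as residue numbers.
#' @return data.frame: resnum, label, distance.
#' @export
contact_residues <- function(structure, lig_xyz, cutoff = 4,
                             anchors = NULL) {
  at <- structure$atoms
  resnums <- sort(unique(at$resnum))
  ord <- order(at$resnum)
  at_s <- at[ord, ]
  runs <- rle(at_s$resnum)
  gend <- cumsum(runs$lengths)
  gstart <- c(1, head(gend, -1) + 1)
  d <- min_group_dist(as.matrix(at_s[, c("x", "y", "z")]),
                      as.matrix(lig_xyz), gstart, gend)
  hit <- d <= cutoff
  resnum <- runs$values[hit]
  label <- as.character(resnum)
  if (!is.null(anchors) && !is.null(structure$annotations)) {
    ann <- structure$annotations
    e <- anchors$entries
    for (k in seq_along(resnum)) {
      a <- ann[ann$resnum == resnum[k], ]
      if (nrow(a) == 1) {
        anc <- e[e$rep == a$rep & e$segment == a$segment, ]
        if (nrow(anc) == 1)
          label[k] <- paste0(a$rep, a$segment,
                             anc$anchor_relpos +
                               (resnum[k] - anc$anchor_resnum))
      }
    }
  }
  data.frame(resnum = resnum, label = label, distance = d[hit])
}
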