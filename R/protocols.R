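# Stateful protocols:
#
#  * In-silico voltage-sensor deactivation: the C-alpha beads of the five
#    S4 basic residues are pulled down through sets of planes normal to the
#    pore axis (default 21 steps of 0.5 Angstrom = 10.5 Angstrom total),
#    free to move within each plane but not to leave it, with the pore
#    repeats held by flat-bottom pins and moved as rigid bodies; each step's
#    MCM starts from the previous step's minimized structure.
#
#  * Ligand egress profiling: the ligand para-carbon is pulled away from
#    the pore axis in radial increments (default 80 steps of 0.4 Angstrom =
#    32 Angstrom); at each step a first MCM runs with backbone fixed and
#    the radius constrained, then a second MCM without the ligand
#    constraint, and the ligand-channel interaction energy, achieved radius
#    and 4-Angstrom contact residues are recorded.

#' Voltage-sensor deactivation schedule
#'
#' @param rep repeat whose S4 is pulled (1-4).
#' @param n_steps number of plane sets (default 21).
#' @param step_dz plane spacing, Angstrom (default 0.5); total commanded
#'   displacement is `n_steps * step_dz`.
#' @param patience per-step MCM patience (default 200).
#' @param pin_free_radius,pin_k pin parameters for the backbone pins.
#' @param mcm an [mcm_config()] template for engine amplitudes.
#' @return Object of class `DeactivationSchedule`.
#' @export
deactivation_schedule <- function(rep, n_steps = 21, step_dz = 0.5,
                                  patience = 200, pin_free_radius = 1,
                                  pin_k = 10, mcm = mcm_config()) {
  stopifnot(n_steps >= 1, step_dz > 0, rep %in% 1:4)
  structure(list(rep = rep, n_steps = n_steps, step_dz = step_dz,
                 patience = patience, pin_free_radius = pin_free_radius,
                 pin_k = pin_k, mcm = mcm,
                 total_dz = n_steps * step_dz),
            class = "DeactivationSchedule")
}

#' Ligand egress schedule
#'
#' @param n_steps number of radial increments (default 80).
#' @param step_dr radial increment, Angstrom (default 0.4); total commanded
#'   radial displacement is `n_steps * step_dr`.
#' @param patience per-MCM patience (default 100).
#' @param two_stage run the second, unconstrained MCM at each step
#'   (default TRUE).
#' @param mcm an [mcm_config()] template.
#' @return Object of class `EgressSchedule`.
#' @export
egress_schedule <- function(n_steps = 80, step_dr = 0.4, patience = 100,
                            two_stage = TRUE,
                            mcm = mcm_config(amp_trans = 0.4, amp_rot = 0.3,
                                             amp_torsion = 0.8)) {
  stopifnot(n_steps >= 0, step_dr > 0)
  structure(list(n_steps = n_steps, step_dr = step_dr, patience = patience,
                 two_stage = two_stage, mcm = mcm,
                 total_dr = n_steps * step_dr),
            class = "EgressSchedule")
}

# Atom indices of a repeat's pore-domain body (everything of that chain
# except the S4 stub beads).
repeat_body <- function(structure, rep) {
  at <- structure$atoms
  s4 <- structure$s4_beads
  idx <- which(at$chain == REPEAT_CHAINS[rep])
  if (!is.null(s4))
    idx <- setdiff(idx, which(at$resnum %in% s4$resnum[s4$rep == rep] &
                                at$chain == REPEAT_CHAINS[rep]))
  idx
}

s4_atom_indices <- function(structure, rep) {
  s4 <- structure$s4_beads
  if (is.null(s4)) stop("structure has no S4 bead annotation")
  rn <- s4$resnum[s4$rep == rep]
  if (length(rn) == 0) stop("no S4 beads for repeat ", rep)
  idx <- which(structure$atoms$resnum %in% rn &
                 structure$atoms$name == "CA" &
                 structure$atoms$chain == REPEAT_CHAINS[rep])
  if (length(idx) != length(rn))
    stop("S4 basic residues of repeat ", rep, " lack CA beads")
  idx
}

#' In-silico deactivation of a voltage-sensing domain
#'
#' Pulls the S4 basic-residue C-alpha beads of one repeat down the pore
#' axis through `n_steps` sets of planes, 5 planes per set (one per bead),
#' chaining each step's MCM from the previous step's minimized structure.
#' Backbone beads of all four repeats are pinned (flat-bottom) and each
#' repeat's pore domain moves as a rigid body, so S4 coupling springs can
#' transmit the downshift into the pore.
#'
#' @param structure a [channel_structure()] with S4 beads and springs (see
#'   [make_toy_channel()]).
#' @param schedule a [deactivation_schedule()].
#' @param params an [energy_params()].
#' @return list with `structures` (one minimized [channel_structure()] per
#'   step), `final`, and `pulled_z` (matrix of achieved bead z per step).
#' @export
deactivate_vsd <- function(structure, schedule, params = energy_params()) {
  pulled <- s4_atom_indices(structure, schedule$rep)
  axis <- structure$pore_axis
  z0 <- axis_coords(coords(structure)[pulled, , drop = FALSE], axis)$z
  bodies <- lapply(1:4, repeat_body, structure = structure)
  bodies <- bodies[vapply(bodies, length, 1L) > 0]
  # pin every backbone bead of the pore bodies at its template position
  at <- structure$atoms
  pin_idx <- intersect(unlist(bodies), which(at$name == "CA"))
  pins <- lapply(pin_idx, function(i)
    pin_restraint(i, as.numeric(at[i, c("x", "y", "z")]),
                  free_radius = schedule$pin_free_radius,
                  k = schedule$pin_k))
  # the other repeats' S4 beads stay put: treat them as part of no DOF set
  current <- structure
  out <- vector("list", schedule$n_steps)
  zmat <- matrix(NA_real_, schedule$n_steps, length(pulled))
  for (s in seq_len(schedule$n_steps)) {
    target_z <- z0 - s * schedule$step_dz
    planes <- lapply(seq_along(pulled), function(k)
      plane_restraint(pulled[k], target_z[k]))
    st <- mcm_state(current, ligand = NULL, params = params,
                    rigid_groups = bodies, cartesian = pulled,
                    restraints = c(pins, planes))
    cfg <- schedule$mcm
    cfg$patience <- schedule$patience
    cfg$seed <- schedule$mcm$seed + 1000 * schedule$rep + s
    run <- mcm_run(st, cfg)
    current <- set_coords(current, run$best$xyz)
    out[[s]] <- current
    zmat[s, ] <- axis_coords(run$best$xyz[pulled, , drop = FALSE], axis)$z
  }
  list(structures = out, final = current, pulled_z = zmat,
       commanded_dz = schedule$total_dz)
}

#' Build resting/activated voltage-sensor state models
#'
#' Applies the deactivation protocol to each listed repeat in order
#' (I, II, III, IV), chaining the minimized structures.  E.g.
#' `which = 1:4` yields a model with four resting sensors (VSD_RRRR-like);
#' `which = c(1, 2, 4)` leaves repeat III activated (VSD_RRAR-like).
#'
#' @param structure a [channel_structure()].
#' @param which integer set of repeats to deactivate (possibly empty).
#' @param schedule_for function(rep) returning the
#'   [deactivation_schedule()] per repeat.
#' @param params an [energy_params()].
#' @return The final [channel_structure()].
#' @export
build_state_models <- function(structure, which,
                               schedule_for = deactivation_schedule,
                               params = energy_params()) {
  for (r in sort(which))
    structure <- deactivate_vsd(structure, schedule_for(r), params)$final
  structure
}

#' MC-minimized ligand egress profile
#'
#' Starting from a bound pose (typically the fenestration/TB pose from
#' docking), the distance between the ligand para-carbon and the pore axis
#' is increased stepwise.  At each step, a first MCM runs with the channel
#' backbone fixed and the para-carbon radius constrained (the constraint
#' leaves azimuth and axial position free), then -- if `two_stage` -- a
#' second MCM without the ligand constraint; the ligand-channel interaction
#' energy after the last stage is recorded and the next step starts from
#' the achieved state.
#'
#' @param structure a [channel_structure()] with types/charges.
#' @param ligand a [ligand_model()] positioned at the starting pose.
#' @param schedule an [egress_schedule()].
#' @param params an [energy_params()].
#' @param flexible side-chain flexibility selection (default `"auto"`).
#' @param anchors optional [anchor_table()] for contact labels.
#' @param start_mcm reproduce the starting pose by an unconstrained MCM
#'   before the scan (default TRUE); set FALSE when the supplied pose is
#'   already minimized (e.g. by a radius-constrained MCM at the binding
#'   site).
#' @return Object of class `EgressProfile`: data.frame `steps` (step,
#'   target_rho, rho, energy, interaction, n_contacts, contacts), plus
#'   `early_exit` flag and the per-step ligand coordinates.
#' @export
egress_profile <- function(structure, ligand, schedule = egress_schedule(),
                           params = energy_params(), flexible = "auto",
                           anchors = NULL, start_mcm = TRUE) {
  pc <- ligand_anchor_index(ligand, "para_carbon")
  n_ch <- nrow(structure$atoms)
  axis <- structure$pore_axis
  lig_idx <- n_ch + seq_len(nrow(ligand$atoms))
  rho0 <- axis_coords(ligand_coords(ligand)[pc, , drop = FALSE], axis)$rho
  lig <- ligand
  record <- function(step, target, st) {
    lxyz <- st$xyz[lig_idx, , drop = FALSE]
    cont <- contact_residues(structure, lxyz, cutoff = 4, anchors = anchors)
    data.frame(step = step, target_rho = target,
               rho = axis_coords(lxyz[pc, , drop = FALSE], axis)$rho,
               energy = st$objective,
               interaction = st$energy[["interaction"]],
               n_contacts = nrow(cont),
               contacts = paste(cont$label, collapse = " "))
  }
  # reproduce the starting (bound) pose by an unconstrained MCM before the
  # scan, so the step-0 energy is the minimized binding-site energy
  st0 <- mcm_state(structure, lig, params, flexible = flexible)
  if (start_mcm) {
    cfg0 <- schedule$mcm
    cfg0$patience <- schedule$patience
    cfg0$seed <- schedule$mcm$seed
    st0 <- mcm_run(st0, cfg0)$best
  }
  rho0 <- axis_coords(st0$xyz[n_ch + pc, , drop = FALSE], axis)$rho
  rows <- list(record(0L, rho0, st0))
  snapshots <- list(st0$xyz[lig_idx, , drop = FALSE])
  early_exit <- FALSE
  if (schedule$n_steps > 0) {
    final_target <- rho0 + schedule$total_dr
    for (s in seq_len(schedule$n_steps)) {
      target <- rho0 + s * schedule$step_dr
      restr <- list(axial_restraint(n_ch + pc, target, group = lig_idx))
      lig <- set_ligand_coords(lig, snapshots[[length(snapshots)]])
      st <- mcm_state(structure, lig, params, flexible = flexible,
                      restraints = restr)
      cfg <- schedule$mcm
      cfg$patience <- schedule$patience
      cfg$seed <- schedule$mcm$seed + 2 * s
      run <- mcm_run(st, cfg)
      st <- run$best
      if (schedule$two_stage) {
        lig <- set_ligand_coords(lig, st$xyz[lig_idx, , drop = FALSE])
        st2 <- mcm_state(structure, lig, params, flexible = flexible)
        cfg$seed <- cfg$seed + 1
        run2 <- mcm_run(st2, cfg)
        st <- run2$best
      }
      rows[[length(rows) + 1]] <- record(s, target, st)
      snapshots[[length(snapshots) + 1]] <- st$xyz[lig_idx, , drop = FALSE]
      rho_now <- axis_coords(st$xyz[n_ch + pc, , drop = FALSE], axis)$rho
      if (rho_now > 1.5 * final_target) {
        early_exit <- TRUE
        break
      }
    }
  }
  structure(list(steps = do.call(rbind, rows), early_exit = early_exit,
                 snapshots = snapshots, schedule = schedule),
            class = "EgressProfile")
}

#' @export
print.EgressProfile <- function(x, ...) {
  cat("<EgressProfile: ", nrow(x$steps), " points, radius ",
      sprintf("%.1f", min(x$steps$target_rho)), " -> ",
      sprintf("%.1f", max(x$steps$target_rho)), " A",
      if (x$early_exit) ", early exit", ">\n", sep = "")
  invisible(x)
}

#' Egress barrier out of the binding-site basin
#'
#' The binding-site energy is the lowest energy recorded at achieved radii
#' within `site_rho` of the innermost point of the scan; the barrier is the
#' highest energy on the remaining outward path above that minimum.
#'
#' @param profile an [egress_profile()] result.
#' @param energy_col recorded energy to use (default `"interaction"`).
#' @param site_width radial extent of the site basin beyond the innermost
#'   achieved radius, Angstrom (default 2.5).
#' @param smooth apply a running median of 3 before locating the peak, so a
#'   single incompletely minimized step does not masquerade as the barrier
#'   (default TRUE).
#' @return list with `site_energy`, `peak`, `barrier` (kcal/mol) and
#'   `site_step` (row index of the site minimum).
#' @export
egress_barrier <- function(profile, energy_col = "interaction",
                           site_width = 2.5, smooth = TRUE) {
  e <- profile$steps[[energy_col]]
  rho <- profile$steps$rho
  in_site <- which(rho <= min(rho) + site_width)
  site_step <- in_site[which.min(e[in_site])]
  path <- e[site_step:length(e)]
  if (smooth && length(path) >= 3)
    path <- stats::runmed(path, 3)
  peak <- max(path)
  list(site_energy = e[site_step], peak = peak,
       barrier = peak - e[site_step], site_step = site_step)
}

#' Analyze an egress (or any 1-D energy) profile
#'
#' Interior minima are steps strictly lower than both neighbours (for
#' plateaus, the first step of the plateau).  The barrier from point A
#' towards point B is the maximum energy on the path between them minus
#' the energy at A.
#'
#' @param profile an [egress_profile()] result, or a numeric energy vector.
#' @param energy_col which recorded energy to analyze (default
#'   `"interaction"`, the ligand-channel interaction energy).
#' @return list with `minima` (indices, 1-based along the profile),
#'   `barriers` (data.frame from, to, barrier), `start_energy`,
#'   `end_energy`, and `start_barrier` (barrier from the first point to the
#'   last, i.e. out of the binding site).
#' @export
analyze_profile <- function(profile, energy_col = "interaction") {
  e <- if (is.numeric(profile)) profile else profile$steps[[energy_col]]
  n <- length(e)
  if (n < 2) stop("profile needs at least 2 points")
  minima <- integer(0)
  for (i in 2:(n - 1)) {
    if (e[i] < e[i - 1]) {
      j <- i
      while (j < n && e[j + 1] == e[i]) j <- j + 1
      if (j < n && e[j + 1] > e[i]) minima <- c(minima, i)
    }
  }
  barrier <- function(a, b) {
    path <- e[min(a, b):max(a, b)]
    max(path) - e[a]
  }
  pts <- unique(c(1, minima, n))
  bl <- list()
  for (k in seq_along(minima)) {
    m <- minima[k]
    bl[[length(bl) + 1]] <- data.frame(from = m, to = 1,
                                       barrier = barrier(m, 1))
    bl[[length(bl) + 1]] <- data.frame(from = m, to = n,
                                       barrier = barrier(m, n))
  }
  list(minima = minima,
       barriers = if (length(bl)) do.call(rbind, bl)
                  else data.frame(from = integer(), to = integer(),
                                  barrier = numeric()),
       start_energy = e[1], end_energy = e[n],
       start_barrier = barrier(1, n))
}
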