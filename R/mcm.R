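# Monte-Carlo-minimization engine over internal coordinates.
#
# A step = random perturbation of a subset of the degrees of freedom
# (ligand rigid-body pose + rotatable torsions, channel side-chain torsions,
# optional per-repeat rigid-body moves and Cartesian beads), followed by
# local energy minimization and Metropolis acceptance at temperature kT.
# The apparent global minimum drives patience-based termination: the run
# stops when `patience` consecutive minimizations fail to improve it.
# Every minimized candidate is offered to a pose stack that clusters
# low-energy complexes within an energy window.

#' MCM engine configuration
#'
#' @param patience consecutive non-improving minimizations before
#'   termination (default 1000).
#' @param n_steps if non-`NULL`, run exactly this many MC-minimizations
#'   instead of using patience (the coarse-refinement mode).
#' @param kT Metropolis acceptance temperature, kcal/mol (default 0.6).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @param amp_trans,amp_rot ligand rigid-body perturbation amplitudes
#'   (Angstrom, radians).
#' @param amp_torsion,amp_chi ligand / side-chain torsion amplitudes (rad).
#' @param amp_rigid_trans,amp_rigid_rot rigid-group amplitudes.
#' @param amp_cart Cartesian bead amplitude (Angstrom).
#' @param move_prob probability that each degree-of-freedom block is
#'   perturbed in a step (at least one always is).
#' @param improve_tol minimum energy decrease (kcal/mol) that counts as
#'   improving the apparent global minimum (default 1e-4).
#' @param maxit local-minimizer iteration cap per MC step.
#' @param max_steps hard cap on MC steps (safety).
#' @param stack_window,stack_capacity,stack_threshold pose-stack parameters;
#'   see [pose_stack()].
#' @return Object of class `MCMConfig`.
#' @export
mcm_config <- function(patience = 1000, n_steps = NULL, kT = 0.6, seed = 1,
                       amp_trans = 1.0, amp_rot = 0.6, amp_torsion = 1.5,
                       amp_chi = 1.5, amp_rigid_trans = 0.3,
                       amp_rigid_rot = 0.05, amp_cart = 0.5,
                       move_prob = 0.5, improve_tol = 1e-4, maxit = 40,
                       max_steps = 100000,
                       stack_window = 7, stack_capacity = 100,
                       stack_threshold = 1.5) {
  stopifnot(patience >= 1, kT > 0, maxit >= 1)
  structure(as.list(environment()), class = "MCMConfig")
}

#' Build an MCM state
#'
#' Binds a channel structure, an optional ligand, the energy model, the
#' movable degrees of freedom and a restraint set into a sampling state.
#'
#' @param structure a [channel_structure()] with types/charges assigned.
#' @param ligand optional [ligand_model()]; its rigid-body pose and
#'   rotatable torsions become degrees of freedom unless `lig_rigid`.
#' @param params an [energy_params()].
#' @param flexible residue numbers whose side-chain torsions are sampled;
#'   `"auto"` selects side chains within `flex_radius` of the ligand or of
#'   any restrained moving atom.
#' @param rigid_groups list of channel atom-index vectors moved as rigid
#'   bodies (used by the deactivation protocol).
#' @param cartesian channel atom indices moved as free Cartesian beads
#'   (the pulled S4 gating-charge beads).
#' @param restraints list of restraint objects (atom indices refer to the
#'   combined channel-then-ligand coordinates).
#' @param lig_rigid freeze the ligand pose/torsions (no ligand DOFs).
#' @param flex_radius selection radius for `flexible = "auto"` (Angstrom).
#' @return Object of class `MCMState` with cached energy.
#' @export
mcm_state <- function(structure, ligand = NULL, params = energy_params(),
                      flexible = NULL, rigid_groups = NULL, cartesian = NULL,
                      restraints = list(), lig_rigid = FALSE,
                      flex_radius = 10) {
  n_ch <- nrow(structure$atoms)
  xyz <- coords(structure)
  if (!is.null(ligand)) xyz <- rbind(xyz, ligand_coords(ligand))
  dimnames(xyz) <- NULL
  axis <- structure$pore_axis

  if (identical(flexible, "auto"))
    flexible <- select_flexible(structure, ligand, cartesian, flex_radius)
  chi <- sidechain_torsions(structure, flexible)

  lig_torsions <- NULL
  nlt <- 0
  if (!is.null(ligand) && !lig_rigid && !is.null(ligand$torsions)) {
    lig_torsions <- ligand$torsions
    nlt <- nrow(lig_torsions)
  }
  has_pose <- !is.null(ligand) && !lig_rigid

  # parameter layout
  off <- 0
  layout <- list()
  if (has_pose) { layout$lig <- 1:6; off <- 6 }
  if (nlt > 0) { layout$ltor <- off + seq_len(nlt); off <- off + nlt }
  if (length(chi) > 0) { layout$chi <- off + seq_along(chi)
                         off <- off + length(chi) }
  if (length(rigid_groups) > 0) {
    layout$rigid <- lapply(seq_along(rigid_groups),
                           function(g) off + (g - 1) * 6 + 1:6)
    off <- off + 6 * length(rigid_groups)
  }
  if (length(cartesian) > 0) {
    layout$cart <- off + seq_len(3 * length(cartesian))
    off <- off + 3 * length(cartesian)
  }

  moving <- unique(c(
    if (!is.null(ligand)) n_ch + seq_len(nrow(ligand$atoms)),
    unlist(lapply(chi, `[[`, "moving")),
    unlist(rigid_groups), cartesian))
  ctx <- energy_context(structure, ligand, params,
                        moving = if (length(moving)) moving)
  ctx <- freeze_static(ctx, xyz)

  st <- structure(list(
    structure = structure, ligand = ligand, params = params,
    n_ch = n_ch, xyz = xyz, axis = axis, ctx = ctx,
    chi = chi, chi_values = rep(0, length(chi)),
    lig_torsions = lig_torsions,
    torsion_values = rep(0, nlt),
    has_pose = has_pose,
    pose = list(q = c(1, 0, 0, 0), t = c(0, 0, 0)),
    rigid_groups = rigid_groups, cartesian = cartesian,
    restraints = restraints, layout = layout, npar = off),
    class = "MCMState")
  st$blob <- build_blob(st)
  st$xyz <- project_restraints(st$xyz, restraints, axis)
  st <- refresh_energy(st)
  st
}

# Pack the state into the flat list consumed by the compiled objective.
build_blob <- function(state) {
  ctx <- state$ctx
  p <- ctx$pairs
  tor <- state$lig_torsions
  has_tor_pot <- !is.null(tor) && !is.null(tor$ref) && any(!is.na(tor$ref))
  tk <- if (has_tor_pot) which(!is.na(tor$ref)) else integer(0)
  pins <- Filter(function(r) r$kind == "pin", state$restraints)
  planes <- Filter(function(r) r$kind == "plane", state$restraints)
  axials <- Filter(function(r) r$kind == "axial", state$restraints)
  n_ch <- state$n_ch
  list(
    has_pose = state$has_pose,
    lig_idx = if (!is.null(state$ligand))
      as.integer(n_ch + seq_len(nrow(state$ligand$atoms))) else integer(0),
    ltor_a1 = if (!is.null(tor)) as.integer(tor$a1 + n_ch) else integer(0),
    ltor_a2 = if (!is.null(tor)) as.integer(tor$a2 + n_ch) else integer(0),
    ltor_moving = if (!is.null(tor))
      lapply(tor$moving, function(m) as.integer(m + n_ch)) else list(),
    chi_a1 = vapply(state$chi, function(c) as.integer(c$a1), 1L),
    chi_a2 = vapply(state$chi, function(c) as.integer(c$a2), 1L),
    chi_moving = lapply(state$chi, function(c) as.integer(c$moving)),
    rigid_groups = lapply(state$rigid_groups, as.integer),
    cart_idx = as.integer(state$cartesian),
    axis_point = state$axis$point, axis_dir = unitize(state$axis$dir),
    plane_atom = vapply(planes, function(r) r$atom, 1L),
    plane_z = vapply(planes, function(r) r$target_z, 1.0),
    axial_atom = vapply(axials, function(r) r$atom, 1L),
    axial_rho = vapply(axials, function(r) r$target_rho, 1.0),
    axial_group = lapply(axials, function(r) as.integer(r$group)),
    pin_atom = vapply(pins, function(r) r$atom, 1L),
    pin_template = if (length(pins))
      do.call(rbind, lapply(pins, `[[`, "template"))
      else matrix(0, 0, 3),
    pin_free = vapply(pins, function(r) r$free_radius, 1.0),
    pin_k = vapply(pins, function(r) r$k, 1.0),
    pair_i = as.integer(p$i), pair_j = as.integer(p$j),
    pair_rmin = p$rmin, pair_eps = p$eps, pair_qfac = p$qfac,
    pair_ion = p$ion, pair_scale = p$scale, pair_cross = p$cross,
    cutoff = state$params$cutoff,
    use_vdw = state$params$use_vdw, use_elec = state$params$use_elec,
    spring_i = if (!is.null(ctx$springs)) as.integer(ctx$springs$i)
      else integer(0),
    spring_j = if (!is.null(ctx$springs)) as.integer(ctx$springs$j)
      else integer(0),
    spring_r0 = if (!is.null(ctx$springs)) ctx$springs$r0 else numeric(0),
    spring_k = if (!is.null(ctx$springs)) ctx$springs$k else numeric(0),
    tor_a1 = if (length(tk)) as.integer(tor$a1[tk] + n_ch) else integer(0),
    tor_a2 = if (length(tk)) as.integer(tor$a2[tk] + n_ch) else integer(0),
    tor_ref = if (length(tk)) as.integer(tor$ref[tk] + n_ch) else integer(0),
    tor_mv = if (length(tk))
      as.integer(vapply(tor$moving[tk], `[`, 1L, 1) + n_ch) else integer(0),
    torsion_barrier = if (state$params$use_torsion)
      state$params$torsion_barrier else 0,
    static_energy = if (!is.null(ctx$static_energy))
      sum(ctx$static_energy[c("vdw", "elec")]) else 0)
}

#' @export
print.MCMState <- function(x, ...) {
  cat("<MCMState: ", x$npar, " DOFs, objective ",
      sprintf("%.3f", x$objective), " kcal/mol>\n", sep = "")
  invisible(x)
}

# Side-chain rotatable bonds for the named residues.  Atoms are ranked by
# side-chain position (CB < G < D < E < Z-level names); rotatable bond k
# connects rank k-1 to rank k and moves all atoms of higher rank.
sidechain_torsions <- function(structure, resnums) {
  if (is.null(resnums) || length(resnums) == 0) return(list())
  rank_of <- function(name) {
    greek <- substr(sub("^[A-Z]", "", name), 1, 1)
    r <- match(greek, c("B", "G", "D", "E", "Z", "H"))
    ifelse(is.na(r), NA_integer_, r)
  }
  out <- list()
  at <- structure$atoms
  for (rn in unique(resnums)) {
    idx <- which(at$resnum == rn)
    ca <- idx[at$name[idx] == "CA"]
    if (length(ca) == 0) next
    side <- idx[!at$name[idx] %in% c("N", "CA", "C", "O")]
    if (length(side) == 0) next
    rk <- rank_of(at$name[side])
    side <- side[!is.na(rk)]; rk <- rk[!is.na(rk)]
    if (length(side) == 0) next
    o <- order(rk); side <- side[o]; rk <- rk[o]
    axis_atoms <- c(ca[1], side)
    for (k in seq_along(side)) {
      moving <- side[rk > rk[k]]
      if (length(moving) == 0) next
      out[[length(out) + 1]] <- list(a1 = axis_atoms[k], a2 = side[k],
                                     moving = moving, resnum = rn)
    }
  }
  out
}

#' Flexible side-chain selection rule
#'
#' Residues with any atom within `radius` of the ligand or of any moving
#' (Cartesian) restrained atom.
#'
#' @param structure a [channel_structure()].
#' @param ligand optional [ligand_model()].
#' @param cartesian channel atom indices that move during the protocol.
#' @param radius selection radius, Angstrom (default 10).
#' @return residue numbers.
#' @export
select_flexible <- function(structure, ligand = NULL, cartesian = NULL,
                            radius = 10) {
  probe <- rbind(if (!is.null(ligand)) ligand_coords(ligand),
                 coords(structure)[cartesian, , drop = FALSE])
  if (is.null(probe) || nrow(probe) == 0) return(integer(0))
  at <- structure$atoms
  resnums <- sort(unique(at$resnum))
  gidx <- split(seq_len(nrow(at)), at$resnum)[as.character(resnums)]
  gstart <- vapply(gidx, min, 1L); gend <- vapply(gidx, max, 1L)
  d <- min_group_dist(coords(structure), probe, gstart, gend)
  resnums[d <= radius]
}

# Apply a parameter vector to the base coordinates of a state (compiled
# fast path; apply_par_r below is the plain-R reference used in tests).
apply_par <- function(state, par) {
  mcm_transform(par, state$xyz, state$blob)
}

# Plain-R reference implementation of the same transform.
apply_par_r <- function(state, par) {
  xyz <- state$xyz
  n_ch <- state$n_ch
  lay <- state$layout
  if (!is.null(lay$ltor)) {
    for (k in seq_len(nrow(state$lig_torsions))) {
      d <- par[lay$ltor[k]]
      if (d != 0)
        xyz <- rotate_about_bond(xyz, state$lig_torsions$a1[k] + n_ch,
                                 state$lig_torsions$a2[k] + n_ch,
                                 state$lig_torsions$moving[[k]] + n_ch, d)
    }
  }
  if (!is.null(lay$lig)) {
    lig_idx <- n_ch + seq_len(nrow(state$ligand$atoms))
    w <- par[lay$lig[4:6]]
    if (any(w != 0)) {
      R <- rotvec_to_matrix(w)
      ctr <- colMeans(state$xyz[lig_idx, , drop = FALSE])
      xyz[lig_idx, ] <- rotate_about(xyz[lig_idx, , drop = FALSE], R, ctr)
    }
    dt <- par[lay$lig[1:3]]
    if (any(dt != 0))
      xyz[lig_idx, ] <- sweep(xyz[lig_idx, , drop = FALSE], 2, dt, "+")
  }
  if (!is.null(lay$chi)) {
    for (k in seq_along(state$chi)) {
      d <- par[lay$chi[k]]
      if (d != 0) {
        ch <- state$chi[[k]]
        xyz <- rotate_about_bond(xyz, ch$a1, ch$a2, ch$moving, d)
      }
    }
  }
  if (!is.null(lay$rigid)) {
    for (g in seq_along(state$rigid_groups)) {
      p <- par[lay$rigid[[g]]]
      idx <- state$rigid_groups[[g]]
      if (any(p != 0)) {
        if (any(p[4:6] != 0)) {
          R <- rotvec_to_matrix(p[4:6])
          ctr <- colMeans(state$xyz[idx, , drop = FALSE])
          xyz[idx, ] <- rotate_about(xyz[idx, , drop = FALSE], R, ctr)
        }
        xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, p[1:3], "+")
      }
    }
  }
  if (!is.null(lay$cart)) {
    d <- matrix(par[lay$cart], ncol = 3, byrow = TRUE)
    xyz[state$cartesian, ] <- xyz[state$cartesian, , drop = FALSE] + d
  }
  project_restraints(xyz, state$restraints, state$axis)
}

state_objective <- function(state, xyz) {
  e <- context_energy(state$ctx, xyz)
  e[["total"]] + restraint_energy(xyz, state$restraints, state$axis)
}

refresh_energy <- function(state) {
  e <- context_energy(state$ctx, state$xyz)
  state$energy <- e
  state$objective <- e[["total"]] +
    restraint_energy(state$xyz, state$restraints, state$axis)
  if (!is.finite(state$objective)) {
    pr <- state$ctx$pairs
    d <- sqrt(rowSums((state$xyz[pr$i, , drop = FALSE] -
                       state$xyz[pr$j, , drop = FALSE])^2))
    worst <- which.min(d)
    stop("non-finite energy; closest pair: atoms ", pr$i[worst], "-",
         pr$j[worst], " at ", sprintf("%.3f", d[worst]), " A")
  }
  state
}

# Commit a parameter vector: update coordinates and bookkeeping.
commit_par <- function(state, par) {
  state$xyz <- apply_par(state, par)
  lay <- state$layout
  if (!is.null(lay$lig)) {
    state$pose$t <- state$pose$t + par[lay$lig[1:3]]
    state$pose$q <- quat_normalize(
      quat_multiply(rotvec_to_quat(par[lay$lig[4:6]]), state$pose$q))
  }
  if (!is.null(lay$ltor))
    state$torsion_values <- wrap_angle(state$torsion_values + par[lay$ltor])
  if (!is.null(lay$chi))
    state$chi_values <- wrap_angle(state$chi_values + par[lay$chi])
  refresh_energy(state)
}

#' Randomly perturb an MCM state
#'
#' A random subset of the degree-of-freedom blocks is perturbed within the
#' configured amplitudes; restrained coordinates are re-projected.  With a
#' given `seed` the candidate is fully deterministic.  Zero amplitudes
#' leave the state unchanged.
#'
#' @param state an [mcm_state()].
#' @param config an [mcm_config()].
#' @param seed optional integer seeding this single perturbation.
#' @return The perturbed state.
#' @export
perturb <- function(state, config = mcm_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (state$npar == 0) return(state)
  par <- numeric(state$npar)
  lay <- state$layout
  # amplitudes of the DOF classes actually present in this state
  present_amps <- c(
    if (!is.null(lay$lig)) c(config$amp_trans, config$amp_rot),
    if (!is.null(lay$ltor)) config$amp_torsion,
    if (!is.null(lay$chi)) config$amp_chi,
    if (!is.null(lay$rigid)) c(config$amp_rigid_trans, config$amp_rigid_rot),
    if (!is.null(lay$cart)) config$amp_cart)
  attempts <- 0
  repeat {
    attempts <- attempts + 1
    touched <- FALSE
    if (!is.null(lay$lig)) {
      if (runif(1) < config$move_prob) {
        par[lay$lig[1:3]] <- runif(3, -config$amp_trans, config$amp_trans)
        touched <- touched || config$amp_trans > 0
      }
      if (runif(1) < config$move_prob) {
        ax <- unitize(rnorm(3))
        par[lay$lig[4:6]] <- ax * runif(1, -config$amp_rot, config$amp_rot)
        touched <- touched || config$amp_rot > 0
      }
    }
    if (!is.null(lay$ltor))
      for (k in seq_along(lay$ltor))
        if (runif(1) < config$move_prob) {
          par[lay$ltor[k]] <- runif(1, -config$amp_torsion,
                                    config$amp_torsion)
          touched <- touched || config$amp_torsion > 0
        }
    if (!is.null(lay$chi))
      for (k in seq_along(lay$chi))
        if (runif(1) < config$move_prob) {
          par[lay$chi[k]] <- runif(1, -config$amp_chi, config$amp_chi)
          touched <- touched || config$amp_chi > 0
        }
    if (!is.null(lay$rigid))
      for (g in seq_along(lay$rigid))
        if (runif(1) < config$move_prob) {
          par[lay$rigid[[g]][1:3]] <- runif(3, -config$amp_rigid_trans,
                                            config$amp_rigid_trans)
          ax <- unitize(rnorm(3))
          par[lay$rigid[[g]][4:6]] <- ax * runif(1, -config$amp_rigid_rot,
                                                 config$amp_rigid_rot)
          touched <- touched ||
            (config$amp_rigid_trans > 0 || config$amp_rigid_rot > 0)
        }
    if (!is.null(lay$cart))
      for (k in seq_along(state$cartesian))
        if (runif(1) < config$move_prob) {
          par[lay$cart[(k - 1) * 3 + 1:3]] <-
            runif(3, -config$amp_cart, config$amp_cart)
          touched <- touched || config$amp_cart > 0
        }
    if (touched || all(present_amps == 0) || attempts >= 100) break
  }
  commit_par(state, par)
}

#' Locally minimize an MCM state
#'
#' Bounded quasi-Newton (L-BFGS-B, numerical gradient) minimization of the
#' objective (nonbonded + bonded + torsion + restraint energy) in the
#' state's degree-of-freedom space, starting from the current coordinates.
#' Per-call box bounds on the parameters keep each minimization local (a
#' clashing start relaxes instead of being ejected); repeated MC steps
#' compose arbitrarily large motions.  Never returns a state with higher
#' energy than the input.
#'
#' @param state an [mcm_state()].
#' @param maxit iteration cap.
#' @return The minimized state.
#' @export
minimize_state <- function(state, maxit = 40) {
  if (state$npar == 0) return(state)
  base <- state$xyz
  blob <- state$blob
  fn <- function(par) mcm_objective(par, base, blob)
  gr <- function(par) mcm_gradient(par, base, blob)
  b <- par_bounds(state)
  res <- optim(numeric(state$npar), fn, gr, method = "L-BFGS-B",
               lower = -b, upper = b,
               control = list(maxit = maxit, factr = 1e9))
  if (res$value < state$objective - 1e-12) state <- commit_par(state, res$par)
  state
}

# Per-parameter bound of a single local minimization.
par_bounds <- function(state) {
  b <- numeric(state$npar)
  lay <- state$layout
  if (!is.null(lay$lig)) b[lay$lig] <- c(rep(2.5, 3), rep(1.2, 3))
  if (!is.null(lay$ltor)) b[lay$ltor] <- pi
  if (!is.null(lay$chi)) b[lay$chi] <- pi
  if (!is.null(lay$rigid))
    for (g in lay$rigid) b[g] <- c(rep(1.5, 3), rep(0.3, 3))
  if (!is.null(lay$cart)) b[lay$cart] <- 2
  b
}

#' Run an MCM trajectory
#'
#' @param state an [mcm_state()].
#' @param config an [mcm_config()].  With `n_steps` set the run performs a
#'   fixed number of MC-minimizations; otherwise it terminates when
#'   `patience` consecutive minimizations fail to improve the apparent
#'   global minimum.
#' @param stack optionally, an existing [pose_stack()] to keep filling.
#' @return list with `best` (lowest-objective state), `trajectory`
#'   (data.frame: step, energy, best, accepted), and `stack`.
#' @export
mcm_run <- function(state, config = mcm_config(), stack = NULL) {
  set.seed(config$seed)
  if (is.null(stack))
    stack <- pose_stack(window = config$stack_window,
                        capacity = config$stack_capacity,
                        sim_threshold = config$stack_threshold)
  current <- state
  best <- state
  counter <- 0
  fixed <- !is.null(config$n_steps)
  steps <- list()
  step <- 0
  stack <- stack_update(stack, state_record(state))
  while (if (fixed) step < config$n_steps
         else (counter < config$patience && step < config$max_steps)) {
    step <- step + 1
    cand <- perturb(current, config)
    cand <- minimize_state(cand, maxit = config$maxit)
    stack <- stack_update(stack, state_record(cand))
    improved <- cand$objective < best$objective - config$improve_tol
    if (improved) { best <- cand; counter <- 0 } else counter <- counter + 1
    dE <- cand$objective - current$objective
    accepted <- dE <= 0 || runif(1) < exp(-dE / config$kT)
    if (accepted) current <- cand
    steps[[step]] <- c(step = step, energy = cand$objective,
                       best = best$objective, accepted = accepted)
  }
  list(best = best,
       trajectory = as.data.frame(do.call(rbind, steps)),
       stack = stack)
}

# Snapshot of a state as a stack record.
state_record <- function(state) {
  sim_idx <- if (!is.null(state$ligand))
    state$n_ch + seq_len(nrow(state$ligand$atoms))
  else unique(c(unlist(state$rigid_groups), state$cartesian,
                unlist(lapply(state$chi, `[[`, "moving"))))
  list(energy = state$objective,
       interaction = state$energy[["interaction"]],
       coords = state$xyz[sim_idx, , drop = FALSE],
       pose = state$pose,
       torsions = state$torsion_values,
       chi = state$chi_values,
       xyz = state$xyz)
}

#' Create an empty pose stack
#'
#' Clustered low-energy records: every retained record lies within `window`
#' kcal/mol of the best record, no two records are closer than
#' `sim_threshold` (ligand heavy-atom RMSD in the common frame; the
#' lower-energy representative of a cluster is kept) and at most `capacity`
#' records are retained.
#'
#' @param window energy window above the best record, kcal/mol (default 7).
#' @param capacity maximum records (default 100).
#' @param sim_threshold clustering RMSD threshold, Angstrom (default 1.5).
#' @return Object of class `PoseStack`.
#' @export
pose_stack <- function(window = 7, capacity = 100, sim_threshold = 1.5) {
  structure(list(records = list(), window = window, capacity = capacity,
                 sim_threshold = sim_threshold),
            class = "PoseStack")
}

#' @export
print.PoseStack <- function(x, ...) {
  e <- stack_energies(x)
  cat("<PoseStack: ", length(x$records), " records",
      if (length(e)) paste0(", energies [", sprintf("%.2f", min(e)), ", ",
                            sprintf("%.2f", max(e)), "]"),
      ">\n", sep = "")
  invisible(x)
}

#' Energies of the records in a stack
#' @param stack a [pose_stack()].
#' @return numeric vector.
#' @export
stack_energies <- function(stack) {
  vapply(stack$records, `[[`, numeric(1), "energy")
}

#' Merge a record into a pose stack
#'
#' The record joins an existing cluster if its similarity coordinates are
#' within the threshold of that cluster's representative (the lower-energy
#' one is kept); otherwise it is inserted.  The stack is then re-pruned to
#' the energy window of the (possibly new) best record and to capacity,
#' evicting the highest-energy records.
#'
#' @param stack a [pose_stack()].
#' @param record list with at least `energy` and `coords` (as produced
#'   internally by the engine, or hand-built in tests).
#' @return The updated stack.
#' @export
stack_update <- function(stack, record) {
  stopifnot(is.finite(record$energy))
  recs <- stack$records
  if (length(recs) > 0 && !is.null(record$coords)) {
    d <- vapply(recs, function(r)
      if (is.null(r$coords) ||
          nrow(r$coords) != nrow(record$coords)) Inf
      else coord_rmsd(r$coords, record$coords), numeric(1))
    nearest <- which.min(d)
    if (length(nearest) && d[nearest] < stack$sim_threshold) {
      if (record$energy < recs[[nearest]]$energy) recs[[nearest]] <- record
      stack$records <- prune_stack(recs, stack)
      return(stack)
    }
  }
  recs[[length(recs) + 1]] <- record
  stack$records <- prune_stack(recs, stack)
  stack
}

prune_stack <- function(recs, stack) {
  if (length(recs) == 0) return(recs)
  e <- vapply(recs, `[[`, numeric(1), "energy")
  keep <- e < min(e) + stack$window
  recs <- recs[keep]; e <- e[keep]
  o <- order(e)
  recs <- recs[o]
  if (length(recs) > stack$capacity) recs <- recs[seq_len(stack$capacity)]
  recs
}

#' Merge two pose stacks
#' @param a,b [pose_stack()] objects with compatible parameters.
#' @return The merged stack.
#' @export
stack_merge <- function(a, b) {
  for (r in b$records) a <- stack_update(a, r)
  a
}
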