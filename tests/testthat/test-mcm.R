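# MCM engine: perturbation, minimization, trajectories, pose-stack
# clustering.

test_that("perturbation is deterministic given a seed and respects zero
           amplitudes", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           pore_pose(toy_ligand_cached()))
  st <- mcm_state(ch, lig, flexible = "auto")
  cfg <- mcm_config()
  a <- perturb(st, cfg, seed = 77)
  b <- perturb(st, cfg, seed = 77)
  expect_identical(a$xyz, b$xyz)
  c2 <- perturb(st, cfg, seed = 78)
  expect_gt(max(abs(a$xyz - c2$xyz)), 1e-8)
  zero <- mcm_config(amp_trans = 0, amp_rot = 0, amp_torsion = 0,
                     amp_chi = 0, amp_rigid_trans = 0, amp_rigid_rot = 0,
                     amp_cart = 0)
  same <- perturb(st, zero, seed = 5)
  expect_equal(same$xyz, st$xyz, tolerance = 1e-12)
})

test_that("repeated torsion perturbations span the configured amplitude", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           pore_pose(toy_ligand_cached()))
  st <- mcm_state(ch, lig, flexible = NULL)
  cfg <- mcm_config(amp_torsion = 1.2, move_prob = 1)
  set.seed(31)
  deltas <- replicate(400, perturb(st, cfg)$torsion_values[1])
  expect_gt(max(deltas), 0.9)
  expect_lt(min(deltas), -0.9)
  expect_lte(max(abs(deltas)), 1.2 + 1e-9)
})

test_that("minimization recovers a quadratic optimum and never increases
           energy", {
  # single free bead under a tight pin: analytic optimum at the template
  atoms <- data.frame(name = "CA", resname = "GLY", resnum = 1,
                      x = 1.3, y = -0.8, z = 0.5, type = "C3", charge = 0)
  s <- channel_structure(atoms)
  pin <- pin_restraint(1L, c(0, 0, 0), free_radius = 0, k = 5)
  st <- mcm_state(s, cartesian = 1L, restraints = list(pin))
  out <- minimize_state(st, maxit = 80)
  expect_lt(max(abs(out$xyz)), 1e-4)
  expect_lte(out$objective, st$objective)
  # already at the minimum: unchanged within tolerance
  again <- minimize_state(out, maxit = 40)
  expect_lt(coord_rmsd(again$xyz, out$xyz), 1e-3)
})

test_that("minimization is non-increasing across random starts", {
  ch <- toy_channel_cached()
  lig0 <- toy_ligand_cached()
  set.seed(12)
  for (k in 1:10) {
    pos <- c(runif(2, -2, 2), runif(1, -4, 2))
    lig <- set_ligand_coords(lig0, sweep(ligand_coords(lig0), 2,
                                         pos - ligand_mass_center(lig0),
                                         "+"))
    st <- mcm_state(ch, lig, flexible = NULL)
    out <- minimize_state(st, maxit = 20)
    expect_lte(out$objective, st$objective + 1e-9)
  }
})

test_that("mcm_run terminates by patience and tracks a monotone best", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           pore_pose(toy_ligand_cached()))
  st <- mcm_state(ch, lig, flexible = NULL)
  st <- minimize_state(st, maxit = 40)
  # patience 1 on a flat landscape (a state with no degrees of freedom
  # can never improve)
  flat <- mcm_state(ch)
  run1 <- mcm_run(flat, mcm_config(patience = 1, seed = 2, maxit = 5))
  expect_equal(nrow(run1$trajectory), 1)
  run <- mcm_run(st, fast_mcm(seed = 3, patience = 8))
  expect_true(all(diff(run$trajectory$best) <= 1e-9))
  # terminated exactly when `patience` candidates failed to improve
  n <- nrow(run$trajectory)
  expect_equal(run$trajectory$best[n - 7], run$trajectory$best[n])
})

test_that("identical seeds give identical trajectories and stacks", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           pore_pose(toy_ligand_cached()))
  st <- mcm_state(ch, lig, flexible = "auto")
  r1 <- mcm_run(st, fast_mcm(seed = 21, patience = 6))
  r2 <- mcm_run(st, fast_mcm(seed = 21, patience = 6))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_equal(stack_energies(r1$stack), stack_energies(r2$stack))
  expect_identical(r1$best$xyz, r2$best$xyz)
})

test_that("the engine finds the deeper of two planted wells", {
  # double-well landscape: two attractor beads of different strength;
  # brute-force enumeration of the wells gives the expected optimum
  atoms <- data.frame(
    name = c("O1", "O2"), resname = "TOY", resnum = 1:2,
    x = c(-4, 4), y = 0, z = 0, type = "O",
    charge = c(-0.25, -0.6), ionized = TRUE)
  s <- channel_structure(atoms)
  probe <- ligand_model(data.frame(name = "N1", element = "N", x = -4,
                                   y = 3.2, z = 0, type = "NP", charge = 1,
                                   ionized = TRUE),
                        anchors = list(ammonium = "N1"))
  # brute-force grid oracle over the symmetry plane (the landscape is
  # rotationally symmetric about the O1-O2 axis, so z = 0 suffices)
  probe_energy <- function(x, y) {
    e <- 0
    for (b in 1:2) {
      r <- sqrt((x - atoms$x[b])^2 + y^2)
      e <- e + pair_vdw(r, "NP", "O") +
        332.06 * atoms$charge[b] / (4 * r^2)
    }
    e
  }
  grid <- expand.grid(x = seq(-10, 10, by = 0.05),
                      y = seq(0.025, 6, by = 0.05))
  e_best <- min(mapply(probe_energy, grid$x, grid$y))
  const <- total_energy(s)$total  # fixed bead-bead term
  hits <- 0
  for (sd in 1:20) {
    st <- mcm_state(s, probe)
    run <- mcm_run(st, mcm_config(patience = 30, seed = sd, maxit = 40,
                                  amp_trans = 5))
    if (abs(run$best$objective - (e_best + const)) < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("stack clustering keeps the window, capacity and dissimilarity
           invariants", {
  mkrec <- function(e, xyz) list(energy = e, coords = xyz)
  base <- matrix(rnorm(24), 8, 3)
  s <- pose_stack(window = 7, capacity = 100, sim_threshold = 1.5)
  s <- stack_update(s, mkrec(0, base))
  s <- stack_update(s, mkrec(1, base))        # same pose: merged
  expect_length(s$records, 1)
  expect_equal(stack_energies(s), 0)          # lower representative kept
  s <- stack_update(s, mkrec(8, base + 5))    # above the window: rejected
  expect_length(s$records, 1)
  s <- stack_update(s, mkrec(5, base + 5))    # distinct pose in window
  expect_length(s$records, 2)
  s <- stack_update(s, mkrec(-10, base + 10)) # new best re-prunes everything
  expect_length(s$records, 1)
  expect_equal(stack_energies(s), -10)
})

test_that("stack invariants hold under random record streams", {
  set.seed(99)
  s <- pose_stack(window = 7, capacity = 20, sim_threshold = 1.5)
  for (k in 1:300) {
    xyz <- matrix(rnorm(12, sd = 4), 4, 3)
    s <- stack_update(s, list(energy = rnorm(1, sd = 6), coords = xyz))
    e <- stack_energies(s)
    expect_lte(length(e), 20)
    expect_lt(max(e) - min(e), 7)
    if (length(s$records) > 1) {
      d <- outer(seq_along(s$records), seq_along(s$records),
                 Vectorize(function(i, j)
                   if (i >= j) Inf else
                     coord_rmsd(s$records[[i]]$coords,
                                s$records[[j]]$coords)))
      expect_gte(min(d), 1.5)
    }
  }
})
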