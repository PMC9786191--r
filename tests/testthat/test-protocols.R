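# Deactivation and egress protocols, profile analysis.

test_that("default schedules command the prescribed total displacements", {
  d <- deactivation_schedule(rep = 3)
  expect_equal(d$n_steps, 21)
  expect_equal(d$step_dz, 0.5)
  expect_equal(d$total_dz, 10.5)
  e <- egress_schedule()
  expect_equal(e$n_steps, 80)
  expect_equal(e$step_dr, 0.4)
  expect_equal(e$total_dr, 32)
})

test_that("plane pulling drives the S4 beads to the commanded planes", {
  ch <- toy_channel_cached()
  sch <- deactivation_schedule(rep = 3, n_steps = 3, step_dz = 1.5,
                               patience = 4,
                               mcm = mcm_config(maxit = 20, seed = 6))
  res <- deactivate_vsd(ch, sch)
  expect_length(res$structures, 3)
  pulled <- poremcm:::s4_atom_indices(ch, 3)
  z0 <- coords(ch)[pulled, 3]
  for (s in 1:3)
    expect_true(all(abs(res$pulled_z[s, ] - (z0 - s * 1.5)) <= 0.05))
  # pinned backbone stayed near its template (free radius + slack)
  body <- intersect(unlist(lapply(1:4, poremcm:::repeat_body,
                                  structure = ch)),
                    which(ch$atoms$name == "CA"))
  dev <- sqrt(rowSums((coords(res$final)[body, , drop = FALSE] -
                       coords(ch)[body, , drop = FALSE])^2))
  expect_lt(max(dev), 1 + 0.8)
})

test_that("a single-step schedule moves the planes by one increment", {
  ch <- toy_channel_cached()
  sch <- deactivation_schedule(rep = 1, n_steps = 1, step_dz = 0.5,
                               patience = 3,
                               mcm = mcm_config(maxit = 15, seed = 2))
  res <- deactivate_vsd(ch, sch)
  expect_length(res$structures, 1)
  pulled <- poremcm:::s4_atom_indices(ch, 1)
  z0 <- coords(ch)[pulled, 3]
  expect_true(all(abs(res$pulled_z[1, ] - (z0 - 0.5)) <= 0.05))
})

test_that("build_state_models with an empty set returns the input", {
  ch <- toy_channel_cached()
  out <- build_state_models(ch, integer(0))
  expect_identical(coords(out), coords(ch))
})

test_that("an egress scan with no steps records only the start", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           tb_fenestration_pose(toy_ligand_cached()))
  sch <- egress_schedule(n_steps = 0, patience = 3,
                         mcm = gentle_mcm(seed = 4, patience = 3))
  prof <- egress_profile(ch, lig, sch, start_mcm = FALSE)
  expect_equal(nrow(prof$steps), 1)
  expect_equal(prof$steps$step, 0L)
})

test_that("constrained egress achieves each commanded radius in turn", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(),
                           tb_fenestration_pose(toy_ligand_cached()))
  sch <- egress_schedule(n_steps = 4, step_dr = 0.5, patience = 4,
                         two_stage = FALSE,
                         mcm = gentle_mcm(seed = 9, patience = 4))
  prof <- egress_profile(ch, lig, sch, start_mcm = FALSE)
  expect_equal(nrow(prof$steps), 5)
  expect_true(all(abs(prof$steps$rho - prof$steps$target_rho) <= 0.05))
  expect_true(all(diff(prof$steps$target_rho) > 0))
})

test_that("egress profile matches a dense brute-force scan of an analytic
           radial landscape", {
  # cylindrically symmetric landscape: two rings of attractor beads; a
  # single charged probe pulled radially must trace the same minimum-energy
  # radial profile as an exhaustive (z, azimuth) grid at each radius
  nring <- 48
  ring <- function(rho, z, resnum0) {
    a <- 2 * pi * seq_len(nring) / nring
    data.frame(name = "O", resname = "TOY",
               resnum = resnum0 + seq_len(nring),
               x = rho * cos(a), y = rho * sin(a), z = z,
               type = "O", charge = -0.3, ionized = FALSE)
  }
  atoms <- rbind(ring(5, 0, 0), ring(13, 0, 100))
  s <- channel_structure(atoms)
  probe <- ligand_model(data.frame(name = "CP", element = "C", x = 1.2,
                                   y = 0, z = 0.5, type = "NP", charge = 1,
                                   ionized = TRUE),
                        anchors = list(para_carbon = "CP"))
  sch <- egress_schedule(n_steps = 14, step_dr = 1, patience = 6,
                         two_stage = FALSE,
                         mcm = mcm_config(maxit = 60, seed = 3,
                                          amp_trans = 1.5, amp_rot = 0.3))
  prof <- egress_profile(s, probe, sch, flexible = NULL, start_mcm = FALSE)
  # oracle: for each target radius, global minimum over a dense (z, az) grid
  oracle <- function(rho) {
    zg <- seq(-8, 8, by = 0.02)
    azg <- seq(0, 2 * pi / nring, length.out = 8)
    best <- Inf
    bead <- as.matrix(atoms[, c("x", "y", "z")])
    for (az in azg) {
      px <- rho * cos(az); py <- rho * sin(az)
      for (z in zg) {
        d2 <- (bead[, 1] - px)^2 + (bead[, 2] - py)^2 + (bead[, 3] - z)^2
        r <- sqrt(d2)
        e <- sum(pair_vdw(r, rep("NP", nrow(bead)),
                          rep("O", nrow(bead))) +
                   332.06 * 1 * atoms$charge / (4 * d2))
        if (e < best) best <- e
      }
    }
    best
  }
  for (k in seq_len(nrow(prof$steps))) {
    expect_equal(prof$steps$interaction[k], oracle(prof$steps$rho[k]),
                 tolerance = 0.1)
  }
})

test_that("profile analysis finds interior minima and barriers", {
  a <- analyze_profile(c(0, 3, -2, 4, 1))
  expect_equal(a$minima, 3)
  b <- a$barriers
  expect_equal(b$barrier[b$from == 3 & b$to == 5], 6)
  expect_equal(b$barrier[b$from == 3 & b$to == 1], 5)
  # monotone increasing profile has no interior minima
  expect_length(analyze_profile(c(1, 2, 3, 4))$minima, 0)
  # plateau tie-break: first step of the plateau
  expect_equal(analyze_profile(c(5, 1, 1, 1, 6))$minima, 2)
  expect_error(analyze_profile(c(1)), "at least 2")
})

test_that("a constructed contact shell is reported residue by residue", {
  # 11 residues planted within 4 A of the probe, mirroring an interim-site
  # census; a 12th residue sits just outside
  probe <- ligand_model(data.frame(name = "CP", element = "C", x = 0, y = 0,
                                   z = 0, type = "C3", charge = 0),
                        anchors = list(para_carbon = "CP"))
  a <- 2 * pi * seq_len(11) / 11
  atoms <- rbind(
    data.frame(name = "CA", resname = "LEU", resnum = 1:11,
               x = 3.5 * cos(a), y = 3.5 * sin(a), z = 0,
               type = "C3", charge = 0),
    data.frame(name = "CA", resname = "LEU", resnum = 12,
               x = 0, y = 0, z = 4.6, type = "C3", charge = 0))
  s <- channel_structure(atoms)
  cont <- contact_residues(s, ligand_coords(probe), cutoff = 4)
  expect_equal(nrow(cont), 11)
  expect_setequal(cont$resnum, 1:11)
})
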