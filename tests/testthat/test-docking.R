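# Random-start docking: start generation, the dock pipeline, pose reports.

test_that("generated starts stay inside the sphere and are seeded", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  cfg <- docking_config(n_starts = 200, seed = 31)
  starts <- generate_starts(cfg, lig, ch)
  expect_length(starts, 200)
  center <- p1_focus(ch)
  d <- vapply(starts, function(s) {
    l <- set_ligand_coords(lig, s$xyz)
    sqrt(sum((ligand_mass_center(l) - center)^2))
  }, numeric(1))
  expect_true(all(d <= 8 + 1e-9))
  # determinism and seed sensitivity
  again <- generate_starts(cfg, lig, ch)
  expect_identical(starts[[7]]$xyz, again[[7]]$xyz)
  other <- generate_starts(docking_config(n_starts = 200, seed = 32), lig, ch)
  expect_gt(max(abs(starts[[7]]$xyz - other[[7]]$xyz)), 1e-6)
})

test_that("zero starts give an empty result", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  cfg <- docking_config(n_starts = 0, n_refine = 0)
  expect_length(generate_starts(cfg, lig, ch), 0)
  res <- dock(ch, lig, cfg)
  expect_length(res$stack$records, 0)
})

test_that("start orientations cover rotation space", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  starts <- generate_starts(docking_config(n_starts = 300, seed = 8), lig, ch)
  # the first quaternion component of a uniform rotation is symmetric
  # around zero and reaches toward the poles
  q1 <- vapply(starts, function(s) s$quat[1], numeric(1))
  expect_gt(max(q1), 0.9)
  expect_lt(min(q1), -0.9)
  expect_lt(abs(mean(q1)), 0.15)
})

test_that("docking recovers a planted pocket pose across seeds", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  ligp <- set_ligand_coords(lig, pore_pose(lig))
  pk <- plant_pocket(ch, ligp, strength = 1, relax = 80)
  hits <- 0
  for (sd in 1:5) {
    cfg <- docking_config(center = c(0, 0, 1), n_starts = 20,
                          coarse_steps = 10, n_refine = 3,
                          refine_patience = 40, seed = sd,
                          mcm = mcm_config(maxit = 25))
    res <- dock(pk$channel, lig, cfg)
    best <- res$stack$records[[1]]
    if (ligand_rmsd(best$coords, pk$optimum, lig) <= 1) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("more starts never worsen the best energy in expectation", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  ligp <- set_ligand_coords(lig, pore_pose(lig))
  pk <- plant_pocket(ch, ligp, strength = 1)
  diffs <- numeric(0)
  for (sd in 1:3) {
    small <- dock(pk$channel, lig,
                  docking_config(n_starts = 4, coarse_steps = 6,
                                 n_refine = 1, refine_patience = 15,
                                 seed = sd, mcm = mcm_config(maxit = 20)))
    large <- dock(pk$channel, lig,
                  docking_config(n_starts = 12, coarse_steps = 6,
                                 n_refine = 2, refine_patience = 15,
                                 seed = sd, mcm = mcm_config(maxit = 20)))
    diffs <- c(diffs, min(stack_energies(small$stack)) -
                 min(stack_energies(large$stack)))
  }
  expect_gte(mean(diffs), -1e-6)
})

test_that("report_poses filters by the interaction window and ranks", {
  mkrec <- function(e, inter, xyz) list(energy = e, interaction = inter,
                                        coords = xyz)
  ch <- toy_channel_cached()
  s <- pose_stack(window = 100)
  base <- tb_fenestration_pose(toy_ligand_cached())
  s <- stack_update(s, mkrec(0, 0, base))
  s <- stack_update(s, mkrec(5, 5, base + 5))
  s <- stack_update(s, mkrec(12, 12, base + 10))
  tab <- report_poses(s, ch, window = 10)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$interaction, c(0, 5))
  best_only <- report_poses(s, ch, window = 0)
  expect_equal(nrow(best_only), 1)
  expect_warning(report_poses(pose_stack(), ch), "empty")
})

test_that("pose classification separates fenestration and inner-pore
           poses", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  expect_equal(classify_pose(ch, tb_fenestration_pose(lig, rho = 10)), "TB")
  expect_equal(classify_pose(ch, pore_pose(lig)), "UDB")
})

test_that("contact residues report planted geometry with labels", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  # ligand in the inner pore touches the outer-pore-bottom residues
  pose <- pore_pose(lig)
  cont <- contact_residues(ch, pose, cutoff = 4, anchors = toy_anchors())
  expect_gt(nrow(cont), 0)
  expect_true(all(cont$distance <= 4))
  # labelled contacts resolve back to the residue numbers
  lab <- cont$label[grepl("^[1-4][opi]", cont$label)]
  for (l in lab)
    expect_true(resolve_label(l, toy_anchors()) %in% cont$resnum)
  # a pose far outside the channel touches nothing
  none <- contact_residues(ch, pose + 100, cutoff = 4)
  expect_equal(nrow(none), 0)
})
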