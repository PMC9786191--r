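# Reduced nonbonded energy model: closed forms, cutoff shifting, brute-force
# equivalence, rigid-motion invariance.

test_that("pair_vdw vanishes exactly at and beyond the cutoff", {
  p <- energy_params()
  expect_identical(pair_vdw(9, "C3", "C3", p), 0)
  expect_identical(pair_vdw(12, "C3", "C3", p), 0)
  # continuity approaching the cutoff
  eps <- 10^-(3:6)
  vals <- pair_vdw(9 - eps, "C3", "C3", p)
  expect_true(all(abs(vals) < abs(pair_vdw(8.5, "C3", "C3", p)) + 1e-12))
  expect_true(all(diff(abs(vals)) < 0))
  expect_lt(abs(vals[4]), 1e-10)
})

test_that("pair_vdw matches the closed-form shifted Lennard-Jones", {
  p <- energy_params()
  tt <- p$type_table
  rm <- 2 * tt$radius[tt$type == "C3"]
  eps <- tt$eps[tt$type == "C3"]
  for (r in c(rm, 3.1, 5, 7.5)) {
    lj <- eps * ((rm / r)^12 - 2 * (rm / r)^6)
    sw <- (1 - (r / 9)^2)^2
    expect_equal(pair_vdw(r, "C3", "C3", p), lj * sw, tolerance = 1e-12)
  }
  expect_error(pair_vdw(3, "C3", "NOPE", p), "unknown atom type")
})

test_that("pair_elec implements the distance-dependent dielectric", {
  p <- energy_params()
  # closed form with the conventional 332.06 constant: eps(r) = 4*r
  expect_equal(pair_elec(1, 1, 3, p, ionized = TRUE),
               332.06 / (4 * 3^2), tolerance = 1e-12)
  expect_identical(pair_elec(0, 1, 5, p), 0)
  expect_equal(pair_elec(0.3, -0.7, 4, p), pair_elec(-0.7, 0.3, 4, p))
  # ionized pairs are exempt from the cutoff, others are shifted to zero
  expect_identical(pair_elec(1, -1, 10, p, ionized = FALSE), 0)
  expect_lt(pair_elec(1, -1, 10, p, ionized = TRUE), 0)
})

brute_force_energy <- function(atoms, bonds, params) {
  # independent O(N^2) double loop written from the model definition
  n <- nrow(atoms)
  graph_dist <- matrix(Inf, n, n); diag(graph_dist) <- 0
  if (!is.null(bonds))
    for (k in seq_len(nrow(bonds))) {
      graph_dist[bonds$i[k], bonds$j[k]] <- 1
      graph_dist[bonds$j[k], bonds$i[k]] <- 1
    }
  for (m in 1:3)  # Floyd-Warshall-ish, enough for distance <= 3
    for (i in 1:n) for (j in 1:n)
      graph_dist[i, j] <- min(graph_dist[i, j],
                              min(graph_dist[i, ] + graph_dist[, j]))
  tt <- params$type_table
  e_vdw <- 0; e_el <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    scale <- if (graph_dist[i, j] <= 2) 0
             else if (graph_dist[i, j] == 3) params$scale14 else 1
    if (scale == 0) next
    r <- sqrt(sum((as.numeric(atoms[i, c("x", "y", "z")]) -
                   as.numeric(atoms[j, c("x", "y", "z")]))^2))
    ri <- tt$radius[tt$type == atoms$type[i]]
    rj <- tt$radius[tt$type == atoms$type[j]]
    ei <- tt$eps[tt$type == atoms$type[i]]
    ej <- tt$eps[tt$type == atoms$type[j]]
    sw <- if (r < params$cutoff) (1 - (r / params$cutoff)^2)^2 else 0
    rm <- ri + rj
    e_vdw <- e_vdw + scale * sqrt(ei * ej) *
      ((rm / r)^12 - 2 * (rm / r)^6) * sw
    ion <- atoms$ionized[i] || atoms$ionized[j]
    q <- 332.06 * atoms$charge[i] * atoms$charge[j] / params$eps0
    e_el <- e_el + scale * q / r^2 * (if (ion) 1 else sw)
  }
  c(vdw = e_vdw, elec = e_el)
}

test_that("total_energy equals the brute-force double loop", {
  set.seed(3)
  n <- 30
  atoms <- data.frame(
    name = paste0("X", 1:n), resname = "TOY", resnum = 1:n,
    x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8),
    type = sample(c("C3", "O", "NP", "CAR"), n, replace = TRUE),
    charge = round(runif(n, -0.5, 0.5), 2),
    ionized = runif(n) < 0.2)
  bonds <- data.frame(i = 1:5, j = 2:6)
  s <- channel_structure(atoms, bonds = bonds)
  e <- total_energy(s)
  bf <- brute_force_energy(atoms, bonds, energy_params())
  expect_equal(e$components[["vdw"]], bf[["vdw"]], tolerance = 1e-6)
  expect_equal(e$components[["elec"]], bf[["elec"]], tolerance = 1e-6)
  expect_equal(e$total, sum(e$components), tolerance = 1e-9)
})

test_that("interaction component contains only ligand-channel cross pairs", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  far <- set_ligand_coords(lig, sweep(ligand_coords(lig), 2, c(500, 0, 0),
                                      "+"))
  e <- total_energy(ch, far)
  # far away: only the ionized-group electrostatics survive, vanishing ~1/r^2
  expect_lt(abs(e$ligand_channel_interaction), 0.01)
  near <- set_ligand_coords(lig, pore_pose(lig))
  e2 <- total_energy(ch, near)
  expect_lt(e2$ligand_channel_interaction, -1)
  # the channel+ligand-internal part is independent of the ligand position
  # (rigid ligand: internal terms identical in both placements)
  expect_equal(e2$total - e2$ligand_channel_interaction,
               e$total - e$ligand_channel_interaction, tolerance = 1e-6)
})

test_that("two neutral atoms beyond the cutoff do not interact", {
  atoms <- data.frame(name = c("A", "B"), resname = "TOY", resnum = 1:2,
                      x = c(0, 12), y = 0, z = 0, type = "C3", charge = 0)
  e <- total_energy(channel_structure(atoms))
  expect_identical(e$total, 0)
})

test_that("energy is invariant under rigid motion of the whole system", {
  ch <- toy_channel_cached()
  lig <- set_ligand_coords(toy_ligand_cached(), pore_pose(toy_ligand_cached()))
  e0 <- total_energy(ch, lig)
  R <- poremcm:::rotvec_to_matrix(c(0.4, -1.1, 0.7))
  t <- c(13, -4, 8)
  ch2 <- apply_transform(ch, list(R = R, t = t))
  lig2 <- set_ligand_coords(lig, sweep(ligand_coords(lig) %*% t(R), 2, t,
                                       "+"))
  e1 <- total_energy(ch2, lig2)
  expect_equal(e1$total, e0$total, tolerance = 1e-6)
  expect_equal(e1$ligand_channel_interaction,
               e0$ligand_channel_interaction, tolerance = 1e-6)
})

test_that("an ammonium bead near the carbonyl site is attracted", {
  ch <- toy_channel_cached()
  probe <- ligand_model(data.frame(name = "N1", element = "N", x = 0, y = 0,
                                   z = 2.5, type = "NP", charge = 1,
                                   ionized = TRUE),
                        anchors = list(ammonium = "N1"))
  e <- total_energy(ch, probe)
  expect_lt(e$ligand_channel_interaction, -5)
})

test_that("untyped atoms are reported", {
  atoms <- data.frame(name = "A", resname = "X", resnum = 1, x = 0, y = 0,
                      z = 0, type = NA_character_, charge = 0)
  expect_error(energy_context(channel_structure(atoms)), "untyped")
})
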