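# Toy channel and ligand generators.

test_that("the fenestration width parameter is planted exactly", {
  for (w in c(8, 10, 12)) {
    ch <- make_toy_channel(toy_channel_spec(fenestration_width = w))
    for (k in 1:4) {
      p <- ch$fenestration_pairs[k, ]
      expect_equal(pair_distance(ch, c(p$resnum_a, p$resnum_b)), w,
                   tolerance = 0.1)
    }
  }
  expect_error(toy_channel_spec(fenestration_width = 2), "too small")
  expect_error(toy_channel_spec(fenestration_width = 25), "exceeds")
})

test_that("construction is deterministic", {
  a <- make_toy_channel()
  b <- make_toy_channel()
  expect_identical(coords(a), coords(b))
  expect_identical(a$atoms, b$atoms)
})

test_that("segment annotations resolve universal labels to real residues", {
  ch <- make_toy_channel()
  anc <- toy_anchors()
  rn <- resolve_label("3i19", anc)
  expect_true(rn %in% ch$atoms$resnum)
  ann <- ch$annotations
  expect_equal(ann$segment[ann$resnum == rn], "i")
  expect_equal(ann$rep[ann$resnum == rn], 3)
  # round-trip through the toy segment ranges
  lab <- label_of(rn, anc, toy_segment_ranges())
  expect_equal(format(lab), "3i19")
  # every annotated residue exists (constructor invariant) and each repeat
  # contributes o, p and i segments
  expect_setequal(unique(ann$segment), c("o", "p", "i"))
  expect_setequal(unique(ann$rep), 1:4)
})

test_that("the channel carries the cation-attractive carbonyl site", {
  ch <- make_toy_channel()
  oxy <- ch$atoms[ch$atoms$name == "O" & ch$atoms$charge < 0, ]
  expect_equal(nrow(oxy), 4)
  expect_equal(oxy$charge, rep(-0.4, 4))
  rho <- sqrt(oxy$x^2 + oxy$y^2)
  expect_true(all(rho < 5))  # at the outer-pore bottom, near the axis
})

test_that("S4 stubs provide five pullable beads per repeat with coupling
           springs", {
  ch <- make_toy_channel()
  for (r in 1:4)
    expect_length(poremcm:::s4_atom_indices(ch, r), 5)
  expect_gt(nrow(ch$springs), 0)
  # coupling springs are at rest in the unrelaxed assembly and close to
  # rest after equilibration (they engage only when S4 is pulled)
  raw <- make_toy_channel(toy_channel_spec(relax = FALSE))
  xyz <- coords(raw)
  len <- sqrt(rowSums((xyz[raw$springs$i, ] - xyz[raw$springs$j, ])^2))
  expect_lt(max(abs(len - raw$springs$r0)), 1e-9)
  xyz <- coords(ch)
  len <- sqrt(rowSums((xyz[ch$springs$i, ] - xyz[ch$springs$j, ])^2))
  expect_lt(max(abs(len - ch$springs$r0) * (ch$springs$k < 20)), 1.0)
})

test_that("mex-like and thio-like ligands have the documented anatomy", {
  mex <- make_toy_ligand(toy_ligand_spec("mex_like"))
  thio <- make_toy_ligand(toy_ligand_spec("thio_like"))
  for (lig in list(mex, thio)) {
    expect_equal(sum(lig$atoms$charge), 1)        # net +1 e
    expect_equal(sum(lig$atoms$name == "CP"), 1)  # one para-carbon
    expect_equal(sum(lig$atoms$name == "N1"), 1)  # one ammonium bead
    ring <- lig$atoms[lig$atoms$type == "CAR", ]
    expect_equal(nrow(ring), 6)
    # the para-carbon is the ring atom farthest from the ammonium bead
    n_xyz <- as.numeric(lig$atoms[1, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(as.matrix(ring[, c("x", "y", "z")]), 2,
                            n_xyz)^2))
    expect_equal(ring$name[which.max(d)], "CP")
  }
  expect_true(any(thio$atoms$element == "S"))
  dist_to_ring <- function(lig) {
    ring <- as.matrix(lig$atoms[lig$atoms$type == "CAR",
                                c("x", "y", "z")])
    sqrt(sum((colMeans(ring) -
                as.numeric(lig$atoms[1, c("x", "y", "z")]))^2))
  }
  expect_gt(dist_to_ring(thio), dist_to_ring(mex))
})

test_that("planted pockets make the pose a local optimum", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  ligp <- set_ligand_coords(lig, pore_pose(lig))
  pk <- plant_pocket(ch, ligp, strength = 1)
  e_opt <- total_energy(pk$channel,
                        set_ligand_coords(lig, pk$optimum))
  # strictly lower interaction than 100 random perturbed poses at >= 2 A
  set.seed(44)
  worse <- 0
  tried <- 0
  while (tried < 100) {
    xyz <- pk$optimum
    R <- poremcm:::rotvec_to_matrix(poremcm:::unitize(rnorm(3)) *
                                      runif(1, 0.2, 0.9))
    ctr <- colMeans(xyz)
    cand <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2,
                  ctr + runif(3, -2.5, 2.5), "+")
    if (ligand_rmsd(cand, pk$optimum, lig) < 2) next
    tried <- tried + 1
    e <- total_energy(pk$channel, set_ligand_coords(lig, cand))
    if (e$ligand_channel_interaction <=
        e_opt$ligand_channel_interaction) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("plant_pocket is a no-op at zero strength and rejects clashes", {
  ch <- toy_channel_cached()
  lig <- toy_ligand_cached()
  ligp <- set_ligand_coords(lig, pore_pose(lig))
  none <- plant_pocket(ch, ligp, strength = 0)
  expect_identical(coords(none$channel), coords(ch))
  expect_length(none$added, 0)
  # a pose buried inside a helix clashes
  bad <- set_ligand_coords(lig, sweep(ligand_coords(lig), 2,
                                      c(8 / sqrt(2), 8 / sqrt(2), 0), "+"))
  expect_error(plant_pocket(ch, bad), "clash")
})

test_that("generated structures round-trip through the structure writers", {
  ch <- make_toy_channel()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, path)
  back <- read_structure(path)
  expect_equal(coords(back), coords(ch), tolerance = 1e-3,
               ignore_attr = TRUE)
})
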