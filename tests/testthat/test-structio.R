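# Structure I/O, superposition, side-chain reference coordinates.

toy_structure <- function(xyz, names = rep("CA", nrow(xyz)),
                          resnames = rep("ALA", nrow(xyz)),
                          resnums = seq_len(nrow(xyz))) {
  channel_structure(data.frame(name = names, resname = resnames,
                               resnum = resnums, x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3]))
}

test_that("PDB write/read round-trips coordinates at PDB precision", {
  ch <- toy_channel_cached()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(ch$atoms))
  expect_equal(back$atoms$resnum, ch$atoms$resnum)
  expect_equal(trimws(back$atoms$name), ch$atoms$name)
  expect_equal(coords(back), coords(ch), tolerance = 1e-3,
               ignore_attr = TRUE)
  # coordinates are exact to the written 3 decimals
  expect_true(max(abs(coords(back) - round(coords(ch), 3))) < 1e-9)
})

test_that("a hand-written two-atom PDB parses bit-exactly", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.500  -1.250   0.125  1.00  0.00           C",
    "END"), path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(coords(s), matrix(c(1, 2.5, 2, -1.25, 3, 0.125), 2, 3),
               ignore_attr = TRUE)
})

test_that("multi-model trajectories round-trip model by model", {
  ch <- toy_channel_cached()
  snaps <- lapply(c(0, 1.5, -2), function(dz) {
    xyz <- coords(ch)
    xyz[, 3] <- xyz[, 3] + dz
    set_coords(ch, xyz)
  })
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(snaps, path)
  back <- read_trajectory(path, template = ch)
  expect_length(back, 3)
  for (m in 1:3)
    expect_equal(coords(back[[m]]), coords(snaps[[m]]), tolerance = 1e-3,
                 ignore_attr = TRUE)
})

test_that("trajectory writer rejects empty and inconsistent input", {
  ch <- toy_channel_cached()
  expect_error(write_trajectory(list(), tempfile()), "empty")
  short <- channel_structure(ch$atoms[1:10, ])
  expect_error(write_trajectory(list(ch, short), tempfile()),
               "inconsistent")
})

test_that("superposition of a structure on itself is the identity", {
  ch <- toy_channel_cached()
  fit <- superpose(ch, ch)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$R, diag(3), tolerance = 1e-10)
  expect_equal(fit$t, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a rigidly moved copy superposes back to zero RMSD", {
  ch <- toy_channel_cached()
  R <- poremcm:::rotvec_to_matrix(c(0, 0, pi / 2))
  moved <- apply_transform(ch, list(R = R, t = c(5, -3, 10)))
  fit <- superpose(moved, ch)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  back <- apply_transform(moved, fit)
  expect_equal(coords(back), coords(ch), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("superposition RMSD matches a brute-force rotation grid search", {
  # 4-point asymmetric pair; oracle scans rotations about z at 1 degree
  # resolution (the optimal rotation is constructed to be about z)
  X <- matrix(c(0, 0, 0, 3, 0, 0, 0, 2, 0, 1, 1, 0), 4, 3, byrow = TRUE)
  ang <- 37 * pi / 180
  Rz <- poremcm:::rotvec_to_matrix(c(0, 0, ang))
  Y <- X %*% t(Rz)
  Y[1, ] <- Y[1, ] + c(0.3, -0.2, 0)  # break exactness
  a <- toy_structure(X)
  b <- toy_structure(Y)
  fit <- superpose(a, b)
  oracle <- Inf
  for (deg in 0:359) {
    Rg <- poremcm:::rotvec_to_matrix(c(0, 0, deg * pi / 180))
    Xg <- X %*% t(Rg)
    # optimal translation at fixed rotation aligns centroids
    Xg <- sweep(Xg, 2, colMeans(Xg) - colMeans(Y))
    oracle <- min(oracle, coord_rmsd(Xg, Y))
  }
  expect_lte(fit$rmsd, oracle + 1e-6)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
})

test_that("superposition needs at least three paired atoms", {
  a <- toy_structure(matrix(rnorm(6), 2, 3))
  expect_error(superpose(a, a), ">= 3")
})

test_that("superposition RMSD is symmetric and rigid-motion invariant", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  Y <- X + matrix(rnorm(30, sd = 0.3), 10, 3)
  a <- toy_structure(X); b <- toy_structure(Y)
  r1 <- superpose(a, b)$rmsd
  r2 <- superpose(b, a)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  moved <- apply_transform(a, list(R = poremcm:::rotvec_to_matrix(
    c(0.3, -0.2, 0.9)), t = c(10, 0, -4)))
  expect_equal(superpose(moved, b)$rmsd, r1, tolerance = 1e-9)
})

test_that("cbeta_coord uses CB, falls back to CA for glycine, else errors", {
  atoms <- data.frame(
    name = c("CA", "CB", "CA", "N"),
    resname = c("ALA", "ALA", "GLY", "XXX"),
    resnum = c(1, 1, 2, 3),
    x = c(0, 1, 0, 9), y = c(0, 2, 0, 9), z = c(0, 3, 0, 9))
  s <- channel_structure(atoms)
  expect_equal(cbeta_coord(s, 1), c(1, 2, 3))
  expect_equal(cbeta_coord(s, 2), c(0, 0, 0))
  expect_error(cbeta_coord(s, 3), "neither")
  expect_error(cbeta_coord(s, 99), "not found")
})

test_that("generated structures survive an I/O round trip with labels", {
  ch <- toy_channel_cached()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, path)
  back <- read_structure(path)
  # the planted fenestration pair is still measurable after the round trip
  p <- ch$fenestration_pairs[3, ]
  expect_equal(pair_distance(back, c(p$resnum_a, p$resnum_b)),
               pair_distance(ch, c(p$resnum_a, p$resnum_b)),
               tolerance = 1e-2)
})
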