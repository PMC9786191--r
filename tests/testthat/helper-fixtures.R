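# Shared fixtures, built once per test run.  Channel construction includes a
# deterministic relaxation, so memoize the common geometries.

.fixtures <- new.env(parent = emptyenv())

toy_channel_cached <- function(width = 12) {
  key <- paste0("ch", width)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_toy_channel(toy_channel_spec(
      fenestration_width = width))
  .fixtures[[key]]
}

toy_ligand_cached <- function(kind = "mex_like") {
  key <- paste0("lig", kind)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_toy_ligand(toy_ligand_spec(kind))
  .fixtures[[key]]
}

# TB-like fenestration pose in the III/IV window (bisector azimuth 270):
# molecule axis radial, para-carbon at radius `rho`, ammonium toward the pore.
tb_fenestration_pose <- function(ligand, rho = 9) {
  lx <- ligand_coords(ligand)
  R <- poremcm:::rotvec_to_matrix(c(0, 0, -pi / 2))
  x <- lx %*% t(R)
  pc <- ligand_anchor_index(ligand, "para_carbon")
  sweep(x, 2, c(0, -rho, 0.5) - x[pc, ], "+")
}

# Inner-pore pose below the carbonyl site: molecule axis down, ammonium at
# the given height on the pore axis.
pore_pose <- function(ligand, n_at = c(0, 0, 2.6)) {
  lx <- ligand_coords(ligand)
  R <- poremcm:::rotvec_to_matrix(c(0, pi / 2, 0))
  x <- lx %*% t(R)
  sweep(x, 2, n_at - x[1, ], "+")
}

# Small engine configuration for fast test runs.
fast_mcm <- function(seed, patience = 10, ...) {
  mcm_config(patience = patience, seed = seed, maxit = 25, ...)
}

# Local-refinement amplitudes used by egress-style runs.
gentle_mcm <- function(seed, patience = 8, maxit = 25) {
  mcm_config(patience = patience, seed = seed, maxit = maxit,
             amp_trans = 0.25, amp_rot = 0.2, amp_torsion = 0.6)
}

# Radius-constrained MCM that settles the ligand at the fenestration binding
# site; returns the minimized state and the ligand model at that pose.
settle_tb_pose <- function(channel, ligand, rho = 9, seed = 5) {
  pose <- tb_fenestration_pose(ligand, rho = rho)
  lig <- set_ligand_coords(ligand, pose)
  n_ch <- nrow(channel$atoms)
  pc <- ligand_anchor_index(ligand, "para_carbon")
  lig_idx <- n_ch + seq_len(nrow(ligand$atoms))
  st <- mcm_state(channel, lig, flexible = "auto",
                  restraints = list(axial_restraint(n_ch + pc, rho,
                                                    group = lig_idx)))
  best <- mcm_run(st, gentle_mcm(seed))$best
  list(state = best,
       ligand = set_ligand_coords(ligand,
                                  best$xyz[lig_idx, , drop = FALSE]))
}
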