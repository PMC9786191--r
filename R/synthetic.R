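# Synthetic four-repeat pseudo-channel and MEX-like toy ligands.
#
# The generator emulates, at united-atom bead resolution, the architecture
# the protocols assume: four pseudo-symmetric repeats each contributing an
# outer helix (S5), a membrane-descending pore helix (P1), an inner helix
# (S6) and a five-bead S4 gating-charge stub; a ring of four backbone
# carbonyl beads at the outer-pore bottom forming a cation-attractive site;
# inter-repeat fenestrations of tunable width flanked by planted C-beta
# beads; and lipid-facing aromatic/polar decor residues on each repeat
# interface (the III/IV interface carries the largest census, providing an
# interim attraction site outside the fenestration).
#
# Geometry: pore axis = +z (extracellular up), distances in Angstrom,
# repeats at azimuths 45/135/225/315 degrees.  Residue numbers are
# (repeat-1)*100 + offset, so each repeat occupies its own hundred.

deg2rad <- function(d) d * pi / 180

cyl <- function(rho, az_deg, z) {
  a <- deg2rad(az_deg)
  c(rho * cos(a), rho * sin(a), z)
}

#' Specification of a synthetic toy channel
#'
#' @param fenestration_width gap (Angstrom) between the planted C-beta pair
#'   flanking each inter-repeat fenestration (default 12, emulating a
#'   channel with activated voltage sensors; narrower values emulate
#'   resting-sensor geometry).
#' @param attractor_strength magnitude of the negative partial charge on the
#'   four outer-pore carbonyl beads (default 0.4 e).
#' @param decor_counts named list of `c(aromatic, polar)` lipid-facing decor
#'   residue counts per interface `"I/II"`, `"II/III"`, `"III/IV"`, `"IV/I"`.
#' @param spring_k force constant of the S4-to-pore coupling springs
#'   (kcal/mol/A^2).
#' @param seed integer; construction is deterministic, the seed only feeds
#'   the optional coordinate `jitter`.
#' @param jitter s.d. of optional Gaussian coordinate noise on helix beads
#'   (default 0, exact geometry).
#' @param relax mechanically equilibrate the assembled repeats (one
#'   deterministic bounded rigid-body minimization under backbone pins)
#'   before planting the exact fenestration width, so the as-built
#'   structure is not under residual strain (default TRUE).
#' @return Object of class `SyntheticChannelSpec`.
#' @export
toy_channel_spec <- function(fenestration_width = 12, attractor_strength = 0.4,
                             decor_counts = list("I/II" = c(3, 2),
                                                 "II/III" = c(9, 1),
                                                 "III/IV" = c(6, 7),
                                                 "IV/I" = c(4, 3)),
                             spring_k = 6, seed = 1, jitter = 0,
                             relax = TRUE) {
  stopifnot(fenestration_width > 0, attractor_strength >= 0, spring_k >= 0)
  if (fenestration_width < 5)
    stop("fenestration_width ", fenestration_width,
         " too small for bead radii")
  if (fenestration_width > 18)
    stop("fenestration_width ", fenestration_width,
         " exceeds the inter-repeat spacing")
  structure(list(fenestration_width = fenestration_width,
                 attractor_strength = attractor_strength,
                 decor_counts = decor_counts, spring_k = spring_k,
                 seed = seed, jitter = jitter, relax = relax),
            class = "SyntheticChannelSpec")
}

REPEAT_CHAINS <- c("I", "II", "III", "IV")

#' Generate a synthetic four-repeat toy channel
#'
#' @param spec a [toy_channel_spec()].
#' @return A [channel_structure()] with segment annotations (o/p/i, anchors
#'   via [toy_anchors()]), pullable S4 beads, coupling springs, and a
#'   `fenestration_pairs` table naming the planted C-beta pair of each
#'   interface.
#' @export
make_toy_channel <- function(spec = toy_channel_spec()) {
  rows <- list()
  bonds <- list()
  springs <- list()
  ann <- list()
  add_atom <- function(name, element, resname, resnum, chain, xyz, type,
                       charge = 0, ionized = FALSE, mass = 12) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, element = element, resname = resname, resnum = resnum,
      chain = chain, x = xyz[1], y = xyz[2], z = xyz[3], type = type,
      charge = charge, ionized = ionized, mass = mass,
      stringsAsFactors = FALSE)
    length(rows)
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)
  add_spring <- function(i, j, r0, k)
    springs[[length(springs) + 1]] <<- data.frame(i = i, j = j, r0 = r0, k = k)
  annotate <- function(resnum, rep, segment)
    ann[[length(ann) + 1]] <<- data.frame(resnum = resnum, rep = rep,
                                          segment = segment)

  half_ang <- asin(spec$fenestration_width / (2 * 11)) * 180 / pi
  sf_resname <- c("ASP", "GLU", "LYS", "ALA")
  sf_charge <- c(-0.2, -0.2, 0.2, 0)
  idx <- list()  # bookkeeping: per repeat, named atom indices
  for (r in 1:4) {
    phi <- 45 + 90 * (r - 1)
    base <- (r - 1) * 100
    chain <- REPEAT_CHAINS[r]
    ids <- list()
    # S5 outer helix, o1..o8, azimuthally offset from S6
    prev <- NA
    for (j in 1:8) {
      i <- add_atom("CA", "C", "LEU", base + j, chain,
                    cyl(13.5, phi - 25, 6 - 1.5 * (j - 1)), "C3")
      annotate(base + j, r, "o")
      if (!is.na(prev)) add_bond(prev, i)
      prev <- i
      if (j == 1) ids$o1 <- i
    }
    # P1 pore helix, p45..p49, descending towards the outer-pore bottom
    prev <- NA
    for (j in 1:5) {
      resname <- c("ILE", "LEU", "VAL", "THR", "THR")[j]
      i <- add_atom("CA", "C", resname, base + 20 + j, chain,
                    cyl(12 - 1.5 * (j - 1), phi + 28, 11 - 1.5 * (j - 1)),
                    "C3")
      annotate(base + 20 + j, r, "p")
      if (!is.na(prev)) add_bond(prev, i)
      prev <- i
      if (j == 4) ids$p48_ca <- i
      if (j == 5) ids$p49_ca <- i
    }
    # backbone carbonyl of p48 facing the outer-pore bottom: the four of
    # these form the cation-attractive site
    o_i <- add_atom("O", "O", "THR", base + 24, chain, cyl(3.2, phi + 10, 3.5),
                    "O", charge = -spec$attractor_strength, mass = 16)
    add_bond(ids$p48_ca, o_i)
    add_bond(ids$p49_ca, o_i)
    # selectivity-filter residue at p50 (DEKA-like ring)
    i <- add_atom("CA", "C", sf_resname[r], base + 26, chain,
                  cyl(3.5, phi + 15, 6.5), "C3", charge = sf_charge[r])
    annotate(base + 26, r, "p")
    add_bond(ids$p49_ca, i)
    # S6 inner helix, i9..i20
    prev <- NA
    for (j in 1:12) {
      relpos <- 8 + j
      resname <- if (relpos == 15) "PHE" else "ILE"
      i <- add_atom("CA", "C", resname, base + 40 + j, chain,
                    cyl(8, phi, 4.5 - 1.5 * (j - 1)), "C3")
      annotate(base + 40 + j, r, "i")
      if (!is.na(prev)) add_bond(prev, i)
      prev <- i
      if (relpos == 12) ids$i12_ca <- i
      if (relpos == 13) ids$i13_ca <- i
    }
    # Fenestration window framing.  The planted width pair: a C-beta on
    # i12 facing the (r, r+1) interface and one on i13 facing the
    # (r-1, r) interface, both at z = 0; each carries a vertical column of
    # side beads so the window is a defined aperture, and horizontal bars
    # close the window above and below.
    for (side in c("next", "prev")) {
      bis <- if (side == "next") phi + 45 else phi - 45
      az <- if (side == "next") bis - half_ang else bis + half_ang
      parent <- if (side == "next") ids$i12_ca else ids$i13_ca
      resnum <- if (side == "next") base + 44 else base + 45
      cb <- add_atom("CB", "C", "ILE", resnum, chain, cyl(11, az, 0), "C3")
      add_bond(parent, cb)
      prevb <- cb
      top <- NA
      for (dz in c(2, 4, -2, -4)) {
        g <- add_atom(paste0("CG", match(dz, c(2, 4, -2, -4))), "C", "ILE",
                      resnum, chain, cyl(11, az, dz), "C3")
        add_bond(if (abs(dz) == 2) cb else prevb, g)
        prevb <- g
        if (dz == 4) top <- g
      }
      if (side == "next") {
        ids$gap_cb_next <- cb
        ids$gap_top_next <- top
      } else {
        ids$gap_cb_prev <- cb
        ids$gap_top_prev <- top
      }
    }
    # window bars close the (r, r+1) fenestration above and below: bead
    # chains spanning the aperture so the framed window is the only
    # passage; the span is capped so the bars never block the tangential
    # approach of the flanking columns when a voltage sensor is pulled
    bar_end <- max(2, min(half_ang - 10, 10))
    n_bar <- max(3, ceiling(2 * bar_end / 9) + 1)
    for (bz in c(5, -5)) {
      resnum <- base + if (bz > 0) 55 else 56
      prevb <- NA
      bar_az <- seq(-bar_end, bar_end, length.out = n_bar)
      for (bk in seq_along(bar_az)) {
        bI <- add_atom(paste0("B", bk), "C", "ILE",
                       resnum, chain, cyl(10.5, phi + 45 + bar_az[bk], bz),
                       "C3")
        if (!is.na(prevb)) add_bond(prevb, bI)
        prevb <- bI
      }
    }
    idx[[r]] <- ids
  }

  # lipid-facing decor residues on each interface: two columns of slots on
  # the interface wall with >= 3.6 A mutual separation, the first slots
  # flanking the egress path near z = 0
  az_off <- c(8, -8, 8, -8, -8, 8, 8, -8, -8, 8, 8, -8, -8)
  z_off <- c(1.85, 0, -1.85, 3.7, -3.7, 5.55, -5.55, 7.4, -7.4,
             9.25, -9.25, 11.1, -11.1)
  polar_side <- list(c("SER", "OG", "O", "OH", -0.30),
                     c("THR", "OG1", "O", "OH", -0.30),
                     c("GLN", "NE2", "N", "N", -0.25))
  for (r in 1:4) {
    key <- paste0(REPEAT_CHAINS[r], "/", REPEAT_CHAINS[r %% 4 + 1])
    counts <- spec$decor_counts[[key]]
    if (is.null(counts)) next
    n_ar <- counts[1]; n_po <- counts[2]
    # interleave the two kinds, starting with the more numerous one
    kinds <- character(0)
    po_left <- n_po; ar_left <- n_ar
    while (po_left + ar_left > 0) {
      if (po_left >= ar_left && po_left > 0) {
        kinds <- c(kinds, "po"); po_left <- po_left - 1
      } else {
        kinds <- c(kinds, "ar"); ar_left <- ar_left - 1
      }
    }
    bis <- 45 + 90 * (r - 1) + 45
    for (d in seq_along(kinds)) {
      owner <- if (d %% 2 == 1) r else r %% 4 + 1
      base <- (owner - 1) * 100
      chain <- REPEAT_CHAINS[owner]
      resnum <- base + 60 + d + (if (owner == r) 0 else 15)
      az <- bis + az_off[d]; z <- z_off[d]
      if (kinds[d] == "ar") {
        ca <- add_atom("CA", "C", "PHE", resnum, chain, cyl(16, az, z), "C3")
        cb <- add_atom("CB", "C", "PHE", resnum, chain, cyl(16.8, az, z),
                       "C3")
        cg <- add_atom("CG", "C", "PHE", resnum, chain, cyl(17.6, az, z),
                       "CAR", charge = -0.15)
        add_bond(ca, cb); add_bond(cb, cg)
      } else {
        ps <- polar_side[[(d - 1) %% 3 + 1]]
        ca <- add_atom("CA", "C", ps[1], resnum, chain, cyl(16, az, z), "C3")
        cb <- add_atom("CB", "C", ps[1], resnum, chain, cyl(16.8, az, z),
                       "C3")
        og <- add_atom(ps[2], ps[3], ps[1], resnum, chain, cyl(17.6, az, z),
                       ps[4], charge = as.numeric(ps[5]),
                       mass = if (ps[3] == "O") 16 else 14)
        add_bond(ca, cb); add_bond(cb, og)
      }
    }
  }

  # S4 gating-charge stubs: five pullable basic beads per repeat, coupled to
  # the pore helices of the neighbouring repeat (the structural contact that
  # lets voltage-sensor deactivation tighten the fenestration) and of the
  # own repeat
  s4 <- list()
  all_xyz <- function(i) {
    a <- rows[[i]]
    c(a$x, a$y, a$z)
  }
  for (r in 1:4) {
    phi <- 45 + 90 * (r - 1)
    base <- (r - 1) * 100
    chain <- REPEAT_CHAINS[r]
    prev <- NA
    bottom <- NA
    for (j in 1:5) {
      i <- add_atom("CA", "C", "ARG", base + 90 + j, chain,
                    cyl(21, phi + 45, 9 - 1.5 * (j - 1)), "C3",
                    charge = 0.1)
      s4[[length(s4) + 1]] <- data.frame(rep = r, resnum = base + 90 + j)
      if (!is.na(prev)) {
        add_bond(prev, i)
        add_spring(prev, i, 1.5, 20)
      }
      prev <- i
      if (j == 5) bottom <- i
    }
    idx[[r]]$s4_bottom <- bottom
  }
  # couple each S4 stub to the two C-beta columns flanking its interface
  # window: pulling the stub below the window stretches the springs and
  # draws the columns (and their rigid repeat bodies) together
  for (r in 1:4) {
    rn <- r %% 4 + 1
    for (target in c(idx[[r]]$gap_top_next, idx[[rn]]$gap_top_prev)) {
      r0 <- vnorm(all_xyz(idx[[r]]$s4_bottom) - all_xyz(target))
      add_spring(idx[[r]]$s4_bottom, target, r0, spec$spring_k)
    }
  }

  atoms <- do.call(rbind, rows)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    atoms$x <- atoms$x + rnorm(nrow(atoms), sd = spec$jitter)
    atoms$y <- atoms$y + rnorm(nrow(atoms), sd = spec$jitter)
    atoms$z <- atoms$z + rnorm(nrow(atoms), sd = spec$jitter)
  }
  ch <- channel_structure(
    atoms,
    annotations = do.call(rbind, ann),
    bonds = do.call(rbind, lapply(bonds, function(b)
      data.frame(i = b[1], j = b[2]))),
    springs = do.call(rbind, springs),
    s4_beads = do.call(rbind, s4))
  ch$fenestration_pairs <- data.frame(
    interface = paste0(REPEAT_CHAINS, "/", REPEAT_CHAINS[c(2, 3, 4, 1)]),
    rep_a = 1:4, resnum_a = (0:3) * 100 + 44,
    rep_b = c(2, 3, 4, 1), resnum_b = (c(2, 3, 4, 1) - 1) * 100 + 45)
  ch$spec <- spec
  if (isTRUE(spec$relax)) {
    # equilibrate the rigid repeat bodies under backbone pins so the
    # as-built structure carries no residual inter-repeat strain, then
    # re-plant the exact fenestration width
    bodies <- lapply(1:4, repeat_body, structure = ch)
    at <- ch$atoms
    pin_idx <- intersect(unlist(bodies), which(at$name == "CA"))
    pins <- lapply(pin_idx, function(i)
      pin_restraint(i, as.numeric(at[i, c("x", "y", "z")])))
    st <- mcm_state(ch, params = energy_params(), rigid_groups = bodies,
                    restraints = pins)
    st <- minimize_state(st, maxit = 100)
    ch <- set_coords(ch, st$xyz)
    gap_names <- c("CB", "CG1", "CG2", "CG3", "CG4")
    for (k in seq_len(nrow(ch$fenestration_pairs))) {
      p <- ch$fenestration_pairs[k, ]
      ia <- which(ch$atoms$resnum == p$resnum_a & ch$atoms$name %in% gap_names)
      ib <- which(ch$atoms$resnum == p$resnum_b & ch$atoms$name %in% gap_names)
      xa <- as.numeric(ch$atoms[ia[1], c("x", "y", "z")])
      xb <- as.numeric(ch$atoms[ib[1], c("x", "y", "z")])
      u <- unitize(xb - xa)
      excess <- (vnorm(xb - xa) - spec$fenestration_width) / 2
      xyz <- coords(ch)
      xyz[ia, ] <- sweep(xyz[ia, , drop = FALSE], 2, excess * u, "+")
      xyz[ib, ] <- sweep(xyz[ib, , drop = FALSE], 2, -excess * u, "+")
      ch <- set_coords(ch, xyz)
    }
  }
  ch
}

#' Anchor table matching [make_toy_channel()] numbering
#'
#' @return A [anchor_table()] for channel `"toy"`: per repeat, o1 at
#'   base+1, p50 at base+26, i9 at base+41 (base = (repeat-1)*100).
#' @export
toy_anchors <- function() {
  base <- (0:3) * 100
  anchor_table(rbind(
    data.frame(rep = 1:4, segment = "o", anchor_relpos = 1,
               anchor_resnum = base + 1),
    data.frame(rep = 1:4, segment = "p", anchor_relpos = 50,
               anchor_resnum = base + 26),
    data.frame(rep = 1:4, segment = "i", anchor_relpos = 9,
               anchor_resnum = base + 41)), channel = "toy")
}

#' @rdname toy_anchors
#' @return For `toy_segment_ranges()`: the residue spans of the toy's
#'   labelled segments (for [label_of()]).
#' @export
toy_segment_ranges <- function() {
  base <- (0:3) * 100
  rbind(data.frame(rep = 1:4, segment = "o", start = base + 1,
                   end = base + 8),
        data.frame(rep = 1:4, segment = "p", start = base + 21,
                   end = base + 26),
        data.frame(rep = 1:4, segment = "i", start = base + 41,
                   end = base + 52))
}

#' Specification of a toy cationic ligand
#'
#' @param kind `"mex_like"` (short ammonium-to-ring linker) or `"thio_like"`
#'   (elongated sulfur-containing linker).
#' @return Object of class `SyntheticLigandSpec`.
#' @export
toy_ligand_spec <- function(kind = c("mex_like", "thio_like")) {
  structure(list(kind = match.arg(kind)), class = "SyntheticLigandSpec")
}

#' Generate a toy MEX-like ligand
#'
#' A united-atom cationic blocker: one ammonium bead (net charge +1 with its
#' linker carbon, flagged ionized), a linker, and a six-carbon aromatic ring
#' whose para-carbon (the ring atom farthest from the ammonium bead) is
#' named `CP` and used as the pulled anchor in egress scans.  The
#' `thio_like` variant inserts a sulfur-containing extension, giving a
#' longer ammonium-to-ring distance.
#'
#' @param spec a [toy_ligand_spec()].
#' @return A [ligand_model()].
#' @export
make_toy_ligand <- function(spec = toy_ligand_spec()) {
  thio <- spec$kind == "thio_like"
  # zig-zag chain (tetrahedral-like bends, so no three bonded atoms are
  # collinear and torsions are well defined)
  at <- list(
    data.frame(name = "N1", element = "N", x = 0, y = 0, z = 0, type = "NP",
               charge = 0.7, ionized = TRUE),
    data.frame(name = "C1", element = "C", x = 1.45, y = 0.35, z = 0,
               type = "C3", charge = 0.3, ionized = TRUE))
  nb <- 2
  bonds <- list(c(1, 2))
  if (thio) {
    at <- c(at, list(
      data.frame(name = "S1", element = "S", x = 2.95, y = -0.15, z = 0,
                 type = "S", charge = 0, ionized = FALSE),
      data.frame(name = "C1B", element = "C", x = 4.25, y = 0.35, z = 0,
                 type = "C3", charge = 0, ionized = FALSE)))
    bonds <- c(bonds, list(c(2, 3), c(3, 4)))
    nb <- 4
  }
  last <- as.numeric(at[[nb]][c("x", "y", "z")])
  u <- c(1.30, -0.52, 0) / vnorm(c(1.30, -0.52, 0))  # ring axis direction
  v <- c(0.52, 1.30, 0) / vnorm(c(0.52, 1.30, 0))    # in-plane normal
  ctr <- last + 2.8 * u
  ring_names <- c("C2", "C3", "C4", "CP", "C5", "C6")
  ring_theta <- c(180, 120, 60, 0, 300, 240)
  for (k in seq_along(ring_names)) {
    th <- deg2rad(ring_theta[k])
    p <- ctr + 1.4 * cos(th) * u + 1.4 * sin(th) * v
    at <- c(at, list(data.frame(
      name = ring_names[k], element = "C", x = p[1], y = p[2], z = p[3],
      type = "CAR", charge = 0, ionized = FALSE)))
  }
  ring0 <- nb  # index of C2 minus 1
  bonds <- c(bonds, list(c(nb, ring0 + 1)),
             lapply(1:5, function(k) c(ring0 + k, ring0 + k + 1)),
             list(c(ring0 + 6, ring0 + 1)))
  atoms <- do.call(rbind, at)
  torsions <- data.frame(
    a1 = c(1, nb), a2 = c(2, ring0 + 1),
    ref = c(NA, nb - 1),
    moving = I(list(setdiff(seq_len(nrow(atoms)), 1:2),
                    (ring0 + 2):(ring0 + 6))))
  lig <- ligand_model(atoms,
                      bonds = do.call(rbind, lapply(bonds, function(b)
                        data.frame(i = b[1], j = b[2]))),
                      torsions = torsions,
                      anchors = list(ammonium = "N1", para_carbon = "CP"),
                      name = toupper(substr(spec$kind, 1, 3)))
  # two-fold ring flip: the four non-attachment, non-para carbons swap
  flip <- seq_len(nrow(atoms))
  flip[ring0 + c(2, 3, 5, 6)] <- ring0 + c(6, 5, 3, 2)
  lig$symmetries <- list(flip)
  lig
}

#' Plant an attractive binding pocket around a ligand pose
#'
#' Adds complementary beads to the channel -- an ionized carboxylate-like
#' bead opposite the ligand ammonium and two aromatic-attractor beads along
#' the ring normal -- so that the supplied pose becomes the energy optimum
#' of its neighbourhood.  Used for docking parameter-recovery tests.
#'
#' @param channel a [channel_structure()].
#' @param ligand a [ligand_model()] positioned at the pose to plant.
#' @param strength scaling of the planted charges (0 = no-op).
#' @param relax patience of the deterministic MCM relaxation that locates
#'   the basin floor of the planted pocket; the relaxed pose is returned as
#'   the known optimum.  `0` skips relaxation.
#' @param params an [energy_params()] (used by the relaxation).
#' @return list with the modified `channel`, the `optimum` ligand
#'   coordinates (the pocket's energy minimum), `input` (the supplied
#'   pose), and `added` (indices of the new atoms).
#' @export
plant_pocket <- function(channel, ligand, strength = 1, relax = 25,
                         params = energy_params()) {
  if (strength == 0)
    return(list(channel = channel, optimum = ligand_coords(ligand),
                input = ligand_coords(ligand), added = integer(0)))
  lxyz <- ligand_coords(ligand)
  cxyz <- coords(channel)
  dmin <- min_group_dist(cxyz, lxyz, 1L, nrow(cxyz))
  if (dmin < 1.8)
    stop("planted pose clashes with the channel (min distance ",
         sprintf("%.2f", dmin), " A)")
  ctr <- colMeans(lxyz)
  xn <- lxyz[ligand_anchor_index(ligand, "ammonium"), ]
  ring <- lxyz[match(c("C2", "C3", "C4", "CP", "C5", "C6"),
                     ligand$atoms$name), ]
  cR <- colMeans(ring)
  nrm <- unitize(pracma_cross(ring[2, ] - ring[1, ], ring[3, ] - ring[1, ]))
  # anchor beads: one opposite the ammonium, one opposite the charged
  # linker carbon (fixing the cation orientation), and a clamp of two
  # aromatic beads at the Lennard-Jones minimum along the ring normal
  xc1 <- lxyz[match("C1", ligand$atoms$name), ]
  d1 <- unitize(xn - ctr)
  perp <- unitize(pracma_cross(d1, nrm))
  clearance <- function(p) min(sqrt(rowSums(sweep(cxyz, 2, p)^2)))
  lig_clearance <- function(p) min(sqrt(rowSums(sweep(lxyz, 2, p)^2)))
  place <- function(from, dirs, dist) {
    for (d in dirs) {
      p <- from + dist * d
      if (clearance(p) >= 2.6 && lig_clearance(p) >= 2.5 &&
          vnorm(p - cR) > 2.5) return(p)
    }
    stop("no clash-free placement for a pocket anchor bead")
  }
  dirs_n <- list(d1, nrm, -nrm, perp, -perp,
                 unitize(d1 + perp), unitize(d1 - perp), -d1)
  n_bead <- place(xn, dirs_n, 2.9)
  # the second anchor must be far from the first so a cation cannot
  # chelate both at once
  d2 <- unitize(xc1 - (xn + cR) / 2)
  c1_bead <- NULL
  for (d in c(list(d2), dirs_n)) {
    p <- xc1 + 2.9 * d
    if (clearance(p) >= 2.6 && lig_clearance(p) >= 2.5 &&
        vnorm(p - cR) > 2.5 && vnorm(p - n_bead) >= 5.5) {
      c1_bead <- p
      break
    }
  }
  # a ring clamp: two triangles of aromatic beads sandwiching the ring
  # plane at the Lennard-Jones contact distance
  u2 <- unitize(ring[1, ] - cR)
  v2 <- unitize(pracma_cross(nrm, u2))
  clamp <- list()
  for (s in c(1, -1))
    for (th in c(0, 2 * pi / 3, 4 * pi / 3))
      clamp[[length(clamp) + 1]] <-
        cR + 3.6 * s * nrm + 1.4 * (cos(th) * u2 + sin(th) * v2)
  clamp <- do.call(rbind, clamp)
  for (k in seq_len(nrow(clamp)))
    if (clearance(clamp[k, ]) < 2.6)
      stop("ring clamp bead ", k, " clashes with channel atoms (",
           sprintf("%.2f", clearance(clamp[k, ])), " A)")
  new_pts <- rbind(n_bead, if (!is.null(c1_bead)) c1_bead, clamp)
  nn <- nrow(new_pts)
  has_c1 <- !is.null(c1_bead)
  base <- max(channel$atoms$resnum) + 1
  new_atoms <- data.frame(
    name = c("OP1", if (has_c1) "OP2", paste0("CP", seq_len(6))),
    element = c("O", if (has_c1) "O", rep("C", 6)),
    resname = "PKT", resnum = base + seq_len(nn) - 1, chain = "P",
    x = new_pts[, 1], y = new_pts[, 2], z = new_pts[, 3],
    type = c("O", if (has_c1) "O", rep("CAR", 6)),
    charge = c(-0.6, if (has_c1) -0.4, rep(-0.1, 6)) * strength,
    ionized = c(TRUE, if (has_c1) TRUE, rep(FALSE, 6)),
    mass = c(16, if (has_c1) 16, rep(12, 6)))
  atoms <- channel$atoms
  added <- nrow(atoms) + seq_len(nn)
  full <- rbind(atoms[, c("name", "element", "resname", "resnum", "chain",
                          "x", "y", "z", "type", "charge", "ionized",
                          "mass")],
                new_atoms)
  out <- channel_structure(full, annotations = channel$annotations,
                           pore_axis = channel$pore_axis,
                           bonds = channel$bonds, springs = channel$springs,
                           s4_beads = channel$s4_beads)
  out$fenestration_pairs <- channel$fenestration_pairs
  out$spec <- channel$spec
  optimum <- lxyz
  if (relax > 0) {
    st <- mcm_state(out, ligand, params, flexible = "auto")
    run <- mcm_run(st, mcm_config(patience = relax, seed = 1, maxit = 30))
    optimum <- run$best$xyz[nrow(out$atoms) + seq_len(nrow(lxyz)), ,
                            drop = FALSE]
  }
  list(channel = out, optimum = optimum, input = lxyz, added = added)
}

# cross product (named to avoid masking); kept local
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
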