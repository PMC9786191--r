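# Reduced nonbonded + torsional energy model.
#
# The model preserves the structural contracts of MCM channel modelling --
# a 9 Angstrom cutoff with a shifting function that zeroes energy and force
# exactly at the cutoff, a distance-dependent dielectric eps(r) = eps0 * r
# (so Coulomb energy falls off as 1/r^2), no cutoff for pairs involving
# ionized groups, 1-2/1-3 exclusions with 1-4 scaling -- while using a small
# united-atom Lennard-Jones type table rather than a full force field.
# Reported quantities are therefore orderings and contracts, not absolute
# kcal/mol values of any published force field.

COULOMB_CONST <- 332.06  # kcal * Angstrom / (mol * e^2)

#' Default united-atom Lennard-Jones type table
#'
#' Per-type radius (Angstrom; pair minimum distance is the sum of radii) and
#' well depth (kcal/mol; pair depth is the geometric mean).
#'
#' @return data.frame with columns `type`, `radius`, `eps`.
#' @export
default_type_table <- function() {
  data.frame(
    type   = c("C3", "CAR", "NP", "N", "O", "OH", "S", "H", "P", "X"),
    radius = c(2.00, 1.95, 1.75, 1.75, 1.60, 1.65, 2.00, 1.20, 2.10, 2.00),
    eps    = c(0.10, 0.12, 0.16, 0.16, 0.20, 0.20, 0.25, 0.02, 0.20, 0.15),
    stringsAsFactors = FALSE)
}

#' Energy model parameters
#'
#' @param cutoff nonbonded distance cutoff in Angstrom (default 9).
#' @param eps0 dimensionless prefactor of the distance-dependent dielectric
#'   `eps(r) = eps0 * r` (default 4).
#' @param type_table Lennard-Jones type table; see [default_type_table()].
#' @param scale14 scaling of 1-4 nonbonded pairs (default 0.5).
#' @param use_vdw,use_elec,use_torsion term switches.
#' @param torsion_barrier threefold torsion barrier height Vn (kcal/mol) for
#'   ligand rotatable bonds: `Vn/2 * (1 + cos(3*phi))`.
#' @return Object of class `EnergyParams`.
#' @export
energy_params <- function(cutoff = 9, eps0 = 4,
                          type_table = default_type_table(),
                          scale14 = 0.5, use_vdw = TRUE, use_elec = TRUE,
                          use_torsion = TRUE, torsion_barrier = 0.3) {
  stopifnot(cutoff > 0, eps0 > 0, all(type_table$eps >= 0))
  structure(list(cutoff = cutoff, eps0 = eps0, type_table = type_table,
                 scale14 = scale14, use_vdw = use_vdw, use_elec = use_elec,
                 use_torsion = use_torsion, torsion_barrier = torsion_barrier),
            class = "EnergyParams")
}

#' Read / write a Lennard-Jones type table as delimited text
#'
#' CSV with columns `type`, `radius`, `eps`.
#'
#' @param path file path.
#' @return [read_type_table()] returns a data.frame usable as the
#'   `type_table` of [energy_params()].
#' @export
read_type_table <- function(path) {
  tt <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("type", "radius", "eps") %in% names(tt)))
  tt
}

#' @rdname read_type_table
#' @param type_table table to write.
#' @export
write_type_table <- function(type_table, path) {
  write.csv(type_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

type_row <- function(type, params) {
  i <- match(type, params$type_table$type)
  if (anyNA(i))
    stop("unknown atom type(s): ",
         paste(unique(type[is.na(i)]), collapse = ", "))
  params$type_table[i, ]
}

#' Pairwise van der Waals energy (12-6 Lennard-Jones with cutoff shifting)
#'
#' The shifting function `S(r) = (1 - (r/cutoff)^2)^2` multiplies the
#' Lennard-Jones term so that energy and its first derivative are exactly
#' zero at the cutoff and beyond.
#'
#' @param r interatomic distance(s), Angstrom (> 0).
#' @param typeA,typeB atom type names from the type table.
#' @param params an [energy_params()].
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
pair_vdw <- function(r, typeA, typeB, params = energy_params()) {
  stopifnot(all(r > 0))
  ta <- type_row(typeA, params); tb <- type_row(typeB, params)
  rm <- ta$radius + tb$radius
  eps <- sqrt(ta$eps * tb$eps)
  s6 <- (rm / r)^6
  sw <- ifelse(r < params$cutoff, (1 - (r / params$cutoff)^2)^2, 0)
  eps * (s6^2 - 2 * s6) * sw
}

#' Pairwise electrostatic energy with distance-dependent dielectric
#'
#' `E = 332.06 * qi * qj / (eps0 * r^2)`.  Pairs where either atom belongs
#' to an ionized group are exempt from the distance cutoff; all other pairs
#' are shifted to zero at the cutoff by the same switching function as
#' [pair_vdw()].
#'
#' @param qi,qj partial charges (elementary charge units).
#' @param r distance(s), Angstrom (> 0).
#' @param params an [energy_params()].
#' @param ionized logical; does the pair involve an ionized group?
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
pair_elec <- function(qi, qj, r, params = energy_params(), ionized = FALSE) {
  stopifnot(all(r > 0))
  e <- COULOMB_CONST * qi * qj / (params$eps0 * r^2)
  if (ionized) return(e)
  sw <- ifelse(r < params$cutoff, (1 - (r / params$cutoff)^2)^2, 0)
  e * sw
}

# Bond-graph distances up to 3 (for 1-2/1-3 exclusion and 1-4 scaling).
# Returns data.frame(i, j, dist) for all pairs at graph distance 1..3.
bonded_neighbourhood <- function(bonds, n) {
  if (is.null(bonds) || nrow(bonds) == 0)
    return(data.frame(i = integer(), j = integer(), dist = integer()))
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  res <- list()
  for (start in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[start] <- 0L
    frontier <- start
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- d
      frontier <- nxt
    }
    found <- which(!is.na(dist) & dist > 0 & seq_len(n) > start)
    if (length(found))
      res[[length(res) + 1]] <- data.frame(i = start, j = found,
                                           dist = dist[found])
  }
  if (length(res) == 0)
    return(data.frame(i = integer(), j = integer(), dist = integer()))
  do.call(rbind, res)
}

# Build the per-pair constant tables for the kernel.  Atoms are the channel
# atoms followed by the ligand atoms; `moving` (atom indices) optionally
# splits the pair list into a static part (energy cached once) and a dynamic
# part re-evaluated per call.
#' Precompute an energy evaluation context
#'
#' Builds the pair list (with 1-2/1-3 exclusions and 1-4 scaling from the
#' bond graphs), per-pair Lennard-Jones and Coulomb constants, and -- when a
#' set of moving atoms is declared -- caches the static-static energy so MCM
#' evaluations only walk pairs involving moving atoms.
#'
#' @param structure a [channel_structure()] with `type`/`charge` assigned.
#' @param ligand optional [ligand_model()].
#' @param params an [energy_params()].
#' @param moving integer indices (into channel atoms then ligand atoms) of
#'   atoms that move during sampling; `NULL` means all.
#' @return An opaque context for [context_energy()].
#' @export
energy_context <- function(structure, ligand = NULL,
                           params = energy_params(), moving = NULL) {
  at <- structure$atoms
  if (anyNA(at$type))
    stop("untyped channel atoms: ",
         paste(head(which(is.na(at$type)), 5), collapse = ", "))
  n_ch <- nrow(at)
  type <- at$type; charge <- at$charge; ion <- at$ionized
  bonds <- structure$bonds
  if (!is.null(ligand)) {
    la <- ligand$atoms
    type <- c(type, la$type); charge <- c(charge, la$charge)
    ion <- c(ion, la$ionized)
    if (!is.null(ligand$bonds)) {
      lb <- data.frame(i = ligand$bonds$i + n_ch, j = ligand$bonds$j + n_ch)
      bonds <- rbind(if (!is.null(bonds)) bonds[, c("i", "j")], lb)
    }
  }
  n <- length(type)
  tr <- type_row(type, params)
  # all unordered pairs
  if (n < 2) {
    pi <- integer(0); pj <- integer(0)
  } else {
    pi <- rep(seq_len(n - 1), times = (n - 1):1)
    pj <- as.integer(unlist(lapply(seq_len(n - 1), function(i) (i + 1):n)))
  }
  scale <- rep(1, length(pi))
  bn <- bonded_neighbourhood(bonds, n)
  if (nrow(bn) > 0) {
    key <- paste(pi, pj)
    bkey <- paste(pmin(bn$i, bn$j), pmax(bn$i, bn$j))
    m <- match(bkey, key)
    scale[m[bn$dist <= 2]] <- 0
    scale[m[bn$dist == 3]] <- params$scale14
  }
  keep <- scale > 0
  pi <- pi[keep]; pj <- pj[keep]; scale <- scale[keep]
  pairs <- list(
    i = pi, j = pj, scale = scale,
    rmin = tr$radius[pi] + tr$radius[pj],
    eps = sqrt(tr$eps[pi] * tr$eps[pj]),
    qfac = COULOMB_CONST * charge[pi] * charge[pj] / params$eps0,
    ion = ion[pi] | ion[pj],
    cross = (pi <= n_ch) != (pj <= n_ch))
  ctx <- list(n_ch = n_ch, n = n, params = params, pairs = pairs,
              springs = structure$springs,
              torsions = if (!is.null(ligand)) ligand$torsions,
              static_energy = NULL, moving = NULL)
  if (!is.null(moving)) {
    mv <- rep(FALSE, n); mv[moving] <- TRUE
    dyn <- mv[pi] | mv[pj]
    ctx$static_pairs <- lapply(pairs, function(v) v[!dyn])
    ctx$pairs <- lapply(pairs, function(v) v[dyn])
    ctx$moving <- which(mv)
  }
  ctx
}

kernel_eval <- function(pairs, xyz, params) {
  nb_pair_energy(xyz, pairs$i, pairs$j, pairs$rmin, pairs$eps, pairs$qfac,
                 pairs$ion, pairs$scale, pairs$cross, params$cutoff,
                 params$use_vdw, params$use_elec)
}

spring_energy <- function(springs, xyz) {
  if (is.null(springs) || nrow(springs) == 0) return(0)
  d <- sqrt(rowSums((xyz[springs$i, , drop = FALSE] -
                     xyz[springs$j, , drop = FALSE])^2))
  sum(springs$k * (d - springs$r0)^2)
}

torsion_energy <- function(torsions, xyz, n_ch, params) {
  if (!params$use_torsion || is.null(torsions) || nrow(torsions) == 0)
    return(0)
  if (is.null(torsions$ref)) return(0)  # free rotors without a reference atom
  vn <- params$torsion_barrier
  e <- 0
  for (k in seq_len(nrow(torsions))) {
    ref <- torsions$ref[k]
    if (is.na(ref)) next
    a1 <- torsions$a1[k] + n_ch; a2 <- torsions$a2[k] + n_ch
    mv <- torsions$moving[[k]][1] + n_ch
    phi <- dihedral_angle(xyz[ref + n_ch, ], xyz[a1, ], xyz[a2, ], xyz[mv, ])
    e <- e + vn / 2 * (1 + cos(3 * phi))
  }
  e
}

#' Evaluate the energy of a coordinate set under a context
#'
#' @param ctx an [energy_context()].
#' @param xyz full coordinate matrix (channel atoms then ligand atoms).
#' @return Named numeric vector: `vdw`, `elec`, `bonded`, `torsion`,
#'   `interaction` (ligand-channel cross terms only) and `total`.
#' @export
context_energy <- function(ctx, xyz) {
  if (!is.null(ctx$static_pairs) && is.null(ctx$static_energy)) {
    # cache cannot be filled lazily without mutating; compute on the fly
    ctx$static_energy <- kernel_eval(ctx$static_pairs, xyz, ctx$params)
  }
  e <- kernel_eval(ctx$pairs, xyz, ctx$params)
  if (!is.null(ctx$static_energy)) e <- e + ctx$static_energy
  bonded <- spring_energy(ctx$springs, xyz)
  tors <- torsion_energy(ctx$torsions, xyz, ctx$n_ch, ctx$params)
  c(vdw = e[["vdw"]], elec = e[["elec"]], bonded = bonded, torsion = tors,
    interaction = e[["cross_vdw"]] + e[["cross_elec"]],
    total = e[["vdw"]] + e[["elec"]] + bonded + tors)
}

# Freeze the static-static energy of a context at given coordinates.
freeze_static <- function(ctx, xyz) {
  if (!is.null(ctx$static_pairs))
    ctx$static_energy <- kernel_eval(ctx$static_pairs, xyz, ctx$params)
  ctx
}

#' Total energy of a channel (+ optional ligand) system
#'
#' Full pairwise sum respecting bonded exclusions; equals a brute-force
#' double loop over all pairs.  The `interaction` component contains only
#' ligand x channel cross pairs.
#'
#' @param structure a [channel_structure()] with types/charges assigned.
#' @param ligand optional [ligand_model()].
#' @param params an [energy_params()].
#' @return Object of class `EnergyBreakdown`: list with `total`, per-term
#'   components and `ligand_channel_interaction` (kcal/mol).
#' @export
total_energy <- function(structure, ligand = NULL, params = energy_params()) {
  ctx <- energy_context(structure, ligand, params)
  xyz <- coords(structure)
  if (!is.null(ligand)) xyz <- rbind(xyz, ligand_coords(ligand))
  e <- context_energy(ctx, xyz)
  structure(list(total = e[["total"]],
                 components = c(vdw = e[["vdw"]], elec = e[["elec"]],
                                bonded = e[["bonded"]],
                                torsion = e[["torsion"]]),
                 ligand_channel_interaction = e[["interaction"]]),
            class = "EnergyBreakdown")
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat("<EnergyBreakdown: total ", sprintf("%.3f", x$total), " kcal/mol (",
      paste(sprintf("%s %.3f", names(x$components), x$components),
            collapse = ", "),
      "); ligand-channel interaction ",
      sprintf("%.3f", x$ligand_channel_interaction), ">\n", sep = "")
  invisible(x)
}
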