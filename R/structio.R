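# Structure containers and I/O.
#
# A ChannelStructure holds an ordered atom table plus pore-domain segment
# annotations and a pore-axis convention (unit axis direction + point; after
# alignment the axis is +z pointing extracellular).  PDB and mmCIF parsing is
# delegated to bio3d; the multi-model trajectory writer emits fixed-width
# MODEL/ENDMDL blocks at standard PDB coordinate precision (3 decimals).

ATOM_COLS <- c("serial", "name", "element", "resname", "resnum", "chain",
               "x", "y", "z", "occ", "b", "het", "type", "charge",
               "ionized", "mass")

#' Construct a ChannelStructure
#'
#' @param atoms data.frame with at least columns `name`, `resname`, `resnum`,
#'   `x`, `y`, `z`.  Missing bookkeeping columns (`serial`, `element`,
#'   `chain`, `occ`, `b`, `het`, `type`, `charge`, `ionized`, `mass`) are
#'   filled with defaults.
#' @param annotations data.frame mapping pore-domain residues to segments:
#'   columns `resnum`, `rep` (1-4), `segment` (k/o/p/i).
#' @param pore_axis list with unit `dir` and `point`; default +z through the
#'   origin (extracellular side at positive z).
#' @param bonds data.frame (`i`, `j`) of covalent bonds between atom indices
#'   (used for nonbonded exclusions).
#' @param springs data.frame (`i`, `j`, `r0`, `k`) of harmonic couplings
#'   (used by the synthetic channel to transmit S4 motion to the pore).
#' @param s4_beads data.frame (`rep`, `resnum`) naming the pullable S4
#'   gating-charge beads per repeat, if present.
#' @return Object of class `ChannelStructure`.
#' @export
channel_structure <- function(atoms, annotations = NULL, pore_axis = NULL,
                              bonds = NULL, springs = NULL, s4_beads = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("name", "resname", "resnum", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms need columns: ", paste(need, collapse = ", "))
  n <- nrow(atoms)
  defaults <- list(serial = seq_len(n), element = "C", chain = "A",
                   occ = 1, b = 0, het = FALSE, type = NA_character_,
                   charge = 0, ionized = FALSE, mass = 12)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  atoms <- atoms[, ATOM_COLS]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$resnum < 1)) stop("residue numbers must be >= 1")
  if (is.null(pore_axis)) pore_axis <- list(point = c(0, 0, 0), dir = c(0, 0, 1))
  pore_axis$dir <- unitize(pore_axis$dir)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    missing <- setdiff(annotations$resnum, atoms$resnum)
    if (length(missing) > 0)
      stop("annotated residues absent from atoms: ",
           paste(head(missing, 5), collapse = ", "))
  }
  structure(list(atoms = atoms, annotations = annotations,
                 pore_axis = pore_axis, bonds = bonds, springs = springs,
                 s4_beads = s4_beads),
            class = "ChannelStructure")
}

#' @export
print.ChannelStructure <- function(x, ...) {
  cat("<ChannelStructure: ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$resnum)), " residues",
      if (!is.null(x$annotations)) paste0(", ", nrow(x$annotations),
                                          " annotated"),
      ">\n", sep = "")
  invisible(x)
}

#' Coordinates of a ChannelStructure as an n x 3 matrix
#' @param structure a [channel_structure()].
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a ChannelStructure
#' @param structure a [channel_structure()].
#' @param xyz n x 3 matrix.
#' @return The updated structure.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms))
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Read a structure from PDB or mmCIF
#'
#' Parsing is delegated to [bio3d::read.pdb()] / [bio3d::read.cif()].
#' Heteroatoms (ligands, ions, waters) are retained but flagged in the `het`
#' column; with `drop_solvent = TRUE` (default) water molecules are removed.
#'
#' @param path file path.
#' @param format `"pdb"` or `"mmcif"` (guessed from the extension by default).
#' @param drop_solvent drop HOH/WAT residues.
#' @return A [channel_structure()] (without segment annotations; attach them
#'   with an anchor table as needed).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           drop_solvent = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  pdb <- if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
         else bio3d::read.cif(path, verbose = FALSE)
  a <- pdb$atom
  if (drop_solvent) a <- a[!a$resid %in% c("HOH", "WAT", "DOD"), ]
  atoms <- data.frame(serial = a$eleno, name = a$elety,
                      element = ifelse(is.na(a$elesy) | a$elesy == "",
                                       substr(trimws(a$elety), 1, 1), a$elesy),
                      resname = a$resid, resnum = a$resno, chain = a$chain,
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      b = ifelse(is.na(a$b), 0, a$b),
                      het = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  channel_structure(atoms)
}

fmt_atom_line <- function(serial, name, resname, chain, resnum, x, y, z,
                          occ, b, element, het) {
  rec <- ifelse(het, "HETATM", "ATOM  ")
  name <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial %% 100000, name, substr(resname, 1, 3),
          substr(chain, 1, 1), resnum %% 10000, x, y, z, occ, b,
          substr(element, 1, 2))
}

#' Write a structure as a (single-model) PDB file
#'
#' @param structure a [channel_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  write_trajectory(list(structure), path, single = TRUE)
}

#' Write an ordered list of structures as a multi-model PDB trajectory
#'
#' All structures must share atom ordering and count.  Each snapshot becomes
#' one MODEL block; coordinates round-trip through [read_structure()] at PDB
#' precision (3 decimals).
#'
#' @param structures non-empty list of [channel_structure()] objects sharing
#'   atom ordering.
#' @param path output file path.
#' @param single write a plain single-model file (no MODEL records); only
#'   valid for a length-1 list.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(structures, path, single = FALSE) {
  if (length(structures) == 0) stop("empty structure list")
  n <- nrow(structures[[1]]$atoms)
  for (s in structures)
    if (nrow(s$atoms) != n)
      stop("inconsistent atom counts across trajectory structures")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(structures)) {
    a <- structures[[m]]$atoms
    if (!single) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(fmt_atom_line(a$serial, a$name, a$resname, a$chain, a$resnum,
                             a$x, a$y, a$z, a$occ, a$b, a$element, a$het),
               con)
    if (!single) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' @param path file path.
#' @param template optional [channel_structure()] whose annotations/bonds are
#'   attached to every snapshot.
#' @return list of [channel_structure()] objects, one per MODEL.
#' @export
read_trajectory <- function(path, template = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  base <- read_structure(path)
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    s <- if (is.null(template)) base else template
    set_coords(s, xyz[seq_len(nrow(s$atoms)), , drop = FALSE])
  })
}

#' Kabsch superposition on a residue selection
#'
#' Computes the proper rotation + translation minimizing the RMSD of paired
#' atoms (default C-alpha) over `selection`, via singular value
#' decomposition with the standard reflection correction.
#'
#' @param mobile,reference [channel_structure()] objects.
#' @param selection residue numbers used for pairing (present in both); if
#'   `NULL`, all residues shared by both structures.
#' @param atom atom name to pair (default `"CA"`).
#' @return list with `R` (3x3 rotation), `t` (translation so that
#'   `x %*% t(R) + t` maps mobile onto reference), `rmsd` (Angstrom), and
#'   `n` (atoms paired).
#' @export
superpose <- function(mobile, reference, selection = NULL, atom = "CA") {
  pick <- function(s) {
    a <- s$atoms[s$atoms$name == atom, ]
    if (!is.null(selection)) a <- a[a$resnum %in% selection, ]
    a[order(a$resnum), ]
  }
  am <- pick(mobile); ar <- pick(reference)
  shared <- intersect(am$resnum, ar$resnum)
  if (length(shared) < 3)
    stop("superposition needs >= 3 paired atoms, got ", length(shared))
  X <- as.matrix(am[match(shared, am$resnum), c("x", "y", "z")])
  Y <- as.matrix(ar[match(shared, ar$resnum), c("x", "y", "z")])
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  if (qr(X0)$rank < 2)
    stop("degenerate (collinear) superposition selection")
  s <- svd(t(X0) %*% Y0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- unname(cy) - as.numeric(R %*% cx)
  fitted <- sweep(X %*% t(R), 2, t_vec, "+")
  list(R = unname(R), t = t_vec, rmsd = coord_rmsd(fitted, Y),
       n = length(shared))
}

#' Apply a rigid transform to a structure
#'
#' @param structure a [channel_structure()].
#' @param transform list with `R` and `t` as returned by [superpose()].
#' @return Transformed structure (pore axis transformed along).
#' @export
apply_transform <- function(structure, transform) {
  xyz <- coords(structure) %*% t(transform$R)
  xyz <- sweep(xyz, 2, transform$t, "+")
  structure <- set_coords(structure, xyz)
  structure$pore_axis$point <-
    as.numeric(transform$R %*% structure$pore_axis$point + transform$t)
  structure$pore_axis$dir <- as.numeric(transform$R %*% structure$pore_axis$dir)
  structure
}

#' Side-chain reference coordinate of a residue (C-beta; C-alpha in glycine)
#'
#' Fenestration widths are measured between C-beta atoms, falling back to
#' C-alpha for glycine (which has no C-beta).
#'
#' @param structure a [channel_structure()].
#' @param resnum residue number.
#' @return numeric(3) coordinates.
#' @export
cbeta_coord <- function(structure, resnum) {
  a <- structure$atoms[structure$atoms$resnum == resnum, ]
  if (nrow(a) == 0) stop("residue ", resnum, " not found")
  for (nm in c("CB", "CA")) {
    hit <- which(a$name == nm)
    if (length(hit) > 0)
      return(as.numeric(a[hit[1], c("x", "y", "z")]))
  }
  stop("residue ", resnum, " has neither CB nor CA")
}
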