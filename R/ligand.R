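# Ligand model: united-atom beads with partial charges, a bond graph,
# rotatable torsions and named anchor atoms (ammonium nitrogen, para-carbon
# of the aromatic ring).  The para-carbon is the atom pulled in egress scans.

#' Construct a LigandModel
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`,
#'   `type`, `charge`; optional `ionized` (atoms belonging to an ionized
#'   group, exempt from the electrostatic cutoff) and `mass`.
#' @param bonds data.frame (`i`, `j`) of bonds between atom indices.
#' @param torsions data.frame of rotatable torsions with columns `a1`, `a2`
#'   (the bond axis, atom indices) and `moving` (list-column of atom indices
#'   rotated with the bond).  May be `NULL` for rigid ligands.
#' @param anchors named list; recognised names are `ammonium` and
#'   `para_carbon`, values are atom names.
#' @param name ligand identifier.
#' @return Object of class `LigandModel`.
#' @export
ligand_model <- function(atoms, bonds = NULL, torsions = NULL,
                         anchors = list(), name = "LIG") {
  atoms <- as.data.frame(atoms)
  need <- c("name", "element", "x", "y", "z", "type", "charge")
  if (!all(need %in% names(atoms)))
    stop("ligand atoms need columns: ", paste(need, collapse = ", "))
  if (is.null(atoms$ionized)) atoms$ionized <- FALSE
  if (is.null(atoms$mass))
    atoms$mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    H = 1.008)[atoms$element]
  if (anyNA(atoms$mass)) atoms$mass[is.na(atoms$mass)] <- 12
  for (nm in names(anchors))
    if (!anchors[[nm]] %in% atoms$name)
      stop("anchor atom '", anchors[[nm]], "' (", nm, ") not in ligand")
  structure(list(atoms = atoms, bonds = bonds, torsions = torsions,
                 anchors = anchors, name = name),
            class = "LigandModel")
}

#' @export
print.LigandModel <- function(x, ...) {
  cat("<LigandModel '", x$name, "': ", nrow(x$atoms), " atoms, net charge ",
      sprintf("%+.2f", sum(x$atoms$charge)),
      if (!is.null(x$torsions)) paste0(", ", nrow(x$torsions), " torsions"),
      ">\n", sep = "")
  invisible(x)
}

#' Ligand coordinates as an n x 3 matrix
#' @param ligand a [ligand_model()].
#' @return numeric matrix.
#' @export
ligand_coords <- function(ligand) {
  as.matrix(ligand$atoms[, c("x", "y", "z")])
}

#' @rdname ligand_coords
#' @param xyz replacement coordinates.
#' @export
set_ligand_coords <- function(ligand, xyz) {
  stopifnot(nrow(xyz) == nrow(ligand$atoms))
  ligand$atoms$x <- xyz[, 1]; ligand$atoms$y <- xyz[, 2]
  ligand$atoms$z <- xyz[, 3]
  ligand
}

#' Mass center of a ligand
#' @param ligand a [ligand_model()].
#' @return numeric(3).
#' @export
ligand_mass_center <- function(ligand) {
  m <- ligand$atoms$mass
  colSums(ligand_coords(ligand) * m) / sum(m)
}

#' Index of a named anchor atom
#' @param ligand a [ligand_model()].
#' @param which `"para_carbon"` or `"ammonium"`.
#' @return integer atom index.
#' @export
ligand_anchor_index <- function(ligand, which = "para_carbon") {
  nm <- ligand$anchors[[which]]
  if (is.null(nm)) stop("ligand has no '", which, "' anchor atom")
  match(nm, ligand$atoms$name)
}

#' Symmetry-corrected ligand RMSD
#'
#' Coordinate RMSD between two poses of the same ligand, minimized over the
#' ligand's automorphisms (e.g. the two-fold flip of a phenyl ring, whose
#' carbons are indistinguishable).  Permutations are supplied by the ligand
#' model (`symmetries`: list of index permutations; the identity is always
#' included).
#'
#' @param a,b n x 3 coordinate matrices of the same ligand.
#' @param ligand the [ligand_model()] (for its symmetry permutations).
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(a, b, ligand = NULL) {
  perms <- c(list(seq_len(nrow(a))),
             if (!is.null(ligand)) ligand$symmetries)
  min(vapply(perms, function(p) coord_rmsd(a, b[p, , drop = FALSE]),
             numeric(1)))
}

#' Read / write a ligand description file
#'
#' Ligands are stored as small YAML files with `name`, `anchors`, an `atoms`
#' table (name, element, x, y, z, type, charge, ionized) and `bonds` /
#' `torsions` lists.
#'
#' @param path file path.
#' @return [read_ligand()] returns a [ligand_model()].
#' @export
read_ligand <- function(path) {
  y <- yaml::read_yaml(path)
  atoms <- do.call(rbind, lapply(y$atoms, as.data.frame))
  bonds <- if (length(y$bonds))
    do.call(rbind, lapply(y$bonds, function(b)
      data.frame(i = b[[1]], j = b[[2]])))
  torsions <- if (length(y$torsions))
    do.call(rbind, lapply(y$torsions, function(t)
      data.frame(a1 = t$axis[[1]], a2 = t$axis[[2]],
                 moving = I(list(unlist(t$moving))))))
  ligand_model(atoms, bonds = bonds, torsions = torsions,
               anchors = y$anchors, name = y$name)
}

#' @rdname read_ligand
#' @param ligand a [ligand_model()] to write.
#' @export
write_ligand <- function(ligand, path) {
  y <- list(name = ligand$name, anchors = ligand$anchors,
            atoms = lapply(seq_len(nrow(ligand$atoms)), function(i)
              as.list(ligand$atoms[i, c("name", "element", "x", "y", "z",
                                        "type", "charge", "ionized")])),
            bonds = if (!is.null(ligand$bonds))
              lapply(seq_len(nrow(ligand$bonds)), function(k)
                c(ligand$bonds$i[k], ligand$bonds$j[k])),
            torsions = if (!is.null(ligand$torsions))
              lapply(seq_len(nrow(ligand$torsions)), function(k)
                list(axis = c(ligand$torsions$a1[k], ligand$torsions$a2[k]),
                     moving = ligand$torsions$moving[[k]])))
  yaml::write_yaml(y, path)
  invisible(path)
}
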