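# Fenestration geometry and lipid-interface residue census.
#
# Fenestration widths are compared as C-beta--C-beta distances (C-alpha in
# glycine) between residues flanking the inter-repeat windows; narrowing on
# voltage-sensor deactivation shows up as negative width differences.  The
# lipid-facing census classifies interface residues as aromatic (F/W/Y) or
# polar (S/T/N/Q) when their side chains point outward, and reports special
# electronegative attractors (glycine backbone oxygens, proline side-chain
# nitrogens, cysteine sulfurs) separately.

AROMATIC_RES <- c("PHE", "TRP", "TYR")
POLAR_RES <- c("SER", "THR", "ASN", "GLN")

#' Distance pair definition
#'
#' @param a,b residue numbers, or label strings resolved through `anchors`.
#' @param interface optional interface tag (`"I/II"` ... `"IV/I"`).
#' @param anchors [anchor_table()] used when `a`/`b` are labels.
#' @return Object of class `DistancePair`.
#' @export
distance_pair <- function(a, b, interface = NA_character_, anchors = NULL) {
  to_num <- function(x) {
    if (is.character(x)) resolve_label(parse_label(x), anchors) else
      as.integer(x)
  }
  a <- to_num(a); b <- to_num(b)
  if (a == b) stop("distance pair must name two different residues")
  structure(list(a = a, b = b, interface = interface),
            class = "DistancePair")
}

#' C-beta to C-beta distance of a residue pair
#'
#' Uses [cbeta_coord()] (C-alpha for glycine) on both residues.
#'
#' @param structure a [channel_structure()].
#' @param pair a [distance_pair()] or numeric length-2 vector of residue
#'   numbers.
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(structure, pair) {
  if (!inherits(pair, "DistancePair"))
    pair <- distance_pair(pair[1], pair[2])
  vnorm(cbeta_coord(structure, pair$a) - cbeta_coord(structure, pair$b))
}

#' Compare residue-pair distances across two structures
#'
#' @param structA,structB [channel_structure()] objects (e.g. activated vs
#'   deactivated states).  Distances are superposition-invariant, so the
#'   structures need not be aligned.
#' @param pairs list of [distance_pair()] objects.
#' @return data.frame: interface, a, b, dA, dB, diff (= dA - dB); pairs
#'   missing in either structure are flagged with NA rather than failing.
#' @export
compare_states <- function(structA, structB, pairs) {
  rows <- lapply(pairs, function(p) {
    dA <- tryCatch(pair_distance(structA, p), error = function(e) NA_real_)
    dB <- tryCatch(pair_distance(structB, p), error = function(e) NA_real_)
    data.frame(interface = p$interface, a = p$a, b = p$b,
               dA = dA, dB = dB, diff = dA - dB,
               missing = is.na(dA) || is.na(dB))
  })
  do.call(rbind, rows)
}

interface_reps <- function(interface) {
  parts <- strsplit(interface, "/")[[1]]
  r <- match(parts, REPEAT_CHAINS)
  if (anyNA(r)) stop("unknown interface tag '", interface, "'")
  r
}

#' Census of lipid-facing aromatic/polar residues of a repeat interface
#'
#' A residue of the two flanking repeats is counted as lipid-facing when its
#' side-chain centroid points outward (angle between the radial direction
#' at the C-alpha and the C-alpha-to-centroid direction below
#' `facing_angle`) and lies beyond `min_radius` from the pore axis.
#' Aromatics are F/W/Y, polars S/T/N/Q (histidine excluded by default);
#' special attractors (glycine backbone O, proline side-chain N, cysteine
#' S) are listed separately.
#'
#' @param structure a [channel_structure()] with chain tags naming repeats.
#' @param interface interface tag (`"I/II"`, `"II/III"`, `"III/IV"`,
#'   `"IV/I"`).
#' @param facing_angle outward-facing angular threshold, degrees
#'   (default 60).
#' @param min_radius outward-exposure radial threshold, Angstrom
#'   (default 10).
#' @param sector_margin azimuthal margin (degrees) around the interface
#'   sector within which residues are considered (default 10).
#' @return Object of class `InterfaceCensus`: lists `aromatic`, `polar`,
#'   `special` (residue numbers) plus per-class counts.
#' @export
classify_interface <- function(structure, interface, facing_angle = 60,
                               min_radius = 10, sector_margin = 10) {
  reps <- interface_reps(interface)
  axis <- structure$pore_axis
  at <- structure$atoms
  if (is.null(at$chain) || !any(at$chain %in% REPEAT_CHAINS))
    stop("structure lacks repeat chain annotations")
  centers <- 45 + 90 * (reps - 1)
  bis_lo <- min(centers); bis_hi <- max(centers)
  if (bis_hi - bis_lo > 180) { bis_lo <- bis_hi; bis_hi <- min(centers) + 360 }
  aromatic <- integer(0); polar <- integer(0); special <- integer(0)
  for (rn in unique(at$resnum[at$chain %in% REPEAT_CHAINS[reps]])) {
    res <- at[at$resnum == rn & at$chain %in% REPEAT_CHAINS[reps], ]
    ca <- res[res$name == "CA", ]
    if (nrow(ca) == 0) next
    ca_xyz <- as.numeric(ca[1, c("x", "y", "z")])
    az <- axis_azimuth(matrix(ca_xyz, 1), axis)
    az_ok <- (az >= bis_lo - sector_margin && az <= bis_hi + sector_margin) ||
      (az + 360 >= bis_lo - sector_margin && az + 360 <= bis_hi +
         sector_margin)
    if (!az_ok) next
    side <- res[!res$name %in% c("N", "CA", "C", "O"), ]
    resname <- res$resname[1]
    # special attractors are detected regardless of side-chain facing
    if (resname == "GLY" && any(res$name == "O")) special <- c(special, rn)
    if (resname == "PRO" && any(res$element == "N" & res$name != "N"))
      special <- c(special, rn)
    if (resname == "CYS" && any(res$element == "S"))
      special <- c(special, rn)
    if (nrow(side) == 0) next
    centroid <- colMeans(as.matrix(side[, c("x", "y", "z")]))
    acc <- axis_coords(matrix(ca_xyz, 1), axis)
    if (acc$rho < 1e-6) next
    radial <- as.numeric(acc$radial[1, ]) / acc$rho
    dirv <- centroid - ca_xyz
    if (vnorm(dirv) < 1e-6) next
    ang <- acos(pmin(1, pmax(-1, sum(unitize(dirv) * radial)))) * 180 / pi
    rho_c <- axis_coords(matrix(centroid, 1), axis)$rho
    if (ang < facing_angle && rho_c >= min_radius) {
      if (resname %in% AROMATIC_RES) aromatic <- c(aromatic, rn)
      else if (resname %in% POLAR_RES) polar <- c(polar, rn)
    }
  }
  structure(list(interface = interface,
                 aromatic = sort(unique(aromatic)),
                 polar = sort(unique(polar)),
                 special = sort(unique(special)),
                 counts = c(aromatic = length(unique(aromatic)),
                            polar = length(unique(polar)),
                            special = length(unique(special)))),
            class = "InterfaceCensus")
}

#' @export
print.InterfaceCensus <- function(x, ...) {
  cat("<InterfaceCensus ", x$interface, ": ", x$counts[["aromatic"]],
      " aromatic, ", x$counts[["polar"]], " polar, ",
      x$counts[["special"]], " special attractors>\n", sep = "")
  invisible(x)
}
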