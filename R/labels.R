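# Universal residue labelling for P-loop channels.
#
# A label such as "4i15" names a pore-domain residue by repeat (1-4), segment
# letter and relative position within the segment: "k" for the S4-S5 linker
# helix, "o" for the outer helix S5, "p" for the P-loop and "i" for the inner
# helix S6.  P-loop positions are numbered relative to p50, the selectivity
# filter residue (the DEKA ring in Nav1.x), so p-relpos values such as p37 or
# p54 sit below/above the filter.  Residues outside the pore domain (e.g. in
# the voltage-sensing domains) carry no label and keep their UniProt numbers.

SEGMENT_LETTERS <- c("k", "o", "p", "i")

#' Create a residue label
#'
#' @param rep repeat number, integer 1-4.
#' @param segment one of `"k"`, `"o"`, `"p"`, `"i"`.
#' @param relpos positive integer position within the segment (relative to
#'   p50 for the P-loop).
#' @return An object of class `ResidueLabel`.
#' @examples
#' residue_label(4, "i", 15)   # F1760 in hNav1.5
#' @export
residue_label <- function(rep, segment, relpos) {
  rep <- as.integer(rep); relpos <- as.integer(relpos)
  if (length(rep) != 1 || is.na(rep) || !rep %in% 1:4)
    stop("repeat must be an integer in 1..4, got '", rep, "'")
  if (length(segment) != 1 || !segment %in% SEGMENT_LETTERS)
    stop("unknown segment letter '", segment, "' (expected k, o, p or i)")
  if (is.na(relpos) || relpos < 1)
    stop("relpos must be a positive integer, got '", relpos, "'")
  structure(list(rep = rep, segment = segment, relpos = relpos),
            class = "ResidueLabel")
}

#' Parse a residue label string
#'
#' Accepts strings like `"4i15"` or `"1p54"`; an optional leading one-letter
#' amino-acid code is tolerated and ignored, so `"F4i15"` parses the same as
#' `"4i15"`.
#'
#' @param text a single label string.
#' @return A [residue_label()] object.
#' @examples
#' parse_label("4i15")
#' parse_label("F4i15")
#' @export
parse_label <- function(text) {
  if (length(text) != 1 || !is.character(text))
    stop("label must be a single string")
  m <- regmatches(text, regexec("^[A-Za-z]?([0-9])([A-Za-z])([0-9]+)$", text))[[1]]
  if (length(m) == 0)
    stop("malformed residue label '", text, "'")
  rep <- as.integer(m[2])
  if (!rep %in% 1:4)
    stop("invalid repeat '", m[2], "' in label '", text, "' (must be 1..4)")
  seg <- tolower(m[3])
  if (!seg %in% SEGMENT_LETTERS)
    stop("unknown segment letter '", m[3], "' in label '", text, "'")
  residue_label(rep, seg, as.integer(m[4]))
}

#' @export
format.ResidueLabel <- function(x, ...) {
  paste0(x$rep, x$segment, x$relpos)
}

#' @export
print.ResidueLabel <- function(x, ...) {
  cat("<ResidueLabel ", format(x), ">\n", sep = "")
  invisible(x)
}

#' @export
`==.ResidueLabel` <- function(e1, e2) {
  e1$rep == e2$rep && e1$segment == e2$segment && e1$relpos == e2$relpos
}

#' Build a segment anchor table
#'
#' An anchor table maps labels to sequential residue numbers of a specific
#' channel.  Each (repeat, segment) pair carries exactly one anchor
#' `(anchor_relpos, anchor_resnum)` and resolution is affine:
#' `resnum = anchor_resnum + (relpos - anchor_relpos)`.
#'
#' @param entries data.frame with columns `rep`, `segment`, `anchor_relpos`,
#'   `anchor_resnum`.
#' @param channel channel identifier string.
#' @return An object of class `SegmentAnchorTable`.
#' @seealso [hnav15_anchors()], [read_anchors()]
#' @export
anchor_table <- function(entries, channel = "unknown") {
  need <- c("rep", "segment", "anchor_relpos", "anchor_resnum")
  if (!all(need %in% names(entries)))
    stop("anchor entries need columns: ", paste(need, collapse = ", "))
  entries <- as.data.frame(entries)[, need]
  key <- paste(entries$rep, entries$segment)
  if (anyDuplicated(key))
    stop("duplicate anchor for (repeat, segment): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(entries$segment %in% SEGMENT_LETTERS))
    stop("unknown segment letter in anchor table")
  structure(list(entries = entries, channel = channel),
            class = "SegmentAnchorTable")
}

#' @export
print.SegmentAnchorTable <- function(x, ...) {
  cat("<SegmentAnchorTable '", x$channel, "', ", nrow(x$entries),
      " anchors>\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Packaged hNav1.5 (UniProt Q14524) anchor table
#'
#' Anchors for the four pore-domain segments of each repeat of the human
#' cardiac sodium channel: the S4-S5 linker start (k1), the S5 start (o1,
#' twelve residues after the linker start; M1652 is 4o1), the DEKA
#' selectivity-filter residues D372/E898/K1419/A1711 at p50, and the S6
#' starts (i1; F1760 is 4i15).
#'
#' @return A [anchor_table()] for channel `"hNav1.5"`.
#' @examples
#' resolve_label(parse_label("4i15"), hnav15_anchors())  # 1760
#' @export
hnav15_anchors <- function() {
  k_start <- c(232, 822, 1317, 1640)
  p50 <- c(372, 898, 1419, 1711)
  i_start <- c(387, 913, 1444, 1746)
  entries <- rbind(
    data.frame(rep = 1:4, segment = "k", anchor_relpos = 1,
               anchor_resnum = k_start),
    data.frame(rep = 1:4, segment = "o", anchor_relpos = 1,
               anchor_resnum = k_start + 12),
    data.frame(rep = 1:4, segment = "p", anchor_relpos = 50,
               anchor_resnum = p50),
    data.frame(rep = 1:4, segment = "i", anchor_relpos = 1,
               anchor_resnum = i_start))
  anchor_table(entries, channel = "hNav1.5")
}

#' Default hNav1.5 pore-domain segment spans
#'
#' Residue-number spans of the labelled segments, used by [label_of()] to
#' decide whether a residue carries a label at all.  Spans are conservative:
#' k covers 12 residues from k1, o covers 25 from o1, p covers p36..p57 and
#' i covers 33 residues from i1.
#'
#' @return data.frame with columns `rep`, `segment`, `start`, `end`.
#' @export
hnav15_segment_ranges <- function() {
  anc <- hnav15_anchors()$entries
  span <- list(k = c(1, 12), o = c(1, 25), p = c(36, 57), i = c(1, 33))
  do.call(rbind, lapply(seq_len(nrow(anc)), function(r) {
    a <- anc[r, ]
    s <- span[[a$segment]]
    data.frame(rep = a$rep, segment = a$segment,
               start = a$anchor_resnum + (s[1] - a$anchor_relpos),
               end = a$anchor_resnum + (s[2] - a$anchor_relpos))
  }))
}

#' Resolve a residue label to a sequential residue number
#'
#' @param label a [residue_label()] or label string.
#' @param anchors a [anchor_table()].
#' @return Integer residue number.
#' @examples
#' resolve_label("4o1", hnav15_anchors())  # 1652
#' @export
resolve_label <- function(label, anchors) {
  if (is.character(label)) label <- parse_label(label)
  stopifnot(inherits(label, "ResidueLabel"),
            inherits(anchors, "SegmentAnchorTable"))
  e <- anchors$entries
  hit <- e$rep == label$rep & e$segment == label$segment
  if (!any(hit))
    stop("no anchor for repeat ", label$rep, " segment '", label$segment,
         "' in channel '", anchors$channel, "'")
  a <- e[hit, ]
  resnum <- a$anchor_resnum + (label$relpos - a$anchor_relpos)
  if (resnum <= 0)
    stop("label ", format(label), " resolves to non-positive residue number ",
         resnum)
  as.integer(resnum)
}

#' Label a sequential residue number, if it lies in a labelled segment
#'
#' Inverse of [resolve_label()] on the covered spans.  Residues outside the
#' pore-domain segments (e.g. voltage-sensor residues) return `NULL`.
#'
#' @param resnum integer residue number.
#' @param anchors a [anchor_table()].
#' @param segment_ranges data.frame with columns `rep`, `segment`, `start`,
#'   `end` giving the residue span of each labelled segment.
#' @return A [residue_label()] or `NULL`.
#' @examples
#' format(label_of(1760, hnav15_anchors(), hnav15_segment_ranges()))  # "4i15"
#' @export
label_of <- function(resnum, anchors, segment_ranges) {
  stopifnot(length(resnum) == 1, inherits(anchors, "SegmentAnchorTable"))
  sr <- as.data.frame(segment_ranges)
  if (any(sr$end < sr$start)) stop("segment range with end < start")
  o <- order(sr$start)
  if (any(sr$start[o][-1] <= sr$end[o][-nrow(sr)]))
    stop("overlapping segment_ranges")
  hit <- which(resnum >= sr$start & resnum <= sr$end)
  if (length(hit) == 0) return(NULL)
  row <- sr[hit, ]
  e <- anchors$entries
  a <- e[e$rep == row$rep & e$segment == row$segment, ]
  if (nrow(a) == 0)
    stop("segment range (", row$rep, row$segment, ") has no anchor")
  residue_label(row$rep, row$segment,
                a$anchor_relpos + (resnum - a$anchor_resnum))
}

#' Read / write anchor tables as delimited text
#'
#' The file format is CSV with columns
#' `channel, rep, segment, anchor_relpos, anchor_resnum`.
#'
#' @param path file path.
#' @return [read_anchors()] returns a [anchor_table()].
#' @export
read_anchors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  anchor_table(df, channel = unique(df$channel)[1])
}

#' @rdname read_anchors
#' @param anchors a [anchor_table()] to write.
#' @export
write_anchors <- function(anchors, path) {
  df <- cbind(channel = anchors$channel, anchors$entries)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
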