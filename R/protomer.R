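#' Atom tables
#'
#' All coordinate data in helicomb lives in tidy atom tables: one row per
#' atom site with columns `element`, `name` (atom label), `resno` (author
#' residue numbering, with any insertion code folded into the ordering),
#' `resname` (3-letter code), `chain`, `x`, `y`, `z` (Angstrom) and
#' `is_heavy` (`element != "H"`).
#'
#' @param element,name,resno,resname,chain,x,y,z atom site fields, recycled
#'   to a common length.
#' @return A tibble with the atom-table columns.
#' @export
atom_table <- function(element, name, resno, resname = "ALA", chain = "A",
                       x = 0, y = 0, z = 0) {
  at <- tibble(element = toupper(as.character(element)),
               name = as.character(name),
               resno = as.integer(resno),
               resname = as.character(resname),
               chain = as.character(chain),
               x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  at$is_heavy <- at$element != "H"
  if (!all(is.finite(c(at$x, at$y, at$z)))) {
    abort("Atom coordinates must be finite.", class = "helicomb_error_atoms")
  }
  at
}

atom_xyz <- function(atoms, heavy_only = FALSE) {
  if (heavy_only) atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  cbind(atoms$x, atoms$y, atoms$z)
}

set_atom_xyz <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

#' Protomer structures
#'
#' A protomer is one subunit of a filament: an atom table plus a label, a
#' one-letter sequence, and a table of secondary-structure segments
#' (`h1`...`h6` and connecting loops, named as in the death-fold convention)
#' given as inclusive author-residue ranges. Segment ranges are used to
#' attribute interface contacts to faces of the six-helix bundle.
#'
#' @param atoms An atom table (see [atom_table()]) with at least one heavy atom.
#' @param label Protomer label (chain id or free text).
#' @param sequence Optional one-letter sequence; derived from `resname` when
#'   `NULL`.
#' @param ss_segments Optional tibble with columns `segment`, `start`, `end`
#'   (inclusive author residue numbers). May be `NULL` for structures without
#'   an annotation.
#' @return An object of class `protomer`.
#' @export
protomer <- function(atoms, label = "A", sequence = NULL, ss_segments = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("element", "name", "resno", "resname", "chain", "x", "y", "z",
            "is_heavy")
  if (!all(need %in% names(atoms))) {
    abort(paste("Atom table must have columns:", paste(need, collapse = ", ")),
          class = "helicomb_error_atoms")
  }
  if (!any(atoms$is_heavy)) {
    abort("Protomer must contain at least one heavy atom.",
          class = "helicomb_error_atoms")
  }
  if (is.unsorted(atoms$resno)) {
    atoms <- arrange(atoms, .data$resno)
  }
  if (is.null(sequence)) {
    res <- distinct(atoms, .data$resno, .data$resname)
    sequence <- paste(aa_three_to_one(res$resname), collapse = "")
  }
  if (!is.null(ss_segments)) {
    ss_segments <- as_tibble(ss_segments)
    stopifnot(all(c("segment", "start", "end") %in% names(ss_segments)))
    span <- range(atoms$resno)
    bad <- ss_segments$start < span[1] | ss_segments$end > span[2] |
      ss_segments$start > ss_segments$end
    if (any(bad)) {
      abort(sprintf("ss_segments outside residue span %d-%d: %s",
                    span[1], span[2],
                    paste(ss_segments$segment[bad], collapse = ", ")),
            class = "helicomb_error_segments")
    }
  }
  structure(list(atoms = atoms, label = label, sequence = sequence,
                 ss_segments = ss_segments),
            class = "protomer")
}

#' @export
print.protomer <- function(x, ...) {
  cat(sprintf("<protomer> %s: %d atoms (%d heavy), residues %d-%d%s\n",
              x$label, nrow(x$atoms), sum(x$atoms$is_heavy),
              min(x$atoms$resno), max(x$atoms$resno),
              if (is.null(x$ss_segments)) "" else
                sprintf(", %d ss segments", nrow(x$ss_segments))))
  invisible(x)
}

#' @rdname protomer
#' @param x A `protomer`.
#' @param ... Unused.
#' @export
tidy.protomer <- function(x, ...) x$atoms

protomer_centroid <- function(p) {
  colMeans(atom_xyz(p$atoms, heavy_only = TRUE))
}

protomer_residues <- function(p) {
  sort(unique(p$atoms$resno))
}

#' Residue numbers covered by a secondary-structure segment
#'
#' @param p A [protomer()].
#' @param segment Segment name(s), e.g. `"h3"` or `c("h5", "loop_h5h6")`.
#' @return Integer vector of author residue numbers (possibly empty).
#' @export
segment_residues <- function(p, segment) {
  if (is.null(p$ss_segments)) return(integer())
  rows <- p$ss_segments[p$ss_segments$segment %in% segment, , drop = FALSE]
  if (nrow(rows) == 0) return(integer())
  sort(unique(unlist(Map(seq.int, rows$start, rows$end))))
}

transform_protomer <- function(p, tf) {
  p$atoms <- set_atom_xyz(p$atoms, apply_transform(tf, atom_xyz(p$atoms)))
  p
}

residue_composition_key <- function(p) {
  res <- distinct(p$atoms, .data$resno, .data$resname)
  paste(res$resno, res$resname, sep = ":", collapse = "|")
}

aa_three_to_one <- function(resname) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", MSE = "M")
  out <- map[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}
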