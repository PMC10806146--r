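## Core structural data model. A `dd_structure` stores the chain -> residue ->
## atom hierarchy as a flat atom table (one row per atom), the representation
## every analysis step consumes:
##   chain (id), resno (author number), insert (insertion code, "" if none),
##   resid (3-letter name), elety (atom name), element, x, y, z.

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `element`, `x`, `y`, `z`.
#' @param title free-text title.
#' @param source provenance note (file path or generator parameters).
#' @return object of class `dd_structure`.
#' @export
dd_structure <- function(atoms, title = "", source = "") {
  req <- c("chain", "resno", "insert", "resid", "elety", "element", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$resid <- toupper(as.character(atoms$resid))
  atoms$elety <- as.character(atoms$elety)
  atoms$element <- as.character(atoms$element)
  if (nrow(atoms) == 0) stop("structure has no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  if (any(atoms$elety == "")) stop("empty atom name")
  ## atom names unique within each residue
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ", key[anyDuplicated(key)])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title, source = source),
            class = "dd_structure")
}

#' @export
print.dd_structure <- function(x, ...) {
  ch <- chain_ids(x)
  cat("dd_structure:", nrow(x$atoms), "atoms,",
      n_residues(x), "residues,", length(ch), "chain(s) [",
      paste(ch, collapse = " "), "]\n")
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

#' @export
#' @rdname dd_structure
chain_ids <- function(s) unique(s$atoms$chain)

#' @export
#' @rdname dd_structure
n_residues <- function(s) {
  length(unique(paste(s$atoms$chain, s$atoms$resno, s$atoms$insert)))
}

residue_keys <- function(s) unique(paste(s$atoms$chain, s$atoms$resno, s$atoms$insert))

#' Extract one chain as a structure
#' @param s a `dd_structure`.
#' @param id chain identifier.
#' @return a `dd_structure` with the single chain.
#' @export
get_chain <- function(s, id) {
  sel <- s$atoms$chain == id
  if (!any(sel)) stop("no chain '", id, "' in structure")
  dd_structure(s$atoms[sel, , drop = FALSE], title = s$title,
               source = paste0(s$source, " [chain ", id, "]"))
}

## Coordinate accessors -------------------------------------------------------

structure_xyz <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

set_structure_xyz <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Apply a rigid transform to a structure
#' @param s a `dd_structure`.
#' @param transform a `dd_rigid`.
#' @return the transformed structure (input untouched).
#' @export
transform_structure <- function(s, transform) {
  set_structure_xyz(s, apply_rigid(structure_xyz(s), transform))
}

#' Select heavy atoms (element != H)
#' @param s a `dd_structure`.
#' @return a `dd_structure` restricted to heavy atoms.
#' @export
heavy_atoms <- function(s) {
  sel <- s$atoms$element != "H"
  if (!any(sel)) stop("no heavy atoms")
  dd_structure(s$atoms[sel, , drop = FALSE], s$title, s$source)
}

## CA coordinates of a chain, in residue order, named by "resno|insert".
ca_coords <- function(s, chain = NULL) {
  at <- s$atoms
  if (!is.null(chain)) at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$elety == "CA", , drop = FALSE]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- paste(at$resno, at$insert, sep = "|")
  m
}

#' One-letter sequence of a chain
#'
#' @param s a `dd_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return a single string; unknown residue names become `"X"`.
#' @export
chain_sequence <- function(s, chain = NULL) {
  if (is.null(chain)) chain <- chain_ids(s)[1]
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no chain '", chain, "'")
  keys <- paste(at$resno, at$insert)
  resid <- at$resid[!duplicated(keys)]
  paste(aa_three_to_one(resid), collapse = "")
}

#' Residue numbers of a chain
#'
#' Author residue numbers in chain order.
#' @param s a `dd_structure`.
#' @param chain chain id; defaults to the first chain.
#' @return integer vector.
#' @export
chain_resnos <- function(s, chain = NULL) {
  if (is.null(chain)) chain <- chain_ids(s)[1]
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  keys <- paste(at$resno, at$insert)
  at$resno[!duplicated(keys)]
}

## PDB I/O --------------------------------------------------------------------

#' Read a PDB file
#'
#' Parses ATOM (and optionally non-water HETATM) records. Waters are skipped
#' by default; for alternate locations the highest-occupancy conformer is
#' kept (ties resolved by file order).
#'
#' @param path PDB file path.
#' @param keep_hetatm keep non-water HETATM records (default FALSE).
#' @return a `dd_structure`.
#' @export
read_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keep_hetatm) keep <- keep | (at$type == "HETATM")
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in '", path, "'")
  ## altloc: keep the highest-occupancy conformer per (chain,res,atom)
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(factor(key, levels = unique(key)), -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), , drop = FALSE]
  ins <- at$insert; ins[is.na(ins)] <- ""
  chain <- at$chain; chain[is.na(chain)] <- " "
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) elem <- NA
  elem <- ifelse(is.na(elem) | elem == "", element_of_atom(at$elety), elem)
  dd_structure(data.frame(chain = chain, resno = at$resno, insert = ins,
                          resid = at$resid, elety = at$elety, element = elem,
                          x = at$x, y = at$y, z = at$z,
                          stringsAsFactors = FALSE),
               title = basename(path), source = normalizePath(path))
}

#' Write a structure to a PDB file
#'
#' Fixed-column ATOM records, coordinates to 3 decimals, chains separated by
#' TER, terminated by END.
#'
#' @param s a `dd_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  at <- s$atoms
  if (nrow(at) + length(chain_ids(s)) > 99999)
    stop("structure exceeds the 99,999 PDB atom-serial limit (",
         nrow(at), " atoms)")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  lines <- character(0)
  for (ch in chain_ids(s)) {
    a <- at[at$chain == ch, , drop = FALSE]
    serials <- serial + seq_len(nrow(a))
    serial <- serial + nrow(a) + 1L  # TER consumes a serial
    name4 <- ifelse(nchar(a$elety) < 4, sprintf(" %-3s", a$elety),
                    sprintf("%-4s", a$elety))
    lines <- c(lines, sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serials, name4, "", substr(a$resid, 1, 3), substr(ch, 1, 1),
      a$resno, ifelse(a$insert == "", " ", a$insert),
      a$x, a$y, a$z, 1, 0, a$element))
    last <- a[nrow(a), ]
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d%1s", serial,
                              substr(last$resid, 1, 3), substr(ch, 1, 1),
                              last$resno,
                              ifelse(last$insert == "", " ", last$insert)))
  }
  writeLines(c(lines, "END"), con)
  invisible(path)
}
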