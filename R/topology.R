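## Amino-acid topology: 3<->1 letter codes, heavy-atom composition,
## ideal-geometry side-chain recipes (internal coordinates), chi torsion
## definitions and the atom sets each chi moves.
##
## Side chains are described as Z-matrix rows: each atom is placed from three
## previously placed atoms (p3-p2-p1) with a bond length (A), a bond angle
## (deg, p2-p1-atom) and a dihedral (deg, p3-p2-p1-atom). The dihedral is
## either bound to a chi variable ("chi1".."chi4", plus a constant offset) or
## fixed. Defaults put every chi at 180 deg (extended rotamer).

AA_THREE <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
AA_ONE <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

#' Convert 3-letter residue names to 1-letter codes
#'
#' Unknown names map to `"X"`.
#' @param x character vector of 3-letter residue names.
#' @return character vector of 1-letter codes.
#' @export
aa_three_to_one <- function(x) {
  i <- match(toupper(x), AA_THREE)
  out <- AA_ONE[i]
  out[is.na(i)] <- "X"
  out
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  i <- match(toupper(x), AA_ONE)
  out <- AA_THREE[i]
  out[is.na(i)] <- "UNK"
  out
}

element_of_atom <- function(name) {
  ## PDB-style heavy-atom names: element is the first non-digit character.
  first <- sub("^[0-9]*", "", name)
  substr(first, 1, 1)
}

## Z-matrix side-chain recipes beyond CB. Parents reference backbone
## (N, CA, C) and previously built side-chain atoms.
.zrow <- function(name, p3, p2, p1, bond, angle, chi = NA, offset = 0, fixed = NA) {
  list(name = name, p3 = p3, p2 = p2, p1 = p1, bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

SIDECHAIN_ZMAT <- list(
  ALA = list(),
  GLY = list(),
  SER = list(.zrow("OG", "N", "CA", "CB", 1.41, 110.5, chi = 1)),
  CYS = list(.zrow("SG", "N", "CA", "CB", 1.81, 114.0, chi = 1)),
  THR = list(.zrow("OG1", "N", "CA", "CB", 1.43, 109.5, chi = 1),
             .zrow("CG2", "N", "CA", "CB", 1.52, 110.5, chi = 1, offset = -120)),
  VAL = list(.zrow("CG1", "N", "CA", "CB", 1.52, 110.5, chi = 1),
             .zrow("CG2", "N", "CA", "CB", 1.52, 110.5, chi = 1, offset = 122)),
  LEU = list(.zrow("CG", "N", "CA", "CB", 1.53, 116.3, chi = 1),
             .zrow("CD1", "CA", "CB", "CG", 1.52, 110.5, chi = 2),
             .zrow("CD2", "CA", "CB", "CG", 1.52, 110.5, chi = 2, offset = 122)),
  ILE = list(.zrow("CG1", "N", "CA", "CB", 1.53, 110.4, chi = 1),
             .zrow("CG2", "N", "CA", "CB", 1.53, 110.5, chi = 1, offset = -122),
             .zrow("CD1", "CA", "CB", "CG1", 1.52, 113.8, chi = 2)),
  ASP = list(.zrow("CG", "N", "CA", "CB", 1.52, 112.6, chi = 1),
             .zrow("OD1", "CA", "CB", "CG", 1.25, 118.5, chi = 2),
             .zrow("OD2", "CA", "CB", "CG", 1.25, 118.5, chi = 2, offset = 180)),
  ASN = list(.zrow("CG", "N", "CA", "CB", 1.52, 112.6, chi = 1),
             .zrow("OD1", "CA", "CB", "CG", 1.23, 120.8, chi = 2),
             .zrow("ND2", "CA", "CB", "CG", 1.33, 116.5, chi = 2, offset = 180)),
  GLU = list(.zrow("CG", "N", "CA", "CB", 1.52, 114.1, chi = 1),
             .zrow("CD", "CA", "CB", "CG", 1.52, 114.1, chi = 2),
             .zrow("OE1", "CB", "CG", "CD", 1.25, 118.5, chi = 3),
             .zrow("OE2", "CB", "CG", "CD", 1.25, 118.5, chi = 3, offset = 180)),
  GLN = list(.zrow("CG", "N", "CA", "CB", 1.52, 114.1, chi = 1),
             .zrow("CD", "CA", "CB", "CG", 1.52, 112.7, chi = 2),
             .zrow("OE1", "CB", "CG", "CD", 1.23, 120.8, chi = 3),
             .zrow("NE2", "CB", "CG", "CD", 1.33, 116.5, chi = 3, offset = 180)),
  MET = list(.zrow("CG", "N", "CA", "CB", 1.52, 114.1, chi = 1),
             .zrow("SD", "CA", "CB", "CG", 1.80, 112.7, chi = 2),
             .zrow("CE", "CB", "CG", "SD", 1.79, 100.9, chi = 3)),
  LYS = list(.zrow("CG", "N", "CA", "CB", 1.52, 114.1, chi = 1),
             .zrow("CD", "CA", "CB", "CG", 1.52, 111.3, chi = 2),
             .zrow("CE", "CB", "CG", "CD", 1.52, 111.3, chi = 3),
             .zrow("NZ", "CG", "CD", "CE", 1.49, 111.9, chi = 4)),
  ARG = list(.zrow("CG", "N", "CA", "CB", 1.52, 114.1, chi = 1),
             .zrow("CD", "CA", "CB", "CG", 1.52, 111.3, chi = 2),
             .zrow("NE", "CB", "CG", "CD", 1.46, 111.5, chi = 3),
             .zrow("CZ", "CG", "CD", "NE", 1.33, 124.0, chi = 4),
             .zrow("NH1", "CD", "NE", "CZ", 1.33, 120.0, fixed = 0),
             .zrow("NH2", "CD", "NE", "CZ", 1.33, 120.0, fixed = 180)),
  HIS = list(.zrow("CG", "N", "CA", "CB", 1.50, 113.8, chi = 1),
             .zrow("ND1", "CA", "CB", "CG", 1.38, 122.7, chi = 2),
             .zrow("CD2", "CA", "CB", "CG", 1.36, 131.1, chi = 2, offset = 180),
             .zrow("CE1", "CB", "CG", "ND1", 1.32, 109.2, fixed = 180),
             .zrow("NE2", "CB", "CG", "CD2", 1.37, 107.2, fixed = 180)),
  PHE = list(.zrow("CG", "N", "CA", "CB", 1.50, 113.8, chi = 1),
             .zrow("CD1", "CA", "CB", "CG", 1.39, 120.7, chi = 2),
             .zrow("CD2", "CA", "CB", "CG", 1.39, 120.7, chi = 2, offset = 180),
             .zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, fixed = 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, fixed = 180),
             .zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, fixed = 0)),
  TYR = list(.zrow("CG", "N", "CA", "CB", 1.50, 113.8, chi = 1),
             .zrow("CD1", "CA", "CB", "CG", 1.39, 120.7, chi = 2),
             .zrow("CD2", "CA", "CB", "CG", 1.39, 120.7, chi = 2, offset = 180),
             .zrow("CE1", "CB", "CG", "CD1", 1.39, 120.0, fixed = 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.39, 120.0, fixed = 180),
             .zrow("CZ", "CG", "CD1", "CE1", 1.39, 120.0, fixed = 0),
             .zrow("OH", "CD1", "CE1", "CZ", 1.38, 120.0, fixed = 180)),
  TRP = list(.zrow("CG", "N", "CA", "CB", 1.50, 113.8, chi = 1),
             .zrow("CD1", "CA", "CB", "CG", 1.37, 126.9, chi = 2),
             .zrow("CD2", "CA", "CB", "CG", 1.43, 126.7, chi = 2, offset = 180),
             .zrow("NE1", "CB", "CG", "CD1", 1.38, 110.2, fixed = 180),
             .zrow("CE2", "CB", "CG", "CD2", 1.41, 107.2, fixed = 180),
             .zrow("CE3", "CB", "CG", "CD2", 1.40, 133.9, fixed = 0),
             .zrow("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, fixed = 180),
             .zrow("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, fixed = 180),
             .zrow("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, fixed = 0)),
  PRO = list(.zrow("CG", "N", "CA", "CB", 1.50, 104.5, chi = 1, offset = -150),
             .zrow("CD", "CA", "CB", "CG", 1.51, 106.1, chi = 2, offset = -145))
)

## Chi torsion atom quadruples per residue type (heavy-atom definitions).
CHI_ATOMS <- list(
  SER = list(c("N","CA","CB","OG")),
  CYS = list(c("N","CA","CB","SG")),
  THR = list(c("N","CA","CB","OG1")),
  VAL = list(c("N","CA","CB","CG1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"), c("CB","CG","CD","OE1")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"), c("CB","CG","SD","CE")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1"))
)

## Atoms distal to each chi bond (the set rotated when the chi changes).
chi_moving_atoms <- function(resname, chi_index) {
  z <- SIDECHAIN_ZMAT[[resname]]
  if (is.null(z)) return(character(0))
  nm <- vapply(z, `[[`, "", "name")
  chis <- vapply(z, function(r) if (is.na(r$chi)) Inf else r$chi, 0)
  ## an atom moves under chi_k if it is introduced at chi_k or later, or is a
  ## fixed-dihedral atom whose parents move
  moving <- nm[chis >= chi_index & is.finite(chis)]
  repeat {
    extra <- vapply(z, function(r) {
      !is.na(r$fixed) && !(r$name %in% moving) &&
        any(c(r$p1, r$p2, r$p3) %in% moving)
    }, TRUE)
    if (!any(extra)) break
    moving <- c(moving, nm[extra])
  }
  moving
}

## Heavy side-chain atom names beyond CB, in build order.
sidechain_atom_names <- function(resname) {
  z <- SIDECHAIN_ZMAT[[resname]]
  if (is.null(z)) return(character(0))
  vapply(z, `[[`, "", "name")
}

## Full heavy-atom complement for a residue type (backbone + CB + side chain).
residue_heavy_atoms <- function(resname) {
  bb <- c("N", "CA", "C", "O")
  if (identical(resname, "GLY")) return(bb)
  c(bb, "CB", sidechain_atom_names(resname))
}

## Intra-residue heavy-atom bond list (pairs of atom names), derived from the
## Z-matrix parentage plus backbone bonds; used for 1-2/1-3 clash exclusions.
residue_bonds <- function(resname) {
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  if (!identical(resname, "GLY")) bonds <- c(bonds, list(c("CA", "CB")))
  for (r in SIDECHAIN_ZMAT[[resname]]) bonds <- c(bonds, list(c(r$p1, r$name)))
  ## ring-closure bonds not expressed by the Z-matrix
  closure <- switch(resname,
    PHE = list(c("CE2", "CZ")),
    TYR = list(c("CE2", "CZ")),
    HIS = list(c("CE1", "NE2")),
    TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
    PRO = list(c("CD", "N")),
    list())
  c(bonds, closure)
}
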