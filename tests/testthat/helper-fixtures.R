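# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no binary data.

.fx <- new.env(parent = emptyenv())

fixture_domain <- function() {
  if (is.null(.fx$domain)) .fx$domain <- make_marker_domain()
  .fx$domain
}

fixture_lattice <- function() {
  if (is.null(.fx$lattice)) .fx$lattice <- make_lattice(subunit = fixture_domain())
  .fx$lattice
}

fixture_octamer <- function() {
  if (is.null(.fx$octamer)) {
    lat <- fixture_lattice()
    .fx$octamer <- build_octamer(fixture_domain(), lat$structure, lat$manifest)
  }
  .fx$octamer
}

# rotation taking unit direction a onto unit direction b
rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    ## 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    return(rotation_about_axis(ax, 180))
  }
  rotation_about_axis(v, acos(max(-1, min(1, cth))) * 180 / pi)
}

atom_xyz <- function(s, resno, elety, chain = NULL) {
  at <- s$atoms
  sel <- at$resno == resno & at$elety == elety
  if (!is.null(chain)) sel <- sel & at$chain == chain
  as.numeric(at[which(sel)[1], c("x", "y", "z")])
}

# Two-subunit toy with a single Lys-Asp salt bridge: the Lys tripeptide at
# helix index 2, the Asp tripeptide at index 1 (partner offset -1, type Ia).
salt_bridge_toy <- function(gap = 3.0) {
  if (!is.null(.fx$salt) && gap == 3.0) return(.fx$salt)
  lysp <- build_peptide(c("ALA", "LYS", "ALA"), resnos = 59:61, chain = "A")
  aspp <- build_peptide(c("ALA", "ASP", "ALA"), resnos = 32:34, chain = "B")
  nz <- atom_xyz(lysp, 60, "NZ"); ce <- atom_xyz(lysp, 60, "CE")
  d_out <- (nz - ce) / sqrt(sum((nz - ce)^2))
  od1 <- atom_xyz(aspp, 33, "OD1"); od2 <- atom_xyz(aspp, 33, "OD2")
  cb <- atom_xyz(aspp, 33, "CB")
  mid <- (od1 + od2) / 2
  d_b <- (mid - cb) / sqrt(sum((mid - cb)^2))
  R <- rot_between(d_b, -d_out)
  aspp <- transform_structure(aspp, rigid_transform(R, c(0, 0, 0)))
  mid2 <- (atom_xyz(aspp, 33, "OD1") + atom_xyz(aspp, 33, "OD2")) / 2
  target <- nz + gap * d_out
  aspp <- transform_structure(aspp, rigid_transform(diag(3), target - mid2))
  toy <- manual_assembly(list(aspp, lysp), helix_indices = c(1, 2),
                         layers = c("PARTNER", "QUERY"))
  if (gap == 3.0) .fx$salt <- toy
  toy
}

# Two-subunit toy with a buried Trp contact (partner at offset -3, type IIa).
trp_contact_toy <- function() {
  if (!is.null(.fx$trp)) return(.fx$trp)
  trpp <- build_peptide(c("ALA", "TRP", "ALA"), resnos = 73:75, chain = "A")
  alap <- build_peptide(c("ALA", "ALA", "ALA"), resnos = 15:17, chain = "B")
  ch2 <- atom_xyz(trpp, 74, "CH2"); cb <- atom_xyz(trpp, 74, "CB")
  d_out <- (ch2 - cb) / sqrt(sum((ch2 - cb)^2))
  bcb <- atom_xyz(alap, 16, "CB"); bca <- atom_xyz(alap, 16, "CA")
  d_b <- (bcb - bca) / sqrt(sum((bcb - bca)^2))
  R <- rot_between(d_b, -d_out)
  alap <- transform_structure(alap, rigid_transform(R, c(0, 0, 0)))
  bcb2 <- atom_xyz(alap, 16, "CB")
  alap <- transform_structure(
    alap, rigid_transform(diag(3), ch2 + 4.0 * d_out - bcb2))
  .fx$trp <- manual_assembly(list(alap, trpp), helix_indices = c(1, 4),
                             layers = c("PARTNER", "QUERY"))
  .fx$trp
}

# A small authored PDB file (3 residues, chain A) for parser tests.
write_toy_pdb <- function(path) {
  s <- build_peptide(c("ALA", "GLY", "TRP"), resnos = 1:3, chain = "A")
  write_pdb(s, path)
  invisible(s)
}
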