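## Ideal-geometry peptide construction (NeRF chaining) and side-chain
## building from the Z-matrix recipes in topology.R. Used by the synthetic
## fixture generator, by template threading and by mutation.

BB_BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231, CA_CB = 1.53)
BB_ANGLE <- c(N_CA_C = 111.0, CA_C_N = 116.6, C_N_CA = 121.7, CA_C_O = 120.5)

## Build CB from backbone N, CA, C (L-configuration improper N-C-CA-CB).
build_cb <- function(N, CA, C) {
  place_atom(N, C, CA, BB_BOND["CA_CB"], 110.1, -122.6)
}

## Build side-chain atoms beyond CB for one residue. `bb` is a named list
## with N, CA, CB (3-vectors). `chi` is a numeric vector of chi values
## (degrees); missing entries default to 180 (extended).
build_sidechain <- function(resname, bb, chi = numeric(0)) {
  z <- SIDECHAIN_ZMAT[[resname]]
  if (is.null(z) || length(z) == 0) return(NULL)
  coords <- bb
  out <- matrix(NA_real_, length(z), 3,
                dimnames = list(vapply(z, `[[`, "", "name"), NULL))
  for (r in z) {
    dihed <- if (!is.na(r$fixed)) r$fixed else {
      base <- if (r$chi <= length(chi) && !is.na(chi[r$chi])) chi[r$chi] else 180
      base + r$offset
    }
    p <- place_atom(coords[[r$p3]], coords[[r$p2]], coords[[r$p1]],
                    r$bond, r$angle, dihed)
    coords[[r$name]] <- p
    out[r$name, ] <- p
  }
  out
}

## Atom rows (data.frame) for one complete residue given backbone coords.
residue_atom_rows <- function(chain, resno, resname, N, CA, C, O,
                              chi = numeric(0)) {
  chain <- unname(chain); resno <- unname(resno); resname <- unname(resname)
  names_ <- c("N", "CA", "C", "O")
  xyz <- rbind(N, CA, C, O)
  if (!identical(resname, "GLY")) {
    CB <- build_cb(N, CA, C)
    sc <- build_sidechain(resname, list(N = N, CA = CA, CB = CB), chi = chi)
    names_ <- c(names_, "CB", rownames(sc))
    xyz <- rbind(xyz, CB, sc)
  }
  rownames(xyz) <- NULL
  data.frame(chain = chain, resno = resno, insert = "", resid = resname,
             elety = names_, element = element_of_atom(names_),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build a peptide from backbone torsions
#'
#' NeRF chain construction with ideal bond lengths/angles; side chains are
#' added in the extended default rotamer.
#'
#' @param resnames character vector of 3-letter residue names.
#' @param resnos residue numbers (default 1..n).
#' @param phi,psi backbone torsions in degrees (recycled).
#' @param chain chain id.
#' @return a `dd_structure`.
#' @export
build_peptide <- function(resnames, resnos = seq_along(resnames),
                          phi = -57, psi = -47, chain = "A") {
  n <- length(resnames)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_BOND["N_CA"], 0, 0)
  C[1, ] <- CA[1, ] + BB_BOND["CA_C"] *
    c(cos(deg2rad(180 - BB_ANGLE["N_CA_C"])),
      sin(deg2rad(180 - BB_ANGLE["N_CA_C"])), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BB_BOND["C_N"], BB_ANGLE["CA_C_N"], psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BB_BOND["N_CA"], BB_ANGLE["C_N_CA"], 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           BB_BOND["CA_C"], BB_ANGLE["N_CA_C"], phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BB_BOND["C_O"], BB_ANGLE["CA_C_O"], psi[i] + 180)
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    residue_atom_rows(chain, resnos[i], toupper(resnames[i]),
                      N[i, ], CA[i, ], C[i, ], O[i, ])
  }))
  dd_structure(rows, title = "built peptide",
               source = sprintf("build_peptide(n=%d)", n))
}

## Helical frame of a fragment: axis (unit, N->C direction), center, and a
## reference direction (perpendicular component of center->CA1).
fragment_frame <- function(frag) {
  ca <- ca_coords(frag)
  center <- colMeans(ca)
  pc <- svd(sweep(ca, 2, center))$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * pc) < 0) pc <- -pc
  ref <- ca[1, ] - center
  ref <- unitize(ref - sum(ref * pc) * pc)
  list(axis = pc, center = center, ref = ref)
}

## Rigidly place a fragment so its helical frame maps onto the target frame.
place_fragment <- function(frag, target_axis, target_ref, target_center) {
  f <- fragment_frame(frag)
  A <- cbind(f$axis, f$ref, pracma_cross(f$axis, f$ref))
  ta <- unitize(target_axis)
  tr <- unitize(target_ref - sum(target_ref * ta) * ta)
  B <- cbind(ta, tr, pracma_cross(ta, tr))
  R <- B %*% t(A)
  t <- as.numeric(target_center - R %*% f$center)
  transform_structure(frag, rigid_transform(R, t))
}
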