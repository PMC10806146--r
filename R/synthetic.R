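## Synthetic layered DD-helix fixtures with known ground truth.
##
## The toy subunit is a three-helix bundle (a synthetic stand-in for the
## ~90-residue six-helix DD fold, reduced to the three helices that carry
## the marker residues) numbered 15..105 in the query (IRAK-M-style)
## numbering. Marker residues sit at the face-pivot-equivalent positions:
## Lys60 (type Ia), Trp74 + surround (type IIa), Arg97/Tyr105 (type IIb),
## Asp19/Asp33 acidic partners, Trp52/Arg56/Gln64 auxiliaries. The bundle
## is oriented inside the lattice so that the nearest-partner geometry of
## the markers reproduces the myddosome offset regime (n-1 for the Ia
## pivot, n-3/n-4 for the IIa pivot, n+4 for the IIb pivot).

MARKER_RESIDUES <- c("18" = "PHE", "19" = "ASP", "20" = "LEU", "21" = "PRO",
                     "22" = "PRO", "23" = "ALA", "33" = "ASP", "52" = "TRP",
                     "56" = "ARG", "60" = "LYS", "64" = "GLN", "74" = "TRP",
                     "78" = "GLN", "97" = "ARG", "105" = "TYR")

## Bundle architecture (residue spans and placement of the three helices).
.BUNDLE <- list(
  helixA = list(from = 15, to = 44, dir = +1, angle = 221, spin_res = 19, spin_phase = 106, tilt = 16),
  helixB = list(from = 47, to = 74, dir = -1, angle = 139, spin_res = 60, spin_phase = 139, tilt = 0),
  helixC = list(from = 78, to = 105, dir = +1, angle = 0, spin_res = 97, spin_phase = -78, tilt = 0),
  bundle_radius = 7.5, ca_rise = 1.5
)

#' Synthetic marker death-domain subunit
#'
#' Builds the packaged toy DD-like fold: a three-helix bundle, poly-alanine
#' except for the face-marker residues, numbered 15..105, centred at the
#' origin with the bundle axis along z.
#'
#' @param chain chain id (default "A").
#' @return a `dd_structure` (one chain, 91 residues, all heavy atoms).
#' @export
make_marker_domain <- function(chain = "A") {
  b <- .BUNDLE
  seqs <- rep("ALA", 105 - 15 + 1)
  names(seqs) <- as.character(15:105)
  seqs[names(MARKER_RESIDUES)] <- MARKER_RESIDUES
  pieces <- list()
  for (hname in c("helixA", "helixB", "helixC")) {
    h <- b[[hname]]
    resnos <- h$from:h$to
    frag <- build_peptide(seqs[as.character(resnos)], resnos = resnos,
                          phi = -57, psi = -47, chain = chain)
    st <- sin(deg2rad(h$tilt)); ct <- cos(deg2rad(h$tilt))
    axis <- c(-st * sin(deg2rad(h$angle)), st * cos(deg2rad(h$angle)),
              h$dir * ct)
    center <- c(b$bundle_radius * cos(deg2rad(h$angle)),
                b$bundle_radius * sin(deg2rad(h$angle)), 0)
    ## choose the spin so that the anchor residue's CA sits at the target
    ## azimuth: first place with an arbitrary reference, measure, correct
    placed <- place_fragment(frag, axis, c(1, 0, 0), center)
    anchor_ca <- ca_coords(placed)[paste0(h$spin_res, "|"), ]
    rel <- anchor_ca - center
    cur_phase <- rad2deg(atan2(rel[2], rel[1]))
    spin <- h$spin_phase - cur_phase
    Rspin <- rotation_about_axis(c(0, 0, 1), spin)
    placed <- transform_structure(
      placed, rigid_transform(Rspin, center - as.numeric(Rspin %*% center)))
    pieces[[hname]] <- placed$atoms
  }
  ## connecting loops (alanine), CA interpolation with a zig-zag offset to
  ## keep local frames non-degenerate; geometrically idealised, not a fold
  loop_rows <- function(resnos, p_from, p_to, chain) {
    nres <- length(resnos)
    do.call(rbind, lapply(seq_len(nres), function(i) {
      f <- i / (nres + 1)
      ca <- p_from + f * (p_to - p_from)
      ## bow the loop toward the bundle axis so it hugs the fold instead of
      ## protruding into the lattice interfaces
      bow <- 4 * f * (1 - f)
      ca[1:2] <- ca[1:2] * (1 - 0.5 * bow)
      ca[3] <- ca[3] - sign(ca[3]) * 4 * bow
      perp <- unitize(pracma_cross(p_to - p_from, c(0, 0, 1)))
      ca <- ca + perp * 1.2 * (-1)^i
      dirb <- unitize(p_from - ca); dirf <- unitize(p_to - ca)
      N <- ca + 1.458 * dirb
      C <- ca + 1.525 * dirf
      O <- C + 1.231 * unitize(pracma_cross(dirf, perp))
      residue_atom_rows(chain, resnos[i], "ALA", N, ca, C, O)
    }))
  }
  caA <- ca_coords(dd_structure(pieces$helixA))
  caB <- ca_coords(dd_structure(pieces$helixB))
  caC <- ca_coords(dd_structure(pieces$helixC))
  loop1 <- loop_rows(45:46, caA[nrow(caA), ], caB[1, ], chain)
  loop2 <- loop_rows(75:77, caB[nrow(caB), ], caC[1, ], chain)
  at <- rbind(pieces$helixA, loop1, pieces$helixB, loop2, pieces$helixC)
  at <- at[order(at$resno), , drop = FALSE]
  at$chain <- chain
  ## centre the bundle at the origin
  s <- dd_structure(at, title = "synthetic marker DD subunit",
                    source = "make_marker_domain()")
  xyz <- structure_xyz(s)
  set_structure_xyz(s, sweep(xyz, 2, colMeans(ca_coords(s))))
}

#' Specification of a synthetic layered DD helix
#'
#' Defaults encode the myddosome-like study geometry: a 6:4:4 layered
#' template (MyD88-, IRAK-4- and IRAK-2-like layers), a left-handed helix
#' with about 3.7 subunits per turn (twist -98 degrees), and rise/radius
#' chosen so that subunits touch at index offsets {1, 3, 4} but not 2.
#'
#' @param layers integer vector of subunits per layer (default c(6, 4, 4)).
#' @param layer_labels labels for the layers.
#' @param twist screw twist per subunit, degrees (negative = left-handed).
#' @param rise screw rise per subunit, angstroms.
#' @param radius helix radius (axis to subunit centre), angstroms.
#' @param noise_sd per-coordinate Gaussian noise sd, angstroms (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return a validated list of class `dd_lattice_spec`.
#' @export
lattice_spec <- function(layers = c(6, 4, 4),
                         layer_labels = c("MYD88", "IRAK4", "IRAK2"),
                         twist = -98, rise = 11.75, radius = 17.0,
                         noise_sd = 0, seed = 1L) {
  stopifnot(length(layers) == length(layer_labels))
  if (rise <= 0) stop("rise must be > 0")
  if (!(abs(twist) > 0 && abs(twist) < 180))
    stop("|twist| must be in (0, 180)")
  if (radius <= 0) stop("radius must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(layers = as.integer(layers), layer_labels = layer_labels,
                 twist = twist, rise = rise, radius = radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dd_lattice_spec")
}

#' Generate a layered helical lattice with known ground truth
#'
#' Places copies of the marker subunit at helix indices 0..N-1 by repeated
#' application of the screw generator; chain ids A, B, C, ... follow helix
#' order. With `noise_sd > 0`, seeded Gaussian noise is added after
#' placement.
#'
#' @param spec a `dd_lattice_spec`.
#' @param subunit the subunit structure to replicate (default
#'   [make_marker_domain()]).
#' @return list with `structure` (multi-chain `dd_structure`) and
#'   `manifest` (ground truth: twist, rise, radius, per-chain layer labels
#'   and helix indices, seed, noise_sd).
#' @export
make_lattice <- function(spec = lattice_spec(), subunit = make_marker_domain()) {
  stopifnot(inherits(spec, "dd_lattice_spec"))
  n_total <- sum(spec$layers)
  if (n_total > 26) stop("at most 26 subunits (single-letter chain ids)")
  ref <- transform_structure(subunit,
                             rigid_transform(diag(3), c(spec$radius, 0, 0)))
  scr <- structure(list(axis_direction = c(0, 0, 1), axis_point = c(0, 0, 0),
                        twist = spec$twist, rise = spec$rise,
                        identity = FALSE), class = "dd_screw")
  chains <- LETTERS[seq_len(n_total)]
  layer_of <- rep(spec$layer_labels, spec$layers)
  at <- do.call(rbind, lapply(seq_len(n_total), function(i) {
    sub <- place_at_index(ref, scr, i - 1)
    a <- sub$atoms
    a$chain <- chains[i]
    a
  }))
  s <- dd_structure(at, title = "synthetic layered DD helix",
                    source = sprintf(
                      "make_lattice(layers=%s, twist=%g, rise=%g, radius=%g, noise_sd=%g, seed=%d)",
                      paste(spec$layers, collapse = ":"), spec$twist,
                      spec$rise, spec$radius, spec$noise_sd, spec$seed))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    xyz <- structure_xyz(s)
    s <- set_structure_xyz(s, xyz + matrix(stats::rnorm(length(xyz),
                                                        sd = spec$noise_sd),
                                           ncol = 3))
  }
  manifest <- list(twist = spec$twist, rise = spec$rise, radius = spec$radius,
                   noise_sd = spec$noise_sd, seed = spec$seed,
                   chains = data.frame(chain = chains, layer = layer_of,
                                       helix_index = seq_len(n_total),
                                       stringsAsFactors = FALSE))
  list(structure = s, manifest = manifest)
}
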