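## Screw-axis description of the helical lattice. A proper rigid transform
## is decomposed into rotation by `twist` degrees about a line (direction
## `axis_direction` through `axis_point`) plus translation `rise` along it.
## Convention: the axis direction is chosen so that rise >= 0; with that
## choice a negative twist advancing along the axis is a LEFT-handed helix.

#' Decompose a rigid transform into screw parameters
#'
#' @param t a `dd_rigid`.
#' @return object of class `dd_screw`: `axis_direction` (unit vector),
#'   `axis_point` (point on the axis, minimum-norm), `twist` (degrees, in
#'   (-180, 180]), `rise` (angstroms, >= 0 by convention), and `identity`
#'   (TRUE when both twist and translation vanish).
#' @export
screw_decompose <- function(t) {
  R <- t$rotation; tr <- t$translation
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- rad2deg(acos(ct))
  svec <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (theta < 1e-7) {
    ## pure translation (or identity)
    rise <- vnorm(tr)
    if (rise < 1e-9)
      return(structure(list(axis_direction = c(0, 0, 1),
                            axis_point = c(0, 0, 0),
                            twist = 0, rise = 0, identity = TRUE),
                       class = "dd_screw"))
    return(structure(list(axis_direction = tr / rise,
                          axis_point = c(0, 0, 0),
                          twist = 0, rise = rise, identity = FALSE),
                     class = "dd_screw"))
  }
  ## rotation axis: null vector of (R - I), robust near theta = 180
  sv <- svd(R - diag(3))
  axis <- sv$v[, 3]
  if (sum(svec * axis) < 0) axis <- -axis
  rise <- sum(tr * axis)
  twist <- theta  # theta in (0, 180]; sign carried by axis choice above
  ## enforce rise >= 0 by flipping the axis (twist flips with it)
  if (rise < -1e-9) {
    axis <- -axis; rise <- -rise; twist <- -twist
  } else if (abs(rise) <= 1e-9) {
    rise <- 0
    if (twist < 0) { axis <- -axis; twist <- -twist }
  }
  if (twist <= -180 + 1e-12) twist <- twist + 360
  ## axis point: minimum-norm solution of (I - R) p = t_perp
  t_perp <- tr - sum(tr * axis) * axis
  A <- diag(3) - R
  sA <- svd(A)
  dinv <- ifelse(sA$d > 1e-9 * max(sA$d), 1 / sA$d, 0)
  p <- as.numeric(sA$v %*% (dinv * crossprod(sA$u, t_perp)))
  p <- p - sum(p * axis) * axis
  structure(list(axis_direction = axis, axis_point = p,
                 twist = twist, rise = rise, identity = FALSE),
            class = "dd_screw")
}

#' Rebuild the rigid transform of a screw (optionally iterated)
#'
#' @param s a `dd_screw`.
#' @param n integer power: the transform advancing `n` subunit steps
#'   (default 1); `n = 0` gives the identity, negative `n` the inverse steps.
#' @return a `dd_rigid`.
#' @export
screw_recompose <- function(s, n = 1) {
  R <- rotation_about_axis(s$axis_direction, n * s$twist)
  tr <- as.numeric(s$axis_point - R %*% s$axis_point) +
    n * s$rise * s$axis_direction
  rigid_transform(R, tr)
}

#' @export
print.dd_screw <- function(x, ...) {
  cat(sprintf("Screw: twist %.4f deg, rise %.4f A, axis (%.4f %.4f %.4f)\n",
              x$twist, x$rise, x$axis_direction[1], x$axis_direction[2],
              x$axis_direction[3]))
  if (isTRUE(x$identity)) cat("  (identity transform)\n")
  invisible(x)
}

#' Helix parameters of a screw generator
#'
#' @param s a `dd_screw`.
#' @return list with `subunits_per_turn` (360/|twist|) and `handedness`
#'   ("left" when the twist is negative for positive advance along the
#'   axis, "right" when positive, NA for degenerate screws).
#' @export
helix_params <- function(s) {
  if (isTRUE(s$identity) || abs(s$twist) < 1e-9)
    return(list(subunits_per_turn = Inf, handedness = NA_character_))
  list(subunits_per_turn = 360 / abs(s$twist),
       handedness = if (s$twist < 0) "left" else "right")
}

#' Rigid transform mapping one subunit onto an equivalent one
#'
#' Kabsch transform carrying subunit `a`'s CA set onto subunit `b`'s, with
#' residue pairing by sequence alignment (identity pairing when the
#' sequences match).
#'
#' @param a,b single-chain `dd_structure` subunits.
#' @param min_pairs minimum CA pairs (default 20).
#' @return a `dd_rigid`.
#' @export
transform_between_subunits <- function(a, b, min_pairs = 20) {
  corr <- align_chains(a, b)
  cc <- corresponding_ca(a, b, corr)
  if (nrow(cc$query) < min_pairs)
    stop("subunits do not align (", nrow(cc$query), " CA pairs < ",
         min_pairs, "); not structurally equivalent")
  kabsch(cc$query, cc$template)$transform
}

#' Place a subunit at an arbitrary helix index
#'
#' Applies the `n`-fold composition of the lattice screw to a reference
#' subunit; `n = 0` returns the reference unchanged, negative `n` walks up
#' the helix.
#'
#' @param reference a `dd_structure` subunit at index 0.
#' @param s the lattice `dd_screw`.
#' @param n integer helix-index offset.
#' @return the placed `dd_structure`.
#' @export
place_at_index <- function(reference, s, n) {
  stopifnot(n == round(n))
  if (n == 0) return(reference)
  transform_structure(reference, screw_recompose(s, n))
}

#' Estimate the lattice generator from an ordered subunit path
#'
#' The generator is the Kabsch transform between consecutive subunits,
#' averaged over all consecutive pairs of the path (rotations averaged by
#' projection of the mean matrix onto SO(3); translations by the mean),
#' then screw-decomposed.
#'
#' @param template multi-chain `dd_structure`.
#' @param chain_order character vector of chain ids along the helix.
#' @return list with `screw` (`dd_screw`), `transform` (`dd_rigid`
#'   generator), `helix` (from [helix_params()]), and `n_pairs`.
#' @export
estimate_lattice <- function(template, chain_order = chain_ids(template)) {
  if (length(chain_order) < 2)
    stop("need at least two chains to estimate a lattice generator")
  trs <- lapply(seq_len(length(chain_order) - 1), function(i) {
    transform_between_subunits(get_chain(template, chain_order[i]),
                               get_chain(template, chain_order[i + 1]))
  })
  Rbar <- Reduce(`+`, lapply(trs, `[[`, "rotation")) / length(trs)
  sv <- svd(Rbar)
  d <- sign(det(sv$u %*% t(sv$v))); if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tbar <- Reduce(`+`, lapply(trs, `[[`, "translation")) / length(trs)
  gen <- rigid_transform(R, tbar)
  scr <- screw_decompose(gen)
  list(screw = scr, transform = gen, helix = helix_params(scr),
       n_pairs = length(trs))
}
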