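## Low-level 3D geometry used across the package.
## Coordinates are plain numeric matrices (n x 3), angstroms; angles in degrees
## at the user surface, radians internally where noted.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Builds the proper rotation matrix for a right-handed rotation of
#' `angle` degrees about the (unnormalised) direction `axis`.
#'
#' @param axis numeric length-3 direction vector.
#' @param angle rotation angle in degrees (right-hand rule about `axis`).
#' @return a 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- unitize(axis)
  th <- deg2rad(angle)
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)  # column-major: K %*% v = a x v
  diag(3) * c1 + s1 * K + (1 - c1) * (a %o% a)
}

## Dihedral angle (degrees, signed, right-hand rule about b->c) for points a-b-c-d.
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitize(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

## Small cross product helper (avoids a dependency for one primitive).
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Natural-extension (NeRF) placement: position atom D given reference atoms
## A-B-C, a bond length C-D, an angle B-C-D (degrees) and a dihedral
## A-B-C-D (degrees). The workhorse of backbone and side-chain building.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               bond * sin(th) * sin(ph))
  bc <- unitize(c - b)
  n <- unitize(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)          # bc, m, n orthonormal frame
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

## Apply a rigid transform (list(rotation, translation)) to an n x 3 matrix.
apply_rigid <- function(xyz, transform) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 translation (angstroms).
#' @return an object of class `dd_rigid` with elements `rotation`,
#'   `translation`; applied as `x' = R x + t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation matrix is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation matrix is a reflection (determinant < 0)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "dd_rigid")
}

## Compose: (s o t)(x) = s(t(x)).
compose_rigid <- function(s, t) {
  rigid_transform(s$rotation %*% t$rotation,
                  as.numeric(s$rotation %*% t$translation) + s$translation)
}

invert_rigid <- function(t) {
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

identity_rigid <- function() rigid_transform()

#' @export
print.dd_rigid <- function(x, ...) {
  cat("Rigid transform (x' = R x + t)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

## Random proper rotation, uniform over SO(3) (quaternion method); used by
## tests and by the brute-force optimality oracle.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
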