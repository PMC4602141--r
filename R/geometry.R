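## Small 3-D geometry helpers shared by the fixture builder and the
## interface analyses.  All coordinates are plain numeric 3-vectors or
## n x 3 matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three reference positions `a`, `b`, `c`, returns the point `d`
#' with `|d - c| = bond`, angle `b-c-d` equal to `angle` and dihedral
#' `a-b-c-d` equal to `dihedral`.
#'
#' @param a,b,c reference positions (numeric 3-vectors).
#' @param bond bond length c-d, Angstrom.
#' @param angle bond angle b-c-d, degrees.
#' @param dihedral torsion a-b-c-d, degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d_local + c)
}

#' Torsion angle of four points, degrees in (-180, 180]
#' @keywords internal
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

## Rotation matrix from axis-angle (axis need not be unit length).
rotation_matrix <- function(axis, theta) {
  u <- unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

## Pairwise distances between the rows of two n x 3 matrices.
cross_distances <- function(xyz_a, xyz_b) {
  a2 <- rowSums(xyz_a^2)
  b2 <- rowSums(xyz_b^2)
  d2 <- outer(a2, b2, "+") - 2 * xyz_a %*% t(xyz_b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
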