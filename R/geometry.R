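# Small 3D geometry toolkit: vectors, torsions, atom placement from internal
# coordinates (NeRF), axis rotations, Kabsch superposition. All coordinates
# are Cartesian Angstrom; angles are degrees at the API surface.

vec_norm <- function(v) sqrt(sum(v * v))

vec_unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

angle_3pt <- function(p1, p2, p3) {
  v1 <- vec_unit(p1 - p2)
  v2 <- vec_unit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Positions atom X given three reference atoms A-B-C such that |C-X| = bond,
#' angle(B,C,X) = angle and dihedral(A,B,C,X) = torsion.
#'
#' @param a,b,c reference positions (numeric 3-vectors).
#' @param bond bond length C-X in Angstrom.
#' @param angle bond angle B-C-X in degrees.
#' @param torsion dihedral A-B-C-X in degrees.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- vec_unit(c - b)
  n <- vec_unit(vec_cross(b - a, bc))
  m <- cbind(bc, vec_cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Rotate points about an arbitrary axis
#'
#' @param pts n x 3 matrix.
#' @param origin point on the axis.
#' @param axis direction (need not be unit length).
#' @param theta rotation angle in degrees (right-handed about `axis`).
#' @keywords internal
rotate_about_axis <- function(pts, origin, axis, theta) {
  u <- vec_unit(axis)
  th <- deg2rad(theta)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pts <- as.matrix(pts)
  t(R %*% (t(pts) - origin) + origin)
}

rotation_matrix_axis <- function(axis, theta) {
  u <- vec_unit(axis)
  th <- deg2rad(theta)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Returns the rotation R and translation t minimizing ||R x + t - y|| over
#' paired coordinate rows, with det(R) = +1.
#'
#' @param x,y n x 3 matrices of paired coordinates.
#' @return list with `R`, `t`, and `rmsd`.
#' @keywords internal
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  fit <- sweep(xc %*% t(R), 2, cy, `+`)
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

coord_rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  sqrt(mean(rowSums((x - y)^2)))
}
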