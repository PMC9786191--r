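# Small geometry helpers shared across modules: rotations, quaternions,
# axis-frame coordinates, RMSD.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix from an axis-angle (Rodrigues) vector
#'
#' @param w numeric(3); direction is the rotation axis, norm is the angle in
#'   radians.  The zero vector gives the identity.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotvec_to_matrix <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

quat_normalize <- function(q) q / vnorm(q)

# Hamilton product, scalar-first convention.
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

rotvec_to_quat <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * (w / th))
}

# Uniform random unit quaternion (Shoemake's subgroup algorithm).
random_quat <- function() {
  u <- runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

quat_to_matrix <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Rotate rows of an n x 3 matrix about a point.
rotate_about <- function(xyz, R, center) {
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
}

# Rotate the atoms indexed by `idx` about the bond a1 -> a2 by angle `phi`.
rotate_about_bond <- function(xyz, a1, a2, idx, phi) {
  axis <- unitize(xyz[a2, ] - xyz[a1, ])
  R <- rotvec_to_matrix(axis * phi)
  xyz[idx, ] <- rotate_about(xyz[idx, , drop = FALSE], R, xyz[a2, ])
  xyz
}

# Dihedral angle (radians, in (-pi, pi]) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2))
}

wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a <= -pi, a + 2 * pi, a)
}

#' Coordinate RMSD between two point sets (no superposition)
#'
#' @param a,b n x 3 coordinate matrices in a common frame.
#' @return root-mean-square deviation in the same units as the input.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# Axial (z) coordinate and cylindrical radius of points relative to an axis
# given as list(point=, dir=).
axis_coords <- function(xyz, axis) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  u <- unitize(axis$dir)
  rel <- sweep(xyz, 2, axis$point)
  z <- as.numeric(rel %*% u)
  radial <- rel - outer(z, u)
  list(z = z, rho = sqrt(rowSums(radial^2)), radial = radial)
}

# Azimuth (degrees in [0, 360)) about the axis, using an arbitrary but fixed
# in-plane reference frame.
axis_azimuth <- function(xyz, axis) {
  u <- unitize(axis$dir)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitize(ref - sum(ref * u) * u)
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  ac <- axis_coords(xyz, axis)
  ang <- atan2(ac$radial %*% e2, ac$radial %*% e1) * 180 / pi
  as.numeric(ang) %% 360
}
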