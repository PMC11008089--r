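# Low-level 3D geometry shared by featurization, synthesis and realization.
# All coordinates are Angstrom; all angles radians unless noted.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector", call. = FALSE)
  a / n
}

# Row-wise cross product for n x 3 matrices (vectorized pair loops).
rcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rdot <- function(a, b) rowSums(a * b)

#' Signed dihedral angle for four points
#'
#' Standard atan2 torsion about the p2-p3 axis, in (-pi, pi].
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors (Angstrom).
#' @return angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as.numeric(dihedral_rows(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

# Vectorized torsion over rows of four n x 3 matrices.
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- rcross(b1, b2)
  n2 <- rcross(b2, b3)
  b2n <- b2 / pmax(sqrt(rdot(b2, b2)), 1e-12)
  m1 <- rcross(b2n, n1)
  x <- rdot(n1, n2)
  y <- rdot(m1, n2)
  ang <- atan2(y, x)
  # map -pi to +pi so the range is (-pi, pi]
  ang[ang <= -pi + 1e-15] <- pi
  ang
}

#' Planar angle at p2 for three points
#'
#' @param p1,p2,p3 length-3 numeric vectors.
#' @return angle in radians, in [0, pi].
#' @export
planar_angle <- function(p1, p2, p3) {
  as.numeric(planar_rows(rbind(p1), rbind(p2), rbind(p3)))
}

planar_rows <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cu <- rdot(u, v) / pmax(sqrt(rdot(u, u) * rdot(v, v)), 1e-12)
  acos(pmin(1, pmax(-1, cu)))
}

#' Place a fourth atom from internal coordinates (NeRF)
#'
#' Given positions a, b, c, places d such that |c-d| = bond, the angle
#' b-c-d equals \code{angle} and the torsion a-b-c-d equals \code{torsion}
#' (same sign convention as \code{\link{dihedral_angle}}).
#'
#' @param a,b,c length-3 numeric vectors.
#' @param bond bond length c-d in Angstrom.
#' @param angle planar angle b-c-d in radians.
#' @param torsion dihedral a-b-c-d in radians.
#' @return length-3 numeric vector.
#' @export
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- vunit(c - b)
  ab <- b - a
  n <- vcross(ab, bc)
  if (vnorm(n) < 1e-10) stop("degenerate geometry: collinear reference atoms", call. = FALSE)
  n <- vunit(n)
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for rotation by theta (radians) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- vunit(u)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Apply rotation R (3x3) and translation t (length 3) to an n x 3 matrix.
rigid_transform <- function(x, R, t = c(0, 0, 0)) {
  sweep(x %*% t(R), 2, -t)
}

#' Optimal proper-rotation superposition (Kabsch)
#'
#' Least-squares RMSD after superposing \code{a} onto \code{b} with a proper
#' rotation (determinant +1; mirror images are never credited).
#'
#' @param a,b n x 3 coordinate matrices, n >= 3.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size", call. = FALSE)
  if (nrow(a) < 3) stop("need at least 3 points", call. = FALSE)
  fit <- kabsch_fit(a, b)
  sqrt(mean(rowSums((fit$a_aligned - sweep(b, 2, fit$centroid_b)) ^ 2)))
}

# Returns the rotation applied to centered a, plus centroids; helper for
# kabsch_rmsd and for aligned-coordinate output.
kabsch_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(a0) %*% b0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, a_aligned = a0 %*% t(R), centroid_a = ca, centroid_b = cb)
}
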