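# Vector geometry kernels shared by all modules.  Coordinates are Angstrom,
# angles are degrees at every user-facing interface and radians only inside
# local arithmetic.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Row-wise cross product of two n x 3 matrices.
mcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

mrownorm <- function(a) sqrt(rowSums(a * a))

#' Measure the angle defined by three points
#'
#' @param p1,p2,p3 Numeric 3-vectors (Angstrom); `p2` is the vertex.
#' @return Angle in degrees in \[0, 180\].
#' @export
measure_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * RAD2DEG
}

#' Measure a torsion (dihedral) angle
#'
#' Returns the dihedral p1-p2-p3-p4 under the IUPAC sign convention
#' (cis = 0 degrees), in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-10 || vnorm(b2) < 1e-10 || vnorm(b3) < 1e-10)
    stop("undefined dihedral: coincident consecutive points")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("undefined dihedral: collinear points")
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * RAD2DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix for a right-handed rotation of `theta` radians about the
# unit axis `u` (Rodrigues form).
rotation_matrix <- function(u, theta) {
  u <- vunit(u)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * (u %*% t(u))
}

# Optimal rigid superposition (Kabsch, via SVD).  Returns the rotation R and
# translation t mapping `mobile` onto `target` (both n x 3), plus the RMSD
# after superposition.
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(target, 2L, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(R = R, t = ct - as.vector(R %*% cm), rmsd = rmsd)
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% t(R), 2L, t, "+")
}

# Even-odd (ray crossing) point-in-polygon test; polygon is an n x 2 matrix.
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Complementary error function via the exact normal-CDF identity.
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a <= -180] <- a[a <= -180] + 360
  a
}
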