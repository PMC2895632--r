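# Low-level 3D geometry: superposition, RMSD, dihedrals and the ideal
# trans-peptide unit used to place carbonyl oxygens and to define backbone
# equilibrium distances.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Optimal rigid-body superposition of two point sets
#'
#' Finds the rotation and translation minimising the RMSD between two
#' matched point sets (Kabsch SVD solution, restricted to proper
#' rotations).  The returned rotation maps the centred mobile set onto the
#' centred target set.
#'
#' @param mobile n x 3 coordinate matrix to be moved.
#' @param target n x 3 coordinate matrix held fixed.
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `coords` (the transformed mobile set) and `rmsd` after superposition.
#'   The transform acts as `coords = mobile %*% t(rotation) + translation`.
#' @keywords internal
superpose_points <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target))
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  xm <- sweep(mobile, 2, cm)
  xt <- sweep(target, 2, ct)
  # Kabsch: the optimal proper rotation from the SVD of the covariance,
  # with the determinant sign corrected so reflections are excluded
  sv <- svd(t(xm) %*% xt)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rotated <- xm %*% t(R)
  translation <- ct - as.numeric(R %*% cm)
  out <- sweep(rotated, 2, ct, `+`)
  list(rotation = R, translation = translation, coords = out,
       rmsd = sqrt(mean(rowSums((out - sweep(xt, 2, ct, `+`))^2))))
}

#' Torsion (dihedral) angle of four points
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in radians in (-pi, pi].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Analytic gradient of the dihedral angle with respect to the four points.
# Returns a list of four length-3 vectors.  Standard rigid-rotation form:
# d(phi)/dp1 = -|b2|/|n1|^2 n1, d(phi)/dp4 = |b2|/|n2|^2 n2, with the inner
# points following from translational/rotational invariance.
dihedral_gradient <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  g1 <- nb2 / sum(n1 * n1) * n1
  g4 <- -nb2 / sum(n2 * n2) * n2
  a <- sum(b1 * b2) / (nb2 * nb2)
  b <- sum(b3 * b2) / (nb2 * nb2)
  g2 <- -(1 + a) * g1 + b * g4
  g3 <- a * g1 - (1 + b) * g4
  list(g1, g2, g3, g4)
}

# Smallest signed angular difference a - b wrapped to (-pi, pi].
angle_wrap <- function(x) {
  atan2(sin(x), cos(x))
}

# Row-wise cross product of two n x 3 matrices.
cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# Batched dihedral angles and (optionally) gradients for a matrix of
# quadruple site indices (nq x 4) into the site matrix S.  Returns
# list(angle, g1..g4) with gi nq x 3; the same formulas as
# dihedral_angle()/dihedral_gradient(), vectorised row-wise.
dihedral_batch <- function(S, quad, gradient = TRUE) {
  p1 <- S[quad[, 1], , drop = FALSE]
  p2 <- S[quad[, 2], , drop = FALSE]
  p3 <- S[quad[, 3], , drop = FALSE]
  p4 <- S[quad[, 4], , drop = FALSE]
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2 / nb2)
  ang <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
  if (!gradient) return(list(angle = ang))
  g1 <- n1 * (nb2 / rowSums(n1^2))
  g4 <- n2 * (-nb2 / rowSums(n2^2))
  a <- rowSums(b1 * b2) / nb2^2
  b <- rowSums(b3 * b2) / nb2^2
  g2 <- g1 * (-(1 + a)) + g4 * b
  g3 <- g1 * a - g4 * (1 + b)
  list(angle = ang, g1 = g1, g2 = g2, g3 = g3, g4 = g4)
}

# ---------------------------------------------------------------------------
# Ideal trans-peptide unit.
#
# Built once from standard covalent geometry (lengths in Angstrom, angles in
# degrees): CA-C' 1.525, C'=O 1.231, C'-N 1.329, N-CA 1.458; CA-C'-N 116.2,
# CA-C'-O 120.8, C'-N-CA 121.7; omega = 180 (trans).  The unit is planar.
# From it we derive the in-plane coordinates of the carbonyl oxygen in the
# frame of its own CA(i) -> CA(i+1) virtual bond, which fixes both the
# CA(i)-O(i) bond equilibrium and the O(i)-CA(i+1) planarity equilibrium.

rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

ideal_peptide_unit <- function() {
  deg <- pi / 180
  ca1 <- c(0, 0)
  cp <- c(1.525, 0)                       # carbonyl carbon C'
  # N at angle CA1-C'-N = 116.2 from the C'->CA1 direction, +y side
  dn <- rot2(c(-1, 0), -116.2 * deg)
  n <- cp + 1.329 * dn
  # O on the opposite side: angle CA1-C'-O = 120.8, -y side
  do <- rot2(c(-1, 0), 120.8 * deg)
  o <- cp + 1.231 * do
  # CA2 from N with angle C'-N-CA2 = 121.7, trans (in plane, far from CA1)
  dc <- unitv(c(cp - n, 0))[1:2]
  ca2a <- n + 1.458 * rot2(dc, 121.7 * deg)
  ca2b <- n + 1.458 * rot2(dc, -121.7 * deg)
  ca2 <- if (vnorm(c(ca2a - ca1, 0)) > vnorm(c(ca2b - ca1, 0))) ca2a else ca2b
  list(ca1 = ca1, cp = cp, o = o, n = n, ca2 = ca2)
}

# In-plane coordinates (a, b) of O relative to CA1 in the orthonormal frame
# u = unit(CA2 - CA1), v = in-plane perpendicular on the O side; plus derived
# equilibrium distances.
peptide_frame_constants <- function() {
  un <- ideal_peptide_unit()
  u <- unitv(c(un$ca2 - un$ca1, 0))[1:2]
  v <- c(-u[2], u[1])
  rel <- un$o - un$ca1
  a <- sum(rel * u)
  b <- sum(rel * v)
  if (b > 0) { v <- -v; b <- -b }        # fix O to the -v side by convention
  b <- abs(sum(rel * c(-u[2], u[1])))
  r_caca <- 3.80                          # virtual CA-CA bond equilibrium
  list(
    o_along = a,                          # component of O along CA->CA
    o_perp = b,                           # perpendicular component (magnitude)
    r0_ca_o = sqrt(a^2 + b^2),            # CA(i)-O(i) equilibrium
    r0_o_ca_next = sqrt((r_caca - a)^2 + b^2),  # O(i)-CA(i+1) equilibrium
    r0_o_ca_prev = sqrt((r_caca + a)^2 + b^2),  # terminal O(N)-CA(N-1)
    r0_ca_ca = r_caca
  )
}

.knotpath_cache <- new.env(parent = emptyenv())

peptide_constants <- function() {
  if (is.null(.knotpath_cache$peptide)) {
    .knotpath_cache$peptide <- peptide_frame_constants()
  }
  .knotpath_cache$peptide
}
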