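#' @title Rigid-body geometry utilities
#' @description Internal helpers: Kabsch least-squares superposition, rigid
#'   transforms, vector angles and plane fits. All coordinates are n x 3
#'   matrices in Angstrom.
#' @name geometry
#' @keywords internal
NULL

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

#' Angle between two vectors in degrees
#' @param u,v numeric length-3 vectors.
#' @return angle in degrees in [0, 180].
#' @keywords internal
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Three-point angle (degrees) at vertex `b`
#' @param a,b,c numeric length-3 points.
#' @keywords internal
point_angle <- function(a, b, c) vec_angle(a - b, c - b)

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' \eqn{\sum_i w_i \| R x_i + t - y_i \|^2} over rigid motions, mapping the
#' moving point set onto the reference set.
#'
#' @param x moving points, n x 3 matrix.
#' @param y reference points, n x 3 matrix (same n).
#' @param w optional non-negative weights, length n.
#' @return list with `R` (3 x 3 rotation, det +1), `t` (length-3
#'   translation) and `rmsd` (weighted RMSD of the superposed pairs).
#' @examples
#' x <- matrix(rnorm(15), 5, 3)
#' tf <- kabsch(x, x)
#' stopifnot(tf$rmsd < 1e-12)
#' @export
kabsch <- function(x, y, w = NULL) {
  x <- rbind(x); y <- rbind(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y))
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  h <- t(xc * w) %*% yc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  dd <- diag(c(1, 1, d))
  rot <- sv$v %*% dd %*% t(sv$u)
  t <- cy - as.vector(rot %*% cx)
  moved <- sweep(x %*% t(rot), 2, t, "+")
  rmsd <- sqrt(sum(w * rowSums((moved - y)^2)))
  list(R = rot, t = t, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param coords n x 3 matrix.
#' @param transform list with `R` and `t` as returned by [kabsch()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  coords <- rbind(coords)
  sweep(coords %*% t(transform$R), 2, transform$t, "+")
}

#' Compose a rotation about the x, y and z axes (degrees) with a translation
#' @keywords internal
euler_transform <- function(rx = 0, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0) {
  torad <- pi / 180
  cx <- cos(rx * torad); sx <- sin(rx * torad)
  cy <- cos(ry * torad); sy <- sin(ry * torad)
  cz <- cos(rz * torad); sz <- sin(rz * torad)
  rotx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  roty <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rotz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  list(R = rotz %*% roty %*% rotx, t = c(tx, ty, tz))
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @keywords internal
axis_rotation <- function(axis, angle_deg) {
  k <- unitize(axis)
  th <- angle_deg * pi / 180
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Best-fit plane through points
#' @param pts n x 3 matrix, n >= 3.
#' @return list with `center` and unit `normal`.
#' @keywords internal
plane_fit <- function(pts) {
  center <- colMeans(pts)
  sv <- svd(sweep(pts, 2, center))
  list(center = center, normal = sv$v[, 3])
}

#' Heavy-atom RMSD between two conformations after optimal superposition
#' @keywords internal
aligned_rmsd <- function(x, y) kabsch(x, y)$rmsd

#' Pairwise squared distances between two point sets
#' @param a n x 3, b m x 3
#' @return n x m matrix of squared distances.
#' @keywords internal
cross_dist2 <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  outer(an, bn, "+") - 2 * (a %*% t(b))
}
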