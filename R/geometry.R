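#' Least-squares plane fit to a set of points
#'
#' Fits the plane minimizing the sum of squared point-plane distances via
#' the SVD of the centered coordinates. The center is the centroid; the
#' normal is the singular vector of the smallest singular value, with its
#' sign canonicalized (z component >= 0; on a tie y >= 0, then x > 0) so
#' downstream angles, all folded to [0, 90] degrees, are deterministic.
#'
#' @param coords numeric matrix (n x 3), n >= 3, not collinear
#' @return list with \code{center} (length-3), \code{normal} (unit length-3)
#'   and \code{rms_dev}, the root-mean-square out-of-plane deviation in
#'   Angstrom
#' @examples
#' hex <- t(sapply(0:5, function(k)
#'   c(1.39 * cos(k * pi / 3), 1.39 * sin(k * pi / 3), 2)))
#' planeFit(hex)
#' @export
planeFit <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3 || ncol(coords) != 3)
    stop("planeFit needs an n x 3 matrix with n >= 3")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  center <- colMeans(coords)
  x <- sweep(coords, 2, center)
  sv <- svd(x, nu = 0)
  # collinear points leave the plane normal undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) points: plane is undetermined")
  normal <- sv$v[, 3]
  normal <- .canonicalSign(normal)
  rms <- sqrt(mean((x %*% normal)^2))
  list(center = center, normal = normal, rms_dev = rms)
}

#' @keywords internal
.canonicalSign <- function(v, eps = 1e-12) {
  s <- if (abs(v[3]) > eps) sign(v[3])
       else if (abs(v[2]) > eps) sign(v[2])
       else sign(v[1])
  if (s < 0) -v else v
}

#' @keywords internal
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Angle between two vectors folded to [0, 90] degrees (sign-insensitive,
# as both ring normals and the center-center line are axial quantities).
#' @keywords internal
.foldedAngle <- function(a, b) {
  ca <- abs(sum(.unit(a) * .unit(b)))
  acos(min(1, ca)) * 180 / pi
}

# Rotation matrix taking unit vector `from` onto unit vector `to`
# (minimal rotation about their common perpendicular).
#' @keywords internal
.rotationBetween <- function(from, to) {
  f <- .unit(from); t <- .unit(to)
  v <- c(f[2] * t[3] - f[3] * t[2],
         f[3] * t[1] - f[1] * t[3],
         f[1] * t[2] - f[2] * t[1])
  c_ <- sum(f * t)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis perpendicular to f
    p <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(p - sum(p * f) * f)
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Orthonormal basis (e1, e2) spanning the plane perpendicular to `normal`.
#' @keywords internal
.planeBasis <- function(normal) {
  n <- .unit(normal)
  p <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(p - sum(p * n) * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}
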