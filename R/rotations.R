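#' Validate a rotation (direction cosine) matrix
#'
#' Checks that `R` is a proper 3x3 rotation matrix: orthonormal
#' (`R %*% t(R) = I`) and with determinant +1.  Throughout the package the
#' convention is that the columns of `R` are the shank X, Y, Z axes expressed
#' in the thigh coordinate system.
#'
#' @param R 3x3 numeric matrix.
#' @param tol elementwise tolerance for orthonormality and for `det(R) - 1`.
#' @return `R`, invisibly, if valid; otherwise an error.
#' @export
check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || !is.numeric(R) ||
      any(!is.finite(R)))
    stop("R must be a finite numeric 3x3 matrix", call. = FALSE)
  if (max(abs(R %*% t(R) - diag(3))) > tol)
    stop("R is not orthonormal within tolerance", call. = FALSE)
  if (abs(det(R) - 1) > tol)
    stop("det(R) != +1: not a proper rotation", call. = FALSE)
  invisible(R)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}
rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}

#' Compose a rotation matrix from ZXY Cardan angles
#'
#' Builds `R = Rz(theta1) Rx(theta2) Ry(theta3)`, the mobile-axis ZXY Cardan
#' sequence used for the knee: flexion-extension about the thigh Z axis,
#' adduction-abduction about the floating axis, internal-external rotation
#' about the shank Y axis.
#'
#' @param theta1,theta2,theta3 Cardan angles in degrees; alternatively
#'   `theta1` may be a length-3 numeric vector.
#' @return A 3x3 rotation matrix (shank axes in the thigh frame).
#' @seealso [extract_cardan_zxy()]
#' @export
compose_cardan_zxy <- function(theta1, theta2 = NULL, theta3 = NULL) {
  if (length(theta1) == 3L && is.null(theta2)) {
    theta3 <- theta1[3L]; theta2 <- theta1[2L]; theta1 <- theta1[1L]
  }
  ang <- c(theta1, theta2, theta3)
  if (length(ang) != 3L || any(!is.finite(ang)))
    stop("three finite Cardan angles (degrees) required", call. = FALSE)
  a <- deg2rad(ang)
  rot_z(a[1L]) %*% rot_x(a[2L]) %*% rot_y(a[3L])
}

#' Extract ZXY Cardan angles from a rotation matrix
#'
#' Inverts [compose_cardan_zxy()]: `theta2 = asin(R[3,2])`,
#' `theta1 = atan2(-R[1,2], R[2,2])`, `theta3 = atan2(-R[3,1], R[3,3])`.
#' The extraction is singular (gimbal lock) when `|R[3,2]|` approaches 1,
#' i.e. adduction-abduction at +/-90 degrees.
#'
#' @param R 3x3 rotation matrix.
#' @param tol gimbal-lock guard on `1 - |R[3,2]|`.
#' @return Named numeric vector `c(theta1, theta2, theta3)` in degrees.
#' @export
extract_cardan_zxy <- function(R, tol = 1e-9) {
  check_rotation(R, tol = 1e-6)
  s2 <- R[3L, 2L]
  if (abs(s2) >= 1 - tol)
    stop("gimbal lock: second Cardan angle at +/-90 degrees", call. = FALSE)
  c(theta1 = rad2deg(atan2(-R[1L, 2L], R[2L, 2L])),
    theta2 = rad2deg(asin(s2)),
    theta3 = rad2deg(atan2(-R[3L, 1L], R[3L, 3L])))
}

#' Extract the attitude (axis-angle) description of a rotation
#'
#' Returns the rotation angle `theta` in `[0, 180]` degrees and the unit
#' rotation axis `k` such that `R` equals the Rodrigues form
#' `cos(theta) I + sin(theta) [k]_x + (1 - cos(theta)) k k^T`.  The attitude
#' vector `theta * k` is the coordinate-free description of the finite
#' joint rotation (helical/screw axis representation).
#'
#' Near `theta = 0` the axis is undefined: the conventional fallback axis
#' `c(0, 0, 1)` (the knee flexion direction) is returned with
#' `degenerate = TRUE`.
#'
#' @param R 3x3 rotation matrix.
#' @param tol degeneracy tolerance on the quaternion vector-part norm.
#' @return List with `theta` (degrees), `k` (unit axis, thigh frame) and
#'   `degenerate` (logical).
#' @export
attitude_from_rotation <- function(R, tol = 1e-9) {
  check_rotation(R, tol = 1e-6)
  # quaternion (Shepperd) extraction: numerically stable for all angles,
  # including near 0 and near 180 degrees
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr >= max(diag(R))) {
    s <- 2 * sqrt(max(1 + tr, 0))
    q <- c(s / 4, (R[3L, 2L] - R[2L, 3L]) / s, (R[1L, 3L] - R[3L, 1L]) / s,
           (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3L + 1L
    l <- j %% 3L + 1L
    s <- 2 * sqrt(max(1 + R[i, i] - R[j, j] - R[l, l], 0))
    v <- numeric(3L)
    v[i] <- s / 4
    v[j] <- (R[j, i] + R[i, j]) / s
    v[l] <- (R[l, i] + R[i, l]) / s
    q <- c((R[l, j] - R[j, l]) / s, v)
  }
  if (q[1L] < 0) q <- -q
  vn <- sqrt(sum(q[2:4]^2))
  th <- 2 * atan2(vn, q[1L])
  if (th < deg2rad(1e-7) || vn < tol) {
    return(list(theta = 0, k = c(0, 0, 1), degenerate = TRUE))
  }
  list(theta = rad2deg(th), k = unitize(q[2:4]), degenerate = FALSE)
}

#' Build a rotation matrix from an attitude state (Rodrigues formula)
#'
#' @param theta rotation angle in degrees (or a list as returned by
#'   [attitude_from_rotation()]).
#' @param k unit rotation axis.
#' @return 3x3 rotation matrix
#'   `cos(theta) I + sin(theta) [k]_x + (1 - cos(theta)) k k^T`.
#' @export
rotation_from_attitude <- function(theta, k = NULL) {
  if (is.list(theta) && is.null(k)) {
    k <- theta$k; theta <- theta$theta
  }
  stopifnot_unit(k, "rotation axis k")
  a <- deg2rad(theta)
  K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0), 3L, 3L)
  diag(3) * cos(a) + sin(a) * K + (1 - cos(a)) * tcrossprod(k)
}

#' Construct the knee joint coordinate system from a rotation matrix
#'
#' The joint coordinate system (JCS) is the non-orthogonal triad: `e1` is the
#' thigh Z axis `c(0, 0, 1)` (flexion-extension), `e3` is the shank Y axis,
#' i.e. the second column of `R`, (internal-external rotation), and the
#' floating axis is `e2 = (e3 x e1) / ||e3 x e1||`, mutually orthogonal to
#' both.  All axes are expressed in the thigh frame.
#'
#' @param R 3x3 rotation matrix (shank axes in thigh frame).
#' @param tol degeneracy guard on `||e3 x e1||`.
#' @return List with unit vectors `e1`, `e2`, `e3`.
#' @export
joint_axes_from_rotation <- function(R, tol = 1e-6) {
  check_rotation(R, tol = 1e-6)
  e1 <- c(0, 0, 1)
  e3 <- R[, 2L]
  cx <- cross3(e3, e1)
  n <- vnorm(cx)
  if (n <= tol)
    stop("degenerate configuration: shank long axis parallel to the flexion axis",
         call. = FALSE)
  list(e1 = e1, e2 = cx / n, e3 = e3)
}

#' Non-orthogonal projection of the attitude vector on the joint axes
#'
#' Decomposes the attitude vector `theta * k` on the joint coordinate system:
#' \deqn{\theta_1 = \frac{(e_2 \times e_3)\cdot k}{(e_1 \times e_2)\cdot e_3}\,\theta,
#' \quad \theta_2 = \frac{(e_3 \times e_1)\cdot k}{(e_1 \times e_2)\cdot e_3}\,\theta,
#' \quad \theta_3 = \frac{(e_1 \times e_2)\cdot k}{(e_1 \times e_2)\cdot e_3}\,\theta.}
#' The components satisfy the exact decomposition identity
#' `theta1 e1 + theta2 e2 + theta3 e3 = theta k`.
#'
#' @param att attitude state (list with `theta` degrees and unit `k`), as
#'   returned by [attitude_from_rotation()].
#' @param axes joint axes (list `e1`, `e2`, `e3`), as returned by
#'   [joint_axes_from_rotation()].
#' @return Named numeric vector `c(theta1, theta2, theta3)` in degrees.
#' @export
project_attitude <- function(att, axes) {
  g <- sum(cross3(axes$e1, axes$e2) * axes$e3)
  if (abs(g) < 1e-9)
    stop("singular joint axis basis: e1 x e2 . e3 ~ 0", call. = FALSE)
  k <- att$k
  th <- att$theta
  c(theta1 = sum(cross3(axes$e2, axes$e3) * k) / g * th,
    theta2 = sum(cross3(axes$e3, axes$e1) * k) / g * th,
    theta3 = sum(cross3(axes$e1, axes$e2) * k) / g * th)
}

#' Relative rotation of the shank with respect to the thigh
#'
#' Given world orientations of the two segments (columns = segment axes in
#' the world frame), returns `R = t(T) %*% S`, whose entries are the table of
#' dot products between shank and thigh axes and whose columns are the shank
#' axes expressed in the thigh frame.
#'
#' @param thigh,shank 3x3 world orientation matrices of the thigh and shank.
#' @return 3x3 relative rotation matrix.
#' @export
relative_rotation <- function(thigh, shank) {
  check_rotation(thigh, tol = 1e-6)
  check_rotation(shank, tol = 1e-6)
  crossprod(thigh, shank)
}
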