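#' Reduce an attitude state and joint axes to the seven independent parameters
#'
#' The unit-norm constraints on `k`, `e1` and `e3` and the construction of
#' the floating axis `e2` leave seven independent quantities describing a
#' knee pose: the rotation angle `theta` and two free components per axis.
#' The dependent "main direction" components are recovered as
#' `kz = sqrt(1 - kx^2 - ky^2)`, `e1z = sqrt(1 - e1x^2 - e1y^2)` and
#' `e3y = sqrt(1 - e3x^2 - e3z^2)`, which assumes the knee convention that
#' the rotation axis and flexion axis point along +Z of the thigh and the
#' shank long axis along +Y.
#'
#' @param att attitude state (list `theta` degrees, unit `k`).
#' @param axes joint axes (list `e1`, `e2`, `e3`), `e2` ignored (it is a
#'   derived quantity).
#' @return Object of class `jcs_params`: named numeric vector
#'   `c(theta, kx, ky, e1x, e1y, e3x, e3z)`, `theta` in degrees.
#' @export
independent_parameters <- function(att, axes) {
  k <- stopifnot_unit(att$k, "k")
  e1 <- stopifnot_unit(axes$e1, "e1")
  e3 <- stopifnot_unit(axes$e3, "e3")
  if (k[3L] <= 0 || e1[3L] <= 0 || e3[2L] <= 0)
    stop(paste("main-direction sign error: the parameterization requires",
               "kz > 0, e1z > 0 and e3y > 0"), call. = FALSE)
  p <- c(theta = as.numeric(att$theta), kx = k[1L], ky = k[2L],
         e1x = e1[1L], e1y = e1[2L], e3x = e3[1L], e3z = e3[3L])
  names(p) <- c("theta", "kx", "ky", "e1x", "e1y", "e3x", "e3z")
  structure(p, class = "jcs_params")
}

#' Reconstruct pose vectors from the seven independent parameters
#'
#' Inverse of [independent_parameters()]: rebuilds the unit vectors `k`,
#' `e1`, `e3` from their free components and the floating axis
#' `e2 = (e3 x e1)/||e3 x e1||`.
#'
#' @param p numeric vector `c(theta, kx, ky, e1x, e1y, e3x, e3z)`.
#' @return List with `theta` (degrees) and unit vectors `k`, `e1`, `e2`, `e3`.
#' @export
reconstruct_from_parameters <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 7L || any(!is.finite(p)))
    stop("p must be 7 finite parameters", call. = FALSE)
  sq <- function(a, b) {
    r <- 1 - a^2 - b^2
    if (r < 0) stop("free components exceed unit norm", call. = FALSE)
    sqrt(r)
  }
  k <- c(p[2L], p[3L], sq(p[2L], p[3L]))
  e1 <- c(p[4L], p[5L], sq(p[4L], p[5L]))
  e3 <- c(p[6L], sq(p[6L], p[7L]), p[7L])
  cx <- cross3(e3, e1)
  n <- vnorm(cx)
  if (n <= 1e-6)
    stop("degenerate configuration: e3 parallel to e1", call. = FALSE)
  list(theta = p[1L], k = k, e1 = e1, e2 = cx / n, e3 = e3)
}

#' Map a cone half-angle to a component standard uncertainty
#'
#' Axis-orientation uncertainty is modelled as a cone of half-angle `alpha`
#' about the nominal direction; the corresponding standard uncertainty of
#' each of the two free (transverse) components of the unit axis is
#' `tan(alpha)`.
#'
#' @param alpha cone half-angle in degrees, `0 <= alpha < 90`.
#' @return `tan(alpha)` (dimensionless), applied identically and
#'   independently to both free components.
#' @export
cone_to_component_uncertainty <- function(alpha) {
  if (any(alpha < 0) || any(alpha >= 90))
    stop("cone half-angle must satisfy 0 <= alpha < 90 degrees", call. = FALSE)
  tan(deg2rad(alpha))
}

#' Specify input uncertainties for the propagation model
#'
#' @param u_theta standard uncertainty of the rotation angle, degrees.
#' @param alpha_k,alpha_e1,alpha_e3 cone half-angles (degrees) describing
#'   the orientation uncertainty of the rotation axis `k`, the flexion axis
#'   `e1` and the shank axis `e3`.
#' @return Object of class `jcs_uinputs`.
#' @export
uncertainty_inputs <- function(u_theta = 5, alpha_k = 5, alpha_e1 = 5,
                               alpha_e3 = 5) {
  u <- c(u_theta = u_theta, alpha_k = alpha_k, alpha_e1 = alpha_e1,
         alpha_e3 = alpha_e3)
  if (any(!is.finite(u)) || any(u < 0))
    stop("input uncertainties must be finite and >= 0", call. = FALSE)
  if (any(u[-1L] >= 90))
    stop("cone half-angles must be < 90 degrees", call. = FALSE)
  structure(as.list(u), class = "jcs_uinputs")
}

#' @export
print.jcs_uinputs <- function(x, ...) {
  cat(sprintf(
    "Input uncertainties: u(theta) = %g deg; cones alpha_k = %g, alpha_e1 = %g, alpha_e3 = %g deg\n",
    x$u_theta, x$alpha_k, x$alpha_e1, x$alpha_e3))
  invisible(x)
}

# per-parameter standard uncertainties in internal units
# (theta in radians, axis components dimensionless), ordered like jcs_params
.param_sd <- function(u) {
  c(deg2rad(u$u_theta),
    rep(cone_to_component_uncertainty(u$alpha_k), 2L),
    rep(cone_to_component_uncertainty(u$alpha_e1), 2L),
    rep(cone_to_component_uncertainty(u$alpha_e3), 2L))
}
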