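#' Numerator/denominator sensitivities of the projected joint angles
#'
#' The projected angles are quotients `theta_i = f_i / g` where
#' `f_1 = theta (e2 x e3).k`, `f_2 = theta (e3 x e1).k`,
#' `f_3 = theta (e1 x e2).k` and the common denominator is the mixed product
#' `g = (e1 x e2).e3`, all expressed in the seven independent pose
#' parameters.  This evaluates `f`, `g` and all first partial derivatives
#' from closed-form expressions generated once symbolically and frozen in
#' the package sources (`R/sensitivity-exact.R`).
#'
#' @param p pose parameters `c(theta, kx, ky, e1x, e1y, e3x, e3z)` with
#'   `theta` in degrees (see [independent_parameters()]).
#' @return Object of class `jcs_sens`: list with `f` (length 3, radians),
#'   `g` (scalar, dimensionless), `df` (3x7 matrix of `df_i/dx_j`), `dg`
#'   (length 7) and `dy_dx` (3x7 matrix of quotient-rule output
#'   sensitivities `(g df - f dg)/g^2`).  Internal angle units are radians.
#' @export
sensitivity_terms <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 7L || any(!is.finite(p)))
    stop("p must be 7 finite parameters", call. = FALSE)
  s <- .sens_eval(deg2rad(p[1L]), p[2L], p[3L], p[4L], p[5L], p[6L], p[7L])
  if (!is.finite(s$g) || abs(s$g) < 1e-9)
    stop("degenerate pose: joint axis mixed product ~ 0", call. = FALSE)
  if (any(!is.finite(c(s$f, s$df, s$dg))))
    stop("degenerate pose: sensitivities are not finite", call. = FALSE)
  dy <- (s$g * s$df - outer(s$f, s$dg)) / s$g^2
  structure(list(f = s$f, g = s$g, df = s$df, dg = s$dg, dy_dx = dy,
                 params = p), class = "jcs_sens")
}

# central finite differences of f and g; independent check path used by the
# validation tests and exposed for diagnostics
#' Finite-difference check of the frozen sensitivities
#'
#' Recomputes all partials of the numerators `f1..f3` and denominator `g`
#' by central finite differences and reports the worst relative error
#' against the closed-form values.
#'
#' @param p pose parameters (degrees for `theta`).
#' @param h finite-difference step on the internal (radian/dimensionless)
#'   scale.
#' @param floor absolute floor in the relative-error denominator.  `f` and
#'   `g` are O(1), so central differences at step `h` carry an absolute
#'   roundoff of about `.Machine$double.eps / h`; partials smaller than the
#'   floor are compared on the absolute scale of the problem instead.
#' @return List with `max_rel_f`, `max_rel_g` and the finite-difference
#'   matrices `df_fd`, `dg_fd`.
#' @export
sensitivity_fd_check <- function(p, h = 1e-6, floor = 1e-3) {
  p <- as.numeric(p)
  x <- c(deg2rad(p[1L]), p[-1L])
  f_of <- function(x) {
    s <- .sens_eval(x[1L], x[2L], x[3L], x[4L], x[5L], x[6L], x[7L])
    c(s$f, s$g)
  }
  df_fd <- matrix(NA_real_, 3L, 7L)
  dg_fd <- numeric(7L)
  for (j in 1:7) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    d <- (f_of(xp) - f_of(xm)) / (2 * h)
    df_fd[, j] <- d[1:3]
    dg_fd[j] <- d[4L]
  }
  s <- .sens_eval(x[1L], x[2L], x[3L], x[4L], x[5L], x[6L], x[7L])
  rel <- function(a, b) abs(a - b) / pmax(abs(b), floor)
  list(max_rel_f = max(rel(s$df, df_fd)),
       max_rel_g = max(rel(s$dg, dg_fd)),
       df_fd = df_fd, dg_fd = dg_fd)
}
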