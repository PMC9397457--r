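.SOURCES <- c("theta", "k", "e1", "e3")
.SOURCE_IDX <- list(theta = 1L, k = 2:3, e1 = 4:5, e3 = 6:7)

#' First-order propagation of input uncertainties at a single knee pose
#'
#' Propagates the standard uncertainty of the rotation angle and the
#' cone-angle uncertainties of the axis orientations to the three projected
#' joint angles by the first-order quotient rule
#' \deqn{u^2(y) = \frac{1}{g^4}\sum_{i=1}^{7}
#'   \left(g\,\frac{\partial f}{\partial x_i} -
#'         f\,\frac{\partial g}{\partial x_i}\right)^2 u^2(x_i),}
#' with the seven inputs treated as uncorrelated.  Component uncertainties
#' are `u(kx) = u(ky) = tan(alpha_k)` and analogously for `e1` and `e3`;
#' `u(theta)` enters directly (converted to radians internally).
#'
#' When the rotation angle is below 1 degree the rotation axis is not
#' identifiable and the axis-related contributions are reported as zero with
#' `degenerate = TRUE`; the `theta` contribution is still computed.
#'
#' @param p pose parameters (see [independent_parameters()]).
#' @param u input uncertainties (see [uncertainty_inputs()]).
#' @return List with `combined` (length 3, degrees), `per_source` (3x4
#'   matrix, outputs x sources `theta`, `k`, `e1`, `e3`, degrees),
#'   `dy_dx` (3x7 output sensitivities) and `degenerate`.
#'   `combined^2 = rowSums(per_source^2)` holds exactly.
#' @export
propagate <- function(p, u) {
  stopifnot(inherits(u, "jcs_uinputs"))
  s <- sensitivity_terms(p)
  usd <- .param_sd(u)
  degenerate <- abs(as.numeric(p)[1L]) < 1
  if (degenerate) usd[2:7] <- 0
  contrib2 <- sweep(s$dy_dx^2, 2L, usd^2, `*`) # 3 x 7, radians^2
  per_source <- sapply(.SOURCE_IDX, function(idx)
    sqrt(rowSums(contrib2[, idx, drop = FALSE])))
  per_source <- rad2deg(matrix(per_source, nrow = 3L,
                               dimnames = list(c("theta1", "theta2", "theta3"),
                                               .SOURCES)))
  combined <- sqrt(rowSums(per_source^2))
  list(combined = combined, per_source = per_source, dy_dx = s$dy_dx,
       degenerate = degenerate)
}

#' Propagate input uncertainties along a gait cycle
#'
#' Applies [propagate()] frame by frame to a gait cycle (typically the
#' across-trials mean cycle from [mean_cycle()], the linearization point of
#' the model).  Produces combined standard-uncertainty curves for the three
#' joint angles plus the per-source breakdown for the four input groups
#' (rotation angle `theta`, rotation axis `k`, joint axes `e1` and `e3`).
#' Because the first-order model is additive in squared contributions, each
#' per-source curve equals the result of propagating that input alone.
#'
#' @param cycle a `jcs_cycle` (or mean cycle) object.
#' @param u input uncertainties (see [uncertainty_inputs()]).
#' @return Object of class `jcs_uprop`: list with `frame_pct`, `combined`
#'   (101x3 matrix, degrees), `per_source` (101x3x4 array, degrees),
#'   `degenerate` (logical), `skipped` (frames where the pose
#'   parameterization failed), `inputs` and `stance_fraction`.
#' @export
propagate_sequence <- function(cycle, u) {
  stopifnot(inherits(cycle, "jcs_cycle") || inherits(cycle, "jcs_mean_cycle"))
  stopifnot(inherits(u, "jcs_uinputs"))
  nf <- length(cycle$frame_pct)
  combined <- matrix(NA_real_, nf, 3L,
                     dimnames = list(NULL, c("theta1", "theta2", "theta3")))
  per_source <- array(NA_real_, dim = c(nf, 3L, 4L),
                      dimnames = list(NULL, c("theta1", "theta2", "theta3"),
                                      .SOURCES))
  degenerate <- logical(nf)
  skipped <- logical(nf)
  for (i in seq_len(nf)) {
    p <- tryCatch(
      independent_parameters(
        list(theta = cycle$theta[i], k = cycle$k[i, ]),
        list(e1 = cycle$e1[i, ], e3 = cycle$e3[i, ])),
      error = function(e) NULL)
    if (is.null(p)) {
      skipped[i] <- TRUE
      next
    }
    pr <- propagate(p, u)
    combined[i, ] <- pr$combined
    per_source[i, , ] <- pr$per_source
    degenerate[i] <- pr$degenerate
  }
  if (all(skipped))
    stop("all frames degenerate: cannot propagate over this cycle",
         call. = FALSE)
  if (any(skipped))
    warning(sum(skipped), " frame(s) skipped: pose parameterization invalid",
            call. = FALSE)
  structure(list(frame_pct = cycle$frame_pct, combined = combined,
                 per_source = per_source, degenerate = degenerate,
                 skipped = skipped, inputs = u,
                 stance_fraction = cycle$stance_fraction %||% 0.616),
            class = "jcs_uprop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname propagate_sequence
#' @export
propagate_uncertainty <- propagate_sequence

#' @export
print.jcs_uprop <- function(x, ...) {
  cat("Propagated knee joint-angle uncertainties (first-order model)\n")
  print(x$inputs)
  pk <- apply(x$combined, 2L, max, na.rm = TRUE)
  cat(sprintf("  peak combined u: theta1 %.2f, theta2 %.2f, theta3 %.2f deg\n",
              pk[1L], pk[2L], pk[3L]))
  if (any(x$degenerate))
    cat("  axis terms zeroed at", sum(x$degenerate),
        "near-zero-rotation frame(s)\n")
  invisible(x)
}

#' @export
summary.jcs_uprop <- function(object, ...) {
  st <- object$frame_pct <= 100 * object$stance_fraction
  out <- list()
  for (ph in c("stance", "swing")) {
    sel <- if (ph == "stance") st else !st
    m <- rbind(combined = colMeans(object$combined[sel, , drop = FALSE],
                                   na.rm = TRUE),
               apply(object$per_source[sel, , , drop = FALSE], c(3L, 2L),
                     mean, na.rm = TRUE))
    out[[ph]] <- m
  }
  structure(out, class = "summary.jcs_uprop")
}

#' @export
print.summary.jcs_uprop <- function(x, ...) {
  for (ph in names(x)) {
    cat("Mean standard uncertainty (deg),", ph, "phase:\n")
    print(round(x[[ph]], 3))
  }
  invisible(x)
}

#' Tabulate propagated uncertainty curves
#'
#' @param x a `jcs_uprop` object.
#' @param ... unused.
#' @return Data frame in the uncertainty CSV schema: `frame_pct`, combined
#'   `u_theta1..u_theta3`, then per-source columns
#'   `src_<source>_u1..u3` for sources `theta`, `k`, `e1`, `e3` (degrees).
#' @export
as.data.frame.jcs_uprop <- function(x, ...) {
  d <- data.frame(frame_pct = x$frame_pct,
                  u_theta1 = x$combined[, 1L], u_theta2 = x$combined[, 2L],
                  u_theta3 = x$combined[, 3L])
  for (s in .SOURCES) {
    for (j in 1:3)
      d[[sprintf("src_%s_u%d", s, j)]] <- x$per_source[, j, s]
  }
  d
}

#' @export
plot.jcs_uprop <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  lab <- c("u(theta1)", "u(theta2)", "u(theta3)")
  for (j in 1:3) {
    graphics::matplot(x$frame_pct,
                      cbind(x$combined[, j], x$per_source[, j, ]),
                      type = "l", lty = c(1, rep(2, 4)),
                      col = c("black", "red", "blue", "darkgreen", "orange"),
                      xlab = "% gait cycle", ylab = "standard uncertainty (deg)",
                      main = lab[j], ...)
    graphics::abline(v = 100 * x$stance_fraction, lty = 3, col = "blue")
    if (j == 1L)
      graphics::legend("topleft", bty = "n", lty = c(1, rep(2, 4)),
                       col = c("black", "red", "blue", "darkgreen", "orange"),
                       legend = c("combined", .SOURCES), cex = 0.8)
  }
  invisible(x)
}

#' Propagate a sweep of input-uncertainty levels along a cycle
#'
#' Runs [propagate_sequence()] once per level with all four inputs set to
#' that level (in degrees), e.g. `levels = c(2, 5, 10)`.
#'
#' @param cycle a `jcs_cycle` object.
#' @param levels numeric vector of input uncertainty levels (degrees).
#' @return Named list of `jcs_uprop` objects, one per level.
#' @export
propagate_sweep <- function(cycle, levels = c(2, 5, 10)) {
  out <- lapply(levels, function(l)
    propagate_sequence(cycle, uncertainty_inputs(l, l, l, l)))
  names(out) <- paste0("u", levels)
  out
}
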