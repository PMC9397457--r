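#' Gait-cycle sequence of knee rotations
#'
#' Packages a time-normalized gait cycle (101 frames, 0..100% of the cycle)
#' of relative shank-to-thigh rotation matrices together with the derived
#' per-frame quantities: attitude state (rotation angle `theta`, unit axis
#' `k`), joint coordinate system axes (`e1`, `e2`, `e3`), ZXY Cardan angles
#' and the non-orthogonal projections of the attitude vector.  Axis
#' continuity is enforced along the cycle: the sign ambiguity of `(theta, k)`
#' is resolved so consecutive axes satisfy `k(t) . k(t+1) > 0`, and frames
#' where the rotation angle is too small to identify the axis are flagged
#' degenerate and their axis interpolated from neighbouring frames.
#'
#' @param R 3x3x101 array of rotation matrices (shank axes in thigh frame),
#'   one slice per frame at 0, 1, ..., 100% of the gait cycle.
#' @param stance_fraction fraction of the cycle in stance phase (default
#'   0.616, a typical adult value).
#' @param session_id,trial_id optional identifiers carried through I/O.
#' @return An object of class `jcs_cycle`: list with `frame_pct`, `R`,
#'   `theta` (degrees, signed after continuity enforcement), `k`, `e1`,
#'   `e2`, `e3` (101x3 matrices), `cardan`, `proj` (101x3, degrees),
#'   `degenerate` (logical) and `stance_fraction`.
#' @export
gait_cycle <- function(R, stance_fraction = 0.616, session_id = 1L,
                       trial_id = 1L) {
  if (!is.array(R) || length(dim(R)) != 3L || !all(dim(R)[1:2] == 3L))
    stop("R must be a 3 x 3 x n_frames array", call. = FALSE)
  nf <- dim(R)[3L]
  if (nf != 101L)
    stop("a gait cycle must have exactly 101 frames (0..100%)", call. = FALSE)
  if (!(stance_fraction > 0 && stance_fraction < 1))
    stop("stance_fraction must be in (0, 1)", call. = FALSE)
  theta <- numeric(nf)
  k <- e1 <- e2 <- e3 <- matrix(NA_real_, nf, 3L)
  cardan <- proj <- matrix(NA_real_, nf, 3L)
  degenerate <- logical(nf)
  for (i in seq_len(nf)) {
    Ri <- R[, , i]
    att <- attitude_from_rotation(Ri)
    theta[i] <- att$theta
    k[i, ] <- att$k
    degenerate[i] <- att$degenerate || abs(att$theta) < 1
    ax <- joint_axes_from_rotation(Ri)
    e1[i, ] <- ax$e1; e2[i, ] <- ax$e2; e3[i, ] <- ax$e3
    cardan[i, ] <- extract_cardan_zxy(Ri)
  }
  cont <- .axis_continuity(theta, k, degenerate)
  theta <- cont$theta; k <- cont$k
  for (i in seq_len(nf)) {
    proj[i, ] <- project_attitude(list(theta = theta[i], k = k[i, ]),
                                  list(e1 = e1[i, ], e2 = e2[i, ], e3 = e3[i, ]))
  }
  colnames(k) <- c("kx", "ky", "kz")
  colnames(cardan) <- colnames(proj) <- c("theta1", "theta2", "theta3")
  structure(list(frame_pct = 0:100, R = R, theta = theta, k = k,
                 e1 = e1, e2 = e2, e3 = e3, cardan = cardan, proj = proj,
                 degenerate = degenerate, stance_fraction = stance_fraction,
                 session_id = session_id, trial_id = trial_id),
            class = "jcs_cycle")
}

# Resolve the (theta, k) <-> (-theta, -k) ambiguity along a cycle and
# interpolate the axis at degenerate frames.  theta * k is preserved frame
# by frame.
.axis_continuity <- function(theta, k, degenerate) {
  nf <- length(theta)
  good <- which(!degenerate)
  ref <- if (length(good) > 0L) k[good[1L], ] else k[1L, ]
  for (i in seq_len(nf)) {
    if (sum(k[i, ] * ref) < 0) {
      k[i, ] <- -k[i, ]
      theta[i] <- -theta[i]
    }
    if (!degenerate[i]) ref <- k[i, ]
  }
  # canonical global sign: the knee rotation axis points along +Z of the
  # thigh, so trials of the same motion share one sign convention (and the
  # independent-parameter reduction, which needs kz > 0, stays applicable)
  kz_ref <- if (length(good) > 0L) sum(k[good, 3L]) else sum(k[, 3L])
  if (kz_ref < 0) {
    k <- -k
    theta <- -theta
  }
  bad <- which(degenerate)
  if (length(bad) > 0L && length(good) > 0L) {
    for (j in 1:3) {
      k[bad, j] <- stats::approx(good, k[good, j], xout = bad, rule = 2)$y
    }
    for (i in bad) k[i, ] <- unitize(k[i, ])
  }
  list(theta = theta, k = k)
}

#' Enforce rotation-axis continuity along a gait cycle
#'
#' Re-applies the sign convention used by [gait_cycle()]: consecutive
#' non-degenerate axes satisfy `k(t) . k(t+1) > 0`, the rotation angle sign
#' is flipped together with the axis so the attitude vector `theta * k` is
#' unchanged, and degenerate frames take an interpolated axis.  Constructed
#' `jcs_cycle` objects already satisfy this, so the operation is idempotent.
#'
#' @param cycle a `jcs_cycle` object.
#' @return The cycle with continuous axes.
#' @export
enforce_axis_continuity <- function(cycle) {
  stopifnot(inherits(cycle, "jcs_cycle"))
  cont <- .axis_continuity(cycle$theta, cycle$k, cycle$degenerate)
  cycle$theta <- cont$theta
  cycle$k <- cont$k
  for (i in seq_along(cycle$theta)) {
    cycle$proj[i, ] <- project_attitude(
      list(theta = cycle$theta[i], k = cycle$k[i, ]),
      list(e1 = cycle$e1[i, ], e2 = cycle$e2[i, ], e3 = cycle$e3[i, ]))
  }
  cycle
}

#' @export
print.jcs_cycle <- function(x, ...) {
  cat("Knee gait cycle (", length(x$frame_pct), " frames, stance ",
      round(100 * x$stance_fraction, 1), "%)\n", sep = "")
  cat(sprintf("  session %s, trial %s\n", x$session_id, x$trial_id))
  cat(sprintf("  rotation angle theta: %.1f to %.1f deg (peak at %d%%)\n",
              min(x$theta), max(x$theta), x$frame_pct[which.max(abs(x$theta))]))
  cat(sprintf("  flexion (Cardan theta1): %.1f to %.1f deg\n",
              min(x$cardan[, 1]), max(x$cardan[, 1])))
  if (any(x$degenerate))
    cat("  degenerate (near-zero rotation) frames:",
        sum(x$degenerate), "\n")
  invisible(x)
}

#' Tabulate the per-frame angles of a gait cycle
#'
#' @param x a `jcs_cycle` object.
#' @param ... unused.
#' @return Data frame in the angles CSV schema: identifiers, frame
#'   percentage, attitude (`theta`, `kx`, `ky`, `kz`), Cardan angles and
#'   projected attitude-vector components, all angles in degrees.
#' @export
as.data.frame.jcs_cycle <- function(x, ...) {
  data.frame(session_id = x$session_id, trial_id = x$trial_id,
             frame_pct = x$frame_pct, theta = x$theta,
             kx = x$k[, 1L], ky = x$k[, 2L], kz = x$k[, 3L],
             cardan1 = x$cardan[, 1L], cardan2 = x$cardan[, 2L],
             cardan3 = x$cardan[, 3L],
             proj1 = x$proj[, 1L], proj2 = x$proj[, 2L],
             proj3 = x$proj[, 3L])
}

#' @export
plot.jcs_cycle <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  lab <- c("flexion-extension", "adduction-abduction", "int-ext rotation")
  for (j in 1:3) {
    graphics::matplot(x$frame_pct, cbind(x$cardan[, j], x$proj[, j]),
                      type = "l", lty = c(1, 2), col = c("black", "red"),
                      xlab = "% gait cycle", ylab = "angle (deg)",
                      main = lab[j], ...)
    graphics::abline(v = 100 * x$stance_fraction, lty = 3, col = "blue")
  }
  invisible(x)
}
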