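#' Across-trials mean gait cycle (model linearization point)
#'
#' Computes, frame by frame, the arithmetic mean of the rotation angle and
#' the mean directions of the rotation axis `k` and joint axes `e1`, `e3`
#' (normalized arithmetic mean vectors; the floating axis `e2` is rebuilt
#' from the mean `e1` and `e3`).  Frames flagged degenerate in a trial are
#' excluded from that trial's contribution to the axis means.  The result is
#' the per-frame mean pose at which the analytical uncertainty model is
#' linearized.
#'
#' @param trials list of `jcs_cycle` objects on the same 101-frame grid,
#'   or a `jcs_dataset`.
#' @return Object of class `jcs_mean_cycle` with the same per-frame fields
#'   as a `jcs_cycle` except `R` (the mean axes need not be consistent with
#'   a single rotation matrix): `theta`, `k`, `e1`, `e2`, `e3`, `cardan`
#'   (mean of the trials' Cardan angles), `proj` (recomputed from the mean
#'   pose), `degenerate`.
#' @export
mean_cycle <- function(trials) {
  if (inherits(trials, "jcs_dataset")) trials <- dataset_trials(trials)
  if (length(trials) == 0L) stop("no trials supplied", call. = FALSE)
  stopifnot(all(vapply(trials, inherits, TRUE, "jcs_cycle")))
  nf <- 101L
  nt <- length(trials)
  theta <- rowMeans(sapply(trials, `[[`, "theta"))
  cardan <- Reduce(`+`, lapply(trials, `[[`, "cardan")) / nt
  mean_dir <- function(field, use_degeneracy = FALSE) {
    out <- matrix(NA_real_, nf, 3L)
    for (i in seq_len(nf)) {
      rows <- t(sapply(trials, function(tr) tr[[field]][i, ]))
      if (use_degeneracy) {
        ok <- !vapply(trials, function(tr) tr$degenerate[i], TRUE)
        if (any(ok)) rows <- rows[ok, , drop = FALSE]
      }
      m <- colMeans(rows)
      if (vnorm(m) < 1e-6)
        stop("mean axis direction undefined at frame ", i - 1L, call. = FALSE)
      out[i, ] <- m / vnorm(m)
    }
    out
  }
  k <- mean_dir("k", use_degeneracy = TRUE)
  e1 <- mean_dir("e1")
  e3 <- mean_dir("e3")
  e2 <- proj <- matrix(NA_real_, nf, 3L)
  for (i in seq_len(nf)) {
    cx <- cross3(e3[i, ], e1[i, ])
    e2[i, ] <- cx / vnorm(cx)
    proj[i, ] <- project_attitude(
      list(theta = theta[i], k = k[i, ]),
      list(e1 = e1[i, ], e2 = e2[i, ], e3 = e3[i, ]))
  }
  colnames(k) <- c("kx", "ky", "kz")
  colnames(cardan) <- colnames(proj) <- c("theta1", "theta2", "theta3")
  structure(list(frame_pct = 0:100, theta = theta, k = k, e1 = e1, e2 = e2,
                 e3 = e3, cardan = cardan, proj = proj,
                 degenerate = abs(theta) < 1, n_trials = nt,
                 stance_fraction = trials[[1L]]$stance_fraction),
            class = "jcs_mean_cycle")
}

#' Angular deviation between two unit vectors
#'
#' @param k,k_ref unit vectors.
#' @return Angle `acos(k . k_ref)` in degrees, in `[0, 180]`.
#' @export
angular_deviation <- function(k, k_ref) {
  stopifnot_unit(k, "k", tol = 1e-6)
  stopifnot_unit(k_ref, "k_ref", tol = 1e-6)
  rad2deg(acos(min(1, max(-1, sum(k * k_ref)))))
}

.QUANTITIES <- c("Rotation angle", "Orientation of the rotation axis",
                 "Flexion-extension angle (Cardan)",
                 "Projected attitude vector onto e1",
                 "Adduction-abduction angle (Cardan)",
                 "Projected attitude vector onto e2",
                 "Internal-external rotation angle (Cardan)",
                 "Projected attitude vector onto e3")

# trials x frames matrix of a scalar quantity
.quantity_matrix <- function(trials, q) {
  switch(q,
         "Rotation angle" = t(sapply(trials, `[[`, "theta")),
         "Flexion-extension angle (Cardan)" =
           t(sapply(trials, function(x) x$cardan[, 1L])),
         "Adduction-abduction angle (Cardan)" =
           t(sapply(trials, function(x) x$cardan[, 2L])),
         "Internal-external rotation angle (Cardan)" =
           t(sapply(trials, function(x) x$cardan[, 3L])),
         "Projected attitude vector onto e1" =
           t(sapply(trials, function(x) x$proj[, 1L])),
         "Projected attitude vector onto e2" =
           t(sapply(trials, function(x) x$proj[, 2L])),
         "Projected attitude vector onto e3" =
           t(sapply(trials, function(x) x$proj[, 3L])),
         stop("unknown quantity"))
}

#' Inter- and intra-session variability table
#'
#' Root-mean-square deviation of each rotational quantity of the knee --
#' rotation angle, orientation of the rotation axis (angular deviation from
#' the mean direction), the three Cardan angles and the three projected
#' attitude-vector components -- pooled over frames and trials:
#' \itemize{
#'   \item intra-session RMSD: deviations from the per-session, per-frame
#'     mean, pooled over all sessions with at least two trials;
#'   \item inter-session RMSD: deviations from the grand per-frame mean over
#'     all trials.
#' }
#'
#' @param dataset a `jcs_dataset` object.
#' @return Object of class `jcs_vartab`: data frame with columns
#'   `quantity`, `inter_session_rmsd`, `intra_session_rmsd` (degrees).
#' @export
rmsd_table <- function(dataset) {
  stopifnot(inherits(dataset, "jcs_dataset"))
  trials <- dataset_trials(dataset)
  nt <- length(trials)
  if (nt < 2L) stop("need at least two trials", call. = FALSE)
  session <- unlist(lapply(seq_along(dataset$sessions), function(s)
    rep(s, length(dataset$sessions[[s]]))))
  reps <- table(session)
  if (!any(reps >= 2L))
    stop("intra-session RMSD needs a session with >= 2 trials", call. = FALSE)
  if (length(dataset$sessions) < 2L)
    warning("inter-session RMSD computed from a single session",
            call. = FALSE)

  rmsd_scalar <- function(Q) {
    grand <- colMeans(Q)
    inter <- sqrt(mean(sweep(Q, 2L, grand)^2))
    dev2 <- c()
    for (s in unique(session)) {
      idx <- which(session == s)
      if (length(idx) < 2L) next
      ms <- colMeans(Q[idx, , drop = FALSE])
      dev2 <- c(dev2, as.numeric(sweep(Q[idx, , drop = FALSE], 2L, ms)^2))
    }
    c(inter = inter, intra = sqrt(mean(dev2)))
  }

  # axis orientation: RMS of angular deviations from the respective mean
  # direction, excluding frames where a trial's axis is unidentifiable
  rmsd_axis <- function() {
    K <- lapply(trials, `[[`, "k")
    degen <- t(sapply(trials, `[[`, "degenerate"))
    mean_dir_of <- function(idx, f) {
      ok <- idx[!degen[idx, f]]
      if (length(ok) == 0L) return(NULL)
      m <- colMeans(do.call(rbind, lapply(K[ok], function(k) k[f, ])))
      if (vnorm(m) < 1e-6) return(NULL)
      m / vnorm(m)
    }
    inter2 <- intra2 <- c()
    for (f in 1:101) {
      gm <- mean_dir_of(seq_len(nt), f)
      if (!is.null(gm)) {
        for (i in seq_len(nt)) if (!degen[i, f])
          inter2 <- c(inter2, angular_deviation(K[[i]][f, ], gm)^2)
      }
      for (s in unique(session)) {
        idx <- which(session == s)
        if (length(idx) < 2L) next
        sm <- mean_dir_of(idx, f)
        if (is.null(sm)) next
        for (i in idx) if (!degen[i, f])
          intra2 <- c(intra2, angular_deviation(K[[i]][f, ], sm)^2)
      }
    }
    c(inter = sqrt(mean(inter2)), intra = sqrt(mean(intra2)))
  }

  out <- matrix(NA_real_, length(.QUANTITIES), 2L)
  for (qi in seq_along(.QUANTITIES)) {
    q <- .QUANTITIES[qi]
    out[qi, ] <- if (q == "Orientation of the rotation axis") rmsd_axis()
    else rmsd_scalar(.quantity_matrix(trials, q))
  }
  structure(data.frame(quantity = .QUANTITIES,
                       inter_session_rmsd = out[, 1L],
                       intra_session_rmsd = out[, 2L]),
            class = c("jcs_vartab", "data.frame"))
}

#' @rdname rmsd_table
#' @param dataset a `jcs_dataset` object.
#' @export
knee_variability <- function(dataset) rmsd_table(dataset)

#' @export
print.jcs_vartab <- function(x, ...) {
  cat("Knee rotational variability, RMSD in degrees:\n")
  y <- x
  y$inter_session_rmsd <- round(y$inter_session_rmsd, 2)
  y$intra_session_rmsd <- round(y$intra_session_rmsd, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Mean and population standard deviation of a set of RMSD values
#'
#' Aggregates a column of a variability table the way summary rows of
#' reproducibility tables are reported: arithmetic mean and population
#' (divisor `n`) standard deviation.
#'
#' @param values numeric vector of RMSD values (degrees).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
summarize_table <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("values must be a non-empty finite numeric vector", call. = FALSE)
  m <- mean(values)
  c(mean = m, sd = sqrt(mean((values - m)^2)))
}

#' Per-frame experimental dispersion curves
#'
#' Sample standard deviation across all trials (the experimental corridor),
#' frame by frame, for the rotation angle, the Cardan angles and the
#' projected attitude-vector components.
#'
#' @param dataset a `jcs_dataset` object (>= 2 trials).
#' @return List with `frame_pct`, `theta` (length 101), `cardan` and `proj`
#'   (101x3 matrices), all in degrees, and `n_trials`.
#' @export
experimental_sd_curves <- function(dataset) {
  stopifnot(inherits(dataset, "jcs_dataset"))
  trials <- dataset_trials(dataset)
  if (length(trials) < 2L) stop("need at least two trials", call. = FALSE)
  sd_mat <- function(get) apply(sapply(trials, get), 1L, stats::sd)
  cardan <- sapply(1:3, function(j) sd_mat(function(x) x$cardan[, j]))
  proj <- sapply(1:3, function(j) sd_mat(function(x) x$proj[, j]))
  colnames(cardan) <- colnames(proj) <- c("theta1", "theta2", "theta3")
  list(frame_pct = 0:100, theta = sd_mat(function(x) x$theta),
       cardan = cardan, proj = proj, n_trials = length(trials))
}

#' Qualitative agreement between analytic and experimental dispersion
#'
#' Compares an analytic standard-uncertainty curve against an experimental
#' standard-deviation curve per gait-cycle phase, using the ratio of phase
#' means `r = mean(analytic) / mean(experimental)` and the five-symbol
#' scheme: `--` highly underestimated (`r < 0.5`), `-` slightly
#' underestimated (`0.5 <= r < 0.8`), `0` good match (`0.8 <= r <= 1.25`),
#' `+` slightly overestimated (`1.25 < r <= 2`), `++` highly overestimated
#' (`r > 2`).  Phases where the experimental mean is (numerically) zero are
#' flagged indeterminate (`NA` label).
#'
#' @param analytic_u,experimental_sd aligned numeric curves on the 0..100%
#'   frame grid (degrees).
#' @param phases named list of `c(lo, hi)` frame-percentage bounds
#'   (inclusive); the default splits stance, early swing and late swing.
#' @return Data frame with `phase`, `ratio`, `label`.
#' @export
classify_agreement <- function(analytic_u, experimental_sd,
                               phases = list(stance = c(0, 61.6),
                                             swing_61.8_85 = c(61.8, 85),
                                             swing_85_100 = c(85.2, 100))) {
  stopifnot(length(analytic_u) == 101L, length(experimental_sd) == 101L)
  pct <- 0:100
  lab <- ratio <- rep(NA_real_, length(phases))
  labs <- character(length(phases))
  for (i in seq_along(phases)) {
    sel <- pct >= phases[[i]][1L] & pct <= phases[[i]][2L]
    me <- mean(experimental_sd[sel], na.rm = TRUE)
    ma <- mean(analytic_u[sel], na.rm = TRUE)
    if (!is.finite(me) || me < 1e-9) {
      labs[i] <- NA_character_
      next
    }
    r <- ma / me
    ratio[i] <- r
    labs[i] <- if (r < 0.5) "--" else if (r < 0.8) "-" else if (r <= 1.25) "0"
    else if (r <= 2) "+" else "++"
  }
  data.frame(phase = names(phases), ratio = ratio, label = labs)
}
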