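#' Configuration of the synthetic knee gait generator
#'
#' Defines a normal-gait knee flexion profile (a small stance bump and a
#' large swing peak) plus dispersion parameters that emulate a multi-session
#' gait reproducibility design: intrinsic variability of the joint motion
#' itself (rotation-angle dispersion `sd_theta`, rotation-axis cone
#' `cone_k`, drawn per trial) and extrinsic variability of the measurement
#' frames (per-session axis tilts `cone_e1_session`, `cone_e3_session`,
#' constant within a session, mimicking marker-placement error).
#'
#' @param stance_fraction fraction of the cycle in stance (default 0.616).
#' @param peak_stance_flexion stance-phase flexion bump peak, degrees.
#' @param peak_swing_flexion swing-phase flexion peak, degrees.
#' @param swing_peak_pct location of the swing peak, % of cycle.
#' @param varus_offset,rotation_offset constant adduction and internal
#'   rotation offsets, degrees.
#' @param sd_theta per-trial rotation-angle dispersion (degrees), applied as
#'   a smooth low-frequency offset curve.
#' @param cone_k per-trial rotation-axis tilt cone half-angle, degrees.
#' @param cone_e1_session,cone_e3_session per-session tilt cone half-angles
#'   (degrees) of the thigh frame (flexion axis `e1`) and shank frame
#'   (longitudinal axis `e3`).
#' @param n_sessions,n_trials design size (default 5 sessions x 8 trials).
#' @param seed integer seed for dataset generation.
#' @return Object of class `jcs_genconfig`.
#' @export
generator_config <- function(stance_fraction = 0.616,
                             peak_stance_flexion = 18,
                             peak_swing_flexion = 60,
                             swing_peak_pct = 72,
                             varus_offset = 2,
                             rotation_offset = 5,
                             sd_theta = 0,
                             cone_k = 0,
                             cone_e1_session = 0,
                             cone_e3_session = 0,
                             n_sessions = 5L,
                             n_trials = 8L,
                             seed = 1L) {
  cfg <- list(stance_fraction = stance_fraction,
              peak_stance_flexion = peak_stance_flexion,
              peak_swing_flexion = peak_swing_flexion,
              swing_peak_pct = swing_peak_pct,
              varus_offset = varus_offset,
              rotation_offset = rotation_offset,
              sd_theta = sd_theta, cone_k = cone_k,
              cone_e1_session = cone_e1_session,
              cone_e3_session = cone_e3_session,
              n_sessions = as.integer(n_sessions),
              n_trials = as.integer(n_trials), seed = as.integer(seed))
  if (!(cfg$stance_fraction > 0 && cfg$stance_fraction < 1))
    stop("stance_fraction must be in (0, 1)", call. = FALSE)
  disp <- c(cfg$sd_theta, cfg$cone_k, cfg$cone_e1_session, cfg$cone_e3_session)
  if (any(disp < 0)) stop("dispersions must be >= 0", call. = FALSE)
  if (cfg$n_sessions < 1L || cfg$n_trials < 1L)
    stop("need at least one session and one trial", call. = FALSE)
  if (!(cfg$swing_peak_pct > 100 * cfg$stance_fraction &&
        cfg$swing_peak_pct < 100))
    stop("swing_peak_pct must lie inside the swing phase", call. = FALSE)
  structure(cfg, class = "jcs_genconfig")
}

# two-bump knee flexion profile (degrees) on the 0..100% grid: a raised
# cosine over stance and an asymmetric raised cosine peaking at
# swing_peak_pct; zero (cycle-periodic) at 0 and 100%
.flexion_profile <- function(cfg, t = 0:100) {
  s <- 100 * cfg$stance_fraction
  p <- cfg$swing_peak_pct
  b1 <- ifelse(t <= s,
               cfg$peak_stance_flexion * 0.5 * (1 - cos(2 * pi * t / s)), 0)
  rise <- cfg$peak_swing_flexion * 0.5 * (1 - cos(pi * (t - s) / (p - s)))
  fall <- cfg$peak_swing_flexion * 0.5 * (1 + cos(pi * (t - p) / (100 - p)))
  b2 <- ifelse(t <= s, 0, ifelse(t <= p, rise, fall))
  b1 + b2
}

#' Deterministic template knee gait cycle
#'
#' Builds the noise-free gait cycle of the generator: per-frame ZXY Cardan
#' angles `(flexion(t), varus_offset, rotation_offset)` composed into
#' rotation matrices, with the two-bump flexion profile of
#' [generator_config()].
#'
#' @param cfg a `jcs_genconfig` object.
#' @return A `jcs_cycle` object.
#' @export
template_knee_cycle <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "jcs_genconfig"))
  flex <- .flexion_profile(cfg)
  R <- array(NA_real_, c(3L, 3L, 101L))
  for (i in 1:101)
    R[, , i] <- compose_cardan_zxy(flex[i], cfg$varus_offset,
                                   cfg$rotation_offset)
  gait_cycle(R, stance_fraction = cfg$stance_fraction)
}

#' Pure-hinge template cycle
#'
#' The template of [template_knee_cycle()] with the varus and rotation
#' offsets removed: every frame is a pure rotation about the thigh Z axis,
#' so projected and Cardan angles coincide exactly with `(flexion, 0, 0)`.
#' Frames where the flexion angle passes near zero are degenerate for the
#' rotation axis and flagged as such.
#'
#' @param cfg a `jcs_genconfig` object (offsets are overridden to zero).
#' @return A `jcs_cycle` object.
#' @export
hinge_template_cycle <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "jcs_genconfig"))
  cfg$varus_offset <- 0
  cfg$rotation_offset <- 0
  template_knee_cycle(cfg)
}

# small rotation from a rotation-vector with the given components (radians)
.tilt_rotation <- function(v) {
  a <- vnorm(v)
  if (a < 1e-15) return(diag(3))
  rotation_from_attitude(rad2deg(a), v / a)
}

#' Draw the per-session extrinsic axis perturbation
#'
#' Samples one fixed tilt `A` of the thigh measurement frame (misplacing
#' the flexion axis `e1`) and one fixed tilt `B` of the shank frame
#' (misplacing the longitudinal axis `e3`), with rotation-vector components
#' of standard deviation `tan(cone)` matching the cone uncertainty model.
#' The same perturbation is applied to every trial of a session, the way a
#' marker-placement error is constant within a session.  Note that a frame
#' tilt carries both the flexion-scaled cross-talk channel of the
#' analytical model and a constant angle-offset channel that the projection
#' model does not describe.
#'
#' @param cfg a `jcs_genconfig` object.
#' @param seed integer seed.
#' @return List with rotation matrices `A` (thigh) and `B` (shank).
#' @export
session_axes_perturbation <- function(cfg, seed) {
  with_local_seed(seed, {
    sA <- cone_to_component_uncertainty(cfg$cone_e1_session)
    sB <- cone_to_component_uncertainty(cfg$cone_e3_session)
    A <- if (sA > 0) .tilt_rotation(c(stats::rnorm(2L, 0, sA), 0)) else diag(3)
    # tilt the shank Y axis: rotate about axes transverse to Y (x and z)
    b <- stats::rnorm(2L, 0, sB)
    B <- if (sB > 0) .tilt_rotation(c(b[1L], 0, b[2L])) else diag(3)
    list(A = A, B = B)
  })
}

#' Generate one perturbed gait trial
#'
#' Applies intrinsic noise to a template cycle -- a smooth periodic
#' rotation-angle offset curve (constant plus first Fourier harmonic, with
#' per-frame standard deviation exactly `sd_theta`) and a fixed per-trial
#' tilt of the rotation axis (`cone_k`) -- then composes the extrinsic
#' per-session measurement-frame tilts: `R_meas = t(A) R_true B`, with `A`
#' the thigh-frame and `B` the shank-frame tilt.  With all dispersions zero
#' the template is returned unchanged.
#'
#' @param template a `jcs_cycle` (see [template_knee_cycle()]).
#' @param cfg a `jcs_genconfig` object.
#' @param session_perturbation list `A`, `B` from
#'   [session_axes_perturbation()] (default: no extrinsic perturbation).
#' @param seed integer seed for the intrinsic noise.
#' @param session_id,trial_id identifiers attached to the trial.
#' @return A `jcs_cycle` object.
#' @export
generate_trial <- function(template, cfg, session_perturbation = NULL,
                           seed = 1L, session_id = 1L, trial_id = 1L) {
  stopifnot(inherits(template, "jcs_cycle"), inherits(cfg, "jcs_genconfig"))
  intrinsic <- cfg$sd_theta > 0 || cfg$cone_k > 0
  A <- session_perturbation$A %||% diag(3)
  B <- session_perturbation$B %||% diag(3)
  extrinsic <- max(abs(A - diag(3)), abs(B - diag(3))) > 0
  if (!intrinsic && !extrinsic) {
    template$session_id <- session_id
    template$trial_id <- trial_id
    return(template)
  }
  R <- template$R
  if (intrinsic) {
    noise <- with_local_seed(seed, list(
      ab = stats::rnorm(3L, 0, cfg$sd_theta),
      rk = stats::rnorm(2L, 0, cone_to_component_uncertainty(cfg$cone_k))))
    t01 <- 2 * pi * (0:100) / 100
    offset <- sqrt(0.5) * (noise$ab[1L] + noise$ab[2L] * cos(t01) +
                             noise$ab[3L] * sin(t01))
    if (cfg$sd_theta == 0) offset[] <- 0
    Q <- if (cfg$cone_k > 0) .tilt_rotation(c(noise$rk, 0)) else diag(3)
    for (i in 1:101) {
      k <- as.numeric(Q %*% template$k[i, ])
      R[, , i] <- rotation_from_attitude(template$theta[i] + offset[i], k)
    }
  }
  if (extrinsic) {
    for (i in 1:101) R[, , i] <- crossprod(A, R[, , i]) %*% B
  }
  gait_cycle(R, stance_fraction = cfg$stance_fraction,
             session_id = session_id, trial_id = trial_id)
}

#' Generate a multi-session synthetic gait dataset
#'
#' Emulates a multi-session single-subject reproducibility design (default
#' five sessions of eight trials): one extrinsic axis perturbation per
#' session shared by its trials, and independent intrinsic noise per trial.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg a `jcs_genconfig` object.
#' @return Object of class `jcs_dataset`: list with `sessions` (list of
#'   lists of `jcs_cycle` trials), `template` and `config`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "jcs_genconfig"))
  template <- template_knee_cycle(cfg)
  seeds <- with_local_seed(cfg$seed, {
    n <- cfg$n_sessions * (1L + cfg$n_trials)
    matrix(sample.int(.Machine$integer.max - 1L, n),
           nrow = cfg$n_sessions)
  })
  sessions <- vector("list", cfg$n_sessions)
  for (s in seq_len(cfg$n_sessions)) {
    pert <- session_axes_perturbation(cfg, seeds[s, 1L])
    trials <- vector("list", cfg$n_trials)
    for (t in seq_len(cfg$n_trials)) {
      trials[[t]] <- generate_trial(template, cfg, pert,
                                    seed = seeds[s, 1L + t],
                                    session_id = s, trial_id = t)
    }
    sessions[[s]] <- trials
  }
  structure(list(sessions = sessions, template = template, config = cfg),
            class = "jcs_dataset")
}

#' Flatten a dataset into a list of trials
#'
#' @param dataset a `jcs_dataset` object.
#' @return List of `jcs_cycle` trials in session-major order.
#' @export
dataset_trials <- function(dataset) {
  stopifnot(inherits(dataset, "jcs_dataset"))
  unlist(dataset$sessions, recursive = FALSE)
}

#' @export
print.jcs_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic knee gait dataset: %d sessions x %d trials (seed %d)\n",
              cfg$n_sessions, cfg$n_trials, cfg$seed))
  cat(sprintf("  intrinsic: sd_theta = %g deg, cone_k = %g deg\n",
              cfg$sd_theta, cfg$cone_k))
  cat(sprintf("  extrinsic (per session): cone_e1 = %g deg, cone_e3 = %g deg\n",
              cfg$cone_e1_session, cfg$cone_e3_session))
  invisible(x)
}
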