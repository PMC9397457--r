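.fmt_num <- function(x) trimws(formatC(x, digits = 9, format = "g"))

.pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("jcsuncert")),
           error = function(e) "dev")
}

# md5 of the canonical JSON of a config list, via a temp file (base tools)
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

.provenance_line <- function(seed = NA, config = NULL) {
  sprintf("# jcsuncert %s seed=%s config_md5=%s", .pkg_version(),
          ifelse(is.na(seed), "NA", seed),
          if (is.null(config)) "NA" else config_hash(config))
}

.write_csv_prov <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_line(seed, config), con)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dataset of gait trials to a pose CSV
#'
#' Writes the `relative` dialect: one row per frame with the row-major
#' entries of the shank-to-thigh rotation matrix, headed by a provenance
#' comment line (tool version, seed, config hash).  Numbers are formatted
#' with 9 significant digits so written files round-trip deterministically.
#'
#' @param dataset a `jcs_dataset` object (or a single `jcs_cycle`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(dataset, path) {
  trials <- if (inherits(dataset, "jcs_cycle")) list(dataset)
  else dataset_trials(dataset)
  cfg <- if (inherits(dataset, "jcs_dataset")) unclass(dataset$config) else NULL
  rows <- lapply(trials, function(tr) {
    Rflat <- t(apply(tr$R, 3L, function(m) as.numeric(t(m))))
    colnames(Rflat) <- paste0("r", c(t(outer(1:3, 1:3, paste0))))
    data.frame(session_id = tr$session_id, trial_id = tr$trial_id,
               frame_pct = tr$frame_pct, Rflat)
  })
  .write_csv_prov(do.call(rbind, rows), path,
                  seed = cfg$seed %||% NA, config = cfg)
}

.DIALECT_REL <- c("session_id", "trial_id", "frame_pct",
                  paste0("r", c(t(outer(1:3, 1:3, paste0)))))
.DIALECT_SEG <- c("session_id", "trial_id", "frame_pct",
                  paste0("t", c(t(outer(1:3, 1:3, paste0)))),
                  paste0("s", c(t(outer(1:3, 1:3, paste0)))))

.row_to_matrix <- function(v) matrix(as.numeric(v), 3L, 3L, byrow = TRUE)

# linear interpolation of a trial onto the 0..100% grid, performed on the
# continuity-enforced rotation-vector (theta * k) representation
.resample_rotations <- function(Rarr, pct) {
  m <- dim(Rarr)[3L]
  rv <- matrix(NA_real_, m, 3L)
  prev <- NULL
  for (i in seq_len(m)) {
    att <- attitude_from_rotation(Rarr[, , i])
    v <- deg2rad(att$theta) * att$k
    if (!is.null(prev) && sum((v - prev)^2) > sum((-v - prev)^2)) v <- -v
    rv[i, ] <- v
    prev <- v
  }
  out <- array(NA_real_, c(3L, 3L, 101L))
  grid <- 0:100
  interp <- sapply(1:3, function(j)
    stats::approx(pct, rv[, j], xout = grid, rule = 2)$y)
  for (i in 1:101) {
    v <- interp[i, ]
    a <- sqrt(sum(v^2))
    out[, , i] <- if (a < 1e-12) diag(3)
    else rotation_from_attitude(rad2deg(a), v / a)
  }
  out
}

#' Read a pose CSV into a gait dataset
#'
#' Auto-detects the dialect from the header: `relative` (columns
#' `r11..r33`, row-major shank-to-thigh rotation) or `segments` (columns
#' `t11..t33`, `s11..s33`, world orientations of thigh and shank, combined
#' with [relative_rotation()]).  Every rotation is validated (orthonormal
#' within 1e-6, positive determinant) and offending data lines are reported
#' by number.  Trials not sampled on the 0..100% integer grid are resampled
#' by linear interpolation of the rotation-vector representation.
#'
#' @param path input file path (UTF-8 CSV, header required, `#` comments
#'   ignored).
#' @param stance_fraction stance fraction attached to the trials.
#' @return A `jcs_dataset` object.
#' @export
read_pose_csv <- function(path, stance_fraction = 0.616) {
  raw <- readLines(path)
  keep <- !startsWith(trimws(raw), "#") & nzchar(trimws(raw))
  file_line <- which(keep) # original line numbers of header + data rows
  d <- utils::read.csv(text = raw[keep], check.names = FALSE)
  nm <- names(d)
  dialect <- if (identical(nm, .DIALECT_REL)) "relative"
  else if (identical(nm, .DIALECT_SEG)) "segments"
  else stop("malformed header: expected the 'relative' or 'segments' pose ",
            "CSV dialect", call. = FALSE)
  if (any(d$frame_pct < 0 | d$frame_pct > 100))
    stop("frame_pct must lie in [0, 100]", call. = FALSE)
  line_no <- file_line[-1L] # data rows; file_line[1] is the header
  get_R <- function(i) {
    R <- if (dialect == "relative") .row_to_matrix(d[i, 4:12])
    else relative_rotation(.row_to_matrix(d[i, 4:12]),
                           .row_to_matrix(d[i, 13:21]))
    tryCatch(check_rotation(R, tol = 1e-6),
             error = function(e)
               stop(sprintf("invalid rotation at data line %d: %s",
                            line_no[i], conditionMessage(e)), call. = FALSE))
    R
  }
  key <- paste(d$session_id, d$trial_id, sep = "\r")
  sessions <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L)
      stop("trial with fewer than 2 frames: session ", d$session_id[idx[1L]],
           " trial ", d$trial_id[idx[1L]], call. = FALSE)
    idx <- idx[order(d$frame_pct[idx])]
    Rarr <- array(NA_real_, c(3L, 3L, length(idx)))
    for (j in seq_along(idx)) Rarr[, , j] <- get_R(idx[j])
    pct <- d$frame_pct[idx]
    if (!identical(as.numeric(pct), as.numeric(0:100)))
      Rarr <- .resample_rotations(Rarr, pct)
    sid <- d$session_id[idx[1L]]
    cyc <- gait_cycle(Rarr, stance_fraction = stance_fraction,
                      session_id = sid, trial_id = d$trial_id[idx[1L]])
    sid_chr <- as.character(sid)
    sessions[[sid_chr]] <- c(sessions[[sid_chr]], list(cyc))
  }
  structure(list(sessions = unname(sessions), template = NULL,
                 config = NULL), class = "jcs_dataset")
}

#' Write per-frame angles of a dataset to CSV
#'
#' Emits the angles schema: identifiers, frame percentage, attitude
#' (`theta`, `kx`, `ky`, `kz`), Cardan angles and projected components
#' (degrees).
#'
#' @param dataset a `jcs_dataset` or `jcs_cycle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(dataset, path) {
  trials <- if (inherits(dataset, "jcs_cycle")) list(dataset)
  else dataset_trials(dataset)
  .write_csv_prov(do.call(rbind, lapply(trials, as.data.frame)), path)
}

#' Write propagated uncertainty curves to CSV
#'
#' @param uprop a `jcs_uprop` object (see [propagate_sequence()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_uncertainty_csv <- function(uprop, path) {
  stopifnot(inherits(uprop, "jcs_uprop"))
  .write_csv_prov(as.data.frame(uprop), path, config = unclass(uprop$inputs))
}

#' Read or validate an uncertainty-inputs JSON configuration
#'
#' Recognized keys: `u_theta_deg`, `alpha_k_deg`, `alpha_e1_deg`,
#' `alpha_e3_deg` (degrees), `sweep` (vector of levels, degrees) and
#' `independent_sources` (logical).  Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return List with `inputs` (a `jcs_uinputs`), `sweep` (numeric or NULL)
#'   and `independent_sources` (logical).
#' @export
read_uncertainty_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  known <- c("u_theta_deg", "alpha_k_deg", "alpha_e1_deg", "alpha_e3_deg",
             "sweep", "independent_sources")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  list(inputs = uncertainty_inputs(cfg$u_theta_deg %||% 5,
                                   cfg$alpha_k_deg %||% 5,
                                   cfg$alpha_e1_deg %||% 5,
                                   cfg$alpha_e3_deg %||% 5),
       sweep = cfg$sweep,
       independent_sources = isTRUE(cfg$independent_sources))
}

#' Read a generator JSON configuration
#'
#' Accepts the argument names of [generator_config()] as JSON keys; unknown
#' keys are rejected.
#'
#' @param path JSON file path.
#' @return A `jcs_genconfig` object.
#' @export
read_generator_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  known <- names(formals(generator_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(generator_config, cfg)
}
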