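#' Published reference RMSD values for knee rotational parameters
#'
#' Inter- and intra-session RMSD values (degrees) of the eight knee
#' rotational quantities -- rotation angle, orientation of the rotation
#' axis, and the Cardan vs projected-attitude-vector versions of the three
#' joint angles -- reported for a healthy adult walking barefoot in a
#' five-session, single-examiner gait reproducibility experiment.  Shipped
#' as a plain-text fixture; used as the worked example for
#' [summarize_table()].
#'
#' @return Data frame with columns `quantity`, `inter_session_rmsd`,
#'   `intra_session_rmsd`.
#' @export
knee_rmsd_reference <- function() {
  utils::read.csv(system.file("extdata", "knee_rmsd_reference.csv",
                              package = "jcsuncert", mustWork = TRUE),
                  check.names = TRUE)
}
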