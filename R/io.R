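# CSV dialects for drive traces and trajectories: header row, UTF-8,
# '.' decimal separator.

#' Read a cytosolic drive trace from CSV
#'
#' Expects columns `time_s` and `ca_cyt_M`.
#'
#' @param path CSV file path.
#' @return A [drive_trace()].
#' @export
read_drive_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("time_s", "ca_cyt_M") %in% names(df))) {
    stop("drive CSV must have columns time_s, ca_cyt_M", call. = FALSE)
  }
  drive_trace(df$time_s, df$ca_cyt_M)
}

#' Write a drive trace to CSV
#'
#' @param drive A [drive_trace()].
#' @param path Output path; written atomically (temp file + rename).
#' @return `path`, invisibly.
#' @export
write_drive_csv <- function(drive, path) {
  stopifnot(inherits(drive, "drive_trace"))
  .write_atomic(path, function(p) {
    utils::write.csv(as.data.frame(drive)[c("time_s", "ca_cyt_M")], p,
                     row.names = FALSE, fileEncoding = "UTF-8")
  })
}

#' Write a simulated trajectory to CSV
#'
#' Columns `time_s`, `ca_total_M`, `ca_free_M`, `flux_ions_per_s`, `mode`.
#'
#' @param traj A `matrix_trajectory`.
#' @param path Output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "matrix_trajectory"))
  cols <- c("time_s", "ca_total_M", "ca_free_M", "flux_ions_per_s", "mode")
  .write_atomic(path, function(p) {
    utils::write.csv(as.data.frame(traj)[cols], p, row.names = FALSE,
                     fileEncoding = "UTF-8")
  })
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV file path.
#' @return A plain data frame (parameter attributes are not persisted).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "ca_total_M", "ca_free_M", "flux_ions_per_s", "mode")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

.write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
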