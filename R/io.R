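#' Read and write the IMU CSV dialect
#'
#' The canonical plain-text interchange format for a downloaded IMU
#' recording: comma-delimited, UTF-8, `.` decimal separator, header row with
#' columns `t, ax, ay, az, gx, gy, gz, qw, qx, qy, qz, marker`. `marker` is
#' 0/1; rows flagged 1 become the recording's event-marker indices.
#' Gyroscope columns are carried through but unused by the analysis.
#'
#' @param path file path.
#' @param g_units if `TRUE`, accelerations in the file are in G and are
#'   converted to m/s^2 (x 9.80665) on read.
#' @return an [imu_recording()].
#' @export
read_imu_csv <- function(path, g_units = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "ax", "ay", "az", "gx", "gy", "gz",
              "qw", "qx", "qy", "qz", "marker")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop(sprintf("%s: empty file", path))
  bad <- which(!stats::complete.cases(df[needed]))
  if (length(bad)) {
    stop(sprintf("%s: malformed row at line %d", path, bad[1L] + 1L))
  }
  if (is.unsorted(df$t, strictly = TRUE)) {
    i <- which(diff(df$t) <= 0)[1L]
    stop(sprintf("%s: non-monotone timestamps at line %d", path, i + 2L))
  }
  acc <- as.matrix(df[c("ax", "ay", "az")])
  if (g_units) acc <- acc * 9.80665
  fs <- 1 / stats::median(diff(df$t))
  imu_recording(timestamps = df$t, accel = acc,
                quat = as.matrix(df[c("qw", "qx", "qy", "qz")]),
                gyro = as.matrix(df[c("gx", "gy", "gz")]),
                fs = fs, markers = which(df$marker != 0))
}

#' @rdname read_imu_csv
#' @param rec an [imu_recording()] to write.
#' @param digits significant digits written (default 12, lossless for
#'   simulated doubles at the precision the pipeline needs).
#' @export
write_imu_csv <- function(rec, path, digits = 12L) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$timestamps)
  marker <- integer(n)
  marker[rec$markers[rec$markers <= n]] <- 1L
  df <- data.frame(t = rec$timestamps,
                   ax = rec$accel[, 1L], ay = rec$accel[, 2L], az = rec$accel[, 3L],
                   gx = rec$gyro[, 1L], gy = rec$gyro[, 2L], gz = rec$gyro[, 3L],
                   qw = rec$quat[, 1L], qx = rec$quat[, 2L],
                   qy = rec$quat[, 3L], qz = rec$quat[, 4L],
                   marker = marker)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the optical-marker CSV dialect
#'
#' Columns `t, x, y, z` (seconds and meters), same delimiter conventions as
#' the IMU dialect. Empty position cells are read as `NA` and handled by the
#' gap-interpolation policy downstream.
#'
#' @param path file path.
#' @return a [marker_trajectory()].
#' @export
read_mocap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop(sprintf("%s: empty file", path))
  if (anyNA(df$t)) stop(sprintf("%s: missing timestamps", path))
  if (is.unsorted(df$t, strictly = TRUE)) {
    i <- which(diff(df$t) <= 0)[1L]
    stop(sprintf("%s: non-monotone timestamps at line %d", path, i + 2L))
  }
  fs <- 1 / stats::median(diff(df$t))
  marker_trajectory(df$t, as.matrix(df[c("x", "y", "z")]), fs = fs)
}

#' @rdname read_mocap_csv
#' @param traj a [marker_trajectory()] to write.
#' @param digits significant digits written.
#' @export
write_mocap_csv <- function(traj, path, digits = 12L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  df <- data.frame(t = traj$timestamps, x = traj$position[, 1L],
                   y = traj$position[, 2L], z = traj$position[, 3L])
  df[] <- lapply(df, function(x) {
    out <- formatC(x, digits = digits, format = "g")
    out[is.na(x)] <- ""
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a cycle set as tidy CSV
#'
#' One row per cycle x bin x channel: columns `participant_id`,
#' `movement_type`, `cycle_index`, `source`, `bin`, `channel`, `value`.
#'
#' @param cycles a [cycle_set()].
#' @param path file path.
#' @export
write_cycle_set_csv <- function(cycles, path) {
  stopifnot(inherits(cycles, "cycle_set"))
  d <- dim(cycles$data)
  chans <- dimnames(cycles$data)[[3L]]
  grid <- expand.grid(cycle = seq_len(d[1L]), bin = seq_len(d[2L]),
                      channel = seq_len(d[3L]))
  df <- data.frame(cycles$labels[grid$cycle, , drop = FALSE],
                   bin = grid$bin, channel = chans[grid$channel],
                   value = cycles$data[as.matrix(grid)])
  df <- df[order(df$participant_id, df$movement_type, df$cycle_index,
                 df$channel, df$bin), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cycle_set_csv
#' @return `read_cycle_set_csv` returns a [cycle_set()].
#' @export
read_cycle_set_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "movement_type", "cycle_index", "source",
              "bin", "channel", "value")
  if (!all(needed %in% names(df))) stop(sprintf("%s: not a cycle-set CSV", path))
  key <- unique(df[c("participant_id", "movement_type", "cycle_index", "source")])
  rownames(key) <- NULL
  n_bins <- max(df$bin)
  chans <- c("ax", "ay", "az", "am")
  data <- array(NA_real_, c(nrow(key), n_bins, 4L))
  idx <- match(paste(df$participant_id, df$movement_type, df$cycle_index, df$source),
               paste(key$participant_id, key$movement_type, key$cycle_index, key$source))
  data[cbind(idx, df$bin, match(df$channel, chans))] <- df$value
  cycle_set(data, key)
}

#' Write a dataset of paired recordings to a directory
#'
#' Emits one `imu_<participant>_<movement>.csv` and
#' `mocap_<participant>_<movement>.csv` pair per recording.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "paired_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (rec in dataset) {
    stem <- sprintf("%s_%s", rec$participant_id, rec$movement_type)
    p1 <- file.path(dir, paste0("imu_", stem, ".csv"))
    p2 <- file.path(dir, paste0("mocap_", stem, ".csv"))
    write_imu_csv(rec$imu, p1)
    write_mocap_csv(rec$mocap, p2)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
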