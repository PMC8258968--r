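#' IMU recording container
#'
#' One recording of a wrist-worn IMU: per-sample device-frame acceleration,
#' the on-board sensor-fusion orientation quaternion (device-to-world,
#' scalar-first), and event-marker sample indices stored by the operator
#' during acquisition.
#'
#' @param timestamps numeric vector of sample times in seconds, uniformly
#'   spaced at `fs`.
#' @param accel n x 3 matrix of device-frame accelerometer output in m/s^2
#'   (specific force: includes the gravity reaction).
#' @param quat n x 4 matrix of unit quaternions `(w, x, y, z)`.
#' @param fs sampling rate in Hz.
#' @param markers integer sample indices (1-based) of stored event markers,
#'   strictly increasing.
#' @param gyro optional n x 3 gyroscope matrix (deg/s); carried through I/O
#'   but unused by the analysis.
#' @param participant_id,movement_type optional label strings.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(timestamps, accel, quat, fs, markers = integer(0),
                          gyro = NULL, participant_id = NA_character_,
                          movement_type = NA_character_) {
  accel <- unname(as.matrix(accel)); quat <- unname(as.matrix(quat))
  n <- length(timestamps)
  stopifnot(nrow(accel) == n, ncol(accel) == 3L,
            nrow(quat) == n, ncol(quat) == 4L, fs > 0)
  if (n > 1L) {
    dt <- diff(timestamps)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 0.25 / fs) {
      stop("timestamps are not uniform at the declared sampling rate")
    }
  }
  qn <- sqrt(rowSums(quat^2))
  if (any(abs(qn - 1) > 1e-3)) stop("quaternion norms deviate from 1 by more than 1e-3")
  quat <- quat / qn
  markers <- as.integer(markers)
  if (length(markers)) {
    if (is.unsorted(markers, strictly = TRUE)) stop("markers must be strictly increasing")
    # the final marker may sit one past the last sample: it closes the last
    # cycle under the half-open segmentation convention
    if (min(markers) < 1L || max(markers) > n + 1L) stop("markers out of range")
  }
  if (is.null(gyro)) gyro <- matrix(0, n, 3L)
  structure(list(timestamps = unname(timestamps), accel = accel, quat = quat,
                 gyro = unname(as.matrix(gyro)), fs = fs, markers = markers,
                 participant_id = participant_id, movement_type = movement_type),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz, %d markers [%s / %s]\n",
              length(x$timestamps), x$fs, length(x$markers),
              x$participant_id, x$movement_type))
  invisible(x)
}

#' Optical-marker trajectory container
#'
#' 3D position time series of one retroreflective marker, as triangulated by
#' an optical motion-capture system.
#'
#' @param timestamps numeric sample times in seconds.
#' @param position n x 3 matrix of positions in meters (world frame:
#'   x mediolateral, y anteroposterior, z vertical).
#' @param fs sampling rate in Hz.
#' @param participant_id,movement_type optional label strings.
#' @return object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(timestamps, position, fs,
                              participant_id = NA_character_,
                              movement_type = NA_character_) {
  position <- unname(as.matrix(position))
  n <- length(timestamps)
  stopifnot(nrow(position) == n, ncol(position) == 3L, fs > 0)
  if (n > 1L && any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, position = position, fs = fs,
                 participant_id = participant_id, movement_type = movement_type),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %d samples @ %g Hz [%s / %s]\n",
              length(x$timestamps), x$fs, x$participant_id, x$movement_type))
  invisible(x)
}

#' World-frame acceleration series
#'
#' Gravity-free motion acceleration in the world frame plus its magnitude
#' `Am = sqrt(Ax^2 + Ay^2 + Az^2)`, for either modality.
#'
#' @param ax,ay,az numeric series, m/s^2.
#' @param fs sampling rate in Hz.
#' @param source `"kid"` (IMU) or `"mocap"` (optical).
#' @param participant_id,movement_type optional label strings.
#' @return object of class `world_accel`.
#' @export
world_accel <- function(ax, ay, az, fs, source = c("kid", "mocap"),
                        participant_id = NA_character_,
                        movement_type = NA_character_) {
  source <- match.arg(source)
  stopifnot(length(ax) == length(ay), length(ay) == length(az), fs > 0)
  structure(list(ax = ax, ay = ay, az = az,
                 am = accel_magnitude(ax, ay, az),
                 fs = fs, source = source,
                 participant_id = participant_id, movement_type = movement_type),
            class = "world_accel")
}

#' @export
print.world_accel <- function(x, ...) {
  cat(sprintf("<world_accel:%s> %d samples @ %g Hz [%s / %s]\n",
              x$source, length(x$ax), x$fs, x$participant_id, x$movement_type))
  invisible(x)
}

#' Segmented, time-normalized movement cycles
#'
#' A set of movement cycles expressed on a normalized (percentage) timescale:
#' a `cycle x bin x channel` array (channels Ax, Ay, Az, Am) plus per-cycle
#' labels. Note the Am channel is binned from the raw-sample magnitude;
#' because averaging does not commute with the Euclidean norm, binned Am is
#' not the norm of the binned components.
#'
#' @param data numeric array `cycle x bin x 4` with dimnames channel =
#'   c("ax","ay","az","am").
#' @param labels data frame with columns `participant_id`, `movement_type`,
#'   `cycle_index`, `source`, one row per cycle.
#' @return object of class `cycle_set`.
#' @export
cycle_set <- function(data, labels) {
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3L] == 4L,
            is.data.frame(labels), nrow(labels) == dim(data)[1L],
            all(c("participant_id", "movement_type", "cycle_index", "source")
                %in% names(labels)))
  dimnames(data)[[3L]] <- c("ax", "ay", "az", "am")
  structure(list(data = data, labels = labels), class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cycle_set> %d cycles x %d bins x %d channels (%d participants, types: %s)\n",
              d[1L], d[2L], d[3L],
              length(unique(x$labels$participant_id)),
              paste(sort(unique(x$labels$movement_type)), collapse = ", ")))
  invisible(x)
}

#' Number of cycles in a cycle set
#' @param x a `cycle_set`.
#' @return integer cycle count.
#' @export
n_cycles <- function(x) {
  stopifnot(inherits(x, "cycle_set"))
  dim(x$data)[1L]
}

#' Combine cycle sets
#' @param ... `cycle_set` objects with identical bin counts.
#' @return a single `cycle_set`.
#' @export
bind_cycle_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "cycle_set")) {
    sets <- sets[[1L]]
  }
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, logical(1), "cycle_set")))
  nb <- unique(vapply(sets, function(s) dim(s$data)[2L], integer(1)))
  if (length(nb) != 1L) stop("cycle sets have differing bin counts")
  data <- do.call(abind3, lapply(sets, `[[`, "data"))
  labels <- do.call(rbind, lapply(sets, `[[`, "labels"))
  rownames(labels) <- NULL
  cycle_set(data, labels)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], integer(1))),
                           d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}
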