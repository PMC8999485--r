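#' Low-pass filter a neck-angle trace
#'
#' Applies the standard kinematic conditioning for inertial-sensor neck angle
#' signals: a 10th-order Butterworth low-pass with a 10 Hz cut-off, run
#' forward-backward (zero phase) so that movement onsets are not delayed.
#' Mirror-image edge padding keeps the start and end of the recording free of
#' filter transients.
#'
#' @param trace An [angle_trace()] with `fs > 2 * cutoff`.
#' @param cutoff Cut-off frequency, Hz.
#' @param order Design order of the one-pass Butterworth filter.
#' @return The filtered [angle_trace()].
#' @export
lowpass_angle <- function(trace, cutoff = 10, order = 10) {
  stopifnot(inherits(trace, "angle_trace"))
  if (trace$fs <= 2 * cutoff)
    stop("sampling rate must exceed twice the cut-off frequency", call. = FALSE)
  bf <- signal::butter(order, cutoff / (trace$fs / 2), type = "low")
  theta <- filtfilt_padded(bf, trace$theta, padlen = round(1.5 * trace$fs))
  angle_trace(theta, fs = trace$fs, axis = trace$axis)
}

# zero-phase filtering with even (mirror) edge padding; exact for signals at
# rest at the boundaries, as movement recordings are
filtfilt_padded <- function(filt, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0L) {
    pre <- x[(padlen + 1L):2L]
    post <- x[(n - 1L):(n - padlen)]
    y <- signal::filtfilt(filt, c(pre, x, post))
    y[(padlen + 1L):(padlen + n)]
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Angular velocity and acceleration by central differences
#'
#' Computes first and second derivatives of an angle trace on its uniform grid
#' using central differences (one-sided at the endpoints). The acceleration is
#' the central difference of the velocity.
#'
#' @param trace An [angle_trace()] with at least 3 samples.
#' @return A list with numeric vectors `velocity` (deg/s) and `acceleration`
#'   (deg/s^2), each the same length as the input.
#' @export
derive_velocity_acceleration <- function(trace) {
  stopifnot(inherits(trace, "angle_trace"))
  theta <- trace$theta
  if (length(theta) < 3L)
    stop("at least 3 samples are required for derivatives", call. = FALSE)
  v <- central_diff(theta, trace$fs)
  a <- central_diff(v, trace$fs)
  list(velocity = v, acceleration = a)
}

central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

#' Segment a cyclic recording into directional movements
#'
#' Splits the recording into alternating directional movements at angular
#' velocity zero crossings, then trims each movement to the region where the
#' angular speed exceeds a fraction (default 5%) of that movement's own peak
#' speed — the standard onset/offset definition for self-paced neck movements.
#' The per-movement reference makes the threshold robust to slow repetitions.
#'
#' @param trace A (filtered) [angle_trace()].
#' @param velocity Angular velocity aligned to `trace`, deg/s.
#' @param threshold Speed threshold as a fraction of the movement's peak speed.
#' @return A list of movement cycles, each a list with `onset_idx`,
#'   `offset_idx` (sample indices into the trace), `direction` (one of
#'   `flexion`, `extension`, `right_rotation`, `left_rotation`), and
#'   `peak_velocity_ref` (the deg/s value used for thresholding). A constant
#'   or sub-threshold recording yields an empty list.
#' @export
segment_cycles <- function(trace, velocity, threshold = 0.05) {
  stopifnot(inherits(trace, "angle_trace"), length(velocity) == length(trace$theta))
  n <- length(velocity)
  if (n < 3L || all(velocity == 0)) return(list())
  sgn <- sign(velocity)
  nz <- which(sgn != 0)
  if (length(nz) == 0L) return(list())
  # carry the nearest nonzero sign across exact zeros so runs are maximal
  sgn[seq_len(nz[1L])] <- sgn[nz[1L]]
  for (i in (nz[1L] + 1L):n) if (sgn[i] == 0) sgn[i] <- sgn[i - 1L]
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(runs$lengths)) {
    idx <- starts[k]:ends[k]
    speed <- abs(velocity[idx])
    peak <- max(speed)
    if (peak <= 0) next
    keep <- which(speed > threshold * peak)
    if (length(keep) == 0L) next
    onset <- idx[min(keep)]
    offset <- idx[max(keep)]
    if (offset - onset < 2L) next
    net <- trace$theta[offset] - trace$theta[onset]
    direction <- if (trace$axis == "flexion_extension") {
      if (net >= 0) "flexion" else "extension"
    } else {
      if (net >= 0) "right_rotation" else "left_rotation"
    }
    out[[length(out) + 1L]] <- list(onset_idx = onset, offset_idx = offset,
                                    direction = direction,
                                    peak_velocity_ref = peak)
  }
  out
}

#' Kinematic features of one movement cycle
#'
#' On the trimmed cycle: range of motion is the angular excursion
#' (`max - min`), mean and peak velocity are taken on the absolute angular
#' velocity, and the number of velocity peaks (the smoothness index) is the
#' count of angular-acceleration zero crossings. Zero-crossing counting uses a
#' hysteresis band of 1% of the cycle's peak acceleration magnitude to
#' suppress chatter from noise around zero.
#'
#' @param cycle One element of [segment_cycles()] output.
#' @param trace The [angle_trace()] the cycle indexes into.
#' @param velocity,acceleration Derivative series aligned to `trace`.
#' @return A list with `rom` (deg), `vmean`, `vpeak` (deg/s), `nvp` (count)
#'   and `direction`.
#' @export
cycle_features <- function(cycle, trace, velocity, acceleration) {
  idx <- cycle$onset_idx:cycle$offset_idx
  if (length(idx) <= 2L)
    stop("degenerate cycle: at least 3 samples required", call. = FALSE)
  theta <- trace$theta[idx]
  v <- velocity[idx]
  a <- acceleration[idx]
  list(
    rom = max(theta) - min(theta),
    vmean = mean(abs(v)),
    vpeak = max(abs(v)),
    nvp = count_sign_changes(a, band = 0.01 * max(abs(a))),
    direction = cycle$direction
  )
}

# sign changes of x outside a +/- band hysteresis region around zero
count_sign_changes <- function(x, band = 0) {
  s <- sign(x[abs(x) > band])
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

#' Aggregate per-cycle features into per-direction summaries
#'
#' Per-direction arithmetic means of range of motion, mean/peak velocity and
#' velocity-peak count, plus the combined ranges of motion
#' (flexion + extension; right + left rotation) on the scale used for
#' reporting total excursion. A direction with no cycles is flagged as
#' missing rather than silently reported as zero.
#'
#' @param features List of per-cycle feature lists from [cycle_features()].
#' @param n_expected Expected repetitions per direction (informational; a
#'   deviation is recorded in the `n_cycles` field, not an error).
#' @return An object of class `kinematic_features`: a list with one element
#'   per direction (each holding `rom`, `vmean`, `vpeak`, `nvp`, `n_cycles`),
#'   plus `rom_combined` where both directions of an axis are present, and a
#'   `missing_directions` character vector.
#' @export
aggregate_features <- function(features, n_expected = 10) {
  if (length(features) == 0L)
    stop("no cycles to aggregate", call. = FALSE)
  dirs <- vapply(features, `[[`, character(1), "direction")
  by_dir <- split(features, dirs)
  out <- lapply(by_dir, function(fl) {
    list(rom = mean(vapply(fl, `[[`, numeric(1), "rom")),
         vmean = mean(vapply(fl, `[[`, numeric(1), "vmean")),
         vpeak = mean(vapply(fl, `[[`, numeric(1), "vpeak")),
         nvp = mean(vapply(fl, `[[`, numeric(1), "nvp")),
         n_cycles = length(fl))
  })
  pairs <- list(flexion_extension = c("flexion", "extension"),
                rotation = c("right_rotation", "left_rotation"))
  rom_combined <- list()
  missing <- character()
  for (axis in names(pairs)) {
    pr <- pairs[[axis]]
    present <- pr %in% names(out)
    if (all(present)) {
      rom_combined[[axis]] <- out[[pr[1]]]$rom + out[[pr[2]]]$rom
    } else if (any(present)) {
      missing <- c(missing, pr[!present])
    }
  }
  structure(c(out, list(rom_combined = rom_combined,
                        missing_directions = missing)),
            class = "kinematic_features")
}

#' Joint position error from repositioning trials
#'
#' For each trial the error is the absolute difference between the mean angle
#' in the final rest window and the mean angle in the starting rest window;
#' the per-side result is the mean over the (typically three) trials.
#'
#' @param trials_right,trials_left Lists of [angle_trace()] repositioning
#'   trials (rotation to the right and left respectively).
#' @param rest_s Length of the start and end rest windows, seconds.
#' @return A list with `jpe_right` and `jpe_left` in degrees (`NA` for a side
#'   with no trials).
#' @export
compute_jpe <- function(trials_right, trials_left, rest_s = 0.75) {
  side <- function(trials) {
    if (length(trials) == 0L) return(NA_real_)
    mean(vapply(trials, trial_error, numeric(1), rest_s = rest_s))
  }
  list(jpe_right = side(trials_right), jpe_left = side(trials_left))
}

trial_error <- function(trace, rest_s) {
  stopifnot(inherits(trace, "angle_trace"))
  nw <- round(rest_s * trace$fs)
  n <- length(trace$theta)
  if (n < 2 * nw || nw < 1)
    stop("trial too short to contain start and final rest windows", call. = FALSE)
  abs(mean(trace$theta[(n - nw + 1L):n]) - mean(trace$theta[1:nw]))
}

#' Full kinematic feature extraction for one cyclic recording
#'
#' Convenience wrapper: low-pass filter, differentiate, segment into
#' movements, compute per-cycle features, and aggregate.
#'
#' @param trace A raw [angle_trace()].
#' @param threshold Onset/offset speed threshold (fraction of per-movement
#'   peak speed).
#' @param cutoff,order Low-pass filter settings; see [lowpass_angle()].
#' @return A `kinematic_features` object (see [aggregate_features()]).
#' @export
extract_kinematics <- function(trace, threshold = 0.05, cutoff = 10, order = 10) {
  filt <- lowpass_angle(trace, cutoff = cutoff, order = order)
  der <- derive_velocity_acceleration(filt)
  cycles <- segment_cycles(filt, der$velocity, threshold = threshold)
  if (length(cycles) == 0L)
    stop("no movements detected in trace", call. = FALSE)
  feats <- lapply(cycles, cycle_features, trace = filt,
                  velocity = der$velocity, acceleration = der$acceleration)
  aggregate_features(feats)
}
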