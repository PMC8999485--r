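#' Angle trace container
#'
#' A uniformly sampled head-angle signal for one movement task, as produced by
#' a forehead-mounted inertial sensor after orientation estimation. Angles are
#' in degrees with the convention that flexion and right rotation are positive
#' and the calibrated natural head position is zero.
#'
#' @param theta Numeric vector of angles in degrees.
#' @param fs Sampling rate in samples/s (inertial sensors here record at 100).
#' @param axis Movement axis, `"flexion_extension"` or `"rotation"`.
#' @return An object of class `angle_trace` with fields `t` (seconds), `theta`
#'   (degrees), `fs` and `axis`.
#' @export
angle_trace <- function(theta, fs = 100, axis = c("flexion_extension", "rotation")) {
  axis <- match.arg(axis)
  theta <- as.numeric(theta)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (anyNA(theta))
    stop("angle trace must not contain missing samples", call. = FALSE)
  structure(
    list(t = (seq_along(theta) - 1L) / fs, theta = theta, fs = fs, axis = axis),
    class = "angle_trace"
  )
}

#' @export
print.angle_trace <- function(x, ...) {
  cat(sprintf("<angle_trace> %s: %d samples @ %g Hz (%.2f s), range %.1f..%.1f deg\n",
              x$axis, length(x$theta), x$fs, length(x$theta) / x$fs,
              min(x$theta), max(x$theta)))
  invisible(x)
}

#' Surface EMG trace container
#'
#' Multichannel surface EMG in microvolts. The canonical montage is bilateral
#' sternocleidomastoid (`scm_left`, `scm_right`) and splenius capitis
#' (`sc_left`, `sc_right`).
#'
#' @param channels Named list or data frame of numeric channel vectors (uV),
#'   all of equal length.
#' @param fs Sampling rate in samples/s (2000 for the EMG system emulated here).
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(channels, fs = 2000) {
  channels <- lapply(channels, as.numeric)
  if (length(channels) < 1L) stop("at least one EMG channel required", call. = FALSE)
  n <- lengths(channels)
  if (length(unique(n)) != 1L) stop("EMG channels must have equal length", call. = FALSE)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("EMG channels must be named", call. = FALSE)
  structure(
    list(t = (seq_len(n[[1L]]) - 1L) / fs, channels = channels, fs = fs),
    class = "emg_trace"
  )
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %d channel(s) [%s]: %d samples @ %g Hz\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              length(x$t), x$fs))
  invisible(x)
}

#' Force trace container
#'
#' A dynamometer force recording. The hand-held craniocervical dynamometer
#' reports Newtons; the fixed-frame cervical unit reports kilograms.
#'
#' @param force Numeric force vector.
#' @param fs Sampling rate in samples/s.
#' @param device `"nod"` (craniocervical flexion, N) or `"mcu"`
#'   (neck flexion/extension, kg).
#' @return An object of class `force_trace` with a `unit` field implied by the
#'   device.
#' @export
force_trace <- function(force, fs = 100, device = c("nod", "mcu")) {
  device <- match.arg(device)
  force <- as.numeric(force)
  if (any(!is.finite(force))) stop("force values must be finite", call. = FALSE)
  structure(
    list(t = (seq_along(force) - 1L) / fs, force = force, fs = fs,
         device = device, unit = if (device == "nod") "N" else "kg"),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %s (%s): %d samples @ %g Hz, peak %.1f %s\n",
              x$device, x$unit, length(x$force), x$fs, max(x$force), x$unit))
  invisible(x)
}
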