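#' Band-pass filter a surface EMG trace
#'
#' Standard surface-EMG conditioning: a 4th-order Butterworth band-pass with a
#' 20-400 Hz pass band, applied forward-backward (zero phase). Removes the DC
#' offset and movement artefact below 20 Hz and high-frequency noise above
#' 400 Hz.
#'
#' @param trace An [emg_trace()]; the sampling rate must exceed 800 samples/s
#'   so the upper band edge is below Nyquist.
#' @param band Two-element pass band in Hz.
#' @param order Design order of the one-pass filter.
#' @return The filtered [emg_trace()].
#' @export
bandpass_emg <- function(trace, band = c(20, 400), order = 4) {
  stopifnot(inherits(trace, "emg_trace"))
  if (trace$fs <= 2 * band[2])
    stop("sampling rate must exceed twice the upper band edge", call. = FALSE)
  bf <- signal::butter(order, band / (trace$fs / 2), type = "pass")
  ch <- lapply(trace$channels, function(x)
    filtfilt_padded(bf, x - mean(x), padlen = round(0.5 * trace$fs)))
  emg_trace(ch, fs = trace$fs)
}

#' Maximal sliding-window RMS amplitude
#'
#' The EMG amplitude estimate: the maximum, over every sample-aligned
#' placement of a sliding window (default 1 s), of the root-mean-square of the
#' signal within the window. The window advances one sample at a time.
#'
#' @param x Numeric signal vector (uV).
#' @param fs Sampling rate, samples/s.
#' @param window_s Window length in seconds; the signal must be at least this
#'   long.
#' @return The maximal windowed RMS, in the signal's units.
#' @export
max_sliding_rms <- function(x, fs, window_s = 1.0) {
  w <- round(window_s * fs)
  n <- length(x)
  if (n < w) stop("signal shorter than the RMS window", call. = FALSE)
  # running sum of squares via cumulative sums: O(n) over all placements
  cs <- cumsum(c(0, x^2))
  ms <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  sqrt(max(ms))
}

#' Normalised sternocleidomastoid activation across submaximal levels
#'
#' For each submaximal craniocervical flexion level, computes the maximal
#' sliding-window RMS of the left and right sternocleidomastoid channels,
#' normalises each side to its own amplitude during the maximal contraction
#' (channel-wise normalisation), and reports the bilateral mean as a
#' percentage. Values can exceed 100: superficial flexors may be more active
#' during a submaximal task than during the maximal contraction itself.
#'
#' @param submax Named list of [emg_trace()]s, one per contraction level
#'   (names are retained as the levels).
#' @param mvc The maximal-contraction [emg_trace()].
#' @param window_s RMS window length, seconds.
#' @param channels Names of the two channels entering the normalisation.
#' @return A data frame with columns `level` and `normalized_amplitude` (%).
#' @export
normalize_ccf_activation <- function(submax, mvc, window_s = 1.0,
                                     channels = c("scm_left", "scm_right")) {
  stopifnot(inherits(mvc, "emg_trace"))
  mvc_rms <- vapply(channels, function(ch)
    max_sliding_rms(mvc$channels[[ch]], mvc$fs, window_s), numeric(1))
  if (any(mvc_rms <= 0))
    stop("maximal-contraction RMS must be positive on every channel", call. = FALSE)
  res <- lapply(names(submax), function(lv) {
    tr <- submax[[lv]]
    norm <- vapply(channels, function(ch)
      max_sliding_rms(tr$channels[[ch]], tr$fs, window_s) / mvc_rms[[ch]] * 100,
      numeric(1))
    data.frame(level = lv, normalized_amplitude = mean(norm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Peak force across maximal-contraction trials
#'
#' The strength estimate: the maximum over trials of each trial's smoothed
#' peak. Smoothing is a 100 ms moving average applied before taking the
#' maximum, so a single-sample spike cannot inflate the estimate.
#'
#' @param trials List of [force_trace()] trials (at least one).
#' @param smooth_s Moving-average length, seconds.
#' @return Peak force in the trials' unit.
#' @export
extract_mvc <- function(trials, smooth_s = 0.1) {
  if (length(trials) < 1L) stop("at least one force trial required", call. = FALSE)
  peaks <- vapply(trials, function(tr) {
    stopifnot(inherits(tr, "force_trace"))
    w <- max(round(smooth_s * tr$fs), 1L)
    sm <- stats::filter(tr$force, rep(1 / w, w), sides = 2)
    max(sm, na.rm = TRUE)
  }, numeric(1))
  if (all(peaks <= 0)) stop("all force trials are zero", call. = FALSE)
  max(peaks)
}

#' Submaximal target forces from a maximal contraction
#'
#' @param mvc Maximal force (> 0).
#' @param fractions Contraction levels as proportions of maximal force.
#' @return Named numeric vector of target forces.
#' @export
submax_targets <- function(mvc, fractions = c(0.2, 0.4, 0.6, 0.8)) {
  if (!is.numeric(mvc) || length(mvc) != 1L || mvc <= 0)
    stop("`mvc` must be a single positive force", call. = FALSE)
  stats::setNames(mvc * fractions, paste0(fractions * 100, "%"))
}

#' Neuromuscular features for one participant's recordings
#'
#' Extracts craniocervical strength, normalised sternocleidomastoid activation
#' at each submaximal level (band-pass filtered, maximal 1 s sliding RMS,
#' channel-wise normalisation, bilateral mean), the pooled activation pairs
#' (mean of the 20/40% levels and of the 60/80% levels), and neck
#' flexion/extension strength.
#'
#' @param rec One participant's recordings as produced by [simulate_cohort()]
#'   with `recordings = TRUE` (elements `ccf` and `mcu`).
#' @param filter_emg Band-pass filter the EMG before amplitude estimation.
#' @return A one-row data frame with `ccf_mvc`, `act_20`, `act_40`, `act_60`,
#'   `act_80`, `ccf_act_20_40`, `ccf_act_60_80`, `mvc_flexion`,
#'   `mvc_extension`.
#' @export
extract_neuromuscular <- function(rec, filter_emg = TRUE) {
  cond <- function(tr) if (filter_emg) bandpass_emg(tr) else tr
  mvc <- cond(rec$ccf$mvc)
  submax <- lapply(rec$ccf$submax, cond)
  act <- normalize_ccf_activation(submax, mvc)
  a <- stats::setNames(act$normalized_amplitude, act$level)
  data.frame(
    ccf_mvc = extract_mvc(list(rec$ccf$mvc_force)),
    act_20 = a[["pct20"]], act_40 = a[["pct40"]],
    act_60 = a[["pct60"]], act_80 = a[["pct80"]],
    ccf_act_20_40 = mean(c(a[["pct20"]], a[["pct40"]])),
    ccf_act_60_80 = mean(c(a[["pct60"]], a[["pct80"]])),
    mvc_flexion = extract_mvc(rec$mcu$flexion),
    mvc_extension = extract_mvc(rec$mcu$extension)
  )
}
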