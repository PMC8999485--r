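# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by naive enumeration so they share no code with the
# implementation they check.

# maximal windowed RMS by explicit loop over every sample-aligned placement
brute_max_rms <- function(x, fs, window_s = 1.0) {
  w <- round(window_s * fs)
  best <- -Inf
  for (i in 1:(length(x) - w + 1)) {
    best <- max(best, sqrt(mean(x[i:(i + w - 1)]^2)))
  }
  best
}

# movement segmentation by exhaustive scan: walk the velocity sample by
# sample, split whenever the sign flips, then trim each run by scanning every
# sample against the 5% threshold from both ends
brute_segment <- function(velocity, threshold = 0.05) {
  n <- length(velocity)
  segs <- list()
  start <- 1
  cur_sign <- 0
  for (i in 1:n) {
    s <- sign(velocity[i])
    if (s != 0 && cur_sign == 0) cur_sign <- s
    if (s != 0 && s != cur_sign) {
      segs[[length(segs) + 1]] <- c(start, i - 1)
      start <- i
      cur_sign <- s
    }
  }
  segs[[length(segs) + 1]] <- c(start, n)
  out <- list()
  for (seg in segs) {
    idx <- seg[1]:seg[2]
    peak <- max(abs(velocity[idx]))
    if (peak <= 0) next
    on <- NA
    off <- NA
    for (i in idx) if (abs(velocity[i]) > threshold * peak) { on <- i; break }
    for (i in rev(idx)) if (abs(velocity[i]) > threshold * peak) { off <- i; break }
    if (is.na(on) || off - on < 2) next
    out[[length(out) + 1]] <- c(onset = on, offset = off)
  }
  out
}

# zero crossings of an analytic function on a dense grid
analytic_zero_crossings <- function(f, lower, upper, n_grid = 200000) {
  t <- seq(lower, upper, length.out = n_grid)
  y <- f(t)
  sum(diff(sign(y[y != 0])) != 0)
}

# closed-form magnitude of a bilinear-transformed Butterworth low-pass at
# frequency f (single pass)
butter_lowpass_gain <- function(f, cutoff, fs, order) {
  r <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  1 / sqrt(1 + r^(2 * order))
}

# closed-form magnitude of a bilinear-transformed Butterworth band-pass
butter_bandpass_gain <- function(f, band, fs, order) {
  W1 <- tan(pi * band[1] / fs)
  W2 <- tan(pi * band[2] / fs)
  W <- tan(pi * f / fs)
  1 / sqrt(1 + ((W^2 - W1 * W2) / (W * (W2 - W1)))^(2 * order))
}

# peak-to-peak amplitude of a settled mid-portion of a sinusoidal response
settled_amplitude <- function(y, drop_frac = 0.3) {
  n <- length(y)
  idx <- round(n * drop_frac):round(n * (1 - drop_frac))
  (max(y[idx]) - min(y[idx])) / 2
}
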