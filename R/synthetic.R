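#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles the generating parameters of the synthetic study: the linear models
#' behind the two longitudinal outcomes, residual noise, monthly dropout, and
#' the per-group location/spread of every baseline feature. Defaults are the
#' package's reference operating point: a three-group cohort (healthy controls,
#' recurrent neck pain in remission, chronic neck pain) whose feature
#' distributions and outcome models resemble a small whiplash follow-up study.
#'
#' The 6-month disability outcome (NDI, 0-50) is generated as
#' `beta0_ndi + beta_episodes * episodes + beta_mvcflex * mvc_flexion + e`,
#' with `e ~ N(0, sigma_ndi)`; monthly days-with-pain as
#' `beta0_days + gamma_episodes * episodes + e`, `e ~ N(0, sigma_days)`.
#'
#' @param beta0_ndi Intercept of the NDI-at-6-months model (NDI units).
#' @param beta_episodes Effect of the previous number of pain episodes on NDI
#'   (NDI units per episode).
#' @param beta_mvcflex Effect of neck flexion strength on NDI (NDI units per kg).
#' @param sigma_ndi Residual SD of the NDI model (NDI units).
#' @param beta0_days,gamma_episodes,sigma_days Analogous parameters of the
#'   days-with-pain model (days, days per episode, days). `sigma_days` is the
#'   between-participant residual SD of the mean-days outcome.
#' @param sigma_days_month Within-participant month-to-month SD of the day
#'   counts around the participant's level (days).
#' @param dropout_prob Per-month probability that a responding participant
#'   stops responding; missingness is monotone (once missing, missing
#'   thereafter).
#' @param group_shifts Data frame of per-group feature means, SDs and truncation
#'   bounds; see [default_feature_params()].
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta0_ndi = 10.23,
                            beta_episodes = 0.54,
                            beta_mvcflex = -0.32,
                            sigma_ndi = 3.5,
                            beta0_days = 2.14,
                            gamma_episodes = 0.40,
                            sigma_days = 2.6,
                            sigma_days_month = 2.7,
                            dropout_prob = 0.026,
                            group_shifts = default_feature_params()) {
  if (sigma_ndi < 0 || sigma_days < 0)
    stop("residual SDs must be non-negative", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("`dropout_prob` must be in [0, 1)", call. = FALSE)
  structure(
    list(beta0_ndi = beta0_ndi, beta_episodes = beta_episodes,
         beta_mvcflex = beta_mvcflex, sigma_ndi = sigma_ndi,
         beta0_days = beta0_days, gamma_episodes = gamma_episodes,
         sigma_days = sigma_days, sigma_days_month = sigma_days_month,
         dropout_prob = dropout_prob,
         group_shifts = group_shifts),
    class = "synthetic_truth"
  )
}

#' Per-group baseline feature parameters of the synthetic cohort
#'
#' One row per baseline feature with the generating mean for each group
#' (healthy, recurrent neck pain, chronic neck pain), a common SD, and
#' truncation bounds applied after noise. Locations mirror the descriptive
#' statistics typical of small cervical whiplash cohorts: reduced range of
#' motion, slower and less smooth movement, higher superficial flexor
#' activation and lower strength in the symptomatic groups.
#'
#' @return A data frame with columns `feature`, `healthy`, `rnp`, `cnp`, `sd`,
#'   `lower`, `upper`.
#' @export
default_feature_params <- function() {
  p <- rbind(
    c("ndi",            0.7,  5.5, 17.5,  3.0,  0,  50),
    c("tsk",           29.1, 35.2, 40.5,  5.5, 11,  44),
    c("eq_vas",        85.5, 78.5, 64.1, 13.0,  0, 100),
    c("eq5d",          0.98, 0.92, 0.68, 0.10,  0,   1),
    c("rom_flexext",   52.6, 49.5, 42.9,  8.0, 15, 110),
    c("rom_rot",       71.5, 67.1, 62.1,  8.0, 20, 140),
    c("nvp_flexext",    8.9, 17.5, 17.0,  6.0,  1,  60),
    c("jpe",            4.0,  4.6,  5.4,  2.4,  0,  25),
    c("ccf_act_20_40", 27.0, 49.0, 61.4, 22.0,  2, 250),
    c("ccf_act_60_80", 58.9, 68.9,110.2, 28.0,  5, 300),
    c("ccf_mvc",       52.1, 44.0, 47.1, 20.0,  8, 150),
    c("mvc_flexion",   20.2, 14.6, 15.3,  6.0,  3,  45),
    c("mvc_extension", 29.6, 15.3, 21.6,  8.0,  3,  80),
    c("vmean_flexion", 72.8, 55.0, 42.9, 15.0, 10, 150),
    c("vmean_extension",66.5, 55.4, 46.7, 15.0, 10, 150),
    c("vmean_rotation",131.8,100.8, 81.0, 28.0, 20, 250),
    c("nvp_rotation",   4.4,  8.8, 10.9,  4.0,  1,  60),
    c("borg_flexion",  12.0, 15.0, 14.7,  2.5,  6,  20),
    c("borg_extension", 8.9,  9.9, 10.4,  2.5,  6,  20)
  )
  out <- data.frame(feature = p[, 1], stringsAsFactors = FALSE)
  for (j in 2:7) out[[c("f", "healthy", "rnp", "cnp", "sd", "lower", "upper")[j]]] <-
    as.numeric(p[, j])
  out
}

#' The 15 candidate predictors of the prognostic models, in canonical order
#' @export
table_predictors <- c(
  "ndi", "tsk", "eq_vas", "eq5d", "episodes", "episode_vas",
  "rom_flexext", "rom_rot", "nvp_flexext", "jpe",
  "ccf_act_20_40", "ccf_act_60_80", "ccf_mvc", "mvc_flexion", "mvc_extension"
)

#' Simulate a cyclic neck-angle recording
#'
#' Generates a repetitive flexion/extension or rotation recording as a cosine
#' carrier (each half-cycle is a raised cosine, so the noiseless movement has a
#' single velocity peak), with optional sinusoidal ripple to inject movement
#' irregularity and additive Gaussian measurement noise.
#'
#' @param rom Peak-to-peak movement amplitude in degrees (> 0).
#' @param n_cycles Number of full movement cycles (>= 1).
#' @param cycle_period Duration of one full cycle in seconds (> 0).
#' @param ripple_amp,ripple_freq Amplitude (degrees) and frequency (Hz) of the
#'   irregularity ripple; `ripple_amp = 0` gives a smooth movement.
#' @param noise_sd SD of additive Gaussian sample noise in degrees.
#' @param fs Sampling rate, samples/s.
#' @param axis Movement axis label for the trace.
#' @param seed Optional integer seed; the output is a pure function of the
#'   arguments and the seed.
#' @return An [angle_trace()].
#' @export
simulate_angle_trace <- function(rom, n_cycles = 10, cycle_period = 3,
                                 ripple_amp = 0, ripple_freq = 3,
                                 noise_sd = 0, fs = 100,
                                 axis = "flexion_extension", seed = NULL) {
  if (rom <= 0) stop("`rom` must be positive", call. = FALSE)
  if (cycle_period <= 0) stop("`cycle_period` must be positive", call. = FALSE)
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  t <- seq(0, n_cycles * cycle_period, by = 1 / fs)
  theta <- -(rom / 2) * cos(2 * pi * t / cycle_period)
  if (ripple_amp > 0)
    theta <- theta + ripple_amp * sin(2 * pi * ripple_freq * t)
  if (noise_sd > 0)
    theta <- theta + with_seed_opt(seed, stats::rnorm(length(t), 0, noise_sd))
  angle_trace(theta, fs = fs, axis = axis)
}

#' Simulate one head-repositioning (joint position error) trial
#'
#' The head starts at the calibrated zero, rotates to a target, holds, and
#' returns to rest at `true_error` degrees from the start, emulating an
#' eyes-closed repositioning trial. Ramps are raised cosines.
#'
#' @param true_error Signed final offset from the start position, degrees.
#' @param target Excursion amplitude in degrees (positive = right rotation).
#' @param noise_sd SD of additive Gaussian sample noise, degrees.
#' @param fs Sampling rate, samples/s.
#' @param seed Optional integer seed.
#' @return An [angle_trace()] with `axis = "rotation"`.
#' @export
simulate_jpe_trial <- function(true_error, target = 60, noise_sd = 0,
                               fs = 100, seed = NULL) {
  ramp <- function(from, to, dur) {
    u <- seq(0, 1, by = 1 / (fs * dur))
    from + (to - from) * (1 - cos(pi * u)) / 2
  }
  hold <- function(value, dur) rep(value, round(fs * dur))
  theta <- c(hold(0, 1), ramp(0, target, 1.5), hold(target, 1),
             ramp(target, true_error, 1.5), hold(true_error, 1.5))
  if (noise_sd > 0)
    theta <- theta + with_seed_opt(seed, stats::rnorm(length(theta), 0, noise_sd))
  angle_trace(theta, fs = fs, axis = "rotation")
}

#' Simulate a multichannel surface EMG recording
#'
#' Band-limited (20-400 Hz) Gaussian noise whose whole-trace RMS on each
#' sternocleidomastoid channel equals `level_fraction * mvc_rms` exactly;
#' splenius capitis channels are generated at a fixed lower gain, and a small
#' fraction of the contralateral signal is mixed in to emulate crosstalk.
#' Because scaling is exact, submaximal recordings generated from the same seed
#' as a maximal recording have an RMS ratio exactly equal to the ratio of their
#' `level_fraction`s.
#'
#' @param level_fraction Contraction level as a proportion of maximal RMS
#'   (> 0; may exceed 1, as superficial flexor activation can exceed its own
#'   maximal-contraction amplitude).
#' @param mvc_rms RMS amplitude at maximal contraction, uV (> 0).
#' @param crosstalk_gain Proportion of the contralateral channel mixed in.
#' @param duration Recording length in seconds.
#' @param fs Sampling rate, samples/s.
#' @param sc_gain Splenius capitis gain relative to the SCM target RMS.
#' @param seed Optional integer seed.
#' @return An [emg_trace()] with channels `scm_left`, `scm_right`, `sc_left`,
#'   `sc_right`.
#' @export
simulate_emg <- function(level_fraction, mvc_rms = 150, crosstalk_gain = 0.1,
                         duration = 5, fs = 2000, sc_gain = 0.3, seed = NULL) {
  if (level_fraction <= 0) stop("`level_fraction` must be positive", call. = FALSE)
  if (mvc_rms <= 0) stop("`mvc_rms` must be positive", call. = FALSE)
  n <- round(duration * fs)
  bp <- signal::butter(4, c(20, 400) / (fs / 2), type = "pass")
  base <- with_seed_opt(seed, {
    replicate(4, as.numeric(signal::filter(bp, stats::rnorm(n))), simplify = FALSE)
  })
  rms <- function(x) sqrt(mean(x^2))
  to_rms <- function(x, target) x / rms(x) * target
  target <- level_fraction * mvc_rms
  mixed <- list(
    scm_left  = base[[1]] + crosstalk_gain * base[[2]],
    scm_right = base[[2]] + crosstalk_gain * base[[1]],
    sc_left   = base[[3]] + crosstalk_gain * base[[4]],
    sc_right  = base[[4]] + crosstalk_gain * base[[3]]
  )
  ch <- list(
    scm_left  = to_rms(mixed$scm_left, target),
    scm_right = to_rms(mixed$scm_right, target),
    sc_left   = to_rms(mixed$sc_left, sc_gain * target),
    sc_right  = to_rms(mixed$sc_right, sc_gain * target)
  )
  emg_trace(ch, fs = fs)
}

#' Simulate a maximal/submaximal isometric force trial
#'
#' Trapezoidal effort: ramp up, plateau at `peak`, ramp down, with optional
#' Gaussian noise on the plateau.
#'
#' @param peak Plateau force (N for the craniocervical dynamometer, kg for the
#'   cervical unit).
#' @param duration Total trial length, seconds.
#' @param fs Sampling rate, samples/s.
#' @param noise_sd SD of additive noise.
#' @param device Passed to [force_trace()].
#' @param seed Optional integer seed.
#' @return A [force_trace()].
#' @export
simulate_force_trial <- function(peak, duration = 3, fs = 100, noise_sd = 0,
                                 device = "nod", seed = NULL) {
  n <- round(duration * fs)
  ramp_n <- round(0.5 * fs)
  up <- seq(0, 1, length.out = ramp_n)
  plateau <- rep(1, max(n - 2 * ramp_n, 1))
  f <- peak * c(up, plateau, rev(up))
  if (noise_sd > 0)
    f <- f + with_seed_opt(seed, stats::rnorm(length(f), 0, noise_sd))
  force_trace(pmax(f, 0), fs = fs, device = device)
}

# split a pooled activation pair (mean of two levels) into its two levels,
# using the level profile typical of healthy controls
split_activation_pair <- function(pair_mean, low_share) {
  c(pair_mean * 2 * low_share, pair_mean * 2 * (1 - low_share))
}

#' Simulate a three-group cohort with known ground truth
#'
#' Draws per-participant demographics, questionnaire scores, and all candidate
#' predictors from group-shifted distributions; generates monthly 12-month
#' outcomes from the linear models in `truth` with monotone dropout; and
#' (optionally) generates the raw task recordings (angle, EMG, force) whose
#' extracted features match the drawn feature values, so the whole extraction
#' pipeline can be exercised end to end.
#'
#' Eligibility is enforced in generation: recurrent-pain participants have at
#' least two previous pain episodes; chronic-pain participants have baseline
#' disability of at least 10/50 and current pain of at least 20/100.
#'
#' @param n_healthy,n_rnp,n_cnp Group sizes (>= 0). Defaults are the reference
#'   cohort: 15 controls, 22 recurrent, 8 chronic.
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer seed; the full output is a pure function of the
#'   arguments and this seed.
#' @param recordings If `TRUE`, also generate raw per-task signal recordings.
#' @return A list of class `synthetic_cohort` with elements `cohort` (one row
#'   per participant), `longitudinal` (participant x month outcomes, RNP only),
#'   `recordings` (list or `NULL`), and `truth`.
#' @export
simulate_cohort <- function(n_healthy = 15, n_rnp = 22, n_cnp = 8,
                            truth = synthetic_truth(), seed = 1,
                            recordings = FALSE) {
  stopifnot(n_healthy >= 0, n_rnp >= 0, n_cnp >= 0)
  with_seed_opt(seed, {
    n <- n_healthy + n_rnp + n_cnp
    group <- rep(c("healthy", "rnp", "cnp"), c(n_healthy, n_rnp, n_cnp))
    cohort <- data.frame(
      participant_id = sprintf("P%03d", seq_len(n)),
      group = group,
      stringsAsFactors = FALSE
    )
    age_mean <- c(healthy = 31.1, rnp = 31.0, cnp = 33.6)
    age_sd <- c(healthy = 5.7, rnp = 11.8, cnp = 8.7)
    p_female <- c(healthy = 0.60, rnp = 0.64, cnp = 0.88)
    cohort$age <- round(rnorm_trunc(n, age_mean[group], age_sd[group], 18, 75))
    cohort$sex <- ifelse(stats::runif(n) < p_female[group], "female", "male")
    cohort$height <- round(rnorm_trunc(n, ifelse(group == "cnp", 1.6, 1.7), 0.1,
                                       1.4, 2.0), 2)
    cohort$weight <- round(rnorm_trunc(
      n, c(healthy = 69.1, rnp = 74.7, cnp = 59.5)[group],
      c(healthy = 14.8, rnp = 18.0, cnp = 9.8)[group], 40, 140), 1)

    fp <- truth$group_shifts
    for (i in seq_len(nrow(fp))) {
      mu <- unlist(fp[i, c("healthy", "rnp", "cnp")])[group]
      cohort[[fp$feature[i]]] <-
        rnorm_trunc(n, mu, fp$sd[i], fp$lower[i], fp$upper[i])
    }
    cohort$borg_flexion <- round(cohort$borg_flexion)
    cohort$borg_extension <- round(cohort$borg_extension)
    # chronic-pain eligibility: NDI >= 10/50
    cohort$ndi[group == "cnp"] <- pmax(cohort$ndi[group == "cnp"], 10)

    # previous pain episodes: truncated (>= 2) negative binomial, RNP only
    cohort$episodes <- NA_real_
    if (n_rnp > 0) {
      ep <- stats::rnbinom(n_rnp * 6, mu = 5.9, size = 2.6)
      ep <- ep[ep >= 2][seq_len(n_rnp)]
      ep[is.na(ep)] <- 2
      cohort$episodes[group == "rnp"] <- ep
    }
    cohort$episode_vas <- NA_real_
    cohort$episode_vas[group == "rnp"] <-
      rnorm_trunc(n_rnp, 56.4, 14.5, 20, 100)
    cohort$current_pain <- NA_real_
    cohort$current_pain[group == "cnp"] <- rnorm_trunc(n_cnp, 56.1, 19.5, 20, 100)
    cohort$pain_duration_months <- NA_real_
    cohort$pain_duration_months[group == "cnp"] <-
      round(rnorm_trunc(n_cnp, 39.1, 41.4, 3, 240))

    longitudinal <- simulate_longitudinal(cohort[group == "rnp", ], truth)
    rec <- if (recordings) lapply(seq_len(n), function(i)
      simulate_participant_recordings(cohort[i, ])) else NULL
    if (recordings) names(rec) <- cohort$participant_id

    structure(list(cohort = cohort, longitudinal = longitudinal,
                   recordings = rec, truth = truth),
              class = "synthetic_cohort")
  })
}

# monthly 12-month outcomes for the recurrent-pain group, with monotone dropout
simulate_longitudinal <- function(rnp, truth) {
  if (nrow(rnp) == 0L)
    return(data.frame(participant_id = character(), month = integer(),
                      ndi = numeric(), days_with_pain = numeric(),
                      mean_vas = numeric()))
  out <- do.call(rbind, lapply(seq_len(nrow(rnp)), function(i) {
    r <- rnp[i, ]
    ndi_mu <- truth$beta0_ndi + truth$beta_episodes * r$episodes +
      truth$beta_mvcflex * r$mvc_flexion
    days_mu <- truth$beta0_days + truth$gamma_episodes * r$episodes +
      stats::rnorm(1, 0, truth$sigma_days)
    ndi <- pmin(pmax(ndi_mu + stats::rnorm(12, 0, truth$sigma_ndi), 0), 50)
    # kept continuous so the noiseless generative model stays exactly linear
    days <- pmin(pmax(
      days_mu + stats::rnorm(12, 0, truth$sigma_days_month), 0), 31)
    # pain intensity on days with pain satisfies the episode definition
    # (>= 20/100), so reported day counts qualify for the outcome
    vas <- ifelse(days > 0, rnorm_trunc(12, 45, 12, 20, 100),
                  rnorm_trunc(12, 5, 5, 0, 19))
    drop <- stats::runif(12) < truth$dropout_prob
    gone <- cumsum(drop) > 0
    ndi[gone] <- NA; days[gone] <- NA; vas[gone] <- NA
    data.frame(participant_id = r$participant_id, month = 1:12,
               ndi = ndi, days_with_pain = days, mean_vas = vas,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# raw task recordings whose extracted features match one participant's drawn
# feature values (exactly for RoM/JPE/EMG normalisation, approximately for
# velocity and smoothness)
simulate_participant_recordings <- function(r) {
  # Each half-cycle sweep covers the full peak-to-peak excursion, and the
  # combined range-of-motion feature is the sum of the two directional means,
  # so the generated peak-to-peak is half the combined-RoM feature. Ripple
  # sits at 8 Hz, inside the 10 Hz kinematic low-pass band; its amplitude is
  # scaled so rougher movements show more acceleration zero crossings
  # (ordering is faithful; the count saturates at the ripple frequency).
  mk_cyclic <- function(feat_rom, vmean, nvp, axis) {
    p2p <- feat_rom / 2
    period <- max(feat_rom / vmean, 0.5)
    rip_f <- 8
    ratio <- min(nvp / (rip_f * period), 1)
    rip_a <- if (nvp >= 3) 1.2 * ratio * (p2p / 2) / (rip_f * period)^2 else 0
    simulate_angle_trace(rom = p2p, n_cycles = 10, cycle_period = period,
                         ripple_amp = rip_a, ripple_freq = rip_f, axis = axis)
  }
  jpe_side <- function(jpe, sign) {
    lapply(1:3, function(k)
      simulate_jpe_trial(true_error = sign * jpe, target = sign * 60))
  }
  levels <- c(0.2, 0.4, 0.6, 0.8)
  act <- c(split_activation_pair(r$ccf_act_20_40, 0.35),
           split_activation_pair(r$ccf_act_60_80, 0.43)) / 100
  emg_seed <- derive_seed(sum(utf8ToInt(r$participant_id)), "emg")
  ccf <- list(
    mvc = simulate_emg(1, mvc_rms = 150, seed = emg_seed),
    mvc_force = simulate_force_trial(r$ccf_mvc, device = "nod"),
    submax = stats::setNames(
      lapply(act, function(a) simulate_emg(a, mvc_rms = 150, seed = emg_seed)),
      paste0("pct", levels * 100))
  )
  list(
    flexion_extension = mk_cyclic(r$rom_flexext,
                                  (r$vmean_flexion + r$vmean_extension) / 2,
                                  r$nvp_flexext, "flexion_extension"),
    rotation = mk_cyclic(r$rom_rot, r$vmean_rotation, r$nvp_rotation, "rotation"),
    jpe_right = jpe_side(r$jpe, +1),
    jpe_left = jpe_side(r$jpe, -1),
    ccf = ccf,
    mcu = list(
      flexion = list(simulate_force_trial(r$mvc_flexion, device = "mcu"),
                     simulate_force_trial(0.95 * r$mvc_flexion, device = "mcu")),
      extension = list(simulate_force_trial(r$mvc_extension, device = "mcu"),
                       simulate_force_trial(0.95 * r$mvc_extension, device = "mcu"))
    )
  )
}

#' Write a synthetic cohort to delimited-text files
#'
#' Writes `cohort.csv`, `longitudinal.csv`, a `truth.json` sidecar with the
#' generator parameters, and (if recordings were generated) per-task signal
#' files under `recordings/` with `time_s` plus value columns.
#'
#' @param sim A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(sim$longitudinal, file.path(dir, "longitudinal.csv"),
                   row.names = FALSE)
  truth <- unclass(sim$truth)
  truth$group_shifts <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$recordings)) {
    rdir <- file.path(dir, "recordings")
    dir.create(rdir, showWarnings = FALSE)
    for (pid in names(sim$recordings)) {
      rec <- sim$recordings[[pid]]
      for (task in c("flexion_extension", "rotation")) {
        tr <- rec[[task]]
        utils::write.csv(data.frame(time_s = tr$t, angle_deg = tr$theta),
                         file.path(rdir, sprintf("%s_%s.csv", pid, task)),
                         row.names = FALSE)
      }
    }
  }
  invisible(dir)
}
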