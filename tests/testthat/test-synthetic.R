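test_that("noiseless cyclic traces have exact peak-to-peak amplitude and are deterministic", {
  tr <- simulate_angle_trace(rom = 50, n_cycles = 10, cycle_period = 3)
  expect_equal(max(tr$theta) - min(tr$theta), 50)

  a <- simulate_angle_trace(rom = 40, noise_sd = 1, seed = 7)
  b <- simulate_angle_trace(rom = 40, noise_sd = 1, seed = 7)
  expect_identical(a$theta, b$theta)

  expect_error(simulate_angle_trace(rom = -5), "positive")
  expect_error(simulate_angle_trace(rom = 50, cycle_period = 0), "positive")
})

test_that("repositioning trials end at the injected error and average correctly", {
  expect_equal(compute_jpe(list(simulate_jpe_trial(0)), list())$jpe_right, 0)
  expect_equal(compute_jpe(list(simulate_jpe_trial(5)), list())$jpe_right, 5)
  trials <- lapply(c(2, 4, 6), simulate_jpe_trial)
  expect_equal(compute_jpe(trials, list())$jpe_right, 4)
})

test_that("EMG generator hits its target RMS and supports supra-maximal levels", {
  mvc <- simulate_emg(1, mvc_rms = 150, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  expect_equal(rms(mvc$channels$scm_left), 150)
  expect_equal(rms(mvc$channels$scm_right), 150)

  # same seed, scaled level: normalisation recovers the level exactly
  half <- simulate_emg(0.5, mvc_rms = 150, seed = 3)
  act <- normalize_ccf_activation(list(l50 = half, l100 = mvc), mvc)
  expect_equal(act$normalized_amplitude[act$level == "l100"], 100)
  expect_equal(act$normalized_amplitude[act$level == "l50"], 50)

  # activation above the maximal contraction is representable
  over <- simulate_emg(1.118, mvc_rms = 150, seed = 3)
  act2 <- normalize_ccf_activation(list(over = over), mvc)
  expect_equal(act2$normalized_amplitude, 111.8)
})

test_that("cohort generation is deterministic and enforces eligibility", {
  s1 <- simulate_cohort(seed = 5)
  s2 <- simulate_cohort(seed = 5)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$longitudinal, s2$longitudinal)

  rnp <- s1$cohort[s1$cohort$group == "rnp", ]
  cnp <- s1$cohort[s1$cohort$group == "cnp", ]
  expect_true(all(rnp$episodes >= 2))
  expect_true(all(cnp$ndi >= 10))
  expect_true(all(cnp$current_pain >= 20))
  expect_equal(nrow(s1$cohort), 45)
  expect_equal(sort(unique(s1$longitudinal$month)), 1:12)

  # missingness is monotone: once a participant stops responding they never return
  for (pid in unique(s1$longitudinal$participant_id)) {
    obs <- !is.na(s1$longitudinal$ndi[s1$longitudinal$participant_id == pid])
    expect_true(all(diff(obs) <= 0))
  }
})

test_that("noiseless cohorts are exactly identifiable by OLS", {
  truth <- synthetic_truth(sigma_ndi = 0, sigma_days = 0,
                           sigma_days_month = 0, dropout_prob = 0)
  sim <- simulate_cohort(n_healthy = 0, n_rnp = 50, n_cnp = 0,
                         truth = truth, seed = 11)
  des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
  fit <- suppressWarnings(fit_ols(des$x[, c("episodes", "mvc_flexion")], des$y))
  expect_equal(fit$terms$beta, c(10.23, 0.54, -0.32), tolerance = 1e-8)
  expect_equal(fit$rmse, 0, tolerance = 1e-6)

  des_d <- build_design(sim$cohort, sim$longitudinal, "days")
  fit_d <- suppressWarnings(fit_ols(des_d$x[, "episodes", drop = FALSE], des_d$y))
  expect_equal(fit_d$terms$beta, c(2.14, 0.40), tolerance = 1e-8)
})

test_that("OLS coefficient recovery matches its exact sampling distribution", {
  # Oracle: with known residual sigma, beta_hat - beta is normal with SE from
  # (X'X)^-1, so the probability of landing within +/-0.1 of truth is known
  # exactly per realised design. The empirical hit count over seeds must match
  # the oracle's expectation within binomial noise.
  n_rep <- 60
  hits <- 0
  expected <- 0
  var_expected <- 0
  sigma <- synthetic_truth()$sigma_ndi
  for (s in seq_len(n_rep)) {
    sim <- simulate_cohort(0, 200, 0, seed = 5000 + s)
    des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
    X <- cbind(1, des$x$episodes, des$x$mvc_flexion)
    se <- sigma * sqrt(diag(solve(crossprod(X))))[2:3]
    p_hit <- prod(2 * stats::pnorm(0.1 / se) - 1)
    expected <- expected + p_hit
    var_expected <- var_expected + p_hit * (1 - p_hit)
    fit <- fit_ols(des$x[, c("episodes", "mvc_flexion")], des$y)
    if (abs(fit$terms$beta[2] - 0.54) <= 0.1 &&
        abs(fit$terms$beta[3] + 0.32) <= 0.1) hits <- hits + 1
  }
  expect_lt(abs(hits - expected), 4 * sqrt(var_expected))
})

test_that("written cohort files round-trip through delimited text", {
  sim <- simulate_cohort(n_healthy = 2, n_rnp = 3, n_cnp = 2, seed = 2)
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  cohort <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(cohort), 7)
  expect_true(all(table_predictors %in% names(cohort)))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$beta_episodes, sim$truth$beta_episodes)
})
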