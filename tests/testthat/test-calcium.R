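# Calcium pipeline: extraction, filtering, compensation, detection,
# activity classification and fate taxonomy.

test_that("ROI trace extraction averages mask pixels", {
  frames <- array(0, dim = c(3, 4, 4))
  roi <- matrix(0L, 4, 4); np <- matrix(0L, 4, 4)
  roi[1, 1] <- 1L; roi[1, 2] <- 1L   # 2-pixel ROI
  np[4, 4] <- 1L
  frames[1, 1, 1] <- 10; frames[1, 1, 2] <- 30   # mean 20
  frames[2, , ] <- 7                              # uniform frame
  frames[3, 4, 4] <- 5
  tr <- extract_roi_traces(frames, roi, np)
  expect_equal(tr$f_roi, c(20, 7, 0))
  expect_equal(tr$f_neuropil, c(0, 7, 5))
  expect_error(extract_roi_traces(frames, matrix(0L, 4, 4), np), "no labels")
  bad_np <- matrix(0L, 4, 4)
  expect_error(extract_roi_traces(frames, roi, bad_np), "neuropil")
})

test_that("movie round-trip recovers the traces painted into ROI pixels", {
  cp <- calcium_sim_params(n_neurons = 4, n_frames = 120, seed = 21,
                           event_rate_per_min = 30)
  sim <- simulate_calcium_recording(cp, movie = TRUE)
  got <- extract_roi_traces(sim$movie$frames, sim$movie$roi_masks,
                            sim$movie$neuropil_masks)
  for (j in 1:4) {
    id <- sprintf("n%03d", j)
    expect_lt(max(abs(got$f_roi[got$neuron_id == id] -
                        sim$traces$f_roi[sim$traces$neuron_id == id])), 1e-6)
    expect_lt(max(abs(got$f_neuropil[got$neuron_id == id] -
                        sim$traces$f_neuropil[sim$traces$neuron_id == id])),
              1e-6)
  }
})

test_that("low-pass filter is zero-phase with the designed frequency response", {
  expect_equal(lowpass_trace(rep(3, 200), 30), rep(3, 200), tolerance = 1e-9)
  expect_error(lowpass_trace(rnorm(100), 30, cutoff_hz = 15), "Nyquist")
  t <- seq(0, 20, by = 1 / 30)
  amp <- function(x) (max(x) - min(x)) / 2
  # passband: 0.5 Hz preserved within 1%
  slow <- sin(2 * pi * 0.5 * t)
  mid <- seq(100, length(t) - 100)
  expect_lt(abs(amp(lowpass_trace(slow, 30)[mid]) - 1), 0.01)
  # stopband: 14 Hz attenuated at least as much as the squared (two-pass)
  # order-2 Butterworth magnitude 1/(1 + (f/fc)^4)
  fast <- sin(2 * pi * 14 * t)
  designed <- 1 / (1 + (14 / 10)^4)
  expect_lt(amp(lowpass_trace(fast, 30)[mid]), designed + 0.05)
  # zero phase: peak of a smooth bump does not move
  bump <- exp(-(t - 10)^2 / 0.5)
  expect_equal(which.max(lowpass_trace(bump, 30)), which.max(bump))
})

test_that("neuropil compensation implements the median-recentred formula", {
  # hand example: f_roi = 100, f_neuropil = (30, 50), alpha = 0.7, median 40
  expect_equal(neuropil_compensate(c(100, 100), c(30, 50), 0.7), c(107, 93))
  # constant neuropil leaves the ROI trace untouched
  x <- rnorm(50)
  expect_equal(neuropil_compensate(x, rep(2.5, 50), 0.7), x)
  # adding a constant to the neuropil trace changes nothing
  np <- rnorm(50)
  expect_equal(neuropil_compensate(x, np, 0.7),
               neuropil_compensate(x, np + 5, 0.7), tolerance = 1e-12)
  expect_error(neuropil_compensate(x, np[-1], 0.7), "lengths differ")
})

test_that("transient detection honours threshold and minimum duration", {
  set.seed(42)
  n <- 3000
  noise <- rnorm(n, 0, 0.1)
  flat <- detect_transients(rep(1, n), 30)
  expect_equal(flat$n_events, 0L)
  expect_false(flat$active)

  sigma <- stats::mad(noise)
  lift <- function(at, len) {
    x <- noise
    x[at:(at + len - 1)] <- x[at:(at + len - 1)] + 10 * sigma
    x
  }
  one <- detect_transients(lift(1000, 30), 30)
  expect_equal(one$n_events, 1L)
  expect_true(one$active)
  # half-open [start, end): a 30-frame elevation spans exactly 30 frames
  expect_equal(one$events$end_frame - one$events$start_frame, 30)
  expect_equal(one$events$start_frame, 999)  # 0-based
  expect_equal(one$frequency_per_min, 60 * 1 * 30 / n)

  short <- detect_transients(lift(1000, 19), 30)
  expect_equal(short$n_events, 0L)
  exact <- detect_transients(lift(1000, 20), 30)
  expect_equal(exact$n_events, 1L)
})

test_that("baseline activity levels split at one transient per minute", {
  train <- function(n_events, minutes = 10) {
    structure(list(frequency_per_min = n_events / minutes,
                   n_events = n_events), class = "transient_train")
  }
  expect_equal(classify_baseline_level(train(12)), "high")   # 1.2/min
  expect_equal(classify_baseline_level(train(10)), "high")   # exactly 1/min
  expect_equal(classify_baseline_level(train(5)), "low")     # 0.5/min
  expect_equal(classify_baseline_level(train(0)), "inactive")
})

test_that("fate taxonomy maps all eight flag combinations exactly once", {
  flags <- expand.grid(baseline = c(FALSE, TRUE), mid = c(FALSE, TRUE),
                       late = c(FALSE, TRUE))
  fate <- classify_fate(flags$baseline, flags$mid, flags$late)
  # baseline-active neurons get exactly one of the four fates
  base_active <- fate[fate$baseline, ]
  expect_equal(sort(base_active$fate_from_baseline),
               sort(c("persistently_active", "regained", "silent_at_mid",
                      "silent_at_late_only")))
  expect_true(all(is.na(fate$fate_from_baseline[!fate$baseline])))
  # late-active neurons get exactly one history label
  late_active <- fate[fate$late, ]
  expect_false(anyNA(late_active$history_at_late))
  expect_true(all(is.na(fate$history_at_late[!fate$late])))
  # spot checks
  expect_equal(fate$fate_from_baseline[fate$baseline & fate$mid & fate$late],
               "persistently_active")
  expect_equal(fate$history_at_late[!fate$baseline & !fate$mid & fate$late],
               "newly_active")
  expect_equal(fate$fate_from_baseline[fate$baseline & !fate$mid & fate$late],
               "regained")
  expect_error(classify_fate(c(TRUE, NA), c(TRUE, TRUE), c(TRUE, TRUE)),
               "missing")
})

test_that("fraction_active is a permutation-invariant plug-in fraction", {
  flags <- c(rep(TRUE, 42), rep(FALSE, 97))   # 42 of 139
  expect_equal(fraction_active(flags), 42 / 139)
  expect_equal(fraction_active(sample(flags)), 42 / 139)
  expect_equal(fraction_active(rep(TRUE, 5)), 1)
  expect_error(fraction_active(logical(0)), "empty")
})

test_that("the trace pipeline classifies silent and active neurons correctly", {
  # silent, noise-only neurons stay inactive through the full chain
  silent <- simulate_calcium_recording(
    calcium_sim_params(n_neurons = 10, n_frames = 4500,
                       event_rate_per_min = 0, seed = 13))
  res_s <- analyze_traces(silent$traces, 30)
  expect_true(all(!res_s$active))
  # strongly active neurons are detected
  busy <- simulate_calcium_recording(
    calcium_sim_params(n_neurons = 10, n_frames = 4500,
                       event_rate_per_min = 4, seed = 14))
  res_b <- analyze_traces(busy$traces, 30)
  expect_true(mean(res_b$active) >= 0.9)
})
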