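# Synthetic-data generators: parameter validation, degenerate dynamics,
# distributional oracles and bit-reproducibility.

test_that("spine simulator parameter validation rejects bad hazards", {
  expect_error(spine_sim_params(elimination_prob = 1.2), "\\[0, 1\\]")
  expect_error(spine_sim_params(formation_rate = -0.1), "non-negative")
  expect_error(spine_sim_params(session_times = "B1"), "2 sessions")
  expect_error(spine_sim_params(morph_type_probs = c(mushroom = 0.7, thin = 0.2,
                                                     stubby = 0.2)), "simplex")
})

test_that("no-dynamics spine tables are constant across sessions", {
  p <- spine_sim_params(n_dendrites = 4, spines_per_dendrite_mean = 15,
                        session_times = c("B1", "B2", "3d", "6d"),
                        elimination_prob = 0, formation_rate = 0, seed = 11)
  tracks <- simulate_spine_tracks(p)$tracks
  per_spine <- tapply(tracks$present, tracks$spine_id, function(x) all(x == 1L))
  expect_true(all(per_spine))
  n_per_session <- table(tracks$session[tracks$present == 1L])
  expect_equal(length(unique(as.integer(n_per_session))), 1L)
})

test_that("certain elimination removes every pre-existing spine", {
  p <- spine_sim_params(n_dendrites = 3, spines_per_dendrite_mean = 30,
                        session_times = c("B1", "B2", "3d"),
                        elimination_prob = c(B2 = 0, `3d` = 1),
                        formation_rate = 0, seed = 4)
  tracks <- simulate_spine_tracks(p)$tracks
  expect_true(all(tracks$present[tracks$session == "3d"] == 0L))
})

test_that("empirical elimination fraction matches the binomial hazard", {
  p <- spine_sim_params(n_dendrites = 100, spines_per_dendrite_mean = 100,
                        session_times = c("B1", "B2", "3d", "6d"),
                        elimination_prob = 0.12, formation_rate = 0, seed = 1)
  tracks <- simulate_spine_tracks(p)$tracks
  tr <- classify_transitions(tracks, p$session_times)
  frac <- sum(tr$n_eliminated) / sum(tr$n_prev)
  expect_lt(abs(frac - 0.12), 0.01)
})

test_that("default spine tables contain no 1,0,1 reappearance pattern", {
  p <- spine_sim_params(n_dendrites = 20, spines_per_dendrite_mean = 40,
                        session_times = c("B1", "B2", "3d", "6d", "9d"),
                        elimination_prob = 0.3, formation_rate = 0.3, seed = 8)
  tracks <- simulate_spine_tracks(p)$tracks
  sessions <- p$session_times
  bad <- tapply(seq_len(nrow(tracks)), tracks$spine_id, function(idx) {
    code <- tracks$present[idx][order(match(tracks$session[idx], sessions))]
    ones <- which(code == 1L)
    any(code[min(ones):max(ones)] == 0L)  # a 0 strictly between two 1s
  })
  expect_false(any(bad))
})

test_that("generators are bit-reproducible for identical seed and params", {
  p <- spine_sim_params(n_dendrites = 5, seed = 99)
  expect_identical(simulate_spine_tracks(p), simulate_spine_tracks(p))
  cp <- calcium_sim_params(n_neurons = 2, n_frames = 500, seed = 99)
  expect_identical(simulate_calcium_recording(cp),
                   simulate_calcium_recording(cp))
  tp <- tracing_sim_params(seed = 99)
  expect_identical(simulate_tracing_experiment(tp),
                   simulate_tracing_experiment(tp))
})

test_that("silent noise-free neuron reduces to baseline after compensation", {
  cp <- calcium_sim_params(n_neurons = 2, n_frames = 1000,
                           event_rate_per_min = 0, noise_sd = 0, seed = 5)
  sim <- simulate_calcium_recording(cp)
  tr <- sim$traces[sim$traces$neuron_id == "n001", ]
  comp <- neuropil_compensate(tr$f_roi, tr$f_neuropil, cp$neuropil_coefficient)
  expect_equal(comp, rep(cp$baseline, 1000), tolerance = 1e-12)
})

test_that("noise-free compensation inverts the contamination construction", {
  cp <- calcium_sim_params(n_neurons = 3, n_frames = 2000, noise_sd = 0,
                           event_rate_per_min = 3, seed = 6)
  sim <- simulate_calcium_recording(cp)
  for (j in 1:3) {
    tr <- sim$traces[sim$traces$neuron_id == sprintf("n%03d", j), ]
    comp <- neuropil_compensate(tr$f_roi, tr$f_neuropil, 0.7)
    expect_lt(max(abs(comp - sim$truth$true_traces[, j])), 1e-9)
  }
})

test_that("ground-truth event counts follow the configured Poisson rate", {
  # 1.2 events/min over 10 min -> Poisson(12) per neuron
  cp <- calcium_sim_params(n_neurons = 200, n_frames = 18000,
                           event_rate_per_min = 1.2, seed = 7)
  sim <- simulate_calcium_recording(cp)
  counts <- lengths(sim$truth$event_frames)
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 200))  # 3 SE
  expect_lt(abs(stats::var(counts) / mean(counts) - 1), 0.35)
})

test_that("tracing simulator respects degenerate and full-sampling cases", {
  p0 <- tracing_sim_params(mean_presyn_per_region = c(somatosensory = 0,
                                                      motor = 0, auditory = 0,
                                                      retrosplenial = 0,
                                                      thalamus = 0), seed = 2)
  sim0 <- simulate_tracing_experiment(p0)
  expect_true(all(sim0$counts$presyn_count == 0))
  pf <- tracing_sim_params(sections_imaged = 18, sections_total = 18,
                           n_starters_true = 77, seed = 2)
  simf <- simulate_tracing_experiment(pf)
  expect_true(all(simf$starters$starter_counted == 77))
})

test_that("tracing counts have the configured Poisson mean", {
  p <- tracing_sim_params(regions = "A",
                          mean_presyn_per_region = c(A = 500),
                          n_brains = 200, seed = 3)
  sim <- simulate_tracing_experiment(p)
  se <- sqrt(500 / 200)
  expect_lt(abs(mean(sim$counts$presyn_count) - 500), 3 * se)
})
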