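test_that("cis kinetics: instant 390 onset, fast 520 relief, slow dark decay", {
  # a single 390 flash then darkness: closed-form thermal decay
  st <- photoswitch_state(light_schedule(0, 10, 390))
  expect_equal(cis_fraction(st, 5), 1)
  expect_equal(cis_fraction(st, 10 + 74 * 60), 0.5, tolerance = 1e-9)
  expect_equal(cis_fraction(st, 10 + 10 * 60), 0.5^(10 / 74),
               tolerance = 1e-9)

  # 520 relief is effectively complete within a 5 s flash
  st2 <- photoswitch_state(light_schedule(c(0, 10), c(10, 15),
                                          c("390", "520")))
  expect_lt(cis_fraction(st2, 15), 1e-4)

  # arbitrary schedules keep the fraction in [0, 1]
  set.seed(301)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    on <- cumsum(runif(n, 5, 30))
    w <- sample(c("390", "520", "dark"), n, replace = TRUE)
    sched <- light_schedule(on, on + runif(n, 0.5, 4.5), w)
    stt <- photoswitch_state(sched)
    cf <- cis_fraction(stt, seq(0, max(sched$t_off) + 50, length.out = 200))
    expect_true(all(cf >= 0 & cf <= 1))
  }

  # darkness decay between flashes matches the closed form from any level
  st3 <- photoswitch_state(light_schedule(c(0, 100), c(5, 105),
                                          c("390", "520")))
  expect_equal(cis_fraction(st3, 65), 0.5^(60 / (74 * 60)),
               tolerance = 1e-9)
})

test_that("neuron specs enforce phenotype constraints", {
  expect_error(neuron_spec("type1", m_390 = 1.2), "m_390 < 1")
  expect_error(neuron_spec("type2", m_390 = 0.8), "m_390 > 1")
  expect_error(neuron_spec("control", m_390 = 0.5), "m_390 = 1")
  expect_error(neuron_spec("type1", m_390 = 0), "<= 0")
  expect_error(neuron_spec("control", intra_isi_s = c(0.05, 0.09)),
               "intra_isi_s")
  specs <- default_neuron_specs()
  expect_equal(specs$type1$m_390, 1.85 / 3.41)
  expect_equal(specs$type2$m_390, 5.25 / 3.48)
  expect_true(all(vapply(specs, function(s) s$tonic_rate_hz, 0) >= 1 &
                    vapply(specs, function(s) s$tonic_rate_hz, 0) <= 10))
})

test_that("simulated trains are reproducible and rate-accurate", {
  spec <- neuron_spec("control", tonic_rate_hz = 4, burst_rate_min = 2)
  a <- simulate_train(spec, duration_s = 300, seed = 11)
  b <- simulate_train(spec, duration_s = 300, seed = 11)
  expect_identical(a$times, b$times)
  c2 <- simulate_train(spec, duration_s = 300, seed = 12)
  expect_false(identical(a$times, c2$times))

  # long-run tonic rate within 3 SE of the spec rate (no bursts)
  tonic <- neuron_spec("control", tonic_rate_hz = 4, burst_rate_min = 0)
  tr <- simulate_train(tonic, duration_s = 1000, seed = 13)
  n_exp <- 4 * 1000
  se <- sqrt(n_exp / tonic$isi_shape)
  expect_lt(abs(n_spikes(tr) - n_exp), 3 * se + 5)

  # under constant 390 the rate is scaled by the multiplier
  t1 <- neuron_spec("type1", tonic_rate_hz = 4, m_390 = 0.5,
                    burst_rate_min = 0)
  sched <- light_schedule(0, 1000, 390)
  tr390 <- simulate_train(t1, sched, duration_s = 1000, seed = 14)
  expect_lt(abs(n_spikes(tr390) - 2000), 3 * sqrt(2000 / 10) + 5)
})

test_that("burst-free specs produce burst-free trains", {
  spec <- neuron_spec("control", tonic_rate_hz = 2, isi_shape = 20,
                      burst_rate_min = 0)
  tr <- simulate_train(spec, duration_s = 200, seed = 15)
  expect_equal(n_bursts(detect_bursts(tr)), 0L)

  bursty <- neuron_spec("control", tonic_rate_hz = 2, isi_shape = 20,
                        burst_rate_min = 6)
  trb <- simulate_train(bursty, duration_s = 200, seed = 16)
  expect_gt(n_bursts(detect_bursts(trb)), 5L)
})

test_that("control trains show near-zero photoswitching over many epochs", {
  sched <- default_schedule(n_cycles = 20)
  idx <- sapply(1:8, function(s) {
    tr <- simulate_train(default_neuron_specs()$control, sched, seed = s)
    f <- epoch_frequencies(tr, sched)
    photoswitching_index(f[["f_520"]], f[["f_390"]])
  })
  expect_lt(abs(mean(idx)), 5)
})

test_that("type 1 index recovery approaches the construction value", {
  m <- 0.54
  spec <- neuron_spec("type1", tonic_rate_hz = 3.4, m_390 = m)
  sched <- default_schedule(n_cycles = 20)
  idx <- sapply(1:10, function(s) {
    tr <- simulate_train(spec, sched, seed = 500 + s)
    f <- epoch_frequencies(tr, sched)
    photoswitching_index(f[["f_520"]], f[["f_390"]])
  })
  expect_lt(abs(mean(idx) - 100 * (1 - m) / m), 15)
  expect_true(all(idx > 0))
})

test_that("cohort simulation reproduces counts, labels and seeds", {
  coh <- simulate_cohort(n_control = 5, n_nonresponder = 6, n_type1 = 4,
                         n_type2 = 2, seed = 42)
  expect_length(coh$trains, 17L)
  expect_equal(as.vector(table(coh$truth$true_class)[c("control",
                                                       "nonresponder",
                                                       "type1", "type2")]),
               c(5L, 6L, 4L, 2L))
  expect_equal(sum(coh$truth$cohort == "control"), 5L)
  coh2 <- simulate_cohort(n_control = 5, n_nonresponder = 6, n_type1 = 4,
                          n_type2 = 2, seed = 42)
  expect_identical(lapply(coh$trains, function(t) t$times),
                   lapply(coh2$trains, function(t) t$times))
})

test_that("nicotine sessions scale the response by the antagonism factor", {
  spec <- neuron_spec("control", tonic_rate_hz = 4, burst_rate_min = 0)
  kern <- nicotine_kernel(g = 2, antagonism = 0.4)
  dark <- injection_event(400, "nicotine", 30, "dark")
  tr <- simulate_nicotine_session(spec, kern, list(dark), 900, seed = 61)
  resp_dark <- as.numeric(response_magnitude(
    sliding_series(tr, kind = "rate"), 400))
  expect_gt(resp_dark, 60)

  sal <- injection_event(400, "saline", 0, "dark")
  trs <- simulate_nicotine_session(spec, kern, list(sal), 900, seed = 62)
  resp_sal <- as.numeric(response_magnitude(
    sliding_series(trs, kind = "rate"), 400))
  expect_lt(abs(resp_sal), 20)

  expect_error(simulate_nicotine_session(spec, kern,
                                         list(injection_event(100,
                                                              "nicotine",
                                                              30)),
                                         900, seed = 63), "baseline")
})

test_that("CPP cohorts realize bias and shift at the frame period", {
  g <- simulate_cpp_cohort(6, conditioning_shift_s = 166,
                           test_noise_sd_s = 0, bias_sd_s = 40, seed = 71)
  ps <- sapply(g$animals, function(a) preference_score(a$test, a$pretest))
  # noise-free construction: every score equals the shift to the frame
  expect_true(all(abs(ps - 166) <= 0.05 + 1e-9))
  # realized shift bookkeeping matches the recovered scores exactly
  expect_equal(ps, g$truth$shift_s, ignore_attr = TRUE)

  g2 <- simulate_cpp_cohort(6, conditioning_shift_s = 166,
                            test_noise_sd_s = 0, bias_sd_s = 40,
                            seed = 71)
  ps2 <- sapply(g2$animals, function(a) preference_score(a$test,
                                                         a$pretest))
  expect_identical(ps, ps2)

  expect_error(simulate_cpp_cohort(4, conditioning_shift_s = 1000,
                                   session_s = 900), "exceeds")
})

test_that("current pairs hit the generating inhibition fraction", {
  exact <- simulate_current_pairs(10, 0.67, noise_cv = 0, seed = 81)
  idx <- photoinhibition_table(exact)$index
  expect_true(all(abs(idx - 67) < 1e-9))

  null <- simulate_current_pairs(200, 0, noise_cv = 0.1, seed = 82)
  expect_lt(abs(mean(photoinhibition_table(null)$index)), 3)

  noisy <- simulate_current_pairs(100, 0.67, noise_cv = 0.1, seed = 83)
  idxn <- photoinhibition_table(noisy)$index
  se <- sd(idxn) / sqrt(length(idxn))
  expect_lt(abs(mean(idxn) - 67), 3 * se + 0.5)
})
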