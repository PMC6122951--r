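test_that("burst detection follows the 80/160 ms scan", {
  # ISIs 50, 50, 200, 700 ms: burst over spikes 1-3
  st <- spike_train("a", c(0, 0.05, 0.10, 0.30, 1.0), 0, 2)
  b <- detect_bursts(st)
  expect_equal(unname(b$bursts), cbind(1L, 3L), ignore_attr = TRUE)
  # ISIs 70, 150, 150, 230 ms: 150 <= 160 keeps the burst open
  st2 <- spike_train("b", c(0, 0.07, 0.22, 0.37, 0.60), 0, 2)
  expect_equal(unname(detect_bursts(st2)$bursts), cbind(1L, 4L),
               ignore_attr = TRUE)
  # no ISI below 80 ms: no bursts
  st3 <- spike_train("c", c(0, 0.2, 0.4), 0, 1)
  expect_equal(n_bursts(detect_bursts(st3)), 0L)
})

test_that("boundary ISIs follow the strict tie rules", {
  # exactly 80 ms does not open a burst
  st <- spike_train("a", c(0, 0.08, 0.16), 0, 1)
  expect_equal(n_bursts(detect_bursts(st)), 0L)
  # 70 ms opens; a subsequent ISI of exactly 160 ms stays inside
  st2 <- spike_train("b", c(0, 0.07, 0.23, 1.0), 0, 2)
  expect_equal(unname(detect_bursts(st2)$bursts), cbind(1L, 3L),
               ignore_attr = TRUE)
  # an ISI just above 160 ms closes
  st3 <- spike_train("c", c(0, 0.07, 0.2301, 1.0), 0, 2)
  expect_equal(unname(detect_bursts(st3)$bursts), cbind(1L, 2L),
               ignore_attr = TRUE)
})

test_that("degenerate trains yield empty burst sets", {
  expect_equal(n_bursts(detect_bursts(spike_train("a", numeric(0), 0, 1))),
               0L)
  expect_equal(n_bursts(detect_bursts(spike_train("a", 0.5, 0, 1))), 0L)
})

test_that("detector matches the brute-force range oracle", {
  for (seed in 1:150) {
    tr <- random_mixed_train(seed)
    got <- detect_bursts(tr)$bursts
    want <- oracle_bursts(tr$times)
    expect_equal(unname(got), unname(want),
                 info = paste("seed", seed))
  }
})

test_that("burst sizes plus non-burst spikes conserve the total", {
  for (seed in 201:240) {
    tr <- random_mixed_train(seed)
    b <- detect_bursts(tr)
    in_bursts <- if (nrow(b$bursts))
      sum(b$bursts[, "end"] - b$bursts[, "start"] + 1L) else 0L
    expect_equal(in_bursts + round((100 - swb_fraction(tr, b)) / 100 *
                                     n_spikes(tr)),
                 n_spikes(tr))
  }
})

test_that("%SWB is the burst-spike share of all spikes", {
  st <- spike_train("a", c(0, 0.05, 0.10, 0.30, 1.0), 0, 2)
  expect_equal(swb_fraction(st, detect_bursts(st)), 60) # 3 of 5
  st2 <- spike_train("b", c(0, 0.2, 0.4), 0, 1)
  expect_equal(swb_fraction(st2, detect_bursts(st2)), 0)
  st3 <- spike_train("c", c(0, 0.05, 0.10), 0, 1)
  expect_equal(swb_fraction(st3, detect_bursts(st3)), 100)
  expect_equal(swb_fraction(spike_train("d", numeric(0), 0, 1),
                            detect_bursts(spike_train("d", numeric(0),
                                                      0, 1))), 0)
  expect_error(swb_fraction(st, detect_bursts(st2)), "train")
})

test_that("sliding windows use 60 s spans stepped by 15 s", {
  tr <- grid_train(2, 300)
  ser <- sliding_series(tr, kind = "rate")
  expect_true(all(abs(ser$value - 2) < 0.02))
  expect_equal(unique(round(diff(ser$center), 9)), 15)
  expect_equal(attr(ser, "window_s") - attr(ser, "step_s"), 45) # overlap
  # truncated trailing windows are dropped: all centers fit the span
  expect_true(all(ser$center + 30 <= 300))

  empty <- spike_train("e", numeric(0), 0, 300)
  expect_true(all(sliding_series(empty, kind = "rate")$value == 0))

  short <- spike_train("s", c(1, 2, 3), 0, 30)
  one <- sliding_series(short, kind = "rate")
  expect_equal(nrow(one), 1L)
  expect_equal(one$value, 3 / 60)
})

test_that("sliding %SWB restricts the fraction to each window", {
  # bursty first half, tonic second half
  burst <- c(outer(c(0, 0.05, 0.10), seq(5, 115, by = 10), "+"))
  tonic <- seq(125, 295, by = 0.5)
  tr <- spike_train("m", sort(c(burst, tonic)), 0, 300)
  b <- detect_bursts(tr)
  ser <- sliding_series(tr, b, kind = "pct_swb")
  expect_equal(ser$value[1L], 100)               # pure bursting
  expect_equal(ser$value[nrow(ser)], 0)          # pure tonic
  expect_true(all(ser$value >= 0 & ser$value <= 100))
})

test_that("sliding rate of a Poisson train converges to its rate", {
  tr <- poisson_train(4, 3000, seed = 7)
  ser <- sliding_series(tr, kind = "rate")
  se <- sd(ser$value) / sqrt(nrow(ser) / 4) # ~4 steps per window overlap
  expect_lt(abs(mean(ser$value) - 4), 3 * max(se, 0.05))
})

test_that("event-aligned histograms bin and normalize correctly", {
  tr <- grid_train(4, 120)
  h <- aligned_histogram(tr, c(30, 60, 90), pre_s = 5, post_s = 5)
  expect_equal(h$n_events, 3L)
  expect_true(all(abs(h$rate - 4) < 1e-9))
  expect_equal(sum(h$counts), sum(h$rate) * h$n_events * h$bin_s)

  # single event, one spike 0.1 s after it: count lands in bin [0, 0.25)
  tr2 <- spike_train("s", 10.1, 0, 20)
  h2 <- aligned_histogram(tr2, 10, pre_s = 5, post_s = 5)
  bin0 <- which(h2$bin_edges == 0)
  expect_equal(h2$counts[1L, bin0], 1L)
  expect_equal(sum(h2$counts), 1L)

  # total count equals spikes inside any event window (events far apart)
  tr3 <- poisson_train(3, 400, seed = 11)
  ev <- c(50, 150, 250, 350)
  h3 <- aligned_histogram(tr3, ev, pre_s = 5, post_s = 5)
  manual <- sum(sapply(ev, function(e)
    sum(tr3$times >= e - 5 & tr3$times < e + 5)))
  expect_equal(sum(h3$counts), manual)
})

test_that("a 20-cycle alternating schedule gives 20 alignment events", {
  sched <- default_schedule(n_cycles = 20)
  ev <- epoch_onsets(sched, "390")
  expect_length(ev, 20L)
  tr <- poisson_train(3, max(sched$t_off), seed = 3)
  h <- aligned_histogram(tr, ev, pre_s = 5, post_s = 5)
  expect_equal(h$n_events, 20L)
})

test_that("aligned_histogram rejects bad inputs", {
  tr <- grid_train(4, 60)
  expect_error(aligned_histogram(tr, numeric(0)), "event")
  expect_error(aligned_histogram(tr, 30, pre_s = 5, post_s = 5,
                                 bin_s = 0.3), "evenly")
})
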