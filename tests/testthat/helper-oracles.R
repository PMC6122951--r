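# Independent oracles and generators used across test files.

# Brute-force burst scanner, independent of the sequential detector:
# enumerates every contiguous spike range, keeps those satisfying the
# burst invariants (opening ISI < onset, internal ISIs <= close,
# following ISI > close or end of train), then selects ranges greedily
# from the left, skipping any range overlapping an already-chosen one.
oracle_bursts <- function(times, onset_ms = 80, close_ms = 160) {
  n <- length(times)
  on_s <- onset_ms / 1000
  cl_s <- close_ms / 1000
  cand <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        isis <- diff(times[i:j])
        if (isis[1L] < on_s && all(isis <= cl_s) &&
            (j == n || times[j + 1L] - times[j] > cl_s))
          cand <- rbind(cand, c(i, j))
      }
    }
  }
  if (!nrow(cand)) return(cbind(start = integer(0), end = integer(0)))
  cand <- cand[order(cand[, 1L]), , drop = FALSE]
  chosen <- matrix(integer(0), ncol = 2)
  last_end <- 0L
  for (k in seq_len(nrow(cand))) {
    if (cand[k, 1L] > last_end) {
      chosen <- rbind(chosen, cand[k, ])
      last_end <- cand[k, 2L]
    }
  }
  colnames(chosen) <- c("start", "end")
  chosen
}

# Random spike train mixing Poisson-like ISIs, injected sub-80 ms burst
# runs, and occasional ISIs pinned exactly to the 80/160 ms boundaries
# to exercise the tie rules.
random_mixed_train <- function(seed, max_spikes = 120) {
  set.seed(seed)
  n <- sample(0:max_spikes, 1L)
  if (n == 0)
    return(spike_train(paste0("r", seed), numeric(0), 0, 10))
  isis <- sapply(seq_len(n), function(i) {
    u <- runif(1)
    if (u < 0.45) rexp(1, rate = runif(1, 2, 8))
    else if (u < 0.8) runif(1, 0.02, 0.075)
    else if (u < 0.9) sample(c(0.08, 0.16), 1L)
    else runif(1, 0.08, 0.3)
  })
  times <- cumsum(isis)
  spike_train(paste0("r", seed), times, 0, ceiling(max(times)) + 1)
}

# Evenly spaced grid train at a given rate
grid_train <- function(rate_hz, duration_s, id = "grid") {
  times <- seq(1 / rate_hz, duration_s, by = 1 / rate_hz)
  times <- times[times < duration_s]
  spike_train(id, times, 0, duration_s)
}

poisson_train <- function(rate_hz, duration_s, seed, id = "pois") {
  set.seed(seed)
  n <- rpois(1L, rate_hz * duration_s)
  spike_train(id, sort(runif(n, 0, duration_s)), 0, duration_s)
}

# rate_series with known values, for testing the response extraction
# without going through a spike train
make_rate_series <- function(centers, values, window_s = 60, step_s = 15,
                             kind = "rate") {
  structure(data.frame(center = centers, value = values),
            window_s = window_s, step_s = step_s, kind = kind,
            class = c("rate_series", "data.frame"))
}

# one all-control cohort's absolute indices, for threshold construction
control_abs_indices <- function(n, schedule, seed, spec = NULL) {
  if (is.null(spec)) spec <- default_neuron_specs()$control
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  sapply(seq_len(n), function(i) {
    tr <- simulate_train(spec, schedule, max(schedule$t_off),
                         seed = seeds[i])
    f <- epoch_frequencies(tr, schedule)
    abs(photoswitching_index(f[["f_520"]], f[["f_390"]]))
  })
}
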