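# Synthetic-data generator. Every input the pipeline consumes can be
# produced here with the statistical structure the analyses assume:
# bistable cis/trans photoswitch kinetics, light-modulated gamma-renewal
# bursting spike trains, nicotine-evoked firing transients,
# occupancy-conditioned arena trajectories and paired current
# amplitudes. All randomness flows from one explicit seed; per-neuron
# sub-seeds are drawn once from the master stream so cohorts are
# reproducible element by element.

# ---- photoswitch state -----------------------------------------------------

#' Cis-fraction trajectory of the tethered photoswitch
#'
#' Piecewise kinetics of the photoswitch's cis (antagonizing) fraction
#' over a light schedule: a 390 nm epoch drives the fraction to 1
#' instantaneously at epoch onset and holds it; a 520 nm epoch relaxes
#' it toward 0 exponentially with time constant `relief_s` (relief from
#' antagonism is sub-second); darkness relaxes it thermally with
#' half-life `t_half_min` (tens of minutes — the bistable memory that
#' removes any need for constant illumination). Periods not covered by
#' an epoch count as darkness.
#'
#' @param schedule a [light_schedule()]; may contain dark epochs.
#' @param t_half_min thermal cis->trans half-life in darkness, minutes
#'   (default 74).
#' @param relief_s time constant of relief under 520 nm, seconds
#'   (default 0.5).
#' @param cis0 cis fraction at time zero (default 0, fully functional).
#' @return a `photoswitch_state` object; evaluate with
#'   [cis_fraction()].
#' @examples
#' sched <- light_schedule(0, 10, 390)
#' st <- photoswitch_state(sched)
#' cis_fraction(st, c(5, 10 + 74 * 60)) # 1 during the flash, 0.5 later
#' @export
photoswitch_state <- function(schedule, t_half_min = 74, relief_s = 0.5,
                              cis0 = 0) {
  stopifnot(t_half_min > 0, relief_s > 0, cis0 >= 0, cis0 <= 1)
  lambda_dark <- log(2) / (t_half_min * 60) # 1/s
  # breakpoints: 0, every epoch boundary
  brk <- sort(unique(c(0, schedule$t_on, schedule$t_off)))
  brk <- brk[brk >= 0]
  seg_mode <- character(0); seg_t0 <- numeric(0); seg_cis0 <- numeric(0)
  cis <- cis0
  for (i in seq_along(brk)) {
    t0 <- brk[i]
    t1 <- if (i < length(brk)) brk[i + 1L] else Inf
    hit <- which(schedule$t_on <= t0 & schedule$t_off > t0)
    mode <- if (length(hit)) {
      w <- schedule$wavelength[hit[1L]]
      if (w == "390") "hold" else if (w == "520") "relief" else "dark"
    } else "dark"
    if (mode == "hold") cis <- 1
    seg_mode <- c(seg_mode, mode)
    seg_t0 <- c(seg_t0, t0)
    seg_cis0 <- c(seg_cis0, cis)
    # value at end of segment becomes the start of the next
    if (is.finite(t1)) {
      dt <- t1 - t0
      cis <- switch(mode,
                    hold = 1,
                    relief = cis * exp(-dt / relief_s),
                    dark = cis * exp(-lambda_dark * dt))
    }
  }
  structure(
    list(t0 = seg_t0, cis0 = seg_cis0, mode = seg_mode,
         t_half_min = t_half_min, relief_s = relief_s,
         lambda_dark = lambda_dark),
    class = "photoswitch_state"
  )
}

#' Evaluate the cis fraction at given times
#'
#' @param state a [photoswitch_state()].
#' @param t numeric vector of times, s (times before zero evaluate to
#'   the initial fraction).
#' @return cis fraction in `[0, 1]`, same length as `t`.
#' @export
cis_fraction <- function(state, t) {
  idx <- findInterval(t, state$t0)
  idx[idx < 1L] <- 1L
  dt <- pmax(t - state$t0[idx], 0)
  c0 <- state$cis0[idx]
  mode <- state$mode[idx]
  out <- numeric(length(t))
  out[mode == "hold"] <- 1
  rel <- mode == "relief"
  out[rel] <- c0[rel] * exp(-dt[rel] / state$relief_s)
  drk <- mode == "dark"
  out[drk] <- c0[drk] * exp(-state$lambda_dark * dt[drk])
  out
}

# ---- neuron specifications -------------------------------------------------

#' Generative specification of one simulated neuron
#'
#' Parameters of the two-state (tonic + burst) point process. Tonic
#' firing is a gamma-renewal process (shape `isi_shape`, so ISI CV =
#' `1/sqrt(isi_shape)`); bursts are entered as a Poisson process at
#' `burst_rate_min` per minute and emit `burst_size_range` spikes with
#' intra-burst ISIs drawn from `intra_isi_s` (all below the 80 ms burst
#' criterion). Under the cis (390 nm-driven) state the tonic and
#' burst-entry rates are both multiplied by `m_390`: below 1 for type 1
#' phenotypes (antagonism removes an excitatory cholinergic drive),
#' above 1 for type 2 (antagonism removes an inhibitory drive), exactly
#' 1 for controls and non-responders.
#'
#' @param type one of `"control"`, `"nonresponder"`, `"type1"`,
#'   `"type2"`.
#' @param tonic_rate_hz tonic firing rate under the functional (trans)
#'   state, Hz; 1-10 Hz for pDA-like specs.
#' @param m_390 rate multiplier under the cis state (> 0).
#' @param isi_shape gamma shape of tonic ISIs (default 10, CV ~ 0.32 —
#'   regular pacemaker-like firing).
#' @param burst_rate_min burst-entry rate, bursts per minute.
#' @param burst_size_range integer range of spikes per burst.
#' @param intra_isi_s range of intra-burst ISIs, seconds (must stay
#'   below 0.08).
#' @param rebound_amp,rebound_tau_s optional transient rate boost after
#'   cis->trans relief (amplitude as a fraction of the tonic rate, decay
#'   time constant in s); 0 disables it (the default).
#' @return a `neuron_spec` list.
#' @export
neuron_spec <- function(type = c("control", "nonresponder", "type1",
                                 "type2"),
                        tonic_rate_hz = 4.5, m_390 = 1, isi_shape = 10,
                        burst_rate_min = 1.5, burst_size_range = c(3L, 6L),
                        intra_isi_s = c(0.025, 0.07),
                        rebound_amp = 0, rebound_tau_s = 1) {
  type <- match.arg(type)
  if (m_390 <= 0 || tonic_rate_hz * m_390 <= 0)
    stop("neuron_spec: rate multiplied to <= 0", call. = FALSE)
  if (type %in% c("control", "nonresponder") && m_390 != 1)
    stop("neuron_spec: control/nonresponder specs must have m_390 = 1",
         call. = FALSE)
  if (type == "type1" && m_390 >= 1)
    stop("neuron_spec: type1 requires m_390 < 1", call. = FALSE)
  if (type == "type2" && m_390 <= 1)
    stop("neuron_spec: type2 requires m_390 > 1", call. = FALSE)
  stopifnot(max(intra_isi_s) < 0.08, isi_shape > 0, burst_rate_min >= 0)
  structure(
    list(type = type, tonic_rate_hz = tonic_rate_hz, m_390 = m_390,
         isi_shape = isi_shape, burst_rate_min = burst_rate_min,
         burst_size_range = as.integer(burst_size_range),
         intra_isi_s = intra_isi_s,
         rebound_amp = rebound_amp, rebound_tau_s = rebound_tau_s),
    class = "neuron_spec"
  )
}

#' Default per-class generator specifications
#'
#' The shipped effect sizes are traceable to the reported group means of
#' the in vivo recordings: type 1 neurons fire ~3.41 Hz under 520 nm and
#' ~1.85 Hz under 390 nm (multiplier 1.85/3.41 ~ 0.54); type 2 fire
#' ~3.48 Hz under 520 nm and ~5.25 Hz under 390 nm (multiplier
#' 5.25/3.48 ~ 1.51). Controls and non-responders are light-independent
#' at a mid-range tonic rate.
#'
#' @return named list of [neuron_spec()]s
#'   (`control`, `nonresponder`, `type1`, `type2`).
#' @export
default_neuron_specs <- function() {
  list(
    control = neuron_spec("control", tonic_rate_hz = 4.5, m_390 = 1),
    nonresponder = neuron_spec("nonresponder", tonic_rate_hz = 4.5,
                               m_390 = 1),
    type1 = neuron_spec("type1", tonic_rate_hz = 3.41,
                        m_390 = 1.85 / 3.41),
    type2 = neuron_spec("type2", tonic_rate_hz = 3.48,
                        m_390 = 5.25 / 3.48)
  )
}

#' Standard alternating-flash schedule
#'
#' A dark baseline followed by alternating 5 s flashes of 390 and
#' 520 nm light.
#'
#' @param n_cycles number of 390/520 alternation cycles (default 20).
#' @param epoch_s flash duration, s (default 5).
#' @param baseline_dark_s dark baseline before the first flash, s
#'   (default 200).
#' @param first wavelength of the first flash (default `"390"`).
#' @return a [light_schedule()].
#' @export
default_schedule <- function(n_cycles = 20, epoch_s = 5,
                             baseline_dark_s = 200, first = "390") {
  other <- if (first == "390") "520" else "390"
  n_ep <- 2L * n_cycles
  on <- baseline_dark_s + (seq_len(n_ep) - 1L) * epoch_s
  w <- rep(c(first, other), n_cycles)
  if (baseline_dark_s > 0) {
    on <- c(0, on); off <- c(baseline_dark_s, on[-1L] + epoch_s)
    w <- c("dark", w)
  } else off <- on + epoch_s
  light_schedule(on, off, w)
}

# ---- spike-train simulation ------------------------------------------------

# instantaneous rate multiplier on a time grid: binary gate on cis state
.gate_multiplier <- function(spec, state, tg) {
  if (is.null(state)) return(rep(1, length(tg)))
  cis <- cis_fraction(state, tg)
  m <- ifelse(cis > 0.5, spec$m_390, 1)
  if (spec$rebound_amp > 0) {
    # transient boost after each relief (cis falling through 0.5)
    drops <- which(diff(cis > 0.5) == -1L)
    for (d in drops) {
      dt <- tg - tg[d]
      m <- m * (1 + spec$rebound_amp * exp(-pmax(dt, 0) /
                                             spec$rebound_tau_s) *
                  (dt >= 0))
    }
  }
  m
}

# gamma-renewal spikes by time rescaling of the cumulative intensity
.renewal_spikes <- function(tg, rate, shape) {
  dt <- diff(tg)
  Lambda <- c(0, cumsum(rate[-length(rate)] * dt))
  total <- Lambda[length(Lambda)]
  if (total <= 0) return(numeric(0))
  n_draw <- max(20L, ceiling(total + 10 * sqrt(total)))
  op <- cumsum(stats::rgamma(n_draw, shape = shape, rate = shape))
  while (op[length(op)] < total)
    op <- c(op, op[length(op)] +
              cumsum(stats::rgamma(n_draw, shape = shape, rate = shape)))
  op <- op[op < total]
  if (!length(op)) return(numeric(0))
  stats::approx(Lambda, tg, xout = op, ties = "ordered")$y
}

#' Simulate a light-modulated bursting spike train
#'
#' Two-state point process: tonic gamma-renewal firing at
#' `tonic_rate_hz` times the light gate, superimposed with bursts whose
#' entries form a Poisson process (also gated) and whose spikes have
#' sub-80 ms intra-burst ISIs. A 2 ms absolute refractory period is
#' enforced after merging. Fully reproducible under `seed`.
#'
#' @param spec a [neuron_spec()].
#' @param schedule optional [light_schedule()]; `NULL` means constant
#'   darkness with a fully functional (trans) receptor.
#' @param duration_s recording duration, s (must cover the schedule).
#' @param seed integer seed.
#' @param neuron_id id for the resulting train.
#' @param dt simulation grid step, s (default 0.005).
#' @param t_half_min,relief_s,cis0 photoswitch kinetics, see
#'   [photoswitch_state()].
#' @return a [spike_train()] over `[0, duration_s]`.
#' @export
simulate_train <- function(spec, schedule = NULL, duration_s = 400,
                           seed = 1L, neuron_id = "sim", dt = 0.005,
                           t_half_min = 74, relief_s = 0.5, cis0 = 0) {
  stopifnot(inherits(spec, "neuron_spec"), duration_s > 0)
  if (!is.null(schedule) && max(schedule$t_off) > duration_s + 1e-9)
    stop("simulate_train: duration does not cover the schedule",
         call. = FALSE)
  set.seed(as.integer(seed))
  state <- if (!is.null(schedule))
    photoswitch_state(schedule, t_half_min, relief_s, cis0)
  tg <- seq(0, duration_s, by = dt)
  mult <- .gate_multiplier(spec, state, tg)
  tonic <- .renewal_spikes(tg, spec$tonic_rate_hz * mult, spec$isi_shape)
  # burst entries: thinned Poisson at the gated rate
  burst_spikes <- numeric(0)
  if (spec$burst_rate_min > 0) {
    max_rate <- spec$burst_rate_min / 60 * max(mult)
    n_cand <- stats::rpois(1L, max_rate * duration_s)
    if (n_cand > 0) {
      cand <- sort(stats::runif(n_cand, 0, duration_s))
      m_at <- stats::approx(tg, mult, xout = cand, rule = 2)$y
      keep <- stats::runif(n_cand) < (spec$burst_rate_min / 60 * m_at) /
        max_rate
      entries <- cand[keep]
      for (tb in entries) {
        size <- sample(seq(spec$burst_size_range[1L],
                           spec$burst_size_range[2L]), 1L)
        isis <- stats::runif(size - 1L, spec$intra_isi_s[1L],
                             spec$intra_isi_s[2L])
        burst_spikes <- c(burst_spikes, tb + c(0, cumsum(isis)))
      }
    }
  }
  times <- sort(c(tonic, burst_spikes))
  times <- times[times >= 0 & times <= duration_s]
  # 2 ms absolute refractory period
  if (length(times) > 1L) {
    keep <- c(TRUE, diff(times) >= 0.002)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= 0.002)
    }
  }
  spike_train(neuron_id, times, 0, duration_s)
}

# ---- cohort simulation -----------------------------------------------------

#' Simulate a multi-neuron photoswitching cohort with ground truth
#'
#' Generates `n_control` light-independent control neurons plus a
#' transduced cohort of non-responders, type 1 and type 2 neurons (the
#' default composition mirrors the reported in vivo class counts:
#' 28 controls; 93 transduced neurons of which 24 type 1, 9 type 2 and
#' 60 non-responding). All neurons share the alternating-flash
#' schedule.
#'
#' @param n_control,n_nonresponder,n_type1,n_type2 class counts.
#' @param specs named list of per-class [neuron_spec()]s (default
#'   [default_neuron_specs()]).
#' @param schedule shared [light_schedule()] (default
#'   [default_schedule()]).
#' @param duration_s recording duration (default: schedule end).
#' @param seed master seed; per-neuron sub-seeds are drawn from it once,
#'   so the i-th neuron is reproducible independently of the others.
#' @return list with `trains` (named list of [spike_train()]s),
#'   `truth` (data.frame: `neuron_id`, `cohort`, `true_class`) and
#'   `schedule`.
#' @export
simulate_cohort <- function(n_control = 28, n_nonresponder = 60,
                            n_type1 = 24, n_type2 = 9,
                            specs = default_neuron_specs(),
                            schedule = default_schedule(),
                            duration_s = NULL, seed = 1L) {
  if (is.null(duration_s)) duration_s <- max(schedule$t_off)
  classes <- rep(c("control", "nonresponder", "type1", "type2"),
                 c(n_control, n_nonresponder, n_type1, n_type2))
  n <- length(classes)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("%s_%03d", classes, stats::ave(seq_len(n), classes,
                                                FUN = seq_along))
  trains <- vector("list", n)
  for (i in seq_len(n)) {
    trains[[i]] <- simulate_train(specs[[classes[i]]], schedule,
                                  duration_s, seed = sub_seeds[i],
                                  neuron_id = ids[i])
  }
  names(trains) <- ids
  list(trains = trains,
       truth = data.frame(neuron_id = ids,
                          cohort = ifelse(classes == "control",
                                          "control", "transduced"),
                          true_class = classes,
                          stringsAsFactors = FALSE),
       schedule = schedule)
}

# ---- nicotine sessions -----------------------------------------------------

#' Nicotine response kernel
#'
#' The firing-rate transient evoked by an intravenous nicotine
#' injection: after `latency_s`, the rate is multiplied by a
#' double-exponential excursion normalized to peak at `g` (so the peak
#' percent variation is `100 * (g - 1)`), rising with `rise_s` and
#' decaying with `decay_s`. With the defaults the peak falls ~45 s after
#' the injection, well within the 200 s analysis horizon, and the
#' transient is broad relative to the 60 s analysis window. Under the
#' cis (antagonized) state the excursion `g - 1` is scaled by
#' `antagonism` — the receptor block attenuates the nicotine response.
#'
#' @param latency_s onset latency, s.
#' @param g peak rate multiplier (> 0).
#' @param rise_s,decay_s rise/decay time constants, s.
#' @param antagonism multiplicative attenuation of the excursion under
#'   cis, in `[0, 1]`.
#' @return a `nicotine_kernel` list.
#' @export
nicotine_kernel <- function(latency_s = 10, g = 2, rise_s = 10,
                            decay_s = 300, antagonism = 0.4) {
  stopifnot(g > 0, rise_s > 0, decay_s > rise_s,
            antagonism >= 0, antagonism <= 1)
  # peak location and height of the unnormalized double exponential
  s_peak <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  h_peak <- exp(-s_peak / decay_s) - exp(-s_peak / rise_s)
  structure(
    list(latency_s = latency_s, g = g, rise_s = rise_s, decay_s = decay_s,
         antagonism = antagonism, s_peak = s_peak, h_peak = h_peak),
    class = "nicotine_kernel"
  )
}

# normalized kernel shape in [0, 1]; s is time since injection
.kernel_shape <- function(kernel, s) {
  s <- s - kernel$latency_s
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- (exp(-s[pos] / kernel$decay_s) -
                 exp(-s[pos] / kernel$rise_s)) / kernel$h_peak
  out
}

#' Simulate a juxtacellular nicotine session
#'
#' Baseline tonic/burst firing (as in [simulate_train()]) whose rate is
#' multiplied, after each injection, by the nicotine kernel. The
#' effective peak multiplier of each injection depends on its light
#' condition: under `"390"` (cis, antagonized) the excursion is scaled
#' by the kernel's antagonism factor; saline injections have no kernel
#' (g = 1). The protocol applies light around the injection, so the
#' condition is carried by each [injection_event()].
#'
#' @param spec a [neuron_spec()].
#' @param kernel a [nicotine_kernel()].
#' @param injections list of [injection_event()]s, time-sorted, first
#'   one at least 300 s into the recording (the >= 5 min baseline).
#' @param duration_s recording duration, s.
#' @param seed integer seed.
#' @param neuron_id id for the train.
#' @param dt simulation grid step, s.
#' @return a [spike_train()].
#' @export
simulate_nicotine_session <- function(spec, kernel, injections,
                                      duration_s, seed = 1L,
                                      neuron_id = "sim", dt = 0.01) {
  tt <- vapply(injections, function(i) i$t, 0)
  if (is.unsorted(tt))
    stop("simulate_nicotine_session: injections must be time-sorted",
         call. = FALSE)
  if (length(tt) && tt[1L] < 300)
    stop("simulate_nicotine_session: first injection before the 5 min ",
         "baseline", call. = FALSE)
  set.seed(as.integer(seed))
  tg <- seq(0, duration_s, by = dt)
  mult <- rep(1, length(tg))
  for (inj in injections) {
    if (inj$substance == "saline") next
    a <- if (inj$light_condition == "390") kernel$antagonism else 1
    mult <- mult * (1 + a * (kernel$g - 1) * .kernel_shape(kernel,
                                                           tg - inj$t))
  }
  rate <- spec$tonic_rate_hz * mult
  tonic <- .renewal_spikes(tg, rate, spec$isi_shape)
  burst_spikes <- numeric(0)
  if (spec$burst_rate_min > 0) {
    max_rate <- spec$burst_rate_min / 60 * max(mult)
    n_cand <- stats::rpois(1L, max_rate * duration_s)
    if (n_cand > 0) {
      cand <- sort(stats::runif(n_cand, 0, duration_s))
      m_at <- stats::approx(tg, mult, xout = cand, rule = 2)$y
      keep <- stats::runif(n_cand) < (spec$burst_rate_min / 60 * m_at) /
        max_rate
      for (tb in cand[keep]) {
        size <- sample(seq(spec$burst_size_range[1L],
                           spec$burst_size_range[2L]), 1L)
        isis <- stats::runif(size - 1L, spec$intra_isi_s[1L],
                             spec$intra_isi_s[2L])
        burst_spikes <- c(burst_spikes, tb + c(0, cumsum(isis)))
      }
    }
  }
  times <- sort(c(tonic, burst_spikes))
  times <- times[times >= 0 & times <= duration_s]
  if (length(times) > 1L) {
    keep <- c(TRUE, diff(times) >= 0.002)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= 0.002)
    }
  }
  spike_train(neuron_id, times, 0, duration_s)
}

# ---- CPP cohort ------------------------------------------------------------

# frame-quantized block trajectory realizing per-zone frame counts
.build_cpp_trajectory <- function(frames_per_zone, map, session_s, fps) {
  period <- 1 / fps
  n_frames <- as.integer(round(session_s * fps))
  zones <- names(frames_per_zone)
  # alternate visits: A C B C A C B C ... sized by splitting each zone's
  # frame budget over its visits
  n_visits <- 4L
  seq_zone <- character(0)
  for (v in seq_len(n_visits))
    seq_zone <- c(seq_zone, "side_A", "center", "side_B", "center")
  alloc <- lapply(zones, function(z) {
    k <- sum(seq_zone == z)
    total <- frames_per_zone[[z]]
    base <- total %/% k
    extra <- total - base * k
    counts <- rep(base, k)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    counts
  })
  names(alloc) <- zones
  taken <- stats::setNames(rep(0L, length(zones)), zones)
  block_zone <- character(0); block_len <- integer(0)
  for (z in seq_zone) {
    taken[z] <- taken[z] + 1L
    block_zone <- c(block_zone, z)
    block_len <- c(block_len, alloc[[z]][taken[z]])
  }
  stopifnot(sum(block_len) == n_frames)
  zone_seq <- rep(block_zone, block_len)
  t <- (seq_len(n_frames) - 1L) * period
  centers <- vapply(map$zones[zone_seq], function(z)
    c((z[1] + z[2]) / 2, (z[3] + z[4]) / 2), numeric(2))
  # small within-zone jitter keeps samples strictly inside the zone
  jitter_x <- stats::runif(n_frames, -1, 1)
  jitter_y <- stats::runif(n_frames, -1, 1)
  trajectory(t, centers[1, ] + jitter_x, centers[2, ] + jitter_y,
             span_s = session_s)
}

#' Simulate a conditioned-place-preference group
#'
#' One group of animals with pretest and test trajectories over the
#' two-chamber arena at 20 frames/s. Each animal has a pretest side bias
#' drawn from `N(0, bias_sd_s)`; the test-phase paired-side occupancy
#' equals the pretest occupancy plus `conditioning_shift_s` plus session
#' noise `N(0, test_noise_sd_s)`, so the group's expected preference
#' score is exactly the conditioning shift (zero for null groups).
#' Trajectories are dwell-block walks whose per-zone frame counts
#' realize those occupancies exactly at the frame period.
#'
#' @param n_animals animals in the group.
#' @param conditioning_shift_s expected preference score, s (0 for
#'   saline/knockout-like/antagonized null groups).
#' @param bias_sd_s SD of the pretest side bias, s.
#' @param test_noise_sd_s SD of the test-session occupancy noise, s.
#' @param session_s session length, s (default 900, i.e. 15 min).
#' @param center_s expected central-compartment time per session, s.
#' @param fps sampling rate, frames/s (default 20).
#' @param map a [zone_map()]; pairing alternates across animals so the
#'   drug is not always paired to the same chamber.
#' @param seed master seed.
#' @return list with `animals`: per animal a list holding `animal_id`,
#'   `paired_side`, `pretest`/`test` [trajectory()]s and scored
#'   [cpp_session()]s; plus `truth` (data.frame with the generating
#'   bias and shift per animal).
#' @export
simulate_cpp_cohort <- function(n_animals = 8, conditioning_shift_s = 0,
                                bias_sd_s = 60, test_noise_sd_s = 60,
                                session_s = 900, center_s = 120, fps = 20,
                                map = default_zone_map(), seed = 1L) {
  if (abs(conditioning_shift_s) >= session_s)
    stop("simulate_cpp_cohort: conditioning shift exceeds the session ",
         "length", call. = FALSE)
  set.seed(as.integer(seed))
  period <- 1 / fps
  n_frames <- as.integer(round(session_s * fps))
  center_frames <- as.integer(round(center_s * fps))
  side_frames_total <- n_frames - center_frames
  animals <- vector("list", n_animals)
  truth <- data.frame(animal_id = character(0), paired_side = character(0),
                      bias_s = numeric(0), shift_s = numeric(0))
  for (i in seq_len(n_animals)) {
    id <- sprintf("m%02d", i)
    paired <- if (i %% 2L) "side_A" else "side_B"
    unpaired <- setdiff(c("side_A", "side_B"), paired)
    amap <- zone_map(map$zones, paired_side = paired)
    bias <- stats::rnorm(1, 0, bias_sd_s)
    noise <- stats::rnorm(1, 0, test_noise_sd_s)
    half <- side_frames_total / 2
    pre_paired <- as.integer(round(half + bias * fps))
    pre_paired <- min(max(pre_paired, 1L), side_frames_total - 1L)
    test_paired <- as.integer(round(pre_paired +
                                      (conditioning_shift_s + noise) * fps))
    test_paired <- min(max(test_paired, 1L), side_frames_total - 1L)
    mk <- function(paired_frames) {
      fpz <- stats::setNames(
        list(0L, 0L, center_frames),
        c(paired, unpaired, "center"))
      fpz[[paired]] <- paired_frames
      fpz[[unpaired]] <- side_frames_total - paired_frames
      .build_cpp_trajectory(fpz[c("side_A", "center", "side_B")], amap,
                            session_s, fps)
    }
    pre_traj <- mk(pre_paired)
    test_traj <- mk(test_paired)
    pre_sess <- cpp_session(id, "pretest", occupancy(pre_traj, amap),
                            paired, session_s)
    test_sess <- cpp_session(id, "test", occupancy(test_traj, amap),
                             paired, session_s)
    animals[[i]] <- list(animal_id = id, paired_side = paired,
                         pretest_trajectory = pre_traj,
                         test_trajectory = test_traj,
                         pretest = pre_sess, test = test_sess)
    truth <- rbind(truth,
                   data.frame(animal_id = id, paired_side = paired,
                              bias_s = (pre_paired - half) * period,
                              shift_s = (test_paired - pre_paired) * period))
  }
  list(animals = animals, truth = truth)
}

# ---- current pairs ---------------------------------------------------------

#' Simulate paired photo-inhibition current measurements
#'
#' Paired evoked-current amplitudes (inward, negative) per cell such
#' that the expected photo-inhibition index is
#' `100 * true_inhibition_fraction`: the 380 nm amplitude is the 525 nm
#' amplitude scaled by `(1 - fraction)` with mean-one multiplicative
#' noise of coefficient of variation `noise_cv`.
#'
#' @param n_cells number of cells.
#' @param true_inhibition_fraction generating inhibition fraction in
#'   `[-1, 1]`.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed integer seed.
#' @param mean_amplitude_pa mean 525 nm amplitude magnitude, pA.
#' @return list of [current_measurement()]s.
#' @export
simulate_current_pairs <- function(n_cells, true_inhibition_fraction,
                                   noise_cv = 0.1, seed = 1L,
                                   mean_amplitude_pa = 100) {
  stopifnot(true_inhibition_fraction >= -1, true_inhibition_fraction <= 1,
            noise_cv >= 0)
  set.seed(as.integer(seed))
  i525 <- -mean_amplitude_pa * exp(stats::rnorm(n_cells, 0, 0.25))
  eta <- 1 + noise_cv * stats::rnorm(n_cells)
  eta <- pmax(eta, 1e-3)
  i380 <- i525 * (1 - true_inhibition_fraction) * eta
  lapply(seq_len(n_cells), function(i)
    current_measurement(sprintf("c%03d", i), i380[i], i525[i]))
}
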