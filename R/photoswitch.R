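# Photoswitching analysis: per-wavelength epoch firing frequencies, the
# photoswitching index, control-derived responder thresholds, and
# type 1 / type 2 classification.
#
# Sign convention: the index is 100 * (f_520 - f_390) / f_390, so a
# positive index means firing is higher under 520 nm (functional
# receptor) than under 390 nm (antagonized). Type 1 neurons (firing
# reduced by antagonism) therefore have positive indices; type 2
# (firing increased under 390 nm) negative.

# spikes falling in epochs of one wavelength, via half-open [on, off)
.spikes_in_epochs <- function(times, schedule, wavelength) {
  ep <- schedule[schedule$wavelength == wavelength, , drop = FALSE]
  if (!nrow(ep)) return(logical(length(times)))
  sel <- logical(length(times))
  for (k in seq_len(nrow(ep)))
    sel <- sel | (times >= ep$t_on[k] & times < ep$t_off[k])
  sel
}

#' Pooled firing frequency per illumination wavelength
#'
#' For each wavelength, the pooled estimate: total spikes falling inside
#' all epochs of that wavelength divided by the total duration of those
#' epochs. Pooling is robust at the low counts a 5 s flash yields; a
#' per-transition variant is available via [per_transition_index()].
#'
#' @param train a [spike_train()].
#' @param schedule a [light_schedule()] containing at least one 390 nm
#'   and one 520 nm epoch.
#' @return named numeric vector `c(f_390 = , f_520 = )`, Hz.
#' @export
epoch_frequencies <- function(train, schedule) {
  for (w in c("390", "520"))
    if (!any(schedule$wavelength == w))
      stop("epoch_frequencies: schedule has no ", w, " nm epoch",
           call. = FALSE)
  dur <- epoch_durations(schedule)
  c(f_390 = sum(.spikes_in_epochs(train$times, schedule, "390")) /
      dur[["390"]],
    f_520 = sum(.spikes_in_epochs(train$times, schedule, "520")) /
      dur[["520"]])
}

#' Photoswitching index
#'
#' Percent change in firing frequency between the 520 nm and 390 nm
#' illumination conditions: `100 * (f_520 - f_390) / f_390`.
#'
#' @param f_520,f_390 pooled firing frequencies, Hz; `f_390` must be
#'   positive (a silent 390 nm condition leaves the index undefined —
#'   recompute the frequencies over a longer span instead).
#' @return signed percent.
#' @examples
#' photoswitching_index(3.41, 1.85) # firing lower under 390 nm
#' @export
photoswitching_index <- function(f_520, f_390) {
  if (f_390 <= 0)
    stop("photoswitching_index: undefined for f_390 = 0; pool more epochs",
         call. = FALSE)
  100 * (f_520 - f_390) / f_390
}

#' Per-transition photoswitching index (sensitivity variant)
#'
#' Instead of pooling all epochs, computes the index at each violet-to-
#' green transition from the two flanking epochs and averages; provided
#' for sensitivity analysis of the pooling choice.
#'
#' @param train a [spike_train()].
#' @param schedule a [light_schedule()] with alternating 390/520 epochs.
#' @return mean of per-transition indices (transitions whose 390-side
#'   rate is zero are dropped), signed percent; `NA` if no transition is
#'   usable.
#' @export
per_transition_index <- function(train, schedule) {
  idx <- which(schedule$wavelength == "390")
  vals <- numeric(0)
  for (i in idx) {
    if (i + 1L > nrow(schedule) || schedule$wavelength[i + 1L] != "520")
      next
    f390 <- sum(train$times >= schedule$t_on[i] &
                  train$times < schedule$t_off[i]) /
      (schedule$t_off[i] - schedule$t_on[i])
    f520 <- sum(train$times >= schedule$t_on[i + 1L] &
                  train$times < schedule$t_off[i + 1L]) /
      (schedule$t_off[i + 1L] - schedule$t_on[i + 1L])
    if (f390 > 0) vals <- c(vals, 100 * (f520 - f390) / f390)
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Responder threshold from a control cohort
#'
#' The responder threshold is the absolute-photoswitching level that
#' excludes a stated fraction of control neurons: the empirical quantile
#' (linear interpolation between order statistics, `quantile type 7`) of
#' the controls' absolute indices at `exclusion_fraction`. A fixed
#' threshold (15% is the conventional value) can be requested instead.
#'
#' @param control_abs_indices absolute photoswitching indices (percent)
#'   of control neurons; at least 5 values for the quantile method.
#' @param exclusion_fraction fraction of controls to exclude (default
#'   0.95).
#' @param method `"control_quantile"` (default) or `"fixed"`.
#' @param fixed_value threshold used when `method = "fixed"` (default
#'   15).
#' @return A `threshold_spec`: list with `value` (percent), `method`,
#'   `exclusion_fraction`.
#' @export
control_threshold <- function(control_abs_indices,
                              exclusion_fraction = 0.95,
                              method = c("control_quantile", "fixed"),
                              fixed_value = 15) {
  method <- match.arg(method)
  stopifnot(exclusion_fraction > 0, exclusion_fraction < 1)
  if (method == "fixed") {
    value <- fixed_value
  } else {
    if (length(control_abs_indices) < 5L)
      stop("control_threshold: need >= 5 control values for the quantile ",
           "method; consider method = 'fixed' (15%)", call. = FALSE)
    value <- unname(stats::quantile(abs(control_abs_indices),
                                    probs = exclusion_fraction, type = 7))
  }
  structure(
    list(value = value, method = method,
         exclusion_fraction = exclusion_fraction),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %.2f%% absolute photoswitching (%s, exclusion %.2f)\n",
              x$value, x$method, x$exclusion_fraction))
  invisible(x)
}

#' Classify a neuron from its photoswitching index
#'
#' Neurons whose absolute index reaches the threshold (>= rule: a neuron
#' sitting exactly at the threshold counts as responding) are split by
#' sign: positive index (firing lower under 390 nm) is type 1, negative
#' index (firing higher under 390 nm) is type 2; the rest are
#' non-responders.
#'
#' @param index signed photoswitching index, percent.
#' @param threshold a `threshold_spec` from [control_threshold()] or a
#'   bare number (percent).
#' @return one of `"nonresponder"`, `"type1"`, `"type2"`.
#' @export
classify_neuron <- function(index, threshold) {
  thr <- if (inherits(threshold, "threshold_spec")) threshold$value
         else as.numeric(threshold)
  if (abs(index) < thr) "nonresponder"
  else if (index > 0) "type1"
  else "type2"
}

#' Spikes-within-bursts frequency per wavelength
#'
#' Over the short (5 s) analysis epochs, bursting is reported as the
#' frequency of spikes within bursts (SWB): per wavelength, the count of
#' SWB falling in that wavelength's epochs divided by the total epoch
#' duration.
#'
#' @param train a [spike_train()].
#' @param bursts its `burst_set` from [detect_bursts()].
#' @param schedule a [light_schedule()] with both wavelengths.
#' @return named vector `c(swb_freq_390 = , swb_freq_520 = )`, Hz.
#' @export
swb_frequency_by_epoch <- function(train, bursts, schedule) {
  if (bursts$n_spikes != length(train$times))
    stop("swb_frequency_by_epoch: bursts were not produced from this train",
         call. = FALSE)
  for (w in c("390", "520"))
    if (!any(schedule$wavelength == w))
      stop("swb_frequency_by_epoch: schedule has no ", w, " nm epoch",
           call. = FALSE)
  dur <- epoch_durations(schedule)
  mask <- .swb_mask(bursts)
  swb_times <- train$times[mask]
  c(swb_freq_390 = sum(.spikes_in_epochs(swb_times, schedule, "390")) /
      dur[["390"]],
    swb_freq_520 = sum(.spikes_in_epochs(swb_times, schedule, "520")) /
      dur[["520"]])
}

#' Full photoswitch work-up of one neuron
#'
#' Convenience wrapper: epoch frequencies, signed and absolute index,
#' SWB frequencies per wavelength, and the class label.
#'
#' @param train a [spike_train()].
#' @param schedule a [light_schedule()].
#' @param threshold a `threshold_spec` or number (percent).
#' @param onset_ms,close_ms burst criteria passed to [detect_bursts()].
#' @return A one-row data.frame (class `photoswitch_result`) with
#'   columns `neuron_id`, `f_390`, `f_520`, `index`, `abs_index`,
#'   `swb_freq_390`, `swb_freq_520`, `label`.
#' @export
photoswitch_result <- function(train, schedule, threshold,
                               onset_ms = 80, close_ms = 160) {
  f <- epoch_frequencies(train, schedule)
  idx <- photoswitching_index(f[["f_520"]], f[["f_390"]])
  bursts <- detect_bursts(train, onset_ms, close_ms)
  swb <- swb_frequency_by_epoch(train, bursts, schedule)
  structure(
    data.frame(neuron_id = train$neuron_id,
               f_390 = f[["f_390"]], f_520 = f[["f_520"]],
               index = idx, abs_index = abs(idx),
               swb_freq_390 = swb[["swb_freq_390"]],
               swb_freq_520 = swb[["swb_freq_520"]],
               label = classify_neuron(idx, threshold),
               stringsAsFactors = FALSE),
    class = c("photoswitch_result", "data.frame")
  )
}

#' Photoswitch results for a whole cohort
#'
#' @param trains list of [spike_train()]s.
#' @param schedule shared [light_schedule()].
#' @param threshold a `threshold_spec` or number (percent).
#' @param ... passed to [photoswitch_result()].
#' @return data.frame, one row per neuron.
#' @export
photoswitch_table <- function(trains, schedule, threshold, ...) {
  out <- do.call(rbind, lapply(trains, photoswitch_result,
                               schedule = schedule, threshold = threshold,
                               ...))
  rownames(out) <- NULL
  out
}

#' Compare control and transduced cohorts
#'
#' Per-cohort mean and SEM of the absolute photoswitching index, the
#' responder fraction at the given threshold, and a two-sample
#' Kolmogorov-Smirnov comparison of the absolute-index distributions
#' (the cumulative-distribution contrast used to establish that
#' transduced neurons photoswitch).
#'
#' @param control_abs,transduced_abs absolute indices (percent) per
#'   cohort, both non-empty.
#' @param threshold a `threshold_spec` or number (percent).
#' @return list with `summary` (data.frame: cohort, n, mean_abs_index,
#'   sem_abs_index, responder_fraction) and `ks` (a `test_result` from
#'   [ks_two_sample()]).
#' @export
cohort_compare <- function(control_abs, transduced_abs, threshold) {
  stopifnot(length(control_abs) > 0, length(transduced_abs) > 0)
  thr <- if (inherits(threshold, "threshold_spec")) threshold$value
         else as.numeric(threshold)
  one <- function(name, x) data.frame(
    cohort = name, n = length(x),
    mean_abs_index = mean(x),
    sem_abs_index = stats::sd(x) / sqrt(length(x)),
    responder_fraction = mean(x >= thr)
  )
  list(summary = rbind(one("control", control_abs),
                       one("transduced", transduced_abs)),
       ks = ks_two_sample(control_abs, transduced_abs))
}
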