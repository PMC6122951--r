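# Pharmacological read-outs: photo-inhibition of agonist-evoked
# currents, and the magnitude of nicotine-evoked firing changes under
# different light conditions.

#' Photo-inhibition index of an evoked current
#'
#' Fractional suppression of an agonist-evoked current under the
#' antagonizing wavelength: `100 * (1 - I_380 / I_525)`. Both amplitudes
#' must use the same sign convention (inward currents negative); the
#' index is invariant to rescaling both by any positive factor. Negative
#' values (current larger under 380 nm) indicate potentiation and are
#' returned with their sign.
#'
#' @param i_380 current amplitude under 380 nm light, pA.
#' @param i_525 current amplitude under 525 nm light, pA; non-zero.
#' @return percent photo-inhibition.
#' @examples
#' photoinhibition_index(-33, -100) # 67% suppression
#' @export
photoinhibition_index <- function(i_380, i_525) {
  if (i_525 == 0)
    stop("photoinhibition_index: undefined for i_525 = 0", call. = FALSE)
  if (i_380 != 0 && sign(i_380) != sign(i_525))
    stop("photoinhibition_index: amplitudes of opposite sign ",
         "(artifactual trace?)", call. = FALSE)
  100 * (1 - i_380 / i_525)
}

#' Current-pair measurement record
#'
#' @param cell_id cell identifier.
#' @param amplitude_380,amplitude_525 evoked current amplitudes, pA
#'   (inward negative).
#' @param agonist agonist name (e.g. `"nicotine"`).
#' @param concentration agonist concentration, micromolar (> 0).
#' @return a `current_measurement` list.
#' @export
current_measurement <- function(cell_id, amplitude_380, amplitude_525,
                                agonist = "nicotine", concentration = 30) {
  stopifnot(is.finite(amplitude_380), is.finite(amplitude_525),
            concentration > 0)
  structure(
    list(cell_id = cell_id, amplitude_380 = amplitude_380,
         amplitude_525 = amplitude_525, agonist = agonist,
         concentration = concentration),
    class = "current_measurement"
  )
}

#' Per-cell photo-inhibition table
#' @param measurements list of [current_measurement()]s.
#' @return data.frame with `cell_id`, `index` (percent).
#' @export
photoinhibition_table <- function(measurements) {
  data.frame(
    cell_id = vapply(measurements, function(m) as.character(m$cell_id), ""),
    index = vapply(measurements, function(m)
      photoinhibition_index(m$amplitude_380, m$amplitude_525), 0)
  )
}

# ---- nicotine responses ----------------------------------------------------

# windows of a rate_series: onset = center - w/2, end = center + w/2
.series_onsets <- function(series) series$center - attr(series, "window_s") / 2
.series_ends <- function(series) series$center + attr(series, "window_s") / 2

#' Pre-injection baseline rate
#'
#' Mean of the sliding-window values whose windows end within
#' `[t - baseline_span_s, t)`, where `t` is the injection time. The
#' protocol guarantees a pre-injection baseline of at least 5 min; the
#' default uses its last 180 s.
#'
#' @param series a `rate_series` from [sliding_series()].
#' @param injection an [injection_event()] (or a bare time in seconds).
#' @param baseline_span_s span before the injection over which windows
#'   are averaged (default 180).
#' @return baseline value (same units as the series).
#' @export
baseline_rate <- function(series, injection, baseline_span_s = 180) {
  t_inj <- if (inherits(injection, "injection_event")) injection$t
           else as.numeric(injection)
  ends <- .series_ends(series)
  sel <- ends > t_inj - baseline_span_s & ends <= t_inj
  if (!any(sel))
    stop("baseline_rate: no complete window ends within the baseline span ",
         "before the injection", call. = FALSE)
  mean(series$value[sel])
}

#' Maximum firing variation after an injection
#'
#' The percent variation from baseline,
#' `100 * (value - baseline) / baseline`, of largest absolute magnitude
#' among sliding windows starting within `horizon_s` of the injection
#' (default 200 s); the sign is preserved, so nicotine-evoked
#' inhibitions come out negative and excitations positive.
#'
#' @param series a `rate_series`.
#' @param injection an [injection_event()] or time (s).
#' @param horizon_s post-injection search horizon, s.
#' @param baseline_span_s passed to [baseline_rate()].
#' @return signed percent; attribute `"partial"` is `TRUE` when the
#'   series ends before the horizon and the search was truncated.
#' @export
response_magnitude <- function(series, injection, horizon_s = 200,
                               baseline_span_s = 180) {
  t_inj <- if (inherits(injection, "injection_event")) injection$t
           else as.numeric(injection)
  base <- baseline_rate(series, t_inj, baseline_span_s)
  if (base <= 0)
    stop("response_magnitude: zero baseline; variation undefined",
         call. = FALSE)
  onsets <- .series_onsets(series)
  sel <- onsets >= t_inj & onsets < t_inj + horizon_s
  if (!any(sel))
    stop("response_magnitude: no window starts within the horizon",
         call. = FALSE)
  partial <- max(.series_ends(series)) < t_inj + horizon_s
  vari <- 100 * (series$value[sel] - base) / base
  out <- vari[which.max(abs(vari))]
  attr(out, "partial") <- partial
  out
}

#' Normalize a light-condition response to the dark response
#'
#' Responses measured under 390 or 520 nm are expressed as a percentage
#' of the same neuron's response in darkness.
#'
#' @param resp_light,resp_dark response magnitudes, signed percent;
#'   `resp_dark` non-zero.
#' @return percent of the dark response.
#' @export
normalize_to_dark <- function(resp_light, resp_dark) {
  if (resp_dark == 0)
    stop("normalize_to_dark: undefined for a zero dark response",
         call. = FALSE)
  100 * resp_light / resp_dark
}

#' Nicotine-evoked change in bursting (%SWB)
#'
#' Same extremum-of-variation contract as [response_magnitude()],
#' applied to the %SWB sliding series. Only neurons with spontaneous
#' baseline bursting are analysable: a neuron with no burst in the
#' baseline span is flagged `not_bursting` and excluded.
#'
#' @param train a [spike_train()].
#' @param bursts its `burst_set`.
#' @param injection an [injection_event()] or time (s).
#' @param horizon_s post-injection search horizon, s.
#' @param window_s,step_s sliding-window parameters.
#' @param baseline_span_s baseline span, s.
#' @return signed percent, or `NA` with attribute `excluded = TRUE` for
#'   a non-bursting neuron.
#' @export
swb_response <- function(train, bursts, injection, horizon_s = 200,
                         window_s = 60, step_s = 15,
                         baseline_span_s = 180) {
  t_inj <- if (inherits(injection, "injection_event")) injection$t
           else as.numeric(injection)
  bt <- burst_table(train, bursts)
  if (!any(bt$start_s < t_inj)) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    return(out)
  }
  series <- sliding_series(train, bursts, window_s = window_s,
                           step_s = step_s, kind = "pct_swb")
  response_magnitude(series, t_inj, horizon_s, baseline_span_s)
}

#' Analyse all injections of a session
#'
#' Runs [response_magnitude()] per injection, independently; warns when
#' the firing has not returned to within 20% of the previous baseline by
#' the next injection (refractory check).
#'
#' @param train a [spike_train()].
#' @param injections list of [injection_event()]s, time-sorted.
#' @param window_s,step_s sliding-window parameters.
#' @param horizon_s,baseline_span_s see [response_magnitude()].
#' @return data.frame with one row per injection: `t`, `substance`,
#'   `light_condition`, `baseline_hz`, `peak_variation`.
#' @export
nicotine_session_table <- function(train, injections, window_s = 60,
                                   step_s = 15, horizon_s = 200,
                                   baseline_span_s = 180) {
  series <- sliding_series(train, window_s = window_s, step_s = step_s,
                           kind = "rate")
  rows <- lapply(seq_along(injections), function(i) {
    inj <- injections[[i]]
    base <- baseline_rate(series, inj, baseline_span_s)
    if (i > 1L) {
      prev_base <- baseline_rate(series, injections[[i - 1L]],
                                 baseline_span_s)
      if (abs(base - prev_base) / prev_base > 0.2)
        warning("injection at ", inj$t, " s: baseline has not returned to ",
                "within 20% of the previous baseline", call. = FALSE)
    }
    data.frame(t = inj$t, substance = inj$substance,
               light_condition = inj$light_condition,
               baseline_hz = base,
               peak_variation = as.numeric(
                 response_magnitude(series, inj, horizon_s,
                                    baseline_span_s)))
  })
  do.call(rbind, rows)
}
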