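# Burst detection and firing-pattern metrics for pDA spike trains.
#
# Bursts follow the standard two-criterion extracellular rule: a burst
# opens at two consecutive spikes separated by less than 80 ms and closes
# at the first inter-spike interval greater than 160 ms. Only the ISI
# criteria are enforced; amplitude adaptation within bursts is not
# observable from sorted spike times.

#' Detect bursts by the 80/160 ms inter-spike-interval rule
#'
#' Left-to-right scan over the train's inter-spike intervals (ISIs): a
#' burst opens at the first spike pair whose ISI is strictly below
#' `onset_ms`; both spikes of the opening pair belong to the burst.
#' Subsequent spikes are appended while the ISI stays at or below
#' `close_ms`; the burst closes at the first ISI strictly above
#' `close_ms` (or at the end of the train), and scanning resumes after
#' the closing spike.
#'
#' @param train a [spike_train()].
#' @param onset_ms burst-opening ISI criterion, ms (default 80; the ISI
#'   must be `< onset_ms`, so exactly 80 ms does not open a burst).
#' @param close_ms burst-closing ISI criterion, ms (default 160; an ISI
#'   of exactly 160 ms keeps the burst open).
#'
#' @return A `burst_set`: list with `bursts`, an integer matrix with
#'   columns `start`, `end` (1-based inclusive spike indices into
#'   `train$times`), plus the parameters used. A train with fewer than
#'   two spikes yields an empty set.
#' @examples
#' st <- spike_train("n1", c(0, 0.05, 0.10, 0.30, 1.0), 0, 2)
#' detect_bursts(st)
#' @export
detect_bursts <- function(train, onset_ms = 80, close_ms = 160) {
  stopifnot(inherits(train, "spike_train"),
            onset_ms > 0, onset_ms <= close_ms)
  tms <- train$times
  n <- length(tms)
  onset_s <- onset_ms / 1000
  close_s <- close_ms / 1000
  starts <- integer(0)
  ends <- integer(0)
  if (n >= 2L) {
    isi <- diff(tms)
    i <- 1L
    while (i < n) {
      if (isi[i] < onset_s) {
        j <- i + 1L
        while (j < n && isi[j] <= close_s) j <- j + 1L
        starts <- c(starts, i)
        ends <- c(ends, j)
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  structure(
    list(bursts = cbind(start = starts, end = ends),
         n_spikes = n, neuron_id = train$neuron_id,
         onset_ms = onset_ms, close_ms = close_ms),
    class = "burst_set"
  )
}

#' @export
print.burst_set <- function(x, ...) {
  nb <- nrow(x$bursts)
  swb <- if (nb) sum(x$bursts[, "end"] - x$bursts[, "start"] + 1L) else 0L
  cat(sprintf("<burst_set> %s: %d burst(s), %d/%d spikes within bursts (%.1f%%)\n",
              x$neuron_id, nb, swb, x$n_spikes,
              if (x$n_spikes) 100 * swb / x$n_spikes else 0))
  invisible(x)
}

#' Number of bursts
#' @param bursts a `burst_set`.
#' @return integer count.
#' @export
n_bursts <- function(bursts) nrow(bursts$bursts)

# logical mask over spikes: TRUE where the spike belongs to some burst
.swb_mask <- function(bursts) {
  mask <- logical(bursts$n_spikes)
  if (nrow(bursts$bursts))
    for (k in seq_len(nrow(bursts$bursts)))
      mask[bursts$bursts[k, "start"]:bursts$bursts[k, "end"]] <- TRUE
  mask
}

#' Percentage of spikes within bursts (%SWB)
#'
#' @param train the [spike_train()] the bursts were detected on.
#' @param bursts the matching `burst_set` from [detect_bursts()].
#' @return percentage in `[0, 100]`; 0 for a spike-free or burst-free
#'   train.
#' @export
swb_fraction <- function(train, bursts) {
  if (bursts$n_spikes != length(train$times))
    stop("swb_fraction: bursts were not produced from this train",
         call. = FALSE)
  if (!length(train$times)) return(0)
  100 * sum(.swb_mask(bursts)) / length(train$times)
}

#' Burst table for export
#'
#' @param train a [spike_train()].
#' @param bursts its `burst_set`.
#' @return data.frame with columns `burst_id`, `start_s`, `end_s`,
#'   `n_spikes`.
#' @export
burst_table <- function(train, bursts) {
  if (bursts$n_spikes != length(train$times))
    stop("burst_table: bursts were not produced from this train",
         call. = FALSE)
  b <- bursts$bursts
  if (!nrow(b))
    return(data.frame(burst_id = integer(), start_s = numeric(),
                      end_s = numeric(), n_spikes = integer()))
  data.frame(burst_id = seq_len(nrow(b)),
             start_s = train$times[b[, "start"]],
             end_s = train$times[b[, "end"]],
             n_spikes = b[, "end"] - b[, "start"] + 1L)
}

# ---- sliding windows -------------------------------------------------------

#' Sliding-window rate or %SWB series
#'
#' Successive overlapping windows over the recording (defaults: 60 s
#' windows advanced in 15 s steps, i.e. a 45 s overlap). Windows are
#' anchored at `t_start` and half-open; a truncated final window is
#' dropped so every value is computed over exactly `window_s`. If the
#' recording is shorter than one window, a single window anchored at
#' `t_start` is used.
#'
#' @param train a [spike_train()].
#' @param bursts a `burst_set` from the same train; required for
#'   `kind = "pct_swb"`, ignored otherwise.
#' @param window_s window length, s.
#' @param step_s step between window onsets, s; must satisfy
#'   `0 < step_s < window_s`.
#' @param kind `"rate"` (spike count / `window_s`, Hz) or `"pct_swb"`
#'   (percentage of the window's spikes that lie within bursts; 0 for an
#'   empty window).
#'
#' @return A `rate_series`: data.frame with `center` (window centre, s)
#'   and `value`, plus attributes `window_s`, `step_s`, `kind`.
#' @export
sliding_series <- function(train, bursts = NULL, window_s = 60, step_s = 15,
                           kind = c("rate", "pct_swb")) {
  kind <- match.arg(kind)
  stopifnot(window_s > step_s, step_s > 0)
  if (kind == "pct_swb") {
    if (is.null(bursts))
      stop("sliding_series: bursts required for kind = 'pct_swb'",
           call. = FALSE)
    if (bursts$n_spikes != length(train$times))
      stop("sliding_series: bursts were not produced from this train",
           call. = FALSE)
  }
  span <- train$t_stop - train$t_start
  onsets <- if (span < window_s) train$t_start
            else seq(train$t_start, train$t_stop - window_s, by = step_s)
  tms <- train$times
  swb <- if (kind == "pct_swb") .swb_mask(bursts)
  value <- vapply(onsets, function(on) {
    sel <- tms >= on & tms < on + window_s
    if (kind == "rate") sum(sel) / window_s
    else if (!any(sel)) 0 else 100 * sum(swb[sel]) / sum(sel)
  }, 0)
  structure(
    data.frame(center = onsets + window_s / 2, value = value),
    window_s = window_s, step_s = step_s, kind = kind,
    class = c("rate_series", "data.frame")
  )
}

#' @export
plot.rate_series <- function(x, ...) {
  kind <- attr(x, "kind")
  graphics::plot(x$center, x$value, type = "l",
                 xlab = "time (s)",
                 ylab = if (kind == "rate") "firing rate (Hz)" else "%SWB",
                 ...)
  invisible(x)
}

# ---- event-aligned histogram ----------------------------------------------

#' Event-aligned spike histogram (PSTH) and raster
#'
#' Bins spike times relative to a set of alignment events (typically
#' light-transition onsets) into uniform bins spanning
#' `[-pre_s, post_s)`; the canonical display is a raster of per-event
#' spike offsets above a peri-stimulus time histogram with a 250 ms bin.
#'
#' @param train a [spike_train()].
#' @param event_times numeric vector of alignment times, s (>= 1 event).
#' @param pre_s,post_s window before/after each event, s.
#' @param bin_s bin width, s (default 0.25); must divide
#'   `pre_s + post_s` evenly.
#'
#' @return An `aligned_histogram`: list with `bin_edges` (length
#'   `n_bins + 1`, s relative to the event), `counts` (matrix, events x
#'   bins), `rate` (Hz per bin: total counts / (`n_events` x `bin_s`)),
#'   `offsets` (list of per-event spike offsets, for rasters) and
#'   `n_events`.
#' @export
aligned_histogram <- function(train, event_times, pre_s = 5, post_s = 5,
                              bin_s = 0.25) {
  if (!length(event_times))
    stop("aligned_histogram: at least one event required", call. = FALSE)
  n_bins_exact <- (pre_s + post_s) / bin_s
  if (abs(n_bins_exact - round(n_bins_exact)) > 1e-9)
    stop("aligned_histogram: bin_s must divide pre_s + post_s evenly",
         call. = FALSE)
  n_bins <- as.integer(round(n_bins_exact))
  edges <- seq(-pre_s, post_s, length.out = n_bins + 1L)
  offsets <- lapply(event_times, function(ev) {
    off <- train$times - ev
    off[off >= -pre_s & off < post_s]
  })
  counts <- t(vapply(offsets, function(off) {
    # half-open bins [edge_i, edge_{i+1})
    tabulate(pmin(floor((off + pre_s) / bin_s) + 1L, n_bins), nbins = n_bins)
  }, integer(n_bins)))
  structure(
    list(bin_edges = edges, counts = counts,
         rate = colSums(counts) / (length(event_times) * bin_s),
         offsets = offsets, n_events = length(event_times), bin_s = bin_s),
    class = "aligned_histogram"
  )
}

#' @export
print.aligned_histogram <- function(x, ...) {
  cat(sprintf("<aligned_histogram> %d event(s), %d bins of %.0f ms, peak %.2f Hz\n",
              x$n_events, length(x$rate), 1000 * x$bin_s, max(x$rate)))
  invisible(x)
}

#' @export
plot.aligned_histogram <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(x$bin_edges), ylim = c(0, x$n_events + 1),
                 xlab = "", ylab = "transition", ...)
  for (i in seq_len(x$n_events))
    if (length(x$offsets[[i]]))
      graphics::points(x$offsets[[i]], rep(i, length(x$offsets[[i]])),
                       pch = "|", cex = 0.6)
  graphics::abline(v = 0, col = "purple")
  mids <- utils::head(x$bin_edges, -1L) + x$bin_s / 2
  graphics::plot(mids, x$rate, type = "s", xlab = "time from event (s)",
                 ylab = "rate (Hz)")
  graphics::abline(v = 0, col = "purple")
  invisible(x)
}
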