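#' photospike: quantification of light-controlled nicotinic signalling
#'
#' Tools for analysing spike trains of putative dopamine (pDA) neurons
#' recorded while a tethered azobenzene photoswitch toggles nicotinic
#' receptors between an antagonized (cis, 390 nm) and a functional
#' (trans, 520 nm) state, plus the pharmacological and behavioural
#' read-outs used alongside such recordings and a synthetic-data
#' generator that emulates them.
#'
#' All times are in seconds internally; file columns carry explicit unit
#' suffixes (`_s`, `_ms`). Every interval (light epoch, analysis window,
#' session phase) is half-open `[on, off)`, so a spike sitting exactly on
#' a boundary belongs to the later interval and is never double-counted.
#'
#' @keywords internal
"_PACKAGE"

# ---- spike_train -----------------------------------------------------------

#' Construct a spike train
#'
#' A spike train is one neuron's sorted spike times over a recording span.
#'
#' @param neuron_id single character id.
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all inside `[t_start, t_stop]`.
#' @param t_start,t_stop recording span in seconds, `t_stop > t_start`.
#'
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train("n1", c(0.1, 0.5, 1.2), t_start = 0, t_stop = 2)
#' n_spikes(st)
#' @export
spike_train <- function(neuron_id, times, t_start, t_stop) {
  stopifnot(is.character(neuron_id), length(neuron_id) == 1L)
  times <- as.numeric(times)
  t_start <- as.numeric(t_start)
  t_stop <- as.numeric(t_stop)
  if (!is.finite(t_start) || !is.finite(t_stop) || t_stop <= t_start)
    stop("spike_train: t_stop must exceed t_start", call. = FALSE)
  if (anyNA(times))
    stop("spike_train: NA spike times for neuron ", neuron_id, call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike_train: times not strictly increasing for neuron ",
         neuron_id, call. = FALSE)
  if (length(times) && (times[1L] < t_start || times[length(times)] > t_stop))
    stop("spike_train: spike outside [t_start, t_stop] for neuron ",
         neuron_id, call. = FALSE)
  structure(
    list(neuron_id = neuron_id, times = times,
         t_start = t_start, t_stop = t_stop),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- x$t_stop - x$t_start
  cat(sprintf("<spike_train> %s: %d spikes over %.1f s (%.2f Hz mean)\n",
              x$neuron_id, length(x$times), dur, length(x$times) / dur))
  invisible(x)
}

#' Number of spikes in a train
#' @param train a [spike_train()].
#' @return integer spike count.
#' @export
n_spikes <- function(train) length(train$times)

#' Mean firing rate of a train
#' @param train a [spike_train()].
#' @return rate in Hz over the full recording span.
#' @export
mean_rate <- function(train) length(train$times) / (train$t_stop - train$t_start)

# ---- light_schedule --------------------------------------------------------

.wavelength_levels <- c("390", "520", "dark")

#' Construct a light schedule
#'
#' An ordered set of non-overlapping illumination epochs. Wavelengths are
#' 390 nm (photoswitch driven to its antagonizing cis state), 520 nm
#' (relief to trans) or dark (code 0 in files): darkness is a first-class
#' epoch so bistability of the cis state across unlit periods can be
#' modelled and analysed.
#'
#' @param t_on,t_off numeric vectors of epoch onsets/offsets in seconds;
#'   epochs are half-open `[t_on, t_off)`.
#' @param wavelength character or numeric vector; one of `"390"`, `"520"`,
#'   `"dark"` (numeric 390, 520, 0 accepted).
#'
#' @return A `light_schedule`: a data.frame with columns `t_on`, `t_off`,
#'   `wavelength`, sorted by onset.
#' @examples
#' sched <- light_schedule(c(0, 5), c(5, 10), c(390, 520))
#' epoch_durations(sched)
#' @export
light_schedule <- function(t_on, t_off, wavelength) {
  t_on <- as.numeric(t_on); t_off <- as.numeric(t_off)
  wavelength <- .normalize_wavelength(wavelength)
  if (length(t_on) != length(t_off) || length(t_on) != length(wavelength))
    stop("light_schedule: column lengths differ", call. = FALSE)
  if (any(!is.finite(t_on)) || any(!is.finite(t_off)))
    stop("light_schedule: non-finite epoch bounds", call. = FALSE)
  if (any(t_off <= t_on))
    stop("light_schedule: every epoch needs t_off > t_on", call. = FALSE)
  ord <- order(t_on)
  t_on <- t_on[ord]; t_off <- t_off[ord]; wavelength <- wavelength[ord]
  if (length(t_on) > 1L && any(t_on[-1L] < t_off[-length(t_off)]))
    stop("light_schedule: epochs overlap", call. = FALSE)
  structure(
    data.frame(t_on = t_on, t_off = t_off, wavelength = wavelength,
               stringsAsFactors = FALSE),
    class = c("light_schedule", "data.frame")
  )
}

.normalize_wavelength <- function(w) {
  w <- as.character(w)
  w[w %in% c("0", "dark", "Dark", "DARK")] <- "dark"
  bad <- !(w %in% .wavelength_levels)
  if (any(bad))
    stop("light_schedule: unknown wavelength code(s): ",
         paste(unique(w[bad]), collapse = ", "), call. = FALSE)
  w
}

#' Total epoch duration per wavelength
#' @param schedule a [light_schedule()].
#' @return named numeric vector of summed durations (s) per wavelength
#'   present in the schedule.
#' @export
epoch_durations <- function(schedule) {
  tapply(schedule$t_off - schedule$t_on, schedule$wavelength, sum)
}

#' Wavelength transition times of a schedule
#'
#' Returns the onset times of epochs of a given wavelength, the usual
#' alignment events for rasters and peri-stimulus time histograms
#' centred on, e.g., the 390 nm flashes.
#'
#' @param schedule a [light_schedule()].
#' @param wavelength epoch type whose onsets are wanted (`"390"`, `"520"`
#'   or `"dark"`).
#' @return numeric vector of onset times (s).
#' @export
epoch_onsets <- function(schedule, wavelength = "390") {
  wavelength <- .normalize_wavelength(wavelength)
  schedule$t_on[schedule$wavelength == wavelength]
}

# ---- neuron_meta, injection_event ------------------------------------------

#' Per-neuron metadata
#'
#' @param neuron_id single character id.
#' @param cohort `"control"` or `"transduced"`.
#' @param half_ap_width action-potential half width, ms (> 0).
#' @param mean_rate mean firing rate, Hz (>= 0).
#' @param isi_cv coefficient of variation of inter-spike intervals (>= 0).
#' @param th_identity optional logical: tyrosine-hydroxylase-confirmed
#'   dopaminergic identity (from juxtacellular labelling), `NA` if unknown.
#'
#' @return A `neuron_meta` list.
#' @export
neuron_meta <- function(neuron_id, cohort, half_ap_width, mean_rate, isi_cv,
                        th_identity = NA) {
  cohort <- match.arg(cohort, c("control", "transduced"))
  stopifnot(half_ap_width > 0, mean_rate >= 0, isi_cv >= 0)
  structure(
    list(neuron_id = neuron_id, cohort = cohort,
         half_ap_width = half_ap_width, mean_rate = mean_rate,
         isi_cv = isi_cv, th_identity = th_identity),
    class = "neuron_meta"
  )
}

#' An intravenous injection event
#'
#' @param t injection time, seconds.
#' @param substance `"saline"` or `"nicotine"`.
#' @param dose dose in micrograms per kilogram (>= 0).
#' @param light_condition illumination condition during the injection
#'   window: `"dark"`, `"390"` or `"520"`. The condition is metadata on
#'   the event (light is applied around the injection by protocol), not
#'   inferred from the schedule.
#'
#' @return An `injection_event` list.
#' @export
injection_event <- function(t, substance, dose, light_condition = "dark") {
  substance <- match.arg(substance, c("saline", "nicotine"))
  light_condition <- match.arg(as.character(light_condition),
                               c("dark", "390", "520"))
  stopifnot(is.finite(t), dose >= 0)
  structure(
    list(t = as.numeric(t), substance = substance, dose = as.numeric(dose),
         light_condition = light_condition),
    class = "injection_event"
  )
}

# ---- recording -------------------------------------------------------------

#' Bundle spike trains, schedule, injections and metadata
#'
#' @param trains list of [spike_train()] objects.
#' @param schedule optional [light_schedule()]; must lie within every
#'   train's span.
#' @param injections optional list of [injection_event()]s, each within
#'   every train's span.
#' @param meta optional list of [neuron_meta()], exactly one per neuron.
#'
#' @return A `recording` list.
#' @export
recording <- function(trains, schedule = NULL, injections = NULL,
                      meta = NULL) {
  stopifnot(is.list(trains), all(vapply(trains, inherits, TRUE, "spike_train")))
  ids <- vapply(trains, function(tr) tr$neuron_id, "")
  if (anyDuplicated(ids))
    stop("recording: duplicate neuron_id in trains", call. = FALSE)
  names(trains) <- ids
  if (!is.null(meta)) {
    mids <- vapply(meta, function(m) m$neuron_id, "")
    if (!setequal(mids, ids) || anyDuplicated(mids))
      stop("recording: meta must hold exactly one entry per neuron",
           call. = FALSE)
    names(meta) <- mids
    meta <- meta[ids]
  }
  span <- c(max(vapply(trains, function(tr) tr$t_start, 0)),
            min(vapply(trains, function(tr) tr$t_stop, 0)))
  if (!is.null(schedule) &&
      (min(schedule$t_on) < span[1L] || max(schedule$t_off) > span[2L]))
    stop("recording: schedule extends outside the common recording span",
         call. = FALSE)
  if (!is.null(injections)) {
    tt <- vapply(injections, function(ii) ii$t, 0)
    if (any(tt < span[1L] | tt > span[2L]))
      stop("recording: injection outside the common recording span",
           call. = FALSE)
  }
  structure(
    list(trains = trains, schedule = schedule, injections = injections,
         meta = meta),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d neuron(s)", length(x$trains)))
  if (!is.null(x$schedule))
    cat(sprintf(", %d light epoch(s)", nrow(x$schedule)))
  if (!is.null(x$injections))
    cat(sprintf(", %d injection(s)", length(x$injections)))
  cat("\n")
  invisible(x)
}

# ---- tabular I/O -----------------------------------------------------------

# comma/tab autodetection on the header line
.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("empty file (no header): ", path, call. = FALSE)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE)
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
}

#' Read a spike table
#'
#' Delimited text (comma or tab, autodetected) with header columns
#' `neuron_id` and `time_s`, one row per spike. The recording span is
#' taken from `t_start`/`t_stop` arguments when given, otherwise inferred
#' as `[0, max time]` (or the per-file extremes if `span = "observed"`).
#'
#' @param path file path.
#' @param t_start,t_stop optional common span in seconds applied to every
#'   neuron; when `NULL` the span is `[0, ceiling(max(time_s))]`.
#'
#' @return list of [spike_train()] objects (possibly empty).
#' @export
load_spike_table <- function(path, t_start = NULL, t_stop = NULL) {
  df <- .read_delim_auto(path)
  .require_cols(df, c("neuron_id", "time_s"), path)
  if (nrow(df) == 0L) return(list())
  df$neuron_id <- as.character(df$neuron_id)
  df$time_s <- as.numeric(df$time_s)
  lo <- if (is.null(t_start)) 0 else t_start
  hi <- if (is.null(t_stop)) ceiling(max(df$time_s)) else t_stop
  out <- lapply(split(df$time_s, df$neuron_id), sort)
  trains <- vector("list", length(out))
  for (i in seq_along(out)) {
    id <- names(out)[i]
    tms <- out[[i]]
    if (length(tms) > 1L && any(diff(tms) == 0)) {
      bad <- tms[which(diff(tms) == 0)[1L]]
      stop("duplicate spike time ", bad, " s for neuron ", id,
           " in ", path, call. = FALSE)
    }
    trains[[i]] <- spike_train(id, tms, lo, hi)
  }
  names(trains) <- names(out)
  trains
}

#' Write a spike table
#' @param trains list of [spike_train()] objects.
#' @param path output path; comma-separated with header `neuron_id,time_s`.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(neuron_id = tr$neuron_id, time_s = tr$times)
  }))
  if (is.null(df)) df <- data.frame(neuron_id = character(), time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a light schedule
#'
#' Delimited text with header columns `t_on_s`, `t_off_s`,
#' `wavelength_nm`; darkness is encoded as wavelength 0.
#'
#' @param path file path.
#' @return a [light_schedule()].
#' @export
load_light_schedule <- function(path) {
  df <- .read_delim_auto(path)
  .require_cols(df, c("t_on_s", "t_off_s", "wavelength_nm"), path)
  light_schedule(df$t_on_s, df$t_off_s, df$wavelength_nm)
}

#' Write a light schedule
#' @param schedule a [light_schedule()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_light_schedule <- function(schedule, path) {
  code <- ifelse(schedule$wavelength == "dark", "0", schedule$wavelength)
  df <- data.frame(t_on_s = schedule$t_on, t_off_s = schedule$t_off,
                   wavelength_nm = code)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an injection event table
#'
#' Columns: `t_s`, `substance`, `dose_ug_kg`, `light_condition`.
#'
#' @param path file path.
#' @return list of [injection_event()]s.
#' @export
load_injection_table <- function(path) {
  df <- .read_delim_auto(path)
  .require_cols(df, c("t_s", "substance", "dose_ug_kg", "light_condition"),
                path)
  lapply(seq_len(nrow(df)), function(i)
    injection_event(df$t_s[i], df$substance[i], df$dose_ug_kg[i],
                    df$light_condition[i]))
}

#' Read a session manifest
#'
#' A JSON manifest binds the data files of one session: spike table,
#' light schedule, injections, per-neuron metadata and the recording
#' span. Paths are resolved relative to the manifest's directory.
#'
#' Expected fields: `spikes` (path), optional `schedule`, `injections`
#' (paths), optional `t_start`, `t_stop` (seconds), optional `meta` (path
#' to a table with columns `neuron_id`, `cohort`, `half_ap_width_ms`,
#' `mean_rate_hz`, `isi_cv`), optional `seed`.
#'
#' @param path path to the JSON manifest.
#' @return a [recording()]; the manifest's `seed` (if any) is attached as
#'   attribute `"seed"`.
#' @export
load_recording <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  trains <- load_spike_table(rel(man$spikes),
                             t_start = man$t_start, t_stop = man$t_stop)
  schedule <- if (!is.null(man$schedule)) load_light_schedule(rel(man$schedule))
  injections <- if (!is.null(man$injections))
    load_injection_table(rel(man$injections))
  meta <- NULL
  if (!is.null(man$meta)) {
    md <- .read_delim_auto(rel(man$meta))
    .require_cols(md, c("neuron_id", "cohort", "half_ap_width_ms",
                        "mean_rate_hz", "isi_cv"), man$meta)
    meta <- lapply(seq_len(nrow(md)), function(i)
      neuron_meta(as.character(md$neuron_id[i]), md$cohort[i],
                  md$half_ap_width_ms[i], md$mean_rate_hz[i], md$isi_cv[i]))
  }
  rec <- recording(trains, schedule, injections, meta)
  attr(rec, "seed") <- man$seed
  rec
}

# ---- putative DA filter ----------------------------------------------------

#' Electrophysiological filter for putative dopamine neurons
#'
#' The classic in vivo identification of putative dopaminergic (pDA)
#' neurons: regular tonic firing, mean rate between 1 and 10 Hz, and a
#' broad action potential (half width above 1.1 ms). "Regular" is
#' operationalized as an inter-spike-interval coefficient of variation at
#' or below `regularity_cv_max`; no standard numeric criterion exists, so
#' the cut-off is explicit and recorded with results that use it.
#'
#' @param meta a [neuron_meta()].
#' @param regularity_cv_max maximal ISI coefficient of variation still
#'   counted as regular (default 1.0).
#' @return `TRUE` iff all three criteria hold.
#' @examples
#' m <- neuron_meta("n1", "control", half_ap_width = 1.3,
#'                  mean_rate = 3, isi_cv = 0.4)
#' is_putative_da(m)
#' @export
is_putative_da <- function(meta, regularity_cv_max = 1.0) {
  meta$mean_rate >= 1 && meta$mean_rate <= 10 &&
    meta$half_ap_width > 1.1 &&
    meta$isi_cv <= regularity_cv_max
}
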