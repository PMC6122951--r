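# Conditioned place preference: trajectory -> per-zone occupancy,
# preference scores, pretest-balanced group assignment, and group
# summaries.

#' Arena trajectory
#'
#' @param t sample times, s, strictly increasing (nominally 20 frames/s).
#' @param x,y positions in arena units.
#' @param span_s session span, s; defaults to the last sample time.
#' @return a `trajectory` data.frame with attribute `span_s`.
#' @export
trajectory <- function(t, x, y, span_s = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(t) == length(x), length(t) == length(y), length(t) > 0)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("trajectory: sample times must be strictly increasing",
         call. = FALSE)
  if (is.null(span_s)) span_s <- t[length(t)]
  stopifnot(span_s > 0)
  structure(data.frame(t = t, x = x, y = y), span_s = span_s,
            class = c("trajectory", "data.frame"))
}

#' Read a trajectory file
#' @param path delimited text with header columns `t_s`, `x`, `y`.
#' @param span_s optional session span, s.
#' @return a [trajectory()].
#' @export
load_trajectory <- function(path, span_s = NULL) {
  df <- .read_delim_auto(path)
  .require_cols(df, c("t_s", "x", "y"), path)
  trajectory(df$t_s, df$x, df$y, span_s)
}

#' Arena zone map
#'
#' Named rectangular zones (`side_A`, `side_B`, `center`) plus the
#' nicotine-paired side. Zones must not overlap.
#'
#' @param zones named list of rectangles, each
#'   `c(xmin, xmax, ymin, ymax)`; must include `side_A` and `side_B`.
#' @param paired_side which side is nicotine-paired: `"side_A"` or
#'   `"side_B"`.
#' @return a `zone_map` list.
#' @export
zone_map <- function(zones, paired_side = "side_A") {
  stopifnot(all(c("side_A", "side_B") %in% names(zones)))
  paired_side <- match.arg(paired_side, c("side_A", "side_B"))
  for (z in zones) stopifnot(length(z) == 4L, z[2] > z[1], z[4] > z[3])
  nm <- names(zones)
  for (i in seq_along(zones)) for (j in seq_along(zones)) {
    if (i >= j) next
    a <- zones[[i]]; b <- zones[[j]]
    if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
      stop("zone_map: zones ", nm[i], " and ", nm[j], " overlap",
           call. = FALSE)
  }
  structure(list(zones = zones, paired_side = paired_side),
            class = "zone_map")
}

#' Default two-chamber zone map
#'
#' Two 11 x 25 rectangular pairing chambers joined by an 11-unit-wide
#' central compartment, laid out along x.
#'
#' @param paired_side nicotine-paired side.
#' @return a [zone_map()].
#' @export
default_zone_map <- function(paired_side = "side_A") {
  zone_map(list(side_A = c(0, 11, 0, 25),
                center = c(11, 22, 0, 11),
                side_B = c(22, 33, 0, 25)),
           paired_side = paired_side)
}

#' Read a zone map from JSON
#' @param path JSON with fields `zones` (named arrays
#'   `[xmin, xmax, ymin, ymax]`) and `paired_side`.
#' @return a [zone_map()].
#' @export
load_zone_map <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  zone_map(lapply(js$zones, as.numeric), paired_side = js$paired_side)
}

# zone label per sample ("off" when outside all zones)
.zone_of <- function(traj, map) {
  lab <- rep("off", nrow(traj))
  for (nm in names(map$zones)) {
    z <- map$zones[[nm]]
    inz <- traj$x >= z[1] & traj$x < z[2] & traj$y >= z[3] & traj$y < z[4]
    lab[inz] <- nm
  }
  lab
}

#' Per-zone occupancy of a trajectory
#'
#' Each inter-sample interval is credited to the zone of its leading
#' sample; the final sample is credited up to the session span. Samples
#' outside every zone accrue to an `off` bucket (with a warning).
#'
#' @param traj a [trajectory()].
#' @param map a [zone_map()].
#' @return named numeric vector of seconds per zone (plus `off`).
#' @export
occupancy <- function(traj, map) {
  lab <- .zone_of(traj, map)
  dt <- c(diff(traj$t), max(attr(traj, "span_s") - traj$t[nrow(traj)], 0))
  out <- tapply(dt, factor(lab, levels = c(names(map$zones), "off")), sum,
                default = 0)
  out <- as.numeric(out); names(out) <- c(names(map$zones), "off")
  if (out[["off"]] > 0)
    warning("occupancy: ", round(out[["off"]], 2),
            " s outside all zones", call. = FALSE)
  out
}

#' A scored CPP session
#'
#' @param animal_id animal identifier.
#' @param phase `"pretest"` or `"test"`.
#' @param occupancy_s named vector of per-zone seconds (from
#'   [occupancy()]).
#' @param paired_side nicotine-paired side.
#' @param span_s session span, s.
#' @return a `cpp_session` list.
#' @export
cpp_session <- function(animal_id, phase, occupancy_s, paired_side,
                        span_s = 900) {
  phase <- match.arg(phase, c("pretest", "test"))
  paired_side <- match.arg(paired_side, c("side_A", "side_B"))
  stopifnot(all(occupancy_s >= 0), sum(occupancy_s) <= span_s + 1e-6)
  structure(
    list(animal_id = animal_id, phase = phase, occupancy = occupancy_s,
         paired_side = paired_side, span_s = span_s),
    class = "cpp_session"
  )
}

#' Preference score
#'
#' Seconds on the nicotine-paired side during the test minus the same
#' measure at pretest. Time in the central compartment never enters the
#' score. A `mode = "difference"` variant scores
#' (paired - unpaired) at test minus the same contrast at pretest, for
#' sensitivity analysis.
#'
#' @param test,pretest [cpp_session()]s of the same animal and pairing.
#' @param mode `"paired_side"` (default) or `"difference"`.
#' @return preference score, seconds.
#' @export
preference_score <- function(test, pretest, mode = c("paired_side",
                                                     "difference")) {
  mode <- match.arg(mode)
  if (test$animal_id != pretest$animal_id)
    stop("preference_score: sessions from different animals", call. = FALSE)
  if (test$paired_side != pretest$paired_side)
    stop("preference_score: pairing differs between sessions", call. = FALSE)
  if (test$phase != "test" || pretest$phase != "pretest")
    stop("preference_score: expected a test and a pretest session",
         call. = FALSE)
  paired <- test$paired_side
  unpaired <- setdiff(c("side_A", "side_B"), paired)
  if (mode == "paired_side")
    test$occupancy[[paired]] - pretest$occupancy[[paired]]
  else
    (test$occupancy[[paired]] - test$occupancy[[unpaired]]) -
      (pretest$occupancy[[paired]] - pretest$occupancy[[unpaired]])
}

#' Bias-balanced group assignment
#'
#' Partition animals into groups of (near-)equal size so that the
#' largest absolute group-mean pretest bias is minimal — every group
#' starts with an initial preference close to zero. Exhaustive search up
#' to 16 animals; beyond that, a seeded randomized-swap descent.
#'
#' @param pretest_scores numeric pretest biases, seconds (one per
#'   animal).
#' @param n_groups number of groups; group sizes differ by at most one.
#' @param seed integer seed for tie-breaking / the swap heuristic.
#' @return list with `assignment` (integer group per animal),
#'   `objective` (max |group mean|), `group_means`.
#' @export
balance_groups <- function(pretest_scores, n_groups, seed = 1L) {
  n <- length(pretest_scores)
  if (n_groups > n)
    stop("balance_groups: more groups than animals", call. = FALSE)
  sizes <- rep(n %/% n_groups, n_groups)
  if (n %% n_groups) sizes[seq_len(n %% n_groups)] <-
      sizes[seq_len(n %% n_groups)] + 1L
  objective <- function(assign) {
    means <- tapply(pretest_scores, factor(assign, levels = seq_len(n_groups)),
                    mean, default = 0)
    max(abs(means))
  }
  if (n <= 16L) {
    best <- NULL; best_obj <- Inf
    recurse <- function(remaining, assign, g) {
      if (g > n_groups) {
        obj <- objective(assign)
        if (obj < best_obj - 1e-12) { best_obj <<- obj; best <<- assign }
        return(invisible(NULL))
      }
      if (g == n_groups) {
        assign[remaining] <- g
        recurse(integer(0), assign, g + 1L)
        return(invisible(NULL))
      }
      # fix the lowest remaining index into group g to kill permutation
      # symmetry between equal-sized groups
      pool <- remaining[-1L]
      combos <- if (sizes[g] == 1L) list(integer(0))
                else if (length(pool) == 1L) list(pool)
                else utils::combn(pool, sizes[g] - 1L, simplify = FALSE)
      for (cc in combos) {
        members <- c(remaining[1L], cc)
        assign[members] <- g
        recurse(setdiff(remaining, members), assign, g + 1L)
      }
      invisible(NULL)
    }
    recurse(seq_len(n), integer(n), 1L)
    assign <- best
  } else {
    set.seed(seed)
    assign <- sample(rep(seq_len(n_groups), sizes))
    best_obj <- objective(assign)
    for (iter in seq_len(2000L)) {
      i <- sample.int(n, 1L); j <- sample.int(n, 1L)
      if (assign[i] == assign[j]) next
      cand <- assign
      cand[c(i, j)] <- cand[c(j, i)]
      obj <- objective(cand)
      if (obj < best_obj) { assign <- cand; best_obj <- obj }
    }
  }
  means <- tapply(pretest_scores, factor(assign, levels = seq_len(n_groups)),
                  mean, default = 0)
  list(assignment = assign, objective = max(abs(means)),
       group_means = as.numeric(means))
}

#' Group summary of preference scores
#'
#' Mean and SEM per group, with a normality-gated one-sample test of
#' each group's scores against zero (no preference).
#'
#' @param scores numeric preference scores, s.
#' @param group factor/vector of group labels, same length.
#' @return data.frame with `group`, `n`, `mean_ps`, `sem_ps`, `test`,
#'   `p_value`.
#' @export
cpp_summary <- function(scores, group) {
  group <- as.factor(group)
  rows <- lapply(levels(group), function(g) {
    x <- scores[group == g]
    tr <- one_sample_test(x, mu0 = 0)
    data.frame(group = g, n = length(x), mean_ps = mean(x),
               sem_ps = stats::sd(x) / sqrt(length(x)),
               test = tr$test_name, p_value = tr$p_raw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
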