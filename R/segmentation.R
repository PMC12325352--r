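# Repetition detection on the task's primary angle curve. A repetition is
# one isolated prominence-filtered maximum with its flanking minima; ROM is
# max - min within the repetition, task duration runs from the start of
# the first repetition to the end of the last.

#' Detect repetitions on an angle curve
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` of the curve's global amplitude; each retained
#' maximum with its flanking minima forms one repetition. Flanking
#' boundaries prefer the nearest local minimum below 10% of the global
#' amplitude (rest plateaus), falling back to the lowest point of the
#' valley. Flagged (`NA`) samples are bridged by linear interpolation for
#' detection purposes and never selected as extrema.
#'
#' @param a an [angle_series()] or numeric vector (degrees).
#' @param expected expected repetition count; a differing detected count
#'   raises a warning (recorded, not fatal).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   global max - min.
#' @return data frame of class `repetition_set`: one row per repetition
#'   with `start`, `peak`, `end` (sample indices), `max_value`,
#'   `min_value`, `rom` (deg); attribute `expected_mismatch` records a
#'   count deviation.
#' @export
detect_repetitions <- function(a, expected = 6L, min_prominence_frac = 0.2) {
  v <- if (inherits(a, "angle_series")) a$values else as.numeric(a)
  n <- length(v)
  if (n < 3) stop("segmentation error: series too short")
  flagged <- is.na(v)
  if (all(flagged)) stop("segmentation error: all samples flagged")
  if (any(flagged)) {
    ok <- which(!flagged)
    v <- stats::approx(ok, v[ok], xout = seq_len(n), rule = 2)$y
  }
  orig <- v
  # orient the curve so repetitions point upward: excursions may run below
  # the resting value (e.g. a left-side bend decreases the inclination)
  if (stats::median(v) - min(v) > max(v) - stats::median(v)) v <- -v
  lo <- min(v); hi <- max(v)
  amp <- hi - lo
  if (amp <= 0) stop("segmentation error: flat curve")

  is_max <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
              FALSE)
  cand <- which(is_max)
  cand <- cand[!flagged[cand]]
  if (!length(cand)) stop("segmentation error: no repetitions found")

  prominence <- vapply(cand, function(i) {
    h <- v[i]
    left <- if (i > 1) v[1:(i - 1)] else h
    higher_l <- which(left > h)
    lbase <- min(left[if (length(higher_l)) (max(higher_l) + 1):(i - 1) else
      seq_along(left)])
    right <- if (i < n) v[(i + 1):n] else h
    higher_r <- which(right > h)
    rbase <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1) else
      seq_along(right)])
    h - max(lbase, rbase)
  }, numeric(1))
  peaks <- cand[prominence >= min_prominence_frac * amp]
  if (!length(peaks)) stop("segmentation error: no repetitions found")

  low_thr <- lo + 0.1 * amp
  boundary <- function(from, to, near_end) {
    idx <- from:to
    vi <- v[idx]
    interior <- idx > 1 & idx < n
    locmin <- vi <= v[pmax(idx - 1, 1)] & vi <= v[pmin(idx + 1, n)] & interior
    pool <- idx[locmin & vi <= low_thr & !flagged[idx]]
    if (!length(pool)) pool <- idx[which(vi == min(vi))]
    if (near_end == "right") max(pool) else min(pool)
  }
  k <- length(peaks)
  start <- integer(k); end <- integer(k)
  for (j in seq_len(k)) {
    lfrom <- if (j == 1) 1L else peaks[j - 1]
    start[j] <- boundary(lfrom, peaks[j] - 1L, "right")
    rto <- if (j == k) n else peaks[j + 1]
    end[j] <- boundary(peaks[j] + 1L, rto, "left")
  }
  reps <- data.frame(start = start, peak = peaks, end = end)
  reps$max_value <- vapply(seq_len(k), function(j)
    max(orig[start[j]:end[j]]), numeric(1))
  reps$min_value <- vapply(seq_len(k), function(j)
    min(orig[start[j]:end[j]]), numeric(1))
  reps$rom <- reps$max_value - reps$min_value
  class(reps) <- c("repetition_set", "data.frame")
  attr(reps, "expected_mismatch") <- if (k != expected) {
    warning(sprintf("detected %d repetitions, expected %d", k, expected))
    k - as.integer(expected)
  } else 0L
  reps
}

#' Pool per-repetition ROMs into one trial value
#'
#' Default rule: arithmetic mean of repetitions 2..n, i.e. the first
#' repetition of the set is excluded to avoid initial measurement bias.
#'
#' @param reps a `repetition_set` (or numeric ROM vector, degrees).
#' @param exclude_first drop the first repetition before averaging.
#' @return pooled ROM (deg).
#' @export
pool_trial <- function(reps, exclude_first = TRUE) {
  roms <- if (is.data.frame(reps)) reps$rom else as.numeric(reps)
  if (exclude_first) {
    if (length(roms) < 2)
      stop("pooling error: need >= 2 repetitions to exclude the first")
    roms <- roms[-1]
  } else if (!length(roms)) stop("pooling error: no repetitions")
  mean(roms)
}

#' Per-participant ROM from the two sets
#'
#' @param set1,set2 pooled ROM of each set (deg); `NA` allowed.
#' @return arithmetic mean, or `NA` (with a message) when a set is missing.
#' @export
participant_rom <- function(set1, set2) {
  if (is.na(set1) || is.na(set2)) {
    message("participant_rom: missing set value, propagating NA")
    return(NA_real_)
  }
  (set1 + set2) / 2
}

#' Pool the two sides of a bilateral task
#'
#' Side pooling is only justified when the preliminary paired left/right
#' comparison (see [side_comparison()]) found no systematic difference.
#'
#' @param left,right per-side participant ROM (deg).
#' @param justified logical from the side-comparison test.
#' @return single pooled value when `justified`, otherwise a named vector
#'   keeping both sides.
#' @export
pool_sides <- function(left, right, justified) {
  if (isTRUE(justified)) (left + right) / 2
  else c(left = left, right = right)
}

#' Task duration from detected repetitions
#'
#' @param reps a `repetition_set`.
#' @param rate sampling rate (Hz).
#' @return duration (s) from the start of the first repetition to the end
#'   of the last.
#' @export
task_duration <- function(reps, rate) {
  if (!nrow(reps)) stop("task_duration: no repetitions")
  (reps$end[nrow(reps)] - reps$start[1]) / rate
}

#' Analyse one trial end to end
#'
#' Interpolates gaps, low-pass filters the markers, computes the task's
#' primary angle, segments repetitions and returns per-repetition ROMs,
#' the pooled ROM and the task duration.
#'
#' @param trajectory a [marker_trajectory_set()].
#' @param metadata a [trial_metadata()].
#' @param fspec a [filter_spec()]; `NULL` skips filtering.
#' @param expected_reps expected repetition count.
#' @param min_prominence_frac prominence threshold fraction.
#' @param max_gap maximum fillable gap (samples).
#' @param exclude_first first-repetition exclusion rule for pooling.
#' @return object of class `trial_result`: list with `metadata`,
#'   `repetitions`, `pooled_rom`, `duration`, `primary_label`,
#'   `rep_count_mismatch`.
#' @export
analyze_trial <- function(trajectory, metadata, fspec = filter_spec(),
                          expected_reps = 6L, min_prominence_frac = 0.2,
                          max_gap = 20L, exclude_first = TRUE) {
  stopifnot(inherits(metadata, "trial_metadata"))
  t <- trajectory
  # restrict to the markers the primary angle needs before filtering
  label <- primary_angle_label(metadata$task)
  pelvis <- intersect(c("RASIS", "LASIS", "RPSIS", "LPSIS"),
                      names(t$positions))
  need <- if (label %in% c("SF", "SA", "SE")) {
    c(pelvis, if (metadata$side == "right") c("RACR", "RELB")
              else c("LACR", "LELB"))
  } else if (label %in% c("SIL", "SIA", "SRL", "SRA")) {
    c(pelvis, "RACR", "LACR")
  } else c(pelvis, "S1", "L3", "L1", "T6", "T1")
  missing <- setdiff(need, names(t$positions))
  if (length(missing))
    stop("task '", metadata$task, "' requires missing marker(s): ",
         paste(missing, collapse = ", "))
  t <- marker_trajectory_set(t$positions[need], t$sample_rate,
                             t$gap_mask[need])
  if (any(vapply(t$gap_mask, any, logical(1))))
    t <- interpolate_gaps(t, max_gap = max_gap)
  if (!is.null(fspec)) t <- lowpass_filter(t, fspec)
  ang <- primary_angle(t, metadata$task, metadata$side)
  reps <- withCallingHandlers(
    detect_repetitions(ang, expected = expected_reps,
                       min_prominence_frac = min_prominence_frac),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(
    list(metadata = metadata, repetitions = reps,
         pooled_rom = pool_trial(reps, exclude_first = exclude_first),
         duration = task_duration(reps, t$sample_rate),
         primary_label = ang$label,
         rep_count_mismatch = attr(reps, "expected_mismatch")),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> %s %s %s (%s): %d reps, pooled ROM %.2f deg, duration %.2f s\n",
    x$metadata$participant_id, x$metadata$session, x$metadata$task,
    x$metadata$side, nrow(x$repetitions), x$pooled_rom, x$duration))
  invisible(x)
}
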