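# Forward-kinematic synthetic-trial generator. Every trial is built from a
# rigid-segment body model driven by one task-specific angle that follows a
# raised-cosine profile per repetition, separated by rest plateaus, so the
# downstream extrema-based segmentation sees one isolated peak per
# repetition with known ground truth.

#' Primary angle label per motor task
#'
#' Maps each task onto the angle whose curve defines its repetitions and
#' ROM: frontal rise -> shoulder flexion (SF), lateral rise -> shoulder
#' abduction (SA), backward push -> shoulder extension (SE), lateral
#' bending -> local spinal inclination (SIL), twist -> local spinal
#' rotation (SRL), anterior flexion -> trunk inclination (TRUNK).
#'
#' @param task task name.
#' @return angle label string.
#' @export
primary_angle_label <- function(task) {
  switch(match.arg(task, names(.task_defaults)),
         frontal_rise = "SF", lateral_rise = "SA", backward_push = "SE",
         lateral_bending = "SIL", twist = "SRL", anterior_flexion = "TRUNK")
}

# per-task defaults: typical active ROM (deg) and repetition period (s)
# consistent with baseline group means (set duration ~= 6 p + 5 * 0.25 p)
.task_defaults <- list(
  frontal_rise     = list(true_rom = 111.22, rep_period = 4.80),
  lateral_rise     = list(true_rom = 107.29, rep_period = 4.26),
  backward_push    = list(true_rom = 29.92,  rep_period = 3.70),
  lateral_bending  = list(true_rom = 37.60,  rep_period = 4.24),
  twist            = list(true_rom = 27.03,  rep_period = 4.40),
  anterior_flexion = list(true_rom = 88.52,  rep_period = 3.08)
)

#' Task profile for trial simulation
#'
#' @param task one of the six motor tasks.
#' @param true_rom mean per-repetition angular excursion (deg); default is
#'   the task's baseline group mean.
#' @param rep_rom_sd SD of the i.i.d. per-repetition ROM deviations (deg).
#' @param n_reps repetitions per set.
#' @param rep_period duration of one repetition (s).
#' @param rest rest-plateau duration between repetitions (s); default a
#'   quarter of `rep_period`.
#' @param trend additive ROM drift per repetition (deg/repetition); positive
#'   values emulate intra-session performance gains, negative values fatigue.
#' @return object of class `task_profile`.
#' @examples
#' task_profile("twist", trend = 1.9)
#' @export
task_profile <- function(task, true_rom = NULL, rep_rom_sd = 3, n_reps = 6,
                         rep_period = NULL, rest = NULL, trend = 0) {
  task <- match.arg(task, names(.task_defaults))
  d <- .task_defaults[[task]]
  true_rom <- if (is.null(true_rom)) d$true_rom else true_rom
  rep_period <- if (is.null(rep_period)) d$rep_period else rep_period
  rest <- if (is.null(rest)) rep_period / 4 else rest
  if (true_rom <= 0) stop("true_rom must be positive")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (rep_period <= 0) stop("rep_period must be positive")
  if (rep_rom_sd < 0 || rest < 0) stop("rep_rom_sd and rest must be >= 0")
  structure(
    list(task = task, true_rom = true_rom, rep_rom_sd = rep_rom_sd,
         n_reps = as.integer(n_reps), rep_period = rep_period, rest = rest,
         trend = trend),
    class = "task_profile"
  )
}

#' @export
print.task_profile <- function(x, ...) {
  cat(sprintf(
    "<task_profile> %s: ROM %.2f deg (sd %.2f, trend %+.2f/rep), %d reps of %.2f s (rest %.2f s)\n",
    x$task, x$true_rom, x$rep_rom_sd, x$trend, x$n_reps, x$rep_period,
    x$rest))
  invisible(x)
}

#' Derive a per-trial seed from a master seed
#'
#' Deterministic counter scheme: `(seed + 97 * counter) mod (2^31 - 1)`,
#' so cohorts with a single master seed get reproducible, distinct
#' per-trial streams.
#'
#' @param seed master seed (integer).
#' @param counter trial counter (integer >= 0).
#' @return integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 97 * as.numeric(counter)) %% 2147483647)
}

# rotate a static point about an axis-aligned line through `pivot` by the
# per-sample angles phi (radians); returns an n x 3 matrix
.rotate_point <- function(p0, pivot, axis, phi) {
  rel <- as.numeric(p0) - as.numeric(pivot)
  cp <- cos(phi); sp <- sin(phi)
  out <- switch(axis,
    X = cbind(rel[1] + 0 * phi,
              rel[2] * cp - rel[3] * sp,
              rel[2] * sp + rel[3] * cp),
    Y = cbind(rel[1] * cp + rel[3] * sp,
              rel[2] + 0 * phi,
              -rel[1] * sp + rel[3] * cp),
    Z = cbind(rel[1] * cp - rel[2] * sp,
              rel[1] * sp + rel[2] * cp,
              rel[3] + 0 * phi))
  sweep(out, 2, as.numeric(pivot), `+`)
}

#' Simulate one trial by forward kinematics
#'
#' The task's driving angle follows, per repetition `r`,
#' `theta_r(t) = (ROM_r / 2) * (1 - cos(2 * pi * t / rep_period))` with
#' `ROM_r = true_rom + trend * (r - 1) + N(0, rep_rom_sd^2)`, repetitions
#' separated by rest plateaus at the neutral posture and preceded/followed
#' by a lead-in/out plateau. Markers are placed by rigid-segment forward
#' kinematics and i.i.d. Gaussian noise of SD `noise_sd` is added to every
#' coordinate. Ground truth records each realised `ROM_r` and the exact
#' first-repetition-start to last-repetition-end duration.
#'
#' @param profile a [task_profile()].
#' @param body a [body_model()].
#' @param noise_sd marker noise SD (mm), >= 0.
#' @param seed integer seed (trial-level).
#' @param side `"left"`, `"right"`, or `"none"` (anterior flexion only).
#' @param sample_rate Hz.
#' @param lead lead-in/out plateau duration (s).
#' @param pelvis_follow fraction of the driving angle applied as pelvic
#'   rotation about the vertical axis (secondary degree of freedom used to
#'   probe angle cross-talk; 0 = rigid pelvis).
#' @return object of class `simulated_trial`: list with `trajectory`
#'   (a [marker_trajectory_set()]), `truth` (list: `rom_per_rep`,
#'   `duration`, `start_index`, `end_index`, `primary_label`), `profile`,
#'   `side`.
#' @examples
#' tr <- simulate_trial(task_profile("frontal_rise", rep_rom_sd = 0),
#'                      noise_sd = 0, seed = 1)
#' tr$truth$rom_per_rep
#' @export
simulate_trial <- function(profile, body = body_model(), noise_sd = 0,
                           seed = 1L, side = c("right", "left", "none"),
                           sample_rate = 100, lead = 0.5,
                           pelvis_follow = 0) {
  stopifnot(inherits(profile, "task_profile"))
  side <- match.arg(side)
  task <- profile$task
  if (task == "anterior_flexion") side <- "none"
  else if (side == "none")
    stop("side must be left or right for task ", task)
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  set.seed(seed)
  nrep <- profile$n_reps
  rom_r <- profile$true_rom + profile$trend * (seq_len(nrep) - 1) +
    stats::rnorm(nrep, 0, profile$rep_rom_sd)
  rom_r <- pmax(rom_r, 1) # active ROM cannot be negative

  n_lead <- max(1L, round(lead * sample_rate))
  n_act <- 2L * max(1L, round(profile$rep_period * sample_rate / 2))
  n_rest <- round(profile$rest * sample_rate)
  n <- 2L * n_lead + nrep * n_act + (nrep - 1L) * n_rest
  theta <- numeric(n)
  cursor <- n_lead
  for (r in seq_len(nrep)) {
    k <- seq_len(n_act) - 1L
    theta[cursor + k + 1L] <- rom_r[r] / 2 * (1 - cos(2 * pi * k / n_act))
    cursor <- cursor + n_act + if (r < nrep) n_rest else 0L
  }
  start_index <- n_lead + 1L            # first active sample (1-based)
  end_index <- n_lead + nrep * n_act + (nrep - 1L) * n_rest + 1L
  duration <- (end_index - start_index) / sample_rate

  phi <- theta * pi / 180
  sgn <- if (side == "left") -1 else 1
  neutral <- body$neutral
  rep_row <- function(p0) matrix(rep(as.numeric(p0), each = n), nrow = n,
                                 dimnames = list(NULL, c("X", "Y", "Z")))
  positions <- lapply(neutral, rep_row)
  L <- body$upper_arm_length
  upper <- c("L3", "L1", "T6", "T1", "RACR", "LACR", "RELB", "LELB")
  pivot <- neutral$S1

  if (task %in% c("frontal_rise", "lateral_rise", "backward_push")) {
    acr <- if (side == "right") "RACR" else "LACR"
    elb <- if (side == "right") "RELB" else "LELB"
    dirm <- switch(task,
      frontal_rise  = cbind(0 * phi, -cos(phi), sin(phi)),
      backward_push = cbind(0 * phi, -cos(phi), -sin(phi)),
      lateral_rise  = cbind(sgn * sin(phi), -cos(phi), 0 * phi))
    positions[[elb]] <- positions[[acr]] + L * dirm
  } else if (task == "lateral_bending") {
    for (m in upper)
      positions[[m]] <- .rotate_point(neutral[[m]], pivot, "Z", -sgn * phi)
  } else if (task == "twist") {
    for (m in upper)
      positions[[m]] <- .rotate_point(neutral[[m]], pivot, "Y", sgn * phi)
  } else { # anterior_flexion
    for (m in upper)
      positions[[m]] <- .rotate_point(neutral[[m]], pivot, "X", phi)
  }

  if (pelvis_follow != 0) {
    pcen <- (neutral$RASIS + neutral$LASIS) / 2
    for (m in c("RASIS", "LASIS", "RPSIS", "LPSIS"))
      positions[[m]] <- .rotate_point(neutral[[m]], pcen, "Y",
                                      pelvis_follow * sgn * phi)
  }

  if (noise_sd > 0)
    positions <- lapply(positions, function(p)
      p + matrix(stats::rnorm(3 * n, 0, noise_sd), nrow = n))

  structure(
    list(trajectory = marker_trajectory_set(positions, sample_rate),
         truth = list(rom_per_rep = rom_r, duration = duration,
                      start_index = start_index, end_index = end_index,
                      primary_label = primary_angle_label(task)),
         profile = profile, side = side, seed = seed),
    class = "simulated_trial"
  )
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(
    "<simulated_trial> %s (%s): %d reps, true ROM %.2f-%.2f deg, duration %.2f s\n",
    x$profile$task, x$side, length(x$truth$rom_per_rep),
    min(x$truth$rom_per_rep), max(x$truth$rom_per_rep), x$truth$duration))
  invisible(x)
}

#' Inject random gaps into a trajectory set
#'
#' Each interior sample of each marker is masked independently with
#' probability `rate`; runs longer than `max_len` are truncated and the
#' first and last samples are never masked, so gaps stay recoverable by
#' linear interpolation.
#'
#' @param t a [marker_trajectory_set()].
#' @param rate per-sample gap probability in `[0, 1)`.
#' @param max_len maximum gap run length (samples).
#' @param seed integer seed.
#' @return a [marker_trajectory_set()] with gaps marked and coordinates
#'   under gaps set `NA`.
#' @export
inject_gaps <- function(t, rate, max_len = 10L, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(t)
  set.seed(seed)
  n <- t$n_samples
  positions <- t$positions
  gaps <- t$gap_mask
  for (m in names(positions)) {
    g <- stats::runif(n) < rate
    g[c(1L, n)] <- FALSE
    r <- rle(g)
    too_long <- r$values & r$lengths > max_len
    if (any(too_long)) {
      ends <- cumsum(r$lengths)
      for (i in which(too_long)) {
        run <- (ends[i] - r$lengths[i] + 1L):ends[i]
        g[run[-seq_len(max_len)]] <- FALSE
      }
    }
    gaps[[m]] <- gaps[[m]] | g
    positions[[m]][g, ] <- NA_real_
  }
  marker_trajectory_set(positions, t$sample_rate, gaps)
}
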