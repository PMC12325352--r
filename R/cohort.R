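#' Reference group statistics used as default cohort parameterization
#'
#' Published-style group means and SDs of the primary-angle ROM (deg) and
#' task duration (s) for each task, group (WG = treated, CG = control) and
#' session (PRE/ACUTE/POST; the control group has no ACUTE session). These
#' numbers parameterize [cohort_spec()] by default so that simulated
#' cohorts reproduce the study conditions: e.g. shoulder-extension ROM
#' rising from 29.92 (15.67) at PRE to 38.73 (17.70) at POST in the
#' treated group while the control group stays near 30 deg.
#'
#' @return data frame with columns `task`, `parameter`, `group`, `session`,
#'   `mean`, `sd`.
#' @export
cohort_reference <- function() {
  row <- function(task, parameter, group, session, mean, sd)
    data.frame(task = task, parameter = parameter, group = group,
               session = session, mean = mean, sd = sd)
  ref <- list(
    # task, parameter, WG PRE/ACUTE/POST (m, sd), CG PRE/POST (m, sd)
    list("frontal_rise", "SF_ROM", c(111.22, 14.38), c(110.47, 14.76),
         c(116.13, 13.18), c(116.27, 13.95), c(115.20, 12.86)),
    list("frontal_rise", "duration", c(34.76, 5.66), c(29.71, 6.13),
         c(31.35, 5.03), c(36.18, 6.93), c(34.68, 8.00)),
    list("lateral_rise", "SA_ROM", c(107.29, 19.52), c(105.92, 21.33),
         c(114.39, 20.86), c(109.57, 21.76), c(113.46, 19.36)),
    list("lateral_rise", "duration", c(30.95, 6.05), c(27.21, 6.21),
         c(28.10, 5.19), c(32.21, 7.41), c(30.55, 7.77)),
    list("backward_push", "SE_ROM", c(29.92, 15.67), c(32.63, 17.54),
         c(38.73, 17.70), c(30.08, 10.94), c(31.07, 8.55)),
    list("backward_push", "duration", c(26.75, 6.82), c(24.81, 5.56),
         c(24.69, 4.18), c(27.22, 4.95), c(25.40, 4.99)),
    list("lateral_bending", "SIL_ROM", c(37.60, 10.88), c(38.73, 10.67),
         c(41.93, 11.26), c(37.28, 7.59), c(36.99, 7.99)),
    list("lateral_bending", "duration", c(30.67, 7.05), c(25.25, 5.38),
         c(27.47, 4.81), c(34.66, 7.10), c(30.83, 5.13)),
    list("twist", "SRL_ROM", c(27.03, 10.32), c(31.30, 11.29),
         c(31.85, 11.74), c(25.17, 9.09), c(25.79, 8.81)),
    list("twist", "duration", c(31.83, 8.28), c(27.91, 5.93),
         c(28.86, 4.68), c(34.51, 8.10), c(32.35, 5.59)),
    list("anterior_flexion", "TRUNK_ROM", c(88.52, 17.53), c(88.25, 17.53),
         c(90.84, 16.16), c(86.71, 15.77), c(87.32, 15.23)),
    list("anterior_flexion", "duration", c(22.26, 6.57), c(19.72, 5.07),
         c(19.30, 3.82), c(25.54, 5.69), c(22.77, 3.80))
  )
  out <- do.call(rbind, lapply(ref, function(r) rbind(
    row(r[[1]], r[[2]], "WG", "PRE", r[[3]][1], r[[3]][2]),
    row(r[[1]], r[[2]], "WG", "ACUTE", r[[4]][1], r[[4]][2]),
    row(r[[1]], r[[2]], "WG", "POST", r[[5]][1], r[[5]][2]),
    row(r[[1]], r[[2]], "CG", "PRE", r[[6]][1], r[[6]][2]),
    row(r[[1]], r[[2]], "CG", "POST", r[[7]][1], r[[7]][2])
  )))
  rownames(out) <- NULL
  out
}

#' Cohort simulation specification
#'
#' Defines a whole simulated study: group sizes, tasks, the group/session
#' distribution of each participant's true primary-angle ROM and task
#' duration (defaults from [cohort_reference()]), the compound-symmetric
#' within-subject correlation of true values across sessions, the
#' repetition structure and marker noise. The treated group (WG) is
#' assessed at PRE, ACUTE and POST; the control group (CG) at PRE and POST.
#'
#' @param n_per_group participants per group (>= 2).
#' @param tasks subset of the six tasks to simulate.
#' @param reference data frame in the format of [cohort_reference()].
#' @param within_correlation correlation of a participant's true values
#'   across sessions (compound symmetry).
#' @param noise_sd marker noise SD (mm).
#' @param rep_rom_sd per-repetition ROM SD (deg).
#' @param n_reps repetitions per set.
#' @param n_sets sets per side (1 or 2).
#' @param both_sides simulate left and right for bilateral tasks.
#' @param rep_period repetition period (s); `NULL` derives it per trial
#'   from the drawn task duration (`duration = n_reps * p + (n_reps - 1) * p / 4`).
#' @param trend_acute ROM drift per repetition in the ACUTE session
#'   (deg/rep), emulating the within-session performance gain seen right
#'   after treatment; 0 by default.
#' @param sessions restrict the simulated sessions (default: PRE/ACUTE/POST
#'   for WG, PRE/POST for CG); e.g. `c("PRE", "POST")` skips ACUTE.
#' @param seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 21, tasks = names(.task_defaults),
                        reference = cohort_reference(),
                        within_correlation = 0.8, noise_sd = 1.0,
                        rep_rom_sd = 3, n_reps = 6, n_sets = 2,
                        both_sides = TRUE, rep_period = NULL,
                        trend_acute = 0, sessions = NULL, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  tasks <- match.arg(tasks, names(.task_defaults), several.ok = TRUE)
  if (within_correlation < 0 || within_correlation > 1)
    stop("within_correlation must be in [0, 1]")
  if (any(reference$sd < 0)) stop("reference SDs must be >= 0")
  structure(
    list(n_per_group = as.integer(n_per_group), tasks = tasks,
         reference = reference, within_correlation = within_correlation,
         noise_sd = noise_sd, rep_rom_sd = rep_rom_sd,
         n_reps = as.integer(n_reps), n_sets = as.integer(n_sets),
         both_sides = isTRUE(both_sides), rep_period = rep_period,
         trend_acute = trend_acute, sessions = sessions,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d/group, %d task(s), %d set(s) x %d reps, noise %.1f mm, rho %.2f, seed %d\n",
    x$n_per_group, length(x$tasks), x$n_sets, x$n_reps, x$noise_sd,
    x$within_correlation, x$seed))
  invisible(x)
}

# draw participant x session true values with compound-symmetric
# within-subject correlation: value_s = mu_s + sd_s * (sqrt(rho) z_i +
# sqrt(1 - rho) e_is)
.draw_truth <- function(spec) {
  rho <- spec$within_correlation
  ref <- spec$reference
  rows <- list()
  for (group in c("WG", "CG")) {
    sessions <- if (group == "WG") c("PRE", "ACUTE", "POST") else c("PRE", "POST")
    if (!is.null(spec$sessions)) sessions <- intersect(sessions, spec$sessions)
    for (i in seq_len(spec$n_per_group)) {
      pid <- sprintf("%s%02d", group, i)
      for (task in spec$tasks) {
        pars <- unique(ref$parameter[ref$task == task])
        for (par in pars) {
          z <- stats::rnorm(1)
          e <- stats::rnorm(length(sessions))
          mu <- sd <- numeric(length(sessions))
          for (k in seq_along(sessions)) {
            sel <- ref$task == task & ref$parameter == par &
              ref$group == group & ref$session == sessions[k]
            if (!any(sel))
              stop("reference is missing ", task, "/", par, " for ",
                   group, " ", sessions[k])
            mu[k] <- ref$mean[sel][1]; sd[k] <- ref$sd[sel][1]
          }
          val <- mu + sd * (sqrt(rho) * z + sqrt(1 - rho) * e)
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pid, group = group, session = sessions,
            task = task, parameter = par, value = val)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  # physical floors: ROM >= 5 deg, duration long enough for the repetitions
  is_rom <- grepl("_ROM$", out$parameter)
  out$value[is_rom] <- pmax(out$value[is_rom], 5)
  out$value[!is_rom] <- pmax(out$value[!is_rom], 5)
  out
}

#' Simulate a whole cohort of marker-level trials
#'
#' Draws each participant's true primary-angle ROM and task duration per
#' session from the configured group/session normal distributions (with
#' within-subject correlation across sessions), then synthesises every
#' trial by forward kinematics via [simulate_trial()]. WG participants get
#' three sessions (PRE/ACUTE/POST), CG two (PRE/POST); bilateral tasks get
#' both sides when `spec$both_sides`, and `spec$n_sets` sets each.
#'
#' @param spec a [cohort_spec()].
#' @param handler optional `function(metadata, trial)` called for every
#'   simulated trial (trial is a `simulated_trial`); when supplied, trials
#'   are not accumulated in memory and only the truth table is returned.
#' @return list with `truth` (long-format data frame of true values,
#'   one row per participant x session x task x parameter) and, without a
#'   handler, `trials`: list of `list(metadata, trial)`.
#' @export
simulate_cohort <- function(spec, handler = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  truth <- .draw_truth(spec)
  trials <- if (is.null(handler)) vector("list", 0L) else NULL
  counter <- 0L
  get_truth <- function(pid, session, task, par) {
    sel <- truth$participant == pid & truth$session == session &
      truth$task == task & truth$parameter == par
    truth$value[sel][1]
  }
  for (pid in unique(truth$participant)) {
    group <- truth$group[truth$participant == pid][1]
    sessions <- if (group == "WG") c("PRE", "ACUTE", "POST") else c("PRE", "POST")
    if (!is.null(spec$sessions)) sessions <- intersect(sessions, spec$sessions)
    for (session in sessions) {
      for (task in spec$tasks) {
        rom_par <- paste0(primary_angle_label(task), "_ROM")
        rom <- get_truth(pid, session, task, rom_par)
        dur <- get_truth(pid, session, task, "duration")
        p <- if (is.null(spec$rep_period)) {
          dur / (spec$n_reps + (spec$n_reps - 1) / 4)
        } else spec$rep_period
        trend <- if (session == "ACUTE") spec$trend_acute else 0
        # inter-repetition variability scales with the movement: capped at
        # 10% of the participant's true ROM
        prof <- task_profile(task, true_rom = rom,
                             rep_rom_sd = min(spec$rep_rom_sd, 0.1 * rom),
                             n_reps = spec$n_reps, rep_period = p,
                             trend = trend)
        sides <- if (task == "anterior_flexion") "none"
                 else if (spec$both_sides) c("right", "left") else "right"
        for (side in sides) {
          for (set_i in seq_len(spec$n_sets)) {
            counter <- counter + 1L
            md <- trial_metadata(pid, group, session, task, side, set_i)
            tr <- simulate_trial(prof, noise_sd = spec$noise_sd,
                                 seed = derive_seed(spec$seed, counter),
                                 side = if (side == "none") "none" else side)
            if (is.null(handler)) {
              trials[[length(trials) + 1L]] <- list(metadata = md, trial = tr)
            } else {
              handler(md, tr)
            }
          }
        }
      }
    }
  }
  if (is.null(handler)) list(truth = truth, trials = trials)
  else list(truth = truth)
}
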