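# Synthetic-trial and cohort generator: ground-truth construction,
# determinism, gap injection, cohort structure and convergence.

test_that("noiseless trials have per-repetition excursions equal to truth", {
  for (task in c("frontal_rise", "twist", "anterior_flexion")) {
    prof <- task_profile(task)
    side <- if (task == "anterior_flexion") "none" else "right"
    tr <- simulate_trial(prof, noise_sd = 0, seed = 2, side = side)
    ang <- primary_angle(tr$trajectory, task, side)
    reps <- detect_repetitions(ang, expected = 6)
    expect_equal(nrow(reps), 6)
    expect_lt(max(abs(reps$rom - tr$truth$rom_per_rep)), 1e-6)
  }
})

test_that("a positive per-repetition trend yields increasing true ROMs", {
  prof <- task_profile("twist", true_rom = 29.66, rep_rom_sd = 0,
                       trend = 1.9)
  tr <- simulate_trial(prof, noise_sd = 0, seed = 1, side = "right")
  expect_true(all(diff(tr$truth$rom_per_rep) > 0))
  expect_equal(tr$truth$rom_per_rep[1], 29.66)
  expect_equal(tr$truth$rom_per_rep[6], 29.66 + 5 * 1.9)
})

test_that("same profile and seed give identical trajectories, different seeds differ", {
  prof <- task_profile("lateral_rise")
  a <- simulate_trial(prof, noise_sd = 1.5, seed = 42, side = "left")
  b <- simulate_trial(prof, noise_sd = 1.5, seed = 42, side = "left")
  c <- simulate_trial(prof, noise_sd = 1.5, seed = 43, side = "left")
  expect_identical(a$trajectory$positions, b$trajectory$positions)
  expect_false(identical(a$trajectory$positions, c$trajectory$positions))
})

test_that("simulate_trial validates its inputs", {
  prof <- task_profile("twist")
  expect_error(simulate_trial(prof, noise_sd = -1, side = "right"),
               "noise_sd")
  expect_error(simulate_trial(prof, side = "none"), "side")
  expect_error(task_profile("twist", true_rom = -5), "positive")
})

test_that("gap injection masks the expected fraction, bounded run length", {
  tr <- simulate_trial(task_profile("twist", rep_period = 2, n_reps = 6),
                       noise_sd = 0, seed = 1, side = "right")
  n <- tr$trajectory$n_samples
  expect_identical(inject_gaps(tr$trajectory, 0)$gap_mask,
                   tr$trajectory$gap_mask)
  tg <- inject_gaps(tr$trajectory, rate = 0.05, max_len = 8, seed = 7)
  counts <- vapply(tg$gap_mask, sum, numeric(1))
  # binomial tolerance: n * 0.05 +- 4 sd per marker
  expect_true(all(abs(counts - 0.05 * n) < 4 * sqrt(n * 0.05 * 0.95) + 8))
  runs <- unlist(lapply(tg$gap_mask, function(g) {
    r <- rle(g); r$lengths[r$values]
  }))
  expect_lte(max(runs), 8)
  expect_false(any(vapply(tg$gap_mask, function(g) g[1] || g[n],
                          logical(1))))
  expect_error(inject_gaps(tr$trajectory, 1.2), "rate")
})

test_that("cohort has the study's session structure and trial counts", {
  spec <- cohort_spec(n_per_group = 2, tasks = c("twist", "anterior_flexion"),
                      n_sets = 2, both_sides = TRUE, noise_sd = 0,
                      rep_period = 1, seed = 5)
  out <- simulate_cohort(spec)
  md <- lapply(out$trials, `[[`, "metadata")
  sessions_wg <- unique(vapply(md[vapply(md, function(m) m$group == "WG",
                                         logical(1))], `[[`,
                               character(1), "session"))
  sessions_cg <- unique(vapply(md[vapply(md, function(m) m$group == "CG",
                                         logical(1))], `[[`,
                               character(1), "session"))
  expect_setequal(sessions_wg, c("PRE", "ACUTE", "POST"))
  expect_setequal(sessions_cg, c("PRE", "POST"))
  # per participant-session: twist 2 sides x 2 sets + flexion 2 sets = 6
  n_ps <- 2 * 3 + 2 * 2 # WG sessions + CG sessions over participants
  expect_length(out$trials, n_ps * 6)
  # truth table covers every participant x session x task x parameter
  expect_equal(nrow(out$truth), n_ps * 2 * 2)
})

test_that("degenerate cohort (all SDs zero) reproduces the configured gains", {
  ref <- cohort_reference()
  ref <- ref[ref$task == "backward_push", ]
  ref$sd <- 0
  spec <- cohort_spec(n_per_group = 3, tasks = "backward_push",
                      reference = ref, noise_sd = 0, rep_rom_sd = 0,
                      n_sets = 1, both_sides = FALSE, rep_period = 1,
                      seed = 2)
  out <- simulate_cohort(spec)
  tr <- out$truth
  wg <- tr[tr$group == "WG" & tr$parameter == "SE_ROM", ]
  gain <- wg$value[wg$session == "POST"] - wg$value[wg$session == "PRE"]
  expect_equal(unique(round(gain, 10)), 38.73 - 29.92)
})

test_that("fixed master seed gives an identical truth table across runs", {
  spec <- cohort_spec(n_per_group = 2, tasks = "twist", n_sets = 1,
                      both_sides = FALSE, rep_period = 1, seed = 99)
  a <- simulate_cohort(spec, handler = function(md, tr) NULL)
  b <- simulate_cohort(spec, handler = function(md, tr) NULL)
  expect_identical(a$truth, b$truth)
})

test_that("cohort sample means converge to the configured distribution", {
  # values-level convergence of the truth draw at large n
  spec <- cohort_spec(n_per_group = 2000, tasks = "backward_push",
                      sessions = c("PRE", "POST"), seed = 31)
  set.seed(spec$seed)
  truth <- romocap:::.draw_truth(spec)
  v <- truth$value[truth$group == "WG" & truth$session == "POST" &
                     truth$parameter == "SE_ROM"]
  se <- 17.70 / sqrt(2000)
  expect_lt(abs(mean(v) - 38.73), 3 * se + 0.1) # +0.1 for the 5-deg floor
})

test_that("secondary pelvic motion leaves local-frame twist unchanged", {
  prof <- task_profile("twist", rep_rom_sd = 0)
  rigid <- simulate_trial(prof, noise_sd = 0, seed = 1, side = "right")
  follow <- simulate_trial(prof, noise_sd = 0, seed = 1, side = "right",
                           pelvis_follow = 0.3)
  a_r <- primary_angle(rigid$trajectory, "twist", "right")
  a_f <- primary_angle(follow$trajectory, "twist", "right")
  # SRL discounts pelvic rotation: the shoulder line moved WITH the pelvis
  # by 0.3 of the drive, so the local angle shrinks by exactly that share
  expect_equal(max(a_f$values) - min(a_f$values),
               0.7 * (max(a_r$values) - min(a_r$values)), tolerance = 1e-6)
  # absolute-frame rotation keeps the full excursion
  s_r <- spine_line_angles(rigid$trajectory,
                           build_local_frame(rigid$trajectory))$SRA
  s_f <- spine_line_angles(follow$trajectory,
                           build_local_frame(follow$trajectory))$SRA
  expect_equal(diff(range(s_f$values)), diff(range(s_r$values)),
               tolerance = 1e-6)
})
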