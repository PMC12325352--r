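# Local-frame construction and the measured-angle set, checked against
# scalar acos/atan2 oracles and rigid-rotation reasoning.

test_that("lab-aligned pelvis yields the identity frame", {
  t <- marker_trajectory_set(
    list(RASIS = cbind(100, 0, 0), LASIS = cbind(-100, 0, 0),
         RPSIS = cbind(20, 0, -150), LPSIS = cbind(-20, 0, -150)),
    100)
  f <- build_local_frame(t)
  expect_equal(as.numeric(f$x), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(as.numeric(f$y), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(f$z), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(f$origin), c(0, 0, 0))
})

test_that("a rotated pelvis produces the rotated identity axes", {
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  p0 <- list(RASIS = c(100, 0, 0), LASIS = c(-100, 0, 0),
             RPSIS = c(20, 0, -150), LPSIS = c(-20, 0, -150))
  t <- marker_trajectory_set(
    lapply(p0, function(p) matrix(as.numeric(R %*% p), nrow = 1)), 100)
  f <- build_local_frame(t)
  expect_equal(as.numeric(f$x), as.numeric(R %*% c(1, 0, 0)),
               tolerance = 1e-9)
  expect_equal(as.numeric(f$y), as.numeric(R %*% c(0, 1, 0)),
               tolerance = 1e-9)
  expect_equal(as.numeric(f$z), as.numeric(R %*% c(0, 0, 1)),
               tolerance = 1e-9)
})

test_that("collinear pelvic landmarks are a degenerate-geometry error", {
  t <- marker_trajectory_set(
    list(RASIS = cbind(100, 0, 0), LASIS = cbind(-100, 0, 0),
         RPSIS = cbind(0, 0, 0), LPSIS = cbind(0, 0, 0)),
    100)
  expect_error(build_local_frame(t), "collinear|degenerate")
})

test_that("frames are orthonormal and right-handed on simulated trials", {
  for (task in c("twist", "anterior_flexion")) {
    tr <- simulate_trial(task_profile(task, rep_period = 1), noise_sd = 2,
                         seed = 6,
                         side = if (task == "twist") "left" else "none")
    f <- build_local_frame(tr$trajectory)
    expect_lt(max(abs(rowSums(f$x * f$y))), 1e-9)
    expect_lt(max(abs(rowSums(f$x^2) - 1)), 1e-9)
    expect_lt(max(abs(rowSums(f$y^2) - 1)), 1e-9)
    zz <- cbind(f$x[, 2] * f$y[, 3] - f$x[, 3] * f$y[, 2],
                f$x[, 3] * f$y[, 1] - f$x[, 1] * f$y[, 3],
                f$x[, 1] * f$y[, 2] - f$x[, 2] * f$y[, 1])
    expect_lt(max(abs(f$z - zz)), 1e-9)
    expect_true(all(f$y[, 2] > 0))
  }
})

test_that("shoulder angles match their planar definitions", {
  bm <- body_model()
  base <- lapply(bm$neutral, as.numeric)
  mk <- function(pos) posture_traj(pos)
  # neutral arm: all three zero
  t0 <- mk(base)
  s0 <- shoulder_angles(t0, build_local_frame(t0), "right")
  expect_equal(s0$SF$values, 0)
  expect_equal(s0$SA$values, 0)
  expect_equal(s0$SE$values, 0)
  # horizontal forward arm: SF = 90
  p <- base; p$RELB <- p$RACR + c(0, 0, 300)
  t1 <- mk(p)
  s1 <- shoulder_angles(t1, build_local_frame(t1), "right")
  expect_equal(s1$SF$values, 90)
  # arm 38.73 deg posterior of -y in the sagittal plane: SE = 38.73
  th <- 38.73 * pi / 180
  p <- base; p$RELB <- p$RACR + 300 * c(0, -cos(th), -sin(th))
  t2 <- mk(p)
  s2 <- shoulder_angles(t2, build_local_frame(t2), "right")
  expect_equal(s2$SE$values, 38.73, tolerance = 1e-9)
  expect_equal(s2$SF$values, -38.73, tolerance = 1e-9)
})

test_that("shoulder-line angles match closed-form dot products", {
  bm <- body_model()
  base <- lapply(bm$neutral, as.numeric)
  t0 <- posture_traj(base)
  f0 <- build_local_frame(t0)
  a0 <- spine_line_angles(t0, f0)
  expect_equal(a0$SIA$values, 90)
  expect_equal(a0$SRA$values, 90)
  expect_equal(a0$SIL$values, 90)
  expect_equal(a0$SRL$values, 90)
  # shoulders tilted 20 deg from horizontal in the frontal plane
  th <- 20 * pi / 180
  p <- base
  p$RACR <- p$LACR + 380 * c(cos(th), sin(th), 0)
  t1 <- posture_traj(p)
  a1 <- spine_line_angles(t1, build_local_frame(t1))
  expect_equal(a1$SIA$values, 70, tolerance = 1e-9)
})

test_that("local angles discount pelvic rotation, lab angles follow it", {
  tr <- simulate_trial(task_profile("twist", rep_rom_sd = 0),
                       noise_sd = 0, seed = 1, side = "right")
  t0 <- tr$trajectory
  t45 <- rotate_traj_y(t0, 45)
  a0 <- spine_line_angles(t0, build_local_frame(t0))
  a45 <- spine_line_angles(t45, build_local_frame(t45))
  expect_lt(max(abs(a45$SRL$values - a0$SRL$values)), 1e-6)
  expect_lt(max(abs(a45$SIL$values - a0$SIL$values)), 1e-6)
  expect_equal(abs(a45$SRA$values - a0$SRA$values),
               rep(45, length(a0$SRA$values)), tolerance = 1e-6)
})

test_that("segment angles follow rigid-rotation oracles", {
  bm <- body_model()
  base <- lapply(bm$neutral, as.numeric)
  # upright neutral: all segment-vs-vertical angles zero
  t0 <- posture_traj(base)
  f0 <- build_local_frame(t0)
  x0 <- flexion_angles(t0, f0)
  for (lab in c("S1L1", "S1L3", "L1T1", "L1T6", "T6T1", "PELVIS", "TRUNK",
                "THORAX"))
    expect_equal(x0[[lab]]$values, 0, info = lab)
  # rigid whole-trunk pitch of 40 deg about x through S1
  th <- 40 * pi / 180
  pitch <- function(p, pivot) {
    r <- p - pivot
    pivot + c(r[1], r[2] * cos(th) - r[3] * sin(th),
              r[2] * sin(th) + r[3] * cos(th))
  }
  p <- base
  for (m in c("L3", "L1", "T6", "T1", "RACR", "LACR", "RELB", "LELB"))
    p[[m]] <- pitch(p[[m]], base$S1)
  t1 <- posture_traj(p)
  x1 <- flexion_angles(t1, build_local_frame(t1))
  expect_equal(x1$S1L1$values, 40, tolerance = 1e-9)
  expect_equal(x1$L1T1$values, 40, tolerance = 1e-9)
  expect_equal(x1$TRUNK$values, 40, tolerance = 1e-9)
  expect_equal(x1$THORAX$values, 0, tolerance = 1e-9)
  # flex only above T6 by 25 deg: T6T1 = 25, S1L1 = 0
  th <- 25 * pi / 180
  p <- base
  for (m in c("T1", "RACR", "LACR", "RELB", "LELB"))
    p[[m]] <- pitch(p[[m]], base$T6)
  t2 <- posture_traj(p)
  x2 <- flexion_angles(t2, build_local_frame(t2))
  expect_equal(x2$T6T1$values, 25, tolerance = 1e-9)
  expect_equal(x2$S1L1$values, 0, tolerance = 1e-9)
})

test_that("all angle operations agree with the scalar oracle on random postures", {
  set.seed(2024)
  worst <- 0
  for (rep in 1:200) {
    pos <- random_posture()
    t <- posture_traj(pos)
    f <- build_local_frame(t)
    fr <- oracle_frame(pos$RASIS, pos$LASIS, (pos$RPSIS + pos$LPSIS) / 2)
    s <- pos$RACR - pos$LACR
    sl <- oracle_to_local(s, fr)
    a <- spine_line_angles(t, f)
    worst <- max(worst,
      abs(a$SIA$values - oracle_axis_angle(s, c(0, 1, 0))),
      abs(a$SRA$values - oracle_axis_angle(s, c(0, 0, 1))),
      abs(a$SIL$values - oracle_axis_angle(sl, c(0, 1, 0))),
      abs(a$SRL$values - oracle_planar_angle(c(sl[1], 0, sl[3]),
                                             c(0, 0, 1), c(1, 0, 0))))
    arm <- pos$RELB - pos$RACR
    al <- oracle_to_local(arm, fr)
    sh <- shoulder_angles(t, f, "right")
    worst <- max(worst,
      abs(sh$SF$values - oracle_planar_angle(c(0, al[2], al[3]),
                                             c(0, -1, 0), c(0, 0, 1))),
      abs(sh$SE$values - oracle_planar_angle(c(0, al[2], al[3]),
                                             c(0, -1, 0), c(0, 0, -1))),
      abs(sh$SA$values - oracle_planar_angle(c(al[1], al[2], 0),
                                             c(0, -1, 0), c(1, 0, 0))))
    x <- flexion_angles(t, f)
    v_s1l1 <- pos$L1 - pos$S1
    v_s1t1 <- pos$T1 - pos$S1
    loc <- oracle_to_local(v_s1l1, fr)
    worst <- max(worst,
      abs(x$S1L1$values - oracle_axis_angle(v_s1l1, c(0, 1, 0))),
      abs(x$T6T1$values - oracle_axis_angle(pos$T1 - pos$T6, c(0, 1, 0))),
      abs(x$PELVIS$values - oracle_planar_angle(c(0, loc[2], loc[3]),
                                                c(0, 1, 0), c(0, 0, 1))),
      abs(x$TRUNK$values - oracle_planar_angle(c(0, v_s1t1[2], v_s1t1[3]),
                                               c(0, 1, 0), c(0, 0, 1))))
  }
  expect_lt(worst, 1e-9)
})

test_that("compute_angles returns the full labelled set in tidy form", {
  tr <- simulate_trial(task_profile("twist", rep_period = 1), noise_sd = 0,
                       seed = 5, side = "right")
  angles <- compute_angles(tr$trajectory)
  expect_true(all(c("SF_right", "SA_left", "SIA", "SIL", "SRA", "SRL",
                    "S1L1", "T6T1", "PELVIS", "TRUNK", "THORAX") %in%
                    names(angles)))
  df <- angles_to_df(angles)
  expect_setequal(names(df),
                  c("sample", "time_s", "label", "value_deg", "frame_used"))
  expect_equal(nrow(df),
               length(angles) * tr$trajectory$n_samples)
  expect_setequal(unique(df$frame_used), c("local", "laboratory"))
})

test_that("noisy markers keep per-sample angle error small after filtering", {
  tr <- simulate_trial(task_profile("anterior_flexion", rep_rom_sd = 0),
                       noise_sd = 2, seed = 12, side = "none")
  clean <- simulate_trial(task_profile("anterior_flexion", rep_rom_sd = 0),
                          noise_sd = 0, seed = 12, side = "none")
  filt <- lowpass_filter(tr$trajectory)
  a_n <- primary_angle(filt, "anterior_flexion", "none")
  a_c <- primary_angle(clean$trajectory, "anterior_flexion", "none")
  expect_lt(max(abs(a_n$values - a_c$values)), 1.5)
})
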