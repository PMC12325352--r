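# Independent oracles used across the suite: per-sample scalar geometry
# via acos/atan2 on normalized dot products, closed-form ANOVA sums of
# squares, and small trajectory builders. Deliberately written without the
# package's vectorised linear algebra.

deg <- function(rad) rad * 180 / pi

oracle_unit <- function(v) v / sqrt(sum(v^2))

# unsigned angle between a vector and an axis
oracle_axis_angle <- function(v, axis) {
  deg(acos(max(-1, min(1, sum(oracle_unit(v) * oracle_unit(axis))))))
}

# signed angle of the projection of v onto the (e_ref, e_pos) plane,
# measured from e_ref toward e_pos
oracle_planar_angle <- function(v, e_ref, e_pos) {
  deg(atan2(sum(v * e_pos), sum(v * e_ref)))
}

# pelvis frame from one sample's landmark positions (3-vectors)
oracle_frame <- function(rasis, lasis, psis) {
  a <- lasis - psis
  b <- rasis - psis
  nrm <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  y <- oracle_unit(nrm)
  if (y[2] < 0) y <- -y
  x0 <- oracle_unit(rasis - lasis)
  x <- oracle_unit(x0 - sum(x0 * y) * y)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  list(x = x, y = y, z = z)
}

oracle_to_local <- function(v, fr) {
  c(sum(v * fr$x), sum(v * fr$y), sum(v * fr$z))
}

rot3 <- function(yaw, pitch, roll) {
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  Rz <- matrix(c(cr, sr, 0, -sr, cr, 0, 0, 0, 1), 3, 3)
  Ry %*% Rx %*% Rz
}

# one random posture: whole body rotated/translated, the upper body (above
# S1) independently rotated, the arms independently elevated; returns
# marker positions as a list of 3-vectors
random_posture <- function() {
  bm <- body_model()
  whole <- stats::runif(3, -pi / 3, pi / 3)
  upper <- stats::runif(3, -pi / 6, pi / 6)
  shift <- stats::rnorm(3, 0, 300)
  R <- rot3(whole[1], whole[2], whole[3])
  R2 <- rot3(upper[1], upper[2], upper[3])
  arm <- stats::runif(2, 0, pi / 2) # random arm elevation per side
  pos <- lapply(bm$neutral, function(p) as.numeric(p))
  pos$RELB <- pos$RACR + bm$upper_arm_length *
    c(sin(arm[1]) * 0.3, -cos(arm[1]), sin(arm[1]) * 0.95)
  pos$LELB <- pos$LACR + bm$upper_arm_length *
    c(-sin(arm[2]) * 0.4, -cos(arm[2]), sin(arm[2]) * 0.9)
  for (m in c("L3", "L1", "T6", "T1", "RACR", "LACR", "RELB", "LELB"))
    pos[[m]] <- as.numeric(R2 %*% (pos[[m]] - pos$S1)) + pos$S1
  lapply(pos, function(p) as.numeric(R %*% p + shift))
}

# one-sample trajectory set from a posture list
posture_traj <- function(pos, rate = 100) {
  marker_trajectory_set(lapply(pos, function(p) matrix(p, nrow = 1)), rate)
}

# replicate a posture over n samples
posture_traj_n <- function(pos, n, rate = 100) {
  marker_trajectory_set(
    lapply(pos, function(p) matrix(rep(p, each = n), nrow = n)), rate)
}

# rigid rotation of a whole trajectory about the laboratory Y axis
rotate_traj_y <- function(t, degrees) {
  th <- degrees * pi / 180
  pos <- lapply(t$positions, function(p) cbind(
    p[, 1] * cos(th) + p[, 3] * sin(th),
    p[, 2],
    -p[, 1] * sin(th) + p[, 3] * cos(th)))
  marker_trajectory_set(pos, t$sample_rate, t$gap_mask)
}

# closed-form one-way repeated-measures ANOVA from a participants x
# sessions matrix
manual_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_sess <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_err <- sum((m - grand)^2) - ss_sess - ss_subj
  f <- (ss_sess / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(f = f, p = stats::pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# the 2 x 2 mixed-design interaction F equals the squared pooled-variance
# t statistic of the between-group comparison of PRE->POST gain scores
manual_interaction <- function(gain_wg, gain_cg) {
  tt <- stats::t.test(gain_wg, gain_cg, var.equal = TRUE)
  list(f = unname(tt$statistic)^2, p = tt$p.value)
}

# long cohort table from a participants x sessions matrix
matrix_to_table <- function(m, group = "WG") {
  data.frame(
    participant = rep(sprintf("%s%03d", group, seq_len(nrow(m))), ncol(m)),
    group = group,
    session = rep(colnames(m), each = nrow(m)),
    value = as.vector(m))
}
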