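# Pelvis-anchored local frame and the measured-angle set.
#
# Conventions: laboratory frame is right-handed, Y vertical (up), Z
# anterior, X from the subject's left to right. The local frame has
# x medial-lateral (left -> right, along the ASIS line re-orthogonalised
# against the pelvic-plane normal), y the upward pelvic-plane normal and
# z = x cross y (anterior). Planar projection angles are signed in
# (-180, 180]; line-vs-axis angles are unsigned in [0, 180].

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.row_norm <- function(a) sqrt(rowSums(a^2))

.row_unit <- function(a, what = "vector") {
  n <- .row_norm(a)
  if (any(n < 1e-9))
    stop("degenerate geometry: zero-length ", what)
  a / n
}

#' Build the pelvis-anchored local reference frame
#'
#' Per sample: the raw medial-lateral direction is `RASIS - LASIS`; the
#' pelvic plane passes through RASIS, LASIS and the PSIS point (midpoint of
#' both PSIS markers when present, the single PSIS otherwise); `y` is the
#' plane normal oriented upward; `x` is the ASIS direction
#' re-orthogonalised against `y` (Gram-Schmidt); `z = x cross y`. The
#' origin is the ASIS midpoint.
#'
#' @param t a [marker_trajectory_set()] with gap-free RASIS, LASIS and at
#'   least one PSIS marker.
#' @return object of class `local_frame`: list of `n x 3` matrices
#'   `origin`, `x`, `y`, `z`.
#' @export
build_local_frame <- function(t) {
  rasis <- marker_xyz(t, "RASIS")
  lasis <- marker_xyz(t, "LASIS")
  has_r <- "RPSIS" %in% names(t$positions)
  has_l <- "LPSIS" %in% names(t$positions)
  if (!has_r && !has_l)
    stop("local frame needs at least one PSIS marker")
  psis <- if (has_r && has_l) {
    (marker_xyz(t, "RPSIS") + marker_xyz(t, "LPSIS")) / 2
  } else if (has_r) marker_xyz(t, "RPSIS") else marker_xyz(t, "LPSIS")

  x0 <- rasis - lasis
  nrm <- .row_cross(lasis - psis, rasis - psis)
  nn <- .row_norm(nrm)
  span <- .row_norm(x0)
  if (any(nn < 1e-6 * pmax(span^2, 1)))
    stop("degenerate geometry: pelvic landmarks are collinear")
  y <- nrm / nn
  flip <- y[, 2] < 0
  y[flip, ] <- -y[flip, ]
  x0u <- x0 / span
  x <- x0u - y * rowSums(x0u * y)
  x <- .row_unit(x, "medial-lateral axis")
  z <- .row_cross(x, y)
  structure(list(origin = (rasis + lasis) / 2, x = x, y = y, z = z),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  cat(sprintf("<local_frame> %d samples; mean y = (%.3f, %.3f, %.3f)\n",
              nrow(x$y), mean(x$y[, 1]), mean(x$y[, 2]), mean(x$y[, 3])))
  invisible(x)
}

# express lab-frame vectors v (n x 3) in the local frame
.to_local <- function(v, frame) {
  cbind(rowSums(v * frame$x), rowSums(v * frame$y), rowSums(v * frame$z))
}

# unsigned angle (deg) between per-sample vectors and a fixed axis
.angle_to_axis <- function(v, axis) {
  u <- .row_unit(v)
  d <- pmin(1, pmax(-1, u %*% matrix(axis, ncol = 1)))
  as.numeric(acos(d)) * 180 / pi
}

# signed planar angle (deg) of the projection of v onto the plane of unit
# vectors (e_ref, e_pos): 0 along e_ref, positive toward e_pos; samples
# whose projection norm is below `frac` of the vector norm are NA
.planar_angle <- function(p_ref, p_pos, vnorm, frac = 0.01) {
  pn <- sqrt(p_ref^2 + p_pos^2)
  ang <- atan2(p_pos, p_ref) * 180 / pi
  ang[pn < frac * vnorm] <- NA_real_
  ang
}

#' Shoulder angles: flexion, abduction, extension
#'
#' The arm vector `a = elbow - acromion` is expressed in the local frame
#' (or laboratory frame). All three are planar projection angles measured
#' from the neutral downward direction `-y`: shoulder flexion SF in the
#' sagittal (y-z) plane, positive anterior; shoulder extension SE the same
#' construction, positive posterior; shoulder abduction SA in the frontal
#' (x-y) plane, positive away from the midline. A neutral arm hanging along
#' `-y` gives 0 for all three. Samples with a near-degenerate projection
#' (norm below 1% of the arm length) are flagged `NA`.
#'
#' @param t a [marker_trajectory_set()].
#' @param frame a [local_frame()][build_local_frame()]; ignored when
#'   `use_frame = "laboratory"`.
#' @param side `"left"` or `"right"`.
#' @param use_frame `"local"` (default) or `"laboratory"`.
#' @return named list of three [angle_series()]: `SF`, `SA`, `SE`.
#' @export
shoulder_angles <- function(t, frame, side = c("right", "left"),
                            use_frame = c("local", "laboratory")) {
  side <- match.arg(side)
  use_frame <- match.arg(use_frame)
  acr <- marker_xyz(t, if (side == "right") "RACR" else "LACR")
  elb <- marker_xyz(t, if (side == "right") "RELB" else "LELB")
  a <- elb - acr
  al <- if (use_frame == "local") .to_local(a, frame) else a
  vn <- .row_norm(al)
  # sagittal plane: reference -y, positive anterior (+z)
  sf <- .planar_angle(-al[, 2], al[, 3], vn)
  se <- .planar_angle(-al[, 2], -al[, 3], vn)
  # frontal plane: reference -y, positive away from midline
  away <- if (side == "right") 1 else -1
  sa <- .planar_angle(-al[, 2], away * al[, 1], vn)
  list(SF = angle_series("SF", sf, t$sample_rate, use_frame, side),
       SA = angle_series("SA", sa, t$sample_rate, use_frame, side),
       SE = angle_series("SE", se, t$sample_rate, use_frame, side))
}

#' Shoulder-line spinal angles: inclination and rotation
#'
#' The shoulder line `s = RACR - LACR` yields four angles: SIA, the
#' unsigned angle between `s` and the vertical laboratory axis Y; SIL, the
#' same against the local vertical y; SRA, the unsigned angle between `s`
#' and the laboratory anterior axis Z; SRL, the signed angle in the local
#' transverse (x-z) plane between the projection of `s` and the local
#' anterior axis z. Level shoulders with no twist give SIA = SIL = SRA =
#' SRL = 90 degrees.
#'
#' @inheritParams shoulder_angles
#' @return named list of four [angle_series()]: `SIA`, `SIL`, `SRA`, `SRL`.
#' @export
spine_line_angles <- function(t, frame) {
  s <- marker_xyz(t, "RACR") - marker_xyz(t, "LACR")
  sl <- .to_local(s, frame)
  vn <- .row_norm(s)
  sia <- .angle_to_axis(s, c(0, 1, 0))
  sra <- .angle_to_axis(s, c(0, 0, 1))
  sil <- .angle_to_axis(sl, c(0, 1, 0))
  srl <- .planar_angle(sl[, 3], sl[, 1], vn)
  rate <- t$sample_rate
  list(SIA = angle_series("SIA", sia, rate, "laboratory"),
       SIL = angle_series("SIL", sil, rate, "local"),
       SRA = angle_series("SRA", sra, rate, "laboratory"),
       SRL = angle_series("SRL", srl, rate, "local"))
}

#' Spinal-segment and trunk angles for anterior flexion
#'
#' Segment angles are the unsigned angles between caudal-to-cranial
#' landmark-pair vectors and the vertical laboratory axis Y: `S1L1`,
#' `S1L3`, `L1T1`, `L1T6`, `T6T1`. `PELVIS` is the signed sagittal-plane
#' angle of the S1->L1 vector from the local vertical y (positive
#' anterior); `TRUNK` the signed sagittal-plane angle of S1->T1 from
#' laboratory Y; `THORAX` the signed angle between the sagittal-plane
#' projections of L1->T1 and S1->L1 (zero whenever the trunk moves as one
#' rigid segment).
#'
#' @inheritParams shoulder_angles
#' @return named list of eight [angle_series()].
#' @export
flexion_angles <- function(t, frame) {
  pt <- function(m) marker_xyz(t, m)
  s1 <- pt("S1"); l3 <- pt("L3"); l1 <- pt("L1"); t6 <- pt("T6"); t1 <- pt("T1")
  Y <- c(0, 1, 0)
  rate <- t$sample_rate
  seg <- function(label, v, frame_used = "laboratory")
    angle_series(label, .angle_to_axis(v, Y), rate, frame_used)

  v_s1l1 <- l1 - s1
  v_s1t1 <- t1 - s1
  v_l1t1 <- t1 - l1

  loc <- .to_local(v_s1l1, frame)
  pelvis <- .planar_angle(loc[, 2], loc[, 3], .row_norm(v_s1l1))
  trunk <- .planar_angle(v_s1t1[, 2], v_s1t1[, 3], .row_norm(v_s1t1))
  # thorax: angle between sagittal projections of L1->T1 and S1->L1
  a2 <- cbind(v_l1t1[, 2], v_l1t1[, 3])
  b2 <- cbind(v_s1l1[, 2], v_s1l1[, 3])
  thorax <- atan2(a2[, 2] * b2[, 1] - a2[, 1] * b2[, 2],
                  rowSums(a2 * b2)) * 180 / pi
  small <- sqrt(rowSums(a2^2)) < 0.01 * .row_norm(v_l1t1) |
    sqrt(rowSums(b2^2)) < 0.01 * .row_norm(v_s1l1)
  thorax[small] <- NA_real_

  list(
    S1L1 = seg("S1L1", v_s1l1),
    S1L3 = seg("S1L3", l3 - s1),
    L1T1 = seg("L1T1", v_l1t1),
    L1T6 = seg("L1T6", t6 - l1),
    T6T1 = seg("T6T1", t1 - t6),
    PELVIS = angle_series("PELVIS", pelvis, rate, "local"),
    TRUNK = angle_series("TRUNK", trunk, rate, "laboratory"),
    THORAX = angle_series("THORAX", thorax, rate, "laboratory")
  )
}

#' Compute every angle series for one trial
#'
#' Builds the local frame and returns all shoulder, shoulder-line and
#' spinal-segment angle series.
#'
#' @param t a gap-free [marker_trajectory_set()].
#' @param sides sides for the shoulder angles (those with both acromion and
#'   elbow markers present are computed).
#' @return named list of [angle_series()]; shoulder angles are suffixed
#'   with `_right` / `_left`.
#' @export
compute_angles <- function(t, sides = c("right", "left")) {
  frame <- build_local_frame(t)
  out <- list()
  for (side in sides) {
    acr <- if (side == "right") "RACR" else "LACR"
    elb <- if (side == "right") "RELB" else "LELB"
    if (all(c(acr, elb) %in% names(t$positions))) {
      sa <- shoulder_angles(t, frame, side)
      names(sa) <- paste0(names(sa), "_", side)
      out <- c(out, sa)
    }
  }
  if (all(c("RACR", "LACR") %in% names(t$positions)))
    out <- c(out, spine_line_angles(t, frame))
  if (all(c("S1", "L3", "L1", "T6", "T1") %in% names(t$positions)))
    out <- c(out, flexion_angles(t, frame))
  out
}

#' Primary angle series of a trial for a given task
#'
#' Convenience wrapper: builds the local frame and returns the single
#' angle series that defines the task's repetitions (see
#' [primary_angle_label()]).
#'
#' @param t a gap-free [marker_trajectory_set()].
#' @param task task name.
#' @param side `"left"`, `"right"` or `"none"`.
#' @return an [angle_series()].
#' @export
primary_angle <- function(t, task, side = "none") {
  frame <- build_local_frame(t)
  label <- primary_angle_label(task)
  if (label %in% c("SF", "SA", "SE")) {
    if (side == "none") stop("task ", task, " needs a side")
    shoulder_angles(t, frame, side)[[label]]
  } else if (label %in% c("SIL", "SRL")) {
    spine_line_angles(t, frame)[[label]]
  } else {
    flexion_angles(t, frame)[[label]]
  }
}

#' Export angle series to a tidy data frame
#'
#' @param angles named list of [angle_series()] (as returned by
#'   [compute_angles()]).
#' @return data frame with columns `sample`, `time_s`, `label`,
#'   `value_deg`, `frame_used`.
#' @export
angles_to_df <- function(angles) {
  do.call(rbind, lapply(angles, function(a) {
    n <- length(a$values)
    data.frame(sample = seq_len(n), time_s = (seq_len(n) - 1) / a$sample_rate,
               label = a$label, value_deg = a$values, frame_used = a$frame)
  }))
}
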