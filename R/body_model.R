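#' Rigid-segment body model for forward kinematics
#'
#' Neutral-posture landmark positions (mm, laboratory frame: Y up, Z
#' anterior, X left-to-right) for the 14-marker upper-body set, built from a
#' handful of segment dimensions. In the neutral posture the pelvis markers
#' are coplanar and horizontal (so the local pelvis frame coincides with the
#' laboratory frame), the spinal landmarks lie on a vertical line posterior
#' to the pelvis origin, the acromions sit level with T1, and the arms hang
#' along -Y.
#'
#' @param asis_width inter-ASIS distance (mm).
#' @param pelvis_depth ASIS-to-PSIS anterior-posterior depth (mm).
#' @param pelvis_height height of the pelvis plane (mm).
#' @param spine_heights named numeric vector of heights above the floor for
#'   S1, L3, L1, T6, T1 (mm); must be strictly increasing caudal to cranial.
#' @param spine_depth posterior offset of the spinous processes (mm).
#' @param acromion_halfwidth lateral offset of each acromion from the
#'   midline (mm).
#' @param upper_arm_length acromion-to-elbow distance (mm).
#' @return object of class `body_model`: list with `neutral` (named list of
#'   1x3 landmark positions) and the dimensions.
#' @examples
#' bm <- body_model()
#' bm$neutral$T1
#' @export
body_model <- function(asis_width = 240, pelvis_depth = 180,
                       pelvis_height = 1000,
                       spine_heights = c(S1 = 1050, L3 = 1180, L1 = 1280,
                                         T6 = 1420, T1 = 1520),
                       spine_depth = 80, acromion_halfwidth = 190,
                       upper_arm_length = 300) {
  stopifnot(asis_width > 0, pelvis_depth > 0, upper_arm_length > 0,
            acromion_halfwidth > 0)
  need <- c("S1", "L3", "L1", "T6", "T1")
  if (!all(need %in% names(spine_heights)))
    stop("spine_heights must name S1, L3, L1, T6, T1")
  sh <- spine_heights[need]
  if (any(diff(sh) <= 0))
    stop("spinal landmarks must be strictly ordered caudal -> cranial")
  xyz <- function(x, y, z) matrix(c(x, y, z), nrow = 1,
                                  dimnames = list(NULL, c("X", "Y", "Z")))
  neutral <- list(
    RASIS = xyz(asis_width / 2, pelvis_height, pelvis_depth / 2),
    LASIS = xyz(-asis_width / 2, pelvis_height, pelvis_depth / 2),
    RPSIS = xyz(asis_width / 4, pelvis_height, -pelvis_depth / 2),
    LPSIS = xyz(-asis_width / 4, pelvis_height, -pelvis_depth / 2),
    S1 = xyz(0, sh[["S1"]], -spine_depth),
    L3 = xyz(0, sh[["L3"]], -spine_depth),
    L1 = xyz(0, sh[["L1"]], -spine_depth),
    T6 = xyz(0, sh[["T6"]], -spine_depth),
    T1 = xyz(0, sh[["T1"]], -spine_depth),
    RACR = xyz(acromion_halfwidth, sh[["T1"]], -spine_depth / 2),
    LACR = xyz(-acromion_halfwidth, sh[["T1"]], -spine_depth / 2)
  )
  neutral$RELB <- neutral$RACR - xyz(0, upper_arm_length, 0)
  neutral$LELB <- neutral$LACR - xyz(0, upper_arm_length, 0)
  structure(
    list(neutral = neutral, asis_width = asis_width,
         pelvis_depth = pelvis_depth, pelvis_height = pelvis_height,
         spine_heights = sh, spine_depth = spine_depth,
         acromion_halfwidth = acromion_halfwidth,
         upper_arm_length = upper_arm_length),
    class = "body_model"
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf(
    "<body_model> %d landmarks; ASIS width %g mm, upper arm %g mm, T1 at %g mm\n",
    length(x$neutral), x$asis_width, x$upper_arm_length,
    x$spine_heights[["T1"]]))
  invisible(x)
}
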