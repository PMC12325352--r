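#' Marker trajectory set
#'
#' Container for the 3D trajectories of one trial: per-marker `n x 3`
#' coordinate matrices (mm, laboratory frame, columns `X`, `Y`, `Z`), the
#' sampling rate and a per-marker logical gap mask (`TRUE` = sample missing).
#' The laboratory convention is right-handed with Y vertical (up), Z anterior
#' and X from the subject's left to right; readers convert into it.
#'
#' @param positions named list of numeric `n x 3` matrices (mm).
#' @param sample_rate sampling rate in Hz.
#' @param gap_mask named list of logical vectors of length `n`; defaults to
#'   all-`FALSE` masks. Coordinates under a gap may be `NA`.
#' @return object of class `marker_trajectory_set` with elements `positions`,
#'   `sample_rate`, `gap_mask`, `n_samples`.
#' @examples
#' pos <- list(S1 = cbind(X = 0, Y = 1000 + 0 * (1:10), Z = -80))
#' mts <- marker_trajectory_set(pos, sample_rate = 100)
#' mts$n_samples
#' @export
marker_trajectory_set <- function(positions, sample_rate, gap_mask = NULL) {
  if (!is.list(positions) || is.null(names(positions)) ||
      any(!nzchar(names(positions))))
    stop("positions must be a named list of n x 3 matrices")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 3L) stop("each marker matrix must have 3 columns (X, Y, Z)")
    colnames(p) <- c("X", "Y", "Z")
    storage.mode(p) <- "double"
    p
  })
  n <- unique(vapply(positions, nrow, integer(1)))
  if (length(n) != 1L)
    stop("all markers must share the same number of samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  if (is.null(gap_mask)) {
    gap_mask <- lapply(positions, function(p) rep(FALSE, nrow(p)))
  } else {
    gap_mask <- gap_mask[names(positions)]
    gap_mask <- lapply(gap_mask, function(g) {
      if (is.null(g)) rep(FALSE, n) else as.logical(g)
    })
    names(gap_mask) <- names(positions)
    if (any(vapply(gap_mask, length, integer(1)) != n))
      stop("gap_mask lengths must equal n_samples")
  }
  for (m in names(positions)) {
    valid <- !gap_mask[[m]]
    if (any(!is.finite(positions[[m]][valid, ])))
      stop("non-finite coordinates outside gaps for marker ", m)
  }
  structure(
    list(positions = positions, sample_rate = as.numeric(sample_rate),
         gap_mask = gap_mask, n_samples = as.integer(n)),
    class = "marker_trajectory_set"
  )
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  ngap <- sum(vapply(x$gap_mask, sum, numeric(1)))
  cat(sprintf(
    "<marker_trajectory_set> %d markers, %d samples @ %g Hz (%.2f s), %d gap samples\n",
    length(x$positions), x$n_samples, x$sample_rate,
    x$n_samples / x$sample_rate, ngap))
  cat("  markers:", paste(names(x$positions), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.marker_trajectory_set` <- function(x, i) {
  marker_trajectory_set(
    lapply(x$positions, function(p) p[i, , drop = FALSE]),
    x$sample_rate,
    lapply(x$gap_mask, function(g) g[i])
  )
}

#' Extract one marker's coordinate matrix
#'
#' @param t a [marker_trajectory_set()].
#' @param marker canonical marker label.
#' @param require_gap_free error if the marker has unfilled gaps.
#' @return `n x 3` matrix.
#' @keywords internal
marker_xyz <- function(t, marker, require_gap_free = TRUE) {
  p <- t$positions[[marker]]
  if (is.null(p)) stop("marker not present: ", marker)
  if (require_gap_free && any(t$gap_mask[[marker]]))
    stop("marker ", marker, " has unfilled gaps")
  p
}

#' Named angle series
#'
#' One named angle sampled over a trial, in degrees, computed in either the
#' pelvis-anchored local frame or the laboratory frame. Samples whose planar
#' projection was numerically indeterminate are `NA` and are excluded from
#' extrema detection downstream.
#'
#' @param label angle label (e.g. `"SF"`, `"SIL"`, `"TRUNK"`).
#' @param values numeric vector, degrees.
#' @param sample_rate Hz.
#' @param frame `"local"` or `"laboratory"`.
#' @param side `"left"`, `"right"` or `"none"`.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(label, values, sample_rate, frame = "local",
                         side = "none") {
  frame <- match.arg(frame, c("local", "laboratory"))
  values <- as.numeric(values)
  if (any(abs(values) > 360, na.rm = TRUE))
    stop("angle values outside [-360, 360] degrees")
  structure(
    list(label = label, values = values, sample_rate = as.numeric(sample_rate),
         frame = frame, side = side),
    class = "angle_series"
  )
}

#' @export
print.angle_series <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<angle_series> %s (%s frame) %d samples @ %g Hz, range [%.2f, %.2f] deg, %d flagged\n",
    x$label, x$frame, length(x$values), x$sample_rate, rng[1], rng[2],
    sum(is.na(x$values))))
  invisible(x)
}
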