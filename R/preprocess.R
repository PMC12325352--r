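#' Low-pass filter specification
#'
#' The marker-coordinate smoother is a low-pass Butterworth filter, by
#' default 5 Hz and zero-phase: a half-order design run forward and
#' backward (net order = `order`), so no lag is introduced. Edge handling
#' uses odd (point-symmetric) reflective padding of `3 * order` samples and
#' steady-state initial conditions, which keeps the DC gain exact.
#'
#' @param cutoff cutoff frequency (Hz), must satisfy `0 < cutoff < rate / 2`.
#' @param order net filter order (even when `zero_phase`); default 4.
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 5, order = 4, zero_phase = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (order < 1) stop("order must be >= 1")
  if (zero_phase && order %% 2 != 0)
    stop("zero-phase filtering needs an even net order")
  structure(list(cutoff = cutoff, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %g Hz low-pass Butterworth, order %d%s\n",
              x$cutoff, x$order,
              if (x$zero_phase) " (zero-phase forward-backward)" else ""))
  invisible(x)
}

# single-pass IIR filter assuming each column was constant at its first
# value for all t <= 0 (steady-state initial conditions, like scipy's
# lfilter_zi); the MA part runs through stats::filter(convolution) and the
# AR part through stats::filter(recursive), both C-level, column-wise.
.filt1 <- function(x, b, a) {
  x <- as.matrix(x)
  nb <- length(b); na <- length(a)
  n <- nrow(x)
  x0 <- x[1, ]
  y0 <- x0 * sum(b) / sum(a)
  head <- matrix(rep(x0, each = nb - 1), nrow = nb - 1)
  z <- stats::filter(rbind(head, x), b, method = "convolution", sides = 1)
  z <- matrix(z, ncol = ncol(x))[nb:(nb - 1 + n), , drop = FALSE]
  if (na > 1) {
    y <- stats::filter(z / a[1], -a[-1] / a[1], method = "recursive",
                       init = matrix(rep(y0, each = na - 1), nrow = na - 1))
    matrix(y, ncol = ncol(x))
  } else z / a[1]
}

#' Low-pass Butterworth filtering of a numeric signal
#'
#' Applies the filter described by a [filter_spec()] to one signal.
#' Zero-phase mode designs a half-order Butterworth and runs it forward
#' and backward over the signal extended by odd reflective padding of
#' `3 * order` samples at each end.
#'
#' @param x numeric vector, or matrix whose columns are filtered
#'   independently.
#' @param rate sampling rate (Hz).
#' @param spec a [filter_spec()].
#' @return filtered vector or matrix, same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' noisy <- sin(2 * pi * t) + rnorm(length(t), 0, 0.1)
#' smooth <- butter_lowpass(noisy, rate = 100)
#' @export
butter_lowpass <- function(x, rate, spec = filter_spec()) {
  if (spec$cutoff >= rate / 2)
    stop("cutoff must be below the Nyquist frequency (", rate / 2, " Hz)")
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  n <- nrow(xm)
  if (n <= 3 * spec$order)
    stop("signal too short: need more than 3 x order samples")
  design_order <- if (spec$zero_phase) spec$order / 2 else spec$order
  bf <- signal::butter(design_order, spec$cutoff / (rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  np <- 3L * spec$order
  pad_head <- 2 * matrix(xm[1, ], np, ncol(xm), byrow = TRUE) -
    xm[seq(np + 1, 2), , drop = FALSE]
  pad_tail <- 2 * matrix(xm[n, ], np, ncol(xm), byrow = TRUE) -
    xm[seq(n - 1, n - np), , drop = FALSE]
  xe <- rbind(pad_head, xm, pad_tail)
  y <- .filt1(xe, b, a)
  if (spec$zero_phase)
    y <- .filt1(y[nrow(y):1, , drop = FALSE], b, a)[nrow(y):1, ,
                                                    drop = FALSE]
  y <- y[(np + 1):(np + n), , drop = FALSE]
  if (vec) as.numeric(y) else y
}

#' Interpolate gaps in marker trajectories
#'
#' Replaces each masked run of length `<= max_gap` by coordinate-wise
#' linear interpolation between the flanking valid samples and clears the
#' gap mask for the filled samples. Gaps touching the first or last sample
#' cannot be interpolated and are an error, as are runs longer than
#' `max_gap`.
#'
#' @param t a [marker_trajectory_set()].
#' @param max_gap maximum fillable gap length in samples (default 20,
#'   i.e. 0.2 s at 100 Hz).
#' @return a gap-free [marker_trajectory_set()].
#' @export
interpolate_gaps <- function(t, max_gap = 20L) {
  positions <- t$positions
  gaps <- t$gap_mask
  for (m in names(positions)) {
    g <- gaps[[m]]
    if (!any(g)) next
    if (g[1] || g[t$n_samples])
      stop("unrecoverable gap at sequence boundary for marker ", m)
    r <- rle(g)
    lens <- r$lengths[r$values]
    if (any(lens > max_gap)) {
      ends <- cumsum(r$lengths)
      bad <- which(r$values & r$lengths > max_gap)[1]
      span <- c(ends[bad] - r$lengths[bad] + 1L, ends[bad])
      stop(sprintf("gap of %d samples (max_gap = %d) for marker %s at samples %d-%d",
                   r$lengths[bad], max_gap, m, span[1], span[2]))
    }
    valid <- which(!g)
    fill <- which(g)
    for (k in 1:3) {
      positions[[m]][fill, k] <- stats::approx(
        valid, positions[[m]][valid, k], xout = fill,
        method = "linear")$y
    }
    gaps[[m]][fill] <- FALSE
  }
  marker_trajectory_set(positions, t$sample_rate, gaps)
}

#' Low-pass filter all marker coordinates of a trial
#'
#' Each coordinate of each marker is filtered independently with
#' [butter_lowpass()]. The trajectory must be gap-free (run
#' [interpolate_gaps()] first); output length equals input length.
#'
#' @param t a gap-free [marker_trajectory_set()].
#' @param spec a [filter_spec()].
#' @return filtered [marker_trajectory_set()].
#' @export
lowpass_filter <- function(t, spec = filter_spec()) {
  if (any(vapply(t$gap_mask, any, logical(1))))
    stop("trajectory has unfilled gaps; run interpolate_gaps() first")
  if (t$n_samples <= 3 * spec$order)
    stop("trial too short to filter: need more than 3 x order samples")
  big <- do.call(cbind, t$positions)
  big <- butter_lowpass(big, t$sample_rate, spec)
  positions <- t$positions
  for (j in seq_along(positions)) {
    positions[[j]][] <- big[, (3 * (j - 1) + 1):(3 * j)]
  }
  marker_trajectory_set(positions, t$sample_rate, t$gap_mask)
}
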