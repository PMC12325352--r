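# Minimal C3D codec: Intel (little-endian) byte order, floating-point 3D
# point data, POINT parameter group only. Covers the subset of the C3D
# specification needed to exchange labelled marker trajectories; no analog
# channels, no events, no multi-byte frame counts beyond 65535.

C3D_PROC_INTEL <- 84L

#' Read marker trajectories from a C3D file
#'
#' Supports Intel-processor C3D files with floating-point 3D point storage
#' (negative `POINT:SCALE`). Point residuals < 0 mark invalid samples and
#' become gaps. Coordinates are converted to mm using `POINT:UNITS` when
#' present (default mm). Labels are mapped through the schema alias table.
#'
#' @param path C3D file path.
#' @param schema a [marker_schema()].
#' @return a [marker_trajectory_set()].
#' @export
read_c3d <- function(path, schema = marker_schema()) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 512) stop("format error: file too short for C3D: ", path)
  if (as.integer(raw[2]) != 0x50)
    stop("format error: not a C3D file (bad magic byte): ", path)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  f32 <- function(off) readBin(raw[(off + 1):(off + 4)], "double",
                               size = 4, endian = "little")
  npoints <- u16(2)
  first_frame <- u16(6)
  last_frame <- u16(8)
  nframes <- last_frame - first_frame + 1L
  scale <- f32(12)
  data_start_blk <- u16(16)
  rate <- f32(20)

  # parameter section
  pstart <- (as.integer(raw[1]) - 1L) * 512L
  if (as.integer(raw[pstart + 4]) != C3D_PROC_INTEL)
    stop("unsupported C3D processor type ", as.integer(raw[pstart + 4]),
         " (only Intel/84 supported)")
  int8 <- function(off) {
    v <- as.integer(raw[off + 1]); if (v > 127) v - 256L else v
  }
  labels <- NULL; units <- "mm"
  pos <- pstart + 4L
  repeat {
    nname <- int8(pos); gid <- int8(pos + 1)
    if (nname == 0L || gid == 0L) break
    nm <- rawToChar(raw[(pos + 3):(pos + 2 + abs(nname))])
    off_field <- pos + 2L + abs(nname)
    nxt <- u16(off_field)
    if (gid > 0L) { # parameter record (group ids: POINT assumed id 1)
      p <- off_field + 2L
      type <- int8(p); ndim <- as.integer(raw[p + 2])
      dims <- if (ndim > 0) as.integer(raw[(p + 3):(p + 2 + ndim)]) else integer()
      dstart <- p + 2L + ndim
      nelem <- if (length(dims)) prod(dims) else 1L
      esz <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[as.character(type)]
      bytes <- raw[(dstart + 1):(dstart + nelem * esz)]
      val <- switch(as.character(type),
        `-1` = rawToChar(bytes),
        `1` = as.integer(bytes),
        `2` = readBin(bytes, "integer", n = nelem, size = 2, endian = "little"),
        `4` = readBin(bytes, "double", n = nelem, size = 4, endian = "little"))
      if (nm == "LABELS" && type == -1L && ndim == 2L) {
        lab <- substring(val, seq(1, by = dims[1], length.out = dims[2]),
                         seq(dims[1], by = dims[1], length.out = dims[2]))
        labels <- trimws(lab)
      } else if (nm == "UNITS" && type == -1L) {
        units <- trimws(val)
      } else if (nm == "RATE" && type == 4L) rate <- val[1]
      else if (nm == "SCALE" && type == 4L) scale <- val[1]
      else if (nm == "FRAMES" && type == 2L) nframes <- val[1]
      else if (nm == "DATA_START" && type == 2L) data_start_blk <- val[1]
      else if (nm == "USED" && type == 2L) npoints <- val[1]
    }
    if (nxt == 0L) break
    pos <- off_field + nxt
  }
  if (scale >= 0)
    stop("unsupported C3D: integer point storage (POINT:SCALE >= 0)")
  if (is.null(labels)) labels <- sprintf("M%03d", seq_len(npoints))
  labels <- labels[seq_len(npoints)]

  mult <- switch(tolower(units), mm = 1, cm = 10, m = 1000, 1)
  doff <- (data_start_blk - 1L) * 512L
  nvals <- npoints * 4L * nframes
  vals <- readBin(raw[(doff + 1):(doff + 4L * nvals)], "double", n = nvals,
                  size = 4, endian = "little")
  arr <- array(vals, dim = c(4L, npoints, nframes))
  canon <- resolve_labels(labels, schema)
  out_labels <- ifelse(is.na(canon), labels, canon)
  positions <- list(); gaps <- list()
  for (j in seq_len(npoints)) {
    xyz <- t(arr[1:3, j, ]) * mult
    g <- arr[4, j, ] < 0
    xyz[g, ] <- NA_real_
    positions[[out_labels[j]]] <- xyz
    gaps[[out_labels[j]]] <- g
  }
  marker_trajectory_set(positions, rate, gaps)
}

#' Write marker trajectories to a C3D file
#'
#' Writes Intel byte order, floating-point point data, a single POINT
#' parameter group (USED, FRAMES, RATE, SCALE, DATA_START, UNITS, LABELS).
#' Gap samples get residual -1 and zeroed coordinates.
#'
#' @param t a [marker_trajectory_set()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_c3d <- function(t, path) {
  labels <- names(t$positions)
  npoints <- length(labels)
  nframes <- t$n_samples
  if (nframes > 65535) stop("C3D writer supports at most 65535 frames")
  lab_w <- max(4L, max(nchar(labels)))
  lab_padded <- formatC(labels, width = lab_w, flag = "-")

  param_payload <- local({
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    wr_rec <- function(name, gid, body) {
      writeBin(as.raw(nchar(name)), con)
      writeBin(packBits(intToBits(gid)[1:8]), con)
      writeBin(charToRaw(name), con)
      writeBin(as.integer(length(body) + 2L), con, size = 2,
               endian = "little") # offset to next record
      writeBin(body, con)
    }
    body_group <- as.raw(0) # zero-length description
    wr_rec("POINT", -1L, body_group)
    par_body <- function(type, dims, data_raw)
      c(packBits(intToBits(type)[1:8]), as.raw(length(dims)), as.raw(dims),
        data_raw, as.raw(0))
    r_i16 <- function(v) {
      cc <- rawConnection(raw(0), "wb"); on.exit(close(cc))
      writeBin(as.integer(v), cc, size = 2, endian = "little")
      rawConnectionValue(cc)
    }
    r_f32 <- function(v) {
      cc <- rawConnection(raw(0), "wb"); on.exit(close(cc))
      writeBin(as.numeric(v), cc, size = 4, endian = "little")
      rawConnectionValue(cc)
    }
    wr_rec("USED", 1L, par_body(2L, integer(), r_i16(npoints)))
    wr_rec("FRAMES", 1L, par_body(2L, integer(), r_i16(nframes)))
    wr_rec("RATE", 1L, par_body(4L, integer(), r_f32(t$sample_rate)))
    wr_rec("SCALE", 1L, par_body(4L, integer(), r_f32(-1)))
    wr_rec("UNITS", 1L, par_body(-1L, 2L, charToRaw("mm")))
    wr_rec("LABELS", 1L,
           par_body(-1L, c(lab_w, npoints),
                    charToRaw(paste(lab_padded, collapse = ""))))
    # terminator record
    writeBin(as.raw(c(0, 0)), con)
    writeBin(as.integer(0), con, size = 2, endian = "little")
    rawConnectionValue(con)
  })

  nparam_blocks <- ceiling((length(param_payload) + 4) / 512)
  data_start_blk <- 2L + nparam_blocks

  con <- file(path, "wb")
  on.exit(close(con))
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  # header block
  writeBin(as.raw(c(2, 0x50)), con)
  w_u16(npoints); w_u16(0L); w_u16(1L); w_u16(nframes); w_u16(10L)
  w_f32(-1) # POINT:SCALE
  w_u16(data_start_blk); w_u16(0L)
  w_f32(t$sample_rate)
  writeBin(raw(512 - 24), con)
  # parameter section
  writeBin(as.raw(c(0x01, 0x50)), con)
  writeBin(as.raw(nparam_blocks), con)
  writeBin(as.raw(C3D_PROC_INTEL), con)
  writeBin(param_payload, con)
  pad <- nparam_blocks * 512 - 4 - length(param_payload)
  if (pad > 0) writeBin(raw(pad), con)
  # data section: frame-major, per point x,y,z,residual as float32
  arr <- array(0, dim = c(4L, npoints, nframes))
  for (j in seq_len(npoints)) {
    xyz <- t$positions[[j]]
    g <- t$gap_mask[[j]]
    xyz[g | !is.finite(xyz)] <- 0
    arr[1:3, j, ] <- t(xyz)
    arr[4, j, ] <- ifelse(g, -1, 0)
  }
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}
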