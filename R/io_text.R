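#' Read marker trajectories from a TRC file
#'
#' Parses the tab-delimited TRC dialect used by Motion Analysis / OpenSim:
#' a `PathFileType` line, a header pair declaring `DataRate`, `NumFrames`,
#' `NumMarkers` and `Units`, a marker-label row, an `X1/Y1/Z1...` row, then
#' one row per sample (`Frame#`, `Time`, coordinates). Empty coordinate
#' cells become gaps. Coordinates are converted to mm (`Units` `m`, `cm` or
#' `mm`). Labels are mapped through the schema's alias table; unrecognised
#' markers are kept under their file label.
#'
#' @param path TRC file path.
#' @param schema a [marker_schema()].
#' @return a [marker_trajectory_set()].
#' @export
read_trc <- function(path, schema = marker_schema()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6 || !grepl("^PathFileType", lines[1]))
    stop("not a TRC file (missing PathFileType header): ", path)
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr[["DataRate"]])
  units <- tolower(hdr[["Units"]])
  if (!is.finite(rate) || rate <= 0) stop("TRC header: invalid DataRate")
  scale <- switch(units, mm = 1, cm = 10, m = 1000,
                  stop("TRC header: unsupported Units '", units, "'"))
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[-(1:2)]
  labels <- labels[nzchar(labels)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  cells <- strsplit(data_lines, "\t")
  ncol_expect <- 2 + 3 * length(labels)
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol_expect)
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    length(row) <- ncol_expect
    row[!nzchar(row) | is.na(row)] <- NA
    mat[i, ] <- suppressWarnings(as.numeric(row))
  }
  canon <- resolve_labels(labels, schema)
  out_labels <- ifelse(is.na(canon), labels, canon)
  positions <- list(); gaps <- list()
  for (j in seq_along(labels)) {
    xyz <- mat[, 2 + (3 * (j - 1) + 1):(3 * j), drop = FALSE] * scale
    g <- apply(is.na(xyz), 1, any)
    positions[[out_labels[j]]] <- xyz
    gaps[[out_labels[j]]] <- g
  }
  marker_trajectory_set(positions, rate, gaps)
}

#' Write marker trajectories to a TRC file
#'
#' @param t a [marker_trajectory_set()] (gaps written as empty cells).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_trc <- function(t, path) {
  labels <- names(t$positions)
  n <- t$n_samples
  hdr <- c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", t$sample_rate, t$sample_rate, n,
            length(labels), t$sample_rate, n),
    paste(c("Frame#", "Time",
            as.vector(rbind(labels, "", ""))), collapse = "\t"),
    paste(c("", "", as.vector(vapply(seq_along(labels), function(j)
      sprintf(c("X%d", "Y%d", "Z%d"), j), character(3)))), collapse = "\t")
  )
  time <- (seq_len(n) - 1) / t$sample_rate
  body <- character(n)
  coord <- matrix("", nrow = n, ncol = 3 * length(labels))
  for (j in seq_along(labels)) {
    xyz <- t$positions[[j]]
    g <- t$gap_mask[[j]]
    txt <- matrix(sprintf("%.6f", xyz), nrow = n)
    txt[g, ] <- ""
    coord[, (3 * (j - 1) + 1):(3 * j)] <- txt
  }
  for (i in seq_len(n))
    body[i] <- paste(c(i, sprintf("%.6f", time[i]), coord[i, ]),
                     collapse = "\t")
  writeLines(c(hdr, "", body), path)
  invisible(path)
}

#' Read marker trajectories from the wide-CSV dialect
#'
#' Dialect: optional comment line `# sample_rate_hz: <Hz>`, then a header
#' `time,<marker>_X,<marker>_Y,<marker>_Z,...`, one row per sample, units mm,
#' `.` decimal separator. Empty cells are gaps. If no rate comment is
#' present the rate is inferred from the time column, which must be
#' uniformly increasing.
#'
#' @param path CSV path.
#' @param schema a [marker_schema()].
#' @return a [marker_trajectory_set()].
#' @export
read_marker_csv <- function(path, schema = marker_schema()) {
  first <- readLines(path, n = 1)
  rate <- NA_real_
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("sample_rate_hz:\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) rate <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time" %in% names(df)) stop("marker CSV must have a 'time' column")
  tm <- df$time
  dt <- diff(tm)
  if (any(dt <= 0)) stop("format error: time column not strictly increasing")
  if (length(dt) > 1 && (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("format error: irregular sampling interval in time column")
  if (!is.finite(rate)) rate <- 1 / stats::median(dt)
  cols <- setdiff(names(df), "time")
  mk <- unique(sub("_[XYZ]$", "", cols))
  positions <- list(); gaps <- list()
  canon <- resolve_labels(mk, schema)
  out_labels <- ifelse(is.na(canon), mk, canon)
  for (j in seq_along(mk)) {
    want <- paste0(mk[j], "_", c("X", "Y", "Z"))
    if (!all(want %in% cols))
      stop("marker CSV: incomplete X/Y/Z triple for ", mk[j])
    xyz <- as.matrix(df[, want])
    g <- apply(is.na(xyz), 1, any)
    positions[[out_labels[j]]] <- xyz
    gaps[[out_labels[j]]] <- g
  }
  marker_trajectory_set(positions, rate, gaps)
}

#' Write marker trajectories to the wide-CSV dialect
#'
#' @param t a [marker_trajectory_set()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_marker_csv <- function(t, path) {
  n <- t$n_samples
  df <- data.frame(time = (seq_len(n) - 1) / t$sample_rate)
  for (m in names(t$positions)) {
    xyz <- t$positions[[m]]
    xyz[t$gap_mask[[m]], ] <- NA
    df[[paste0(m, "_X")]] <- xyz[, 1]
    df[[paste0(m, "_Y")]] <- xyz[, 2]
    df[[paste0(m, "_Z")]] <- xyz[, 3]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %g", t$sample_rate), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a cohort result table
#'
#' Long-format UTF-8 CSV with `.` decimal separator and columns
#' `participant, group, session, task, parameter, value` plus any extra
#' columns present (e.g. `side`, `set_index`, `repetition`). Duplicate
#' logical keys are an integrity error.
#'
#' @param results data frame (a cohort table).
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_cohort_table <- function(results, path) {
  need <- c("participant", "group", "session", "task", "parameter", "value")
  if (!is.data.frame(results) || nrow(results) == 0)
    stop("cohort table must be a non-empty data frame")
  if (!all(need %in% names(results)))
    stop("cohort table must have columns: ", paste(need, collapse = ", "))
  keycols <- intersect(c("participant", "session", "task", "parameter",
                         "side", "set_index", "repetition"), names(results))
  key <- do.call(paste, c(results[keycols], sep = "\r"))
  if (anyDuplicated(key))
    stop("integrity error: duplicate (participant, session, task, parameter) rows")
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort result table
#'
#' @param path CSV path written by [write_cohort_table()].
#' @return data frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read a trial file by extension
#'
#' Dispatches on file extension: `.c3d` to [read_c3d()], `.trc` to
#' [read_trc()], `.csv` to [read_marker_csv()].
#'
#' @param path file path.
#' @param schema a [marker_schema()].
#' @return a [marker_trajectory_set()].
#' @export
read_trial <- function(path, schema = marker_schema()) {
  switch(tolower(tools::file_ext(path)),
         c3d = read_c3d(path, schema),
         trc = read_trc(path, schema),
         csv = read_marker_csv(path, schema),
         stop("unsupported trial file extension: ", path))
}
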