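## Marker-track text I/O. The native format is a CSV with one row per frame:
## frame,time_s,<marker>_x,<marker>_y,<marker>_z,... (coordinates in mm).
## A TRC reader is provided for data exported from optical capture software.

#' Write marker tracks as delimited text
#'
#' @param tracks named list of n_frames x 3 matrices (mm), one per marker.
#' @param path output CSV path.
#' @param frame_rate frames per second (stored in a header comment).
#' @return `path`, invisibly.
#' @export
write_marker_tracks <- function(tracks, path, frame_rate = 120) {
  nfr <- nrow(tracks[[1]])
  stopifnot(all(vapply(tracks, nrow, 1L) == nfr))
  cols <- lapply(names(tracks), function(nm) {
    m <- tracks[[nm]]
    setNames(as.data.frame(m), paste0(nm, c("_x", "_y", "_z")))
  })
  df <- cbind(data.frame(frame = seq_len(nfr) - 1L,
                         time_s = (seq_len(nfr) - 1L) / frame_rate),
              do.call(cbind, cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cartstrain marker tracks, units mm, frame_rate_hz %g",
                     frame_rate), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read marker tracks written by [write_marker_tracks()]
#'
#' @param path CSV path.
#' @return list with `tracks` (named list of n x 3 matrices), `frame_rate`,
#'   `time_s`.
#' @export
read_marker_tracks <- function(path) {
  first <- readLines(path, 1)
  frame_rate <- 120
  skip <- 0
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexpr("frame_rate_hz [0-9.]+", first))
    if (length(m)) frame_rate <- as.numeric(sub("frame_rate_hz ", "", m))
    skip <- 1
  }
  df <- read.csv(path, skip = skip, check.names = FALSE)
  xcols <- grep("_x$", names(df), value = TRUE)
  markers <- sub("_x$", "", xcols)
  tracks <- lapply(markers, function(nm)
    unname(as.matrix(df[, paste0(nm, c("_x", "_y", "_z"))])))
  names(tracks) <- markers
  list(tracks = tracks, frame_rate = frame_rate, time_s = df$time_s)
}

#' Read a TRC motion-capture file
#'
#' Parses the tab-delimited TRC convention (two metadata rows, a marker-name
#' header row, a coordinate-label row, then frame rows with
#' `Frame# Time X1 Y1 Z1 ...`). Units are converted to mm when the header
#' declares m or cm.
#'
#' @param path TRC file.
#' @return list with `tracks`, `frame_rate`, `time_s` as in
#'   [read_marker_tracks()].
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta_keys <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- setNames(as.list(meta_vals), meta_keys)
  frame_rate <- as.numeric(meta[["DataRate"]] %||% 120)
  units <- meta[["Units"]] %||% "mm"
  scale <- switch(units, mm = 1, cm = 10, m = 1000,
                  stop("unknown TRC units: ", units))
  hdr <- strsplit(lines[4], "\t")[[1]]
  markers <- hdr[nzchar(hdr)][-(1:2)]   # drop Frame#, Time
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vals <- lapply(strsplit(data_lines, "\t"), as.numeric)
  m <- do.call(rbind, vals)
  tracks <- lapply(seq_along(markers), function(k)
    m[, 2 + (k - 1) * 3 + (1:3), drop = FALSE] * scale)
  names(tracks) <- markers
  list(tracks = tracks, frame_rate = frame_rate, time_s = m[, 2])
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
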