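## Minimal NIfTI-1 I/O (uncompressed .nii, float32, plus a JSON sidecar with
## echo times). No NIfTI package is available in this R stack, so the 348-byte
## header is written directly; only the fields this pipeline needs are
## populated (dims, voxel size, scanner affine via srow_*).

nifti_header_blank <- function() {
  raw(348)
}

#' Write a 3-D or 4-D array as an uncompressed NIfTI-1 file
#'
#' @param data numeric array, 3 or 4 dimensions (float32 on disk).
#' @param path output `.nii` path.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @param origin lab-frame coordinates of voxel (1,1,1), mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  dims <- dim(data)
  stopifnot(length(dims) %in% c(3, 4))
  nd <- length(dims)
  con <- file(path, "wb")
  on.exit(close(con))
  wB <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wB(348L, 4)                                    # sizeof_hdr
  writeBin(raw(36), con)                         # unused
  dimv <- c(nd, dims, rep(1L, 7 - nd))
  wB(as.integer(dimv), 2)                        # dim[8]
  writeBin(raw(14), con)                         # intent_p1..3, intent_code
  wB(16L, 2)                                     # datatype = FLOAT32
  wB(32L, 2)                                     # bitpix
  wB(0L, 2)                                      # slice_start
  pixdim <- c(1, voxel_size, rep(1, 7 - 3))
  wB(as.numeric(pixdim), 4)                      # pixdim[8]
  wB(352, 4)                                     # vox_offset
  wB(c(1, 0), 4)                                 # scl_slope, scl_inter
  writeBin(raw(2 + 1 + 1), con)                  # slice_end, slice_code, xyzt_units
  wB(c(0, 0, 0), 4)                              # cal_max, cal_min, slice_duration
  wB(0, 4)                                       # toffset
  wB(c(0L, 0L), 4)                               # glmax, glmin
  writeBin(raw(80 + 24), con)                    # descrip, aux_file
  wB(c(0L, 1L), 2)                               # qform_code=0, sform_code=1
  wB(rep(0, 6), 4)                               # quatern b,c,d, qoffset x,y,z
  srow <- rbind(c(voxel_size[1], 0, 0, origin[1]),
                c(0, voxel_size[2], 0, origin[2]),
                c(0, 0, voxel_size[3], origin[3]))
  wB(as.numeric(t(srow)), 4)                     # srow_x/y/z
  writeBin(raw(16), con)                         # intent_name
  writeChar("n+1", con, eos = NULL)              # magic
  writeBin(raw(1), con)
  writeBin(raw(4), con)                          # extension flag
  wB(as.numeric(data), 4)
  invisible(path)
}

#' Read an uncompressed float32 NIfTI-1 file written by [write_nifti()]
#'
#' @param path `.nii` path.
#' @return list with `data` (array), `voxel_size`, `origin`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rB <- function(what, n, size) readBin(con, what, n, size = size, endian = "little")
  szh <- rB("integer", 1, 4)
  if (szh != 348L) stop("not a NIfTI-1 file")
  readBin(con, "raw", 36)
  dimv <- rB("integer", 8, 2)
  nd <- dimv[1]
  dims <- dimv[2:(1 + nd)]
  readBin(con, "raw", 14)
  dtype <- rB("integer", 1, 2)
  if (dtype != 16L) stop("only FLOAT32 NIfTI supported")
  rB("integer", 1, 2); rB("integer", 1, 2)
  pixdim <- rB("numeric", 8, 4)
  vox_offset <- rB("numeric", 1, 4)
  seek(con, 280)  # srow_x begins here
  srow <- matrix(rB("numeric", 12, 4), 3, 4, byrow = TRUE)
  seek(con, vox_offset)
  data <- array(rB("numeric", prod(dims), 4), dim = dims)
  list(data = data, voxel_size = pixdim[2:4], origin = srow[, 4])
}

#' Write the JSON sidecar carrying echo-time metadata
#' @param echo_times_ms numeric vector, ms.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_echo_sidecar <- function(echo_times_ms, path) {
  jsonlite::write_json(list(echo_times_ms = echo_times_ms), path, digits = NA)
  invisible(path)
}

#' Read the echo-time JSON sidecar
#' @param path sidecar path.
#' @return numeric vector of echo times, ms.
#' @export
read_echo_sidecar <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$echo_times_ms)
}
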