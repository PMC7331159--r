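## PLY and STL mesh I/O. PLY supports optional per-vertex scalar properties
## (used for thickness / strain / T2* maps); binary little-endian by default
## per the pipeline's external interface, ASCII available for inspection.

#' Write a triangle surface as PLY
#'
#' @param surface `TriSurface`.
#' @param path output file path.
#' @param vertex_props optional named list of per-vertex numeric vectors
#'   written as additional `float` vertex properties (e.g. `thickness_mm`,
#'   `strain`).
#' @param format `"binary_little_endian"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path, vertex_props = NULL,
                      format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  V <- surface$vertices
  F0 <- surface$faces - 1L
  nprop <- length(vertex_props)
  if (nprop && any(vapply(vertex_props, length, 1L) != nrow(V)))
    stop("vertex property length mismatch")
  hdr <- c("ply",
           sprintf("format %s 1.0", format),
           "comment cartstrain surface",
           sprintf("comment role %s", surface$role),
           sprintf("element vertex %d", nrow(V)),
           "property float x", "property float y", "property float z",
           if (nprop) sprintf("property float %s", names(vertex_props)),
           sprintf("element face %d", nrow(F0)),
           "property list uchar int vertex_indices",
           "end_header")
  vp <- if (nprop) do.call(cbind, vertex_props) else NULL
  vdata <- cbind(V, vp)
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(vdata, 1, function(r) paste(formatC(r, digits = 9, format = "g"), collapse = " ")), con)
    writeLines(paste(3, F0[, 1], F0[, 2], F0[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(vdata)), con, size = 4, endian = "little")
    # interleave uchar count with int32 indices
    for (i in seq_len(nrow(F0))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F0[i, ]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Read a PLY triangle surface
#'
#' Reads ASCII or binary little-endian PLY files with float vertex
#' coordinates, optional extra float vertex properties, and triangular faces.
#'
#' @param path PLY file.
#' @param role role tag to assign.
#' @return `TriSurface`; extra vertex properties attached as
#'   `attr(x, "vertex_props")` (named list).
#' @export
read_ply <- function(path, role = "cartilage") {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200) stop("malformed PLY header")
  }
  fmt <- sub("^format ", "", grep("^format", hdr, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex ", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*face ", "", grep("^element face", hdr, value = TRUE)[1]))
  vstart <- which(grepl("^element vertex", hdr))
  vend <- which(grepl("^element face", hdr))
  pnames <- sub("^property float ", "", grep("^property float", hdr[vstart:vend], value = TRUE))
  np <- length(pnames)
  if (grepl("ascii", fmt)) {
    vl <- readLines(con, nv)
    vdata <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), nv, np, byrow = TRUE)
    fl <- readLines(con, nf)
    fdata <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), nf, 4, byrow = TRUE)
    faces <- fdata[, 2:4, drop = FALSE] + 1L
  } else {
    vdata <- matrix(readBin(con, "numeric", nv * np, size = 4, endian = "little"),
                    nv, np, byrow = TRUE)
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3L) stop("only triangular faces supported")
      faces[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  }
  s <- tri_surface(vdata[, 1:3, drop = FALSE], faces, role = role)
  if (np > 3) {
    props <- lapply(4:np, function(k) vdata[, k])
    names(props) <- pnames[4:np]
    attr(s, "vertex_props") <- props
  }
  s
}

#' Write a triangle surface as ASCII STL
#' @param surface `TriSurface`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path) {
  V <- surface$vertices; F <- surface$faces
  n <- face_normals(surface)
  con <- file(path, "w")
  on.exit(close(con))
  cat("solid cartstrain\n", file = con)
  for (i in seq_len(nrow(F))) {
    cat(sprintf("facet normal %g %g %g\n outer loop\n", n[i, 1], n[i, 2], n[i, 3]), file = con)
    for (k in 1:3) {
      v <- V[F[i, k], ]
      cat(sprintf("  vertex %g %g %g\n", v[1], v[2], v[3]), file = con)
    }
    cat(" endloop\nendfacet\n", file = con)
  }
  cat("endsolid cartstrain\n", file = con)
  invisible(path)
}
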