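# Mesh exchange: ASCII PLY (with optional per-vertex scalar, e.g. a distance
# map) and binary STL.

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [surface_mesh()].
#' @param path destination `.ply`.
#' @param scalar optional per-vertex scalar (e.g. `DistanceMap$distance`),
#'   written as property `quality`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, scalar = NULL) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nv)
    hdr <- c(hdr, "property float quality")
  }
  hdr <- c(hdr, paste("element face", nt),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- mesh$vertices
  if (!is.null(scalar)) vm <- cbind(vm, scalar)
  writeLines(apply(format(vm, trim = TRUE, digits = 9), 1, paste,
                   collapse = " "), con)
  if (nt)
    writeLines(paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                     mesh$triangles[, 3] - 1), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path a `.ply` written by [write_ply()] or another tool (ASCII,
#'   x/y/z leading vertex properties, triangular faces).
#' @return a [surface_mesh()]; any `quality` property is attached as
#'   attribute `"scalar"`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  hdr <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", hdr))) stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr,
                                                   value = TRUE)))
  nt <- as.integer(sub("element face ", "", grep("^element face", hdr,
                                                 value = TRUE)))
  vprops <- grep("^property (float|double)", hdr, value = TRUE)
  vlines <- lines[end + seq_len(nv)]
  vm <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
               nrow = nv, byrow = TRUE)
  flines <- lines[end + nv + seq_len(nt)]
  fm <- matrix(as.integer(unlist(strsplit(trimws(flines), "\\s+"))),
               nrow = max(nt, 1), byrow = TRUE)
  if (nt && any(fm[, 1] != 3)) stop("only triangular faces are supported")
  tri <- if (nt) fm[, 2:4, drop = FALSE] + 1L else
    matrix(integer(0), 0, 3)
  mesh <- surface_mesh(vm[, 1:3, drop = FALSE], tri,
                       name = basename(path))
  if (length(vprops) >= 4) attr(mesh, "scalar") <- vm[, 4]
  mesh
}

#' Write a mesh as binary STL
#'
#' @param mesh a [surface_mesh()].
#' @param path destination `.stl`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  v <- mesh$vertices
  tr <- mesh$triangles
  for (t in seq_len(nt)) {
    a <- v[tr[t, 1], ]; b <- v[tr[t, 2], ]; c_ <- v[tr[t, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, a, b, c_)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}
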