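#' Read and write volumes as NIfTI
#'
#' Voxel width goes to pixdim and the world origin (center of the first
#' voxel) to the sform translation.
#'
#' @param vol a [Volume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readVolumeNifti` returns a [Volume-class]; `writeVolumeNifti`
#'   returns `path` invisibly.
#' @export
writeVolumeNifti <- function(vol, path) {
  w <- vol@voxelWidth
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- c(w, w, w)
  m <- diag(c(w, w, w, 1))
  m[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  xf <- RNifti::xform(img)
  w <- RNifti::pixdim(img)[1]
  if (!is.finite(w) || w <= 0) w <- abs(xf[1, 1])
  Volume(arr, w, as.numeric(xf[1:3, 4]))
}

#' Read and write meshes in FreeSurfer binary surface format
#'
#' Big-endian triangle-surface files (magic 0xFFFFFE, two newline-terminated
#' comment lines, vertex and face counts, float32 coordinates, int32
#' zero-based faces).
#'
#' @param mesh a [TriangleMesh-class].
#' @param path file path.
#' @return `readFreeSurferSurface` returns a [TriangleMesh-class].
#' @export
writeFreeSurferSurface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xfe)), con)
  writeChar("created by foliaflat\n\n", con, eos = NULL)
  writeBin(as.integer(c(nrow(mesh@vertices), nrow(mesh@triangles))), con,
           size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh@vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh@triangles) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' @rdname writeFreeSurferSurface
#' @export
readFreeSurferSurface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 254L)))
    stop(sprintf("not a FreeSurfer triangle surface (magic %s at offset 0)",
                 paste(sprintf("%02x", as.integer(magic)), collapse = " ")))
  # comment terminated by two consecutive newlines
  newlines <- 0L
  while (newlines < 2L) {
    ch <- readBin(con, "raw", 1L)
    if (!length(ch)) stop("truncated FreeSurfer surface header")
    newlines <- if (ch == as.raw(10L)) newlines + 1L else 0L
  }
  counts <- readBin(con, "integer", 2L, size = 4L, endian = "big")
  nv <- counts[1]; nf <- counts[2]
  v <- readBin(con, "numeric", 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", 3L * nf, size = 4L, endian = "big")
  TriangleMesh(matrix(v, ncol = 3, byrow = TRUE),
               matrix(f, ncol = 3, byrow = TRUE) + 1L)
}

#' Read and write per-vertex maps in FreeSurfer curv format
#'
#' The "new" big-endian curv format: magic 0xFFFFFF, vertex count, face
#' count, values-per-vertex (1), float32 values.
#'
#' @param map a [VertexScalarMap-class] or numeric vector.
#' @param path file path.
#' @param nFaces face count stored in the header.
#' @return `readFreeSurferCurv` returns a numeric vector.
#' @export
writeFreeSurferCurv <- function(map, path, nFaces = 0L) {
  vals <- if (is(map, "VertexScalarMap")) map@values else as.numeric(map)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xff)), con)
  writeBin(as.integer(c(length(vals), nFaces, 1L)), con, size = 4L,
           endian = "big")
  writeBin(vals, con, size = 4L, endian = "big")
  invisible(path)
}

#' @rdname writeFreeSurferCurv
#' @export
readFreeSurferCurv <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(255L, 255L, 255L)))
    stop(sprintf("not a new-format curv file (magic %s at offset 0)",
                 paste(sprintf("%02x", as.integer(magic)), collapse = " ")))
  hdr <- readBin(con, "integer", 3L, size = 4L, endian = "big")
  readBin(con, "numeric", hdr[1] * hdr[3], size = 4L, endian = "big")
}

#' Read and write meshes as ASCII PLY
#'
#' @param mesh a [TriangleMesh-class].
#' @param path file path.
#' @param comment optional comment line.
#' @return `readPly` returns a [TriangleMesh-class].
#' @export
writePly <- function(mesh, path, comment = "foliaflat surface") {
  nv <- nrow(mesh@vertices); nf <- nrow(mesh@triangles)
  hdr <- c("ply", "format ascii 1.0", paste("comment", comment),
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  vlines <- sprintf("%.9g %.9g %.9g", mesh@vertices[, 1], mesh@vertices[, 2],
                    mesh@vertices[, 3])
  flines <- sprintf("3 %d %d %d", mesh@triangles[, 1] - 1L,
                    mesh@triangles[, 2] - 1L, mesh@triangles[, 3] - 1L)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}

#' @rdname writePly
#' @param flat a [FlatMap-class]; written as a PLY mesh in the z = 0 plane.
#' @export
writeFlatMapPly <- function(flat, path, comment = "foliaflat flat map") {
  writePly(TriangleMesh(cbind(flat@coords2d, 0), flat@triangles), path,
           comment = comment)
}

#' @rdname writePly
#' @export
readPly <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply"))
    stop("not a PLY file (missing 'ply' magic on line 1)")
  endHdr <- match("end_header", lines)
  if (is.na(endHdr)) stop("malformed PLY: no end_header")
  hdr <- lines[seq_len(endHdr)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                   value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)[1]))
  vl <- lines[endHdr + seq_len(nv)]
  v <- matrix(as.numeric(unlist(strsplit(vl, " +"))), ncol = 3, byrow = TRUE)
  fl <- lines[endHdr + nv + seq_len(nf)]
  fparts <- strsplit(fl, " +")
  f <- t(vapply(fparts, function(p) as.integer(p[2:4]), integer(3))) + 1L
  TriangleMesh(v, f)
}
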