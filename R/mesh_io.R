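#' Read and write triangle meshes
#'
#' Minimal mesh IO for the formats used by the pipeline. PLY is written
#' either as `binary_little_endian` (positions as 32-bit floats, the
#' compact interchange default) or as ASCII; both flavours are read back.
#' OBJ and ASCII STL are supported for interoperability with modelling
#' tools. An optional per-vertex scalar is stored in a PLY `quality`
#' property (used for curvature overlays in external viewers).
#'
#' @param mesh a [triangle_mesh()].
#' @param path file path.
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @param quality optional numeric per-vertex scalar written as a float
#'   `quality` property.
#' @return `write_*` return `path` invisibly; `read_mesh` returns a
#'   [triangle_mesh()] (with attribute `quality` if present in the file).
#' @export
write_ply <- function(mesh, path, binary = TRUE, quality = NULL) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_q <- !is.null(quality)
  if (has_q && length(quality) != nv)
    cs_abort("quality must have one value per vertex", "cranioshape_input_error")
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           if (has_q) "property float quality",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  V <- mesh$vertices
  F0 <- mesh$faces - 1L
  if (binary) {
    vdat <- t(V)
    if (has_q) vdat <- rbind(vdat, as.numeric(quality))
    writeBin(as.numeric(vdat), con, size = 4, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(F0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    vl <- if (has_q)
      sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], quality)
    else sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    writeLines(vl, con, sep = "\n")
    writeLines(sprintf("3 %d %d %d", F0[, 1], F0[, 2], F0[, 3]), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         cs_abort(sprintf("unsupported mesh format '%s'", ext),
                  "cranioshape_format_error"))
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) cs_abort("truncated PLY header", "cranioshape_format_error")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE)[1])
  nv <- as.integer(sub("^element vertex ", "",
                       grep("^element vertex ", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element face ", "",
                       grep("^element face ", hdr, value = TRUE)[1]))
  vel <- grep("^element vertex", hdr)
  fel <- grep("^element face", hdr)
  vprops <- grep("^property ", hdr[seq(vel + 1, fel - 1)], value = TRUE)
  pnames <- vapply(strsplit(vprops, " "), function(s) s[length(s)], "")
  np <- length(pnames)
  if (startsWith(fmt, "binary_little_endian")) {
    vdat <- readBin(con, "numeric", n = nv * np, size = 4, endian = "little")
    vdat <- matrix(vdat, ncol = np, byrow = TRUE)
    F <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1))
      ix <- readBin(con, "integer", n = cnt, size = 4, endian = "little")
      if (cnt != 3L)
        cs_abort("only triangle faces are supported", "cranioshape_format_error")
      F[i, ] <- ix + 1L
    }
  } else if (startsWith(fmt, "ascii")) {
    txt <- readLines(con)
    vdat <- matrix(scan(text = txt[seq_len(nv)], quiet = TRUE),
                   ncol = np, byrow = TRUE)
    frows <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    F <- t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  } else {
    cs_abort(sprintf("unsupported PLY format '%s'", fmt),
             "cranioshape_format_error")
  }
  mesh <- triangle_mesh(vdat[, match(c("x", "y", "z"), pnames)], F)
  if ("quality" %in% pnames)
    attr(mesh, "quality") <- vdat[, match("quality", pnames)]
  mesh
}

#' @rdname write_ply
#' @export
write_obj <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
               sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_obj <- function(path) {
  txt <- readLines(path)
  vl <- grep("^v ", txt, value = TRUE)
  fl <- grep("^f ", txt, value = TRUE)
  V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3, byrow = TRUE)
  fidx <- lapply(strsplit(sub("^f ", "", fl), "\\s+"),
                 function(r) as.integer(sub("/.*$", "", r)))
  F <- do.call(rbind, fidx)
  triangle_mesh(V, F)
}

#' @rdname write_ply
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("solid cranioshape", con)
  for (i in seq_len(nrow(F))) {
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g",
                         V[F[i, ], 1], V[F[i, ], 2], V[F[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid cranioshape", con)
  invisible(path)
}
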