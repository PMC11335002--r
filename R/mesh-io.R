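#' Read a triangulated mesh from OBJ, PLY or STL
#'
#' Supports Wavefront OBJ (ascii), PLY (ascii and binary little/big endian,
#' float or double coordinates) and STL (ascii and binary). Polygonal faces
#' are fan-triangulated. The repair pass of [tri_mesh()] (duplicate-vertex
#' weld, degenerate-face drop) is applied, and the source path is recorded as
#' provenance.
#'
#' @param path file path.
#' @param format one of `"obj"`, `"ply"`, `"stl"`; guessed from the file
#'   extension by default.
#' @param label mesh label; defaults to the file name.
#' @return a [tri_mesh()].
#' @export
load_mesh <- function(path, format = NULL, label = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("obj", "ply", "stl"))
  raw <- switch(format,
                obj = .read_obj(path),
                ply = .read_ply(path),
                stl = .read_stl(path))
  if (is.null(raw$vertices) || nrow(raw$vertices) == 0L)
    stop("no vertices parsed from ", path)
  tri_mesh(raw$vertices, raw$faces,
           label = if (is.null(label)) basename(path) else label,
           repair = TRUE, provenance = normalizePath(path))
}

#' Write a mesh to OBJ, PLY (ascii) or STL (ascii)
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path) {
  format <- match.arg(tolower(tools::file_ext(path)), c("obj", "ply", "stl"))
  switch(format,
         obj = .write_obj(mesh, path),
         ply = .write_ply(mesh, path),
         stl = .write_stl(mesh, path))
  invisible(path)
}

.fan_triangulate <- function(idx_list) {
  out <- list()
  for (ix in idx_list) {
    if (length(ix) < 3L) next
    for (t in 2:(length(ix) - 1L))
      out[[length(out) + 1L]] <- ix[c(1L, t, t + 1L)]
  }
  do.call(rbind, out)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ file has no vertices: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    ix <- as.integer(vapply(strsplit(x, "/"), `[`, "", 1))
    ix[ix < 0] <- nrow(V) + 1L + ix[ix < 0]
    ix
  })
  list(vertices = V, faces = .fan_triangulate(faces))
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unterminated PLY header: ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  el_lines <- grep("^element", header)
  elements <- list()
  for (i in seq_along(el_lines)) {
    parts <- strsplit(trimws(header[el_lines[i]]), "\\s+")[[1]]
    upto <- if (i < length(el_lines)) el_lines[i + 1] - 1L else length(header) - 1L
    props <- header[(el_lines[i] + 1L):upto]
    props <- props[startsWith(trimws(props), "property")]
    elements[[parts[2]]] <- list(count = as.integer(parts[3]), props = props)
  }
  ve <- elements[["vertex"]]; fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY lacks vertex/face elements: ", path)
  vprop <- lapply(strsplit(trimws(ve$props), "\\s+"), function(x) x[2:3])
  vtypes <- vapply(vprop, `[`, "", 1)
  vnames <- vapply(vprop, `[`, "", 2)
  xyz <- match(c("x", "y", "z"), vnames)
  if (anyNA(xyz)) stop("PLY vertex element lacks x/y/z: ", path)

  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vrows <- strsplit(trimws(body[seq_len(ve$count)]), "\\s+")
    V <- do.call(rbind, lapply(vrows, function(x) as.numeric(x[xyz])))
    frows <- strsplit(trimws(body[ve$count + seq_len(fe$count)]), "\\s+")
    faces <- lapply(frows, function(x) as.integer(x[-1]) + 1L)
    return(list(vertices = V, faces = .fan_triangulate(faces)))
  }
  endian <- if (fmt == "binary_little_endian") "little" else "big"
  rd <- function(type, n = 1L) {
    switch(type,
           float = readBin(con, "double", n, size = 4L, endian = endian),
           float32 = readBin(con, "double", n, size = 4L, endian = endian),
           double = readBin(con, "double", n, size = 8L, endian = endian),
           float64 = readBin(con, "double", n, size = 8L, endian = endian),
           char = , int8 = readBin(con, "integer", n, size = 1L, signed = TRUE, endian = endian),
           uchar = , uint8 = readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian),
           short = , int16 = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = endian),
           ushort = , uint16 = readBin(con, "integer", n, size = 2L, signed = FALSE, endian = endian),
           int = , int32 = , uint = , uint32 = readBin(con, "integer", n, size = 4L, endian = endian),
           stop("unsupported PLY property type: ", type))
  }
  V <- matrix(NA_real_, ve$count, 3L)
  for (i in seq_len(ve$count)) {
    row <- numeric(length(vtypes))
    for (j in seq_along(vtypes)) row[j] <- rd(vtypes[j])
    V[i, ] <- row[xyz]
  }
  fprop <- strsplit(trimws(fe$props[1]), "\\s+")[[1]]
  cnt_type <- fprop[3]; idx_type <- fprop[4]
  faces <- vector("list", fe$count)
  for (i in seq_len(fe$count)) {
    k <- rd(cnt_type)
    faces[[i]] <- rd(idx_type, k) + 1L
  }
  list(vertices = V, faces = .fan_triangulate(faces))
}

.write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment", mesh$label),
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
}

.read_stl <- function(path) {
  # sniff: ascii STL starts with "solid" and contains "facet"
  head <- readBin(path, "raw", 512L)
  is_ascii <- length(grepRaw("^\\s*solid", head)) > 0 &&
    length(grepRaw("facet", head)) > 0
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
    if (is.null(coords) || nrow(coords) %% 3L != 0L)
      stop("malformed ascii STL: ", path)
    n <- nrow(coords) / 3L
    F <- matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE)
    return(list(vertices = coords, faces = F))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  V <- matrix(NA_real_, 3L * n, 3L)
  for (i in seq_len(n)) {
    rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
    V[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", 2L)
  }
  list(vertices = V, faces = matrix(seq_len(3L * n), ncol = 3L, byrow = TRUE))
}

.write_stl <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh$vertices; F <- mesh$faces
  writeLines(paste("solid", gsub("\\s+", "_", mesh$label)), con)
  for (k in seq_len(nrow(F))) {
    a <- V[F[k, 1], ]; b <- V[F[k, 2], ]; c <- V[F[k, 3], ]
    n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
           (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
           (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", c(a[1], b[1], c[1]),
                         c(a[2], b[2], c[2]), c(a[3], b[3], c[3])),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid", con)
}
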