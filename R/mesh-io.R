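#' Triangle mesh constructor
#'
#' A minimal triangle-mesh container: an `M x 3` vertex matrix in mm and an
#' `F x 3` integer face matrix of 1-based vertex indices.  Meshes used as
#' shape-model training data must additionally be *corresponded*: the same
#' vertex index denotes the same anatomical location on every shape.
#'
#' @param vertices numeric `M x 3` matrix of vertex coordinates (mm).
#' @param faces integer `F x 3` matrix of 1-based vertex indices.
#' @param anatomy optional label (e.g. `"femur-like"`, `"tibia-like"`) used
#'   by the joint collision machinery to sanity-check argument order.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, anatomy = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an M x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, anatomy = anatomy),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$anatomy)) "" else paste0(" (", x$anatomy, ")")))
  invisible(x)
}

mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "obj", "stl"))
    stop("unsupported mesh format: ", ext)
  ext
}

#' Read a triangle mesh (PLY, OBJ or STL)
#'
#' ASCII PLY, OBJ and STL are supported, plus binary (little-endian) STL.
#' STL files carry no shared-vertex structure, so exactly coincident
#' vertices are merged on read.
#'
#' @param path path to a `.ply`, `.obj` or `.stl` file.
#' @return A [tri_mesh].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  switch(mesh_format(path),
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path))
}

#' Write a triangle mesh (ASCII PLY, OBJ or STL)
#'
#' @param mesh a [tri_mesh].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tri_mesh"))
  switch(mesh_format(path),
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  fmt <- grep("^format ", lines, value = TRUE)[1]
  if (!grepl("ascii", fmt)) stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated: ", path)
  header <- lines[seq_len(endh)]
  nvert <- nface <- NA_integer_
  props <- character()
  cur <- ""
  for (h in header) {
    tok <- strsplit(trimws(h), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nvert <- as.integer(tok[3])
      if (cur == "face") nface <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      props <- c(props, tok[3])
    }
  }
  if (is.na(nvert) || is.na(nface)) stop("PLY missing vertex/face counts")
  ixyz <- match(c("x", "y", "z"), props)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(endh + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- strsplit(trimws(body[seq_len(nvert)]), "\\s+")
  V <- t(vapply(vl, function(v) as.numeric(v[ixyz]), numeric(3)))
  fl <- strsplit(trimws(body[nvert + seq_len(nface)]), "\\s+")
  F <- t(vapply(fl, function(v) {
    n <- as.integer(v[1])
    if (n != 3L) stop("non-triangular PLY face")
    as.integer(v[2:4]) + 1L
  }, integer(3)))
  tri_mesh(V, F)
}

write_ply <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0L) stop("OBJ has no vertices: ", path)
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(v) as.numeric(v[2:4]), numeric(3)))
  F <- t(vapply(strsplit(trimws(fl), "\\s+"), function(v) {
    if (length(v) != 4L) stop("non-triangular OBJ face")
    as.integer(vapply(strsplit(v[2:4], "/"), `[`, character(1), 1L))
  }, integer(3)))
  tri_mesh(V, F)
}

write_obj <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  ntri <- if (sz >= 84) readBin(con, "integer", 1L, size = 4L,
                                endian = "little") else -1L
  is_binary <- (sz == 84 + 50 * as.numeric(ntri))
  close(con)
  tris <- if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
  merge_stl_vertices(tris)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  tris <- matrix(0, ntri * 3L, 3L)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    tris[(t - 1L) * 3L + 1:3, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
  }
  tris
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: ", path)
  t(vapply(strsplit(trimws(vl), "\\s+"),
           function(v) as.numeric(v[2:4]), numeric(3)))
}

merge_stl_vertices <- function(tris) {
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "_")
  idx <- match(key, unique(key))
  V <- tris[!duplicated(key), , drop = FALSE]
  F <- matrix(idx, ncol = 3L, byrow = TRUE)
  tri_mesh(V, F)
}

write_stl <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (t in seq_len(nrow(F))) {
    p <- V[F[t, ], , drop = FALSE]
    n <- vec_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g", p[, 1], p[, 2], p[, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
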