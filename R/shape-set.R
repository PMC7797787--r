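#' Corresponded shape set
#'
#' Bundles `N >= 2` corresponded triangle meshes: every shape has the same
#' number of vertices `M`, the same face connectivity, and vertex `k` marks
#' the same anatomical location on every shape.  This is the training input
#' of the statistical shape models.
#'
#' @param shapes list of [tri_mesh] objects with identical topology.
#' @param names optional character vector of per-shape identifiers.
#' @return An object of class `shape_set` with elements `shapes`, `faces`
#'   (the shared face list) and `names`.
#' @export
shape_set <- function(shapes, names = NULL) {
  if (!is.list(shapes) || length(shapes) < 2L)
    stop("a shape set needs at least 2 shapes")
  if (!all(vapply(shapes, inherits, logical(1), "tri_mesh")))
    stop("all shapes must be tri_mesh objects")
  M <- nrow(shapes[[1]]$vertices)
  faces <- shapes[[1]]$faces
  for (i in seq_along(shapes)) {
    if (nrow(shapes[[i]]$vertices) != M)
      stop(sprintf("vertex-count mismatch: shape %d has %d vertices, expected %d",
                   i, nrow(shapes[[i]]$vertices), M))
    if (!identical(shapes[[i]]$faces, faces))
      stop(sprintf("face-list mismatch at shape %d", i))
    if (!all(is.finite(shapes[[i]]$vertices)))
      stop(sprintf("non-finite coordinates in shape %d", i))
  }
  if (is.null(names)) names <- sprintf("shape%03d", seq_along(shapes))
  structure(list(shapes = shapes, faces = faces, names = as.character(names)),
            class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("shape_set: N = %d corresponded meshes, M = %d vertices, %d faces\n",
              length(x$shapes), nrow(x$shapes[[1]]$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
length.shape_set <- function(x) length(x$shapes)

#' Load a corresponded shape set from mesh files
#'
#' @param paths character vector (length >= 2) of PLY/OBJ/STL files.
#' @param names per-shape identifiers; defaults to file basenames.
#' @return A [shape_set]; errors on any topology mismatch between files.
#' @export
load_shape_set <- function(paths, names = NULL) {
  if (length(paths) < 2L) stop("need at least 2 mesh files")
  shapes <- lapply(paths, read_mesh)
  if (is.null(names))
    names <- tools::file_path_sans_ext(basename(paths))
  shape_set(shapes, names)
}

#' Flatten a mesh to a shape vector and back
#'
#' The shape vector stores vertex coordinates in the fixed order
#' `(x1, y1, z1, ..., xM, yM, zM)`.  Kernel distances depend only on the
#' vector norm, but the preimage linear algebra depends on this layout, so
#' it is part of the model contract.
#'
#' @param shape a [tri_mesh] or an `M x 3` vertex matrix.
#' @return `flatten_shape`: numeric vector of length `3 M`.
#' @export
flatten_shape <- function(shape) {
  V <- if (inherits(shape, "tri_mesh")) shape$vertices else as.matrix(shape)
  if (!all(is.finite(V))) stop("non-finite coordinates")
  as.vector(t(V))
}

#' @rdname flatten_shape
#' @param v a shape vector of length `3 M`.
#' @param faces shared face list for the rebuilt mesh (may be a 0-row
#'   matrix when only vertices are needed).
#' @return `unflatten_shape`: a [tri_mesh].
#' @export
unflatten_shape <- function(v, faces) {
  if (length(v) %% 3L != 0L)
    stop("shape vector length must be divisible by 3")
  tri_mesh(matrix(v, ncol = 3L, byrow = TRUE), faces)
}

# vertex matrix from shape vector, no mesh wrapper
vec_to_vertices <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

# Kabsch rotation R (right-multiplies row-vertices) aligning B onto A,
# both centred, no scaling: B %*% R ~ A
kabsch_rotation <- function(A, B) {
  H <- crossprod(B, A)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Rigid (generalized Procrustes) alignment of a shape set
#'
#' Removes translation and rotation differences between the corresponded
#' shapes by iterative alignment to the evolving mean; scale is *not*
#' normalized, so size remains part of the shape signal and model errors
#' stay in mm.  All centroids end at the origin and the procedure is
#' idempotent to numerical precision.
#'
#' @param set a [shape_set].
#' @param max_iter maximum mean-shape iterations.
#' @param tol convergence tolerance on the mean-shape change (mm).
#' @return The aligned [shape_set].
#' @export
rigid_align_set <- function(set, max_iter = 20L, tol = 1e-10) {
  stopifnot(inherits(set, "shape_set"))
  Vs <- lapply(set$shapes, function(s) {
    V <- s$vertices
    V - matrix(colMeans(V), nrow(V), 3L, byrow = TRUE)
  })
  for (V in Vs)
    if (max(abs(V)) < 1e-12)
      stop("degenerate shape: all vertices coincident")
  ref <- Vs[[1]]
  for (it in seq_len(max_iter)) {
    Vs <- lapply(Vs, function(V) V %*% kabsch_rotation(ref, V))
    newref <- Reduce(`+`, Vs) / length(Vs)
    if (max(abs(newref - ref)) < tol) { ref <- newref; break }
    ref <- newref
  }
  shapes <- mapply(function(s, V) tri_mesh(V, s$faces, s$anatomy),
                   set$shapes, Vs, SIMPLIFY = FALSE)
  out <- shape_set(shapes, set$names)
  for (a in setdiff(names(attributes(set)), c("names", "class")))
    attr(out, a) <- attr(set, a)
  out
}

# N x 3M matrix of flattened, row-per-shape training vectors
shape_matrix <- function(set) {
  t(vapply(set$shapes, flatten_shape,
           numeric(3L * nrow(set$shapes[[1]]$vertices))))
}
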