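#' Pair femoral condyle and tibial plateau contact patches
#'
#' Knee collision only occurs between the femoral condyles and the tibial
#' plateau, so the collision test is restricted to those patches.  At a
#' reference (extended) configuration the tibial plateau is taken as the
#' top decile of tibia vertices along the tibial long axis (principal axis
#' oriented toward the femur); each plateau vertex is paired with its
#' nearest femur vertex at reference, and a bottom plane is fit to the
#' lowest tibia vertices.  Patch indices and the plane are stored in the
#' bones' local coordinates so they transform rigidly with any pose.
#'
#' @param femur,tibia [tri_mesh] objects.  When the meshes carry
#'   `anatomy` labels the argument order is checked.
#' @param femur_pose,tibia_pose reference poses placing both bones in a
#'   common frame (default: identity).
#' @param top_frac fraction of the tibia span treated as plateau (and,
#'   mirrored, as the bottom-plane fit set).
#' @param max_pair_frac pairs whose reference distance exceeds this
#'   fraction of the tibia extent are dropped: only the contact region
#'   can collide, and far-apart pairs across the curved plateau rim make
#'   the height comparison meaningless at deep flexion.
#' @return An object of class `collision_geometry` with
#'   `plateau_vertex_ids`, `condyle_vertex_ids` (paired 1:1),
#'   `bottom_plane` (unit normal + offset, tibia-local) .
#' @export
pair_contact_patches <- function(femur, tibia,
                                 femur_pose = pose(), tibia_pose = pose(),
                                 top_frac = 0.1, max_pair_frac = 0.15) {
  stopifnot(inherits(femur, "tri_mesh"), inherits(tibia, "tri_mesh"))
  if (!is.null(femur$anatomy) && !is.null(tibia$anatomy) &&
      (grepl("tibia", femur$anatomy) || grepl("femur", tibia$anatomy)))
    stop("patch orientation check failed: femur/tibia arguments swapped?")
  Vf <- apply_pose(femur$vertices, femur_pose)
  Vt <- apply_pose(tibia$vertices, tibia_pose)
  # tibial long axis: principal axis, oriented toward the femur
  ct <- colMeans(Vt)
  ax <- svd(sweep(Vt, 2L, ct), nu = 0L, nv = 1L)$v[, 1]
  if (sum(ax * (colMeans(Vf) - ct)) < 0) ax <- -ax
  h <- drop(sweep(Vt, 2L, ct) %*% ax)
  span <- diff(range(h))
  if (span < 1e-9) stop("degenerate tibia: zero extent along long axis")
  plateau <- which(h >= max(h) - top_frac * span)
  bottom <- which(h <= min(h) + top_frac * span)
  if (length(plateau) == 0L || length(bottom) == 0L) stop("empty patch")
  # pair each plateau vertex with its nearest femur vertex at reference;
  # keep only contact-region pairs
  condyle <- vapply(plateau, function(i) {
    d2 <- rowSums(sweep(Vf, 2L, Vt[i, ])^2)
    which.min(d2)
  }, integer(1))
  pair_d <- sqrt(rowSums((Vf[condyle, , drop = FALSE] -
                            Vt[plateau, , drop = FALSE])^2))
  extent <- max(stats::dist(Vt[c(plateau[1], bottom[1],
                                 which.max(h), which.min(h)), ]))
  extent <- max(extent, diff(range(h)))
  keep <- which(pair_d <= max_pair_frac * extent)
  if (length(keep) == 0L)
    stop("empty patch: no contact-region pairs within max_pair_frac")
  plateau <- plateau[keep]
  condyle <- condyle[keep]
  # orientation sanity: paired femur vertices must sit above the plateau
  if (stats::median(drop(sweep(Vf[condyle, , drop = FALSE], 2L, ct) %*% ax)) <
      stats::median(h[plateau]))
    stop("patch orientation check failed: femur does not lie beyond the plateau")
  # bottom plane in world coords at reference, then mapped to tibia-local
  d_world <- mean(drop(Vt[bottom, , drop = FALSE] %*% ax))
  Rt <- rotation_matrix(tibia_pose)
  n_local <- drop(t(Rt) %*% ax)
  d_local <- d_world - sum(ax * c(tibia_pose$tx, tibia_pose$ty,
                                  tibia_pose$tz))
  structure(list(plateau_vertex_ids = plateau,
                 condyle_vertex_ids = condyle,
                 bottom_plane = list(normal = n_local, offset = d_local)),
            class = "collision_geometry")
}

#' @export
print.collision_geometry <- function(x, ...) {
  cat(sprintf("collision_geometry: %d plateau/condyle vertex pairs\n",
              length(x$plateau_vertex_ids)))
  invisible(x)
}

#' Fast paired-vertex collision test
#'
#' Poses both bones, transforms the tibial bottom plane rigidly with the
#' tibia, and compares for every pair the distance of the plateau vertex
#' (`h1`) and of its corresponding femoral condyle vertex (`h2`) to the
#' bottom plane.  A condyle vertex sinking below its plateau partner
#' (`h2 < h1 - tol`) signals interpenetration.  Being distance-based, the
#' test is independent of the flexion of either bone, and rigidly moving
#' both bones together never changes the outcome.
#'
#' @param geom a `collision_geometry` from [pair_contact_patches].
#' @param femur,tibia the same [tri_mesh] objects used to build `geom`.
#' @param femur_pose,tibia_pose candidate poses.
#' @param tol contact tolerance (mm).
#' @return `H1`: 1 if a collision is detected, else 0.
#' @export
detect_collision <- function(geom, femur, tibia, femur_pose, tibia_pose,
                             tol = 0.1) {
  stopifnot(inherits(geom, "collision_geometry"))
  Rt <- rotation_matrix(tibia_pose)
  tt <- c(tibia_pose$tx, tibia_pose$ty, tibia_pose$tz)
  n_w <- drop(Rt %*% geom$bottom_plane$normal)
  d_w <- geom$bottom_plane$offset + sum(n_w * tt)
  Pp <- apply_pose(tibia$vertices[geom$plateau_vertex_ids, , drop = FALSE],
                   tibia_pose)
  Pc <- apply_pose(femur$vertices[geom$condyle_vertex_ids, , drop = FALSE],
                   femur_pose)
  h1 <- drop(Pp %*% n_w) - d_w
  h2 <- drop(Pc %*% n_w) - d_w
  as.integer(any(h2 < h1 - tol))
}

#' Collision penalty score
#'
#' `Ec = big_C * H1`: zero without collision, a large constant with one.
#' The penalty does not strictly prohibit collisions; it makes
#' interpenetrating configurations unattractive to the optimizer.
#'
#' @param H1 collision indicator in `{0, 1}`.
#' @param big_C large positive constant.
#' @return `0` or `big_C`.
#' @export
collision_score <- function(H1, big_C = 1e6) {
  big_C * as.numeric(H1 != 0)
}

#' Brute-force mesh intersection test (reference oracle)
#'
#' Exhaustive triangle-triangle intersection (separating-axis test with
#' bounding-box pre-rejection) between two posed meshes.  Used as the
#' independent cross-check for [detect_collision]; far too slow for the
#' optimization loop.
#'
#' @param mesh1,mesh2 [tri_mesh] objects.
#' @param pose1,pose2 poses of the two meshes.
#' @param tol separation tolerance (mm).
#' @return `TRUE` if any triangles intersect.
#' @export
meshes_intersect <- function(mesh1, mesh2, pose1 = pose(), pose2 = pose(),
                             tol = 0) {
  V1 <- apply_pose(mesh1$vertices, pose1)
  V2 <- apply_pose(mesh2$vertices, pose2)
  meshes_intersect_cpp(V1, mesh1$faces - 1L, V2, mesh2$faces - 1L, tol)
}
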