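#' Perspective camera model (point source + planar detector)
#'
#' Models the fluoroscope as an x-ray point source at the origin and a
#' planar image receptor at `z = source_to_image_distance`.  A 3-D point
#' `(x, y, z)` (camera frame, mm, `z > 0`) maps to the pixel
#' `principal_point + (sid / pixel_pitch) * (x/z, y/z)`.
#' Image convention: origin at the top-left pixel, x to the right, y down,
#' 0-based pixel indices; camera x is image-right and camera y image-down.
#'
#' @param source_to_image_distance source-to-detector distance (mm).
#' @param pixel_pitch detector pixel size (mm/pixel).
#' @param image_size `c(width, height)` in pixels.
#' @param principal_point `c(x, y)` pixel coordinates of the optical axis;
#'   defaults to the image center.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(source_to_image_distance, pixel_pitch,
                         image_size = c(320L, 240L),
                         principal_point = NULL) {
  if (source_to_image_distance <= 0) stop("source_to_image_distance must be > 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L))
    stop("image_size must be c(width, height)")
  if (is.null(principal_point))
    principal_point <- (image_size - 1) / 2
  if (any(principal_point < 0) || any(principal_point > image_size - 1))
    stop("principal point outside image")
  structure(list(sid = source_to_image_distance,
                 pitch = pixel_pitch,
                 image_size = image_size,
                 principal_point = as.numeric(principal_point)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: SID %.4g mm, pitch %.4g mm/px, image %dx%d px\n",
              x$sid, x$pitch, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Read / write a camera description (YAML)
#'
#' YAML keys: `sid_mm`, `pixel_pitch_mm`, `image_size_px`,
#' `principal_point_px`.
#'
#' @param path YAML file path.
#' @return `read_camera`: a [camera_model].
#' @export
read_camera <- function(path) {
  y <- yaml::read_yaml(path)
  camera_model(y$sid_mm, y$pixel_pitch_mm,
               image_size = unlist(y$image_size_px),
               principal_point = if (is.null(y$principal_point_px)) NULL
                                 else unlist(y$principal_point_px))
}

#' @rdname read_camera
#' @param cam a [camera_model].
#' @export
write_camera <- function(cam, path) {
  yaml::write_yaml(list(sid_mm = cam$sid,
                        pixel_pitch_mm = cam$pitch,
                        image_size_px = as.integer(cam$image_size),
                        principal_point_px = cam$principal_point), path)
  invisible(path)
}

#' Six-degree-of-freedom rigid pose
#'
#' Rotations `alpha`, `beta`, `gamma` (degrees) about the camera x
#' (anterior-posterior), y (proximal-distal) and z (medial-lateral) axes,
#' composed as `R = Rgamma %*% Rbeta %*% Ralpha` (x-rotation applied
#' first), plus a translation `(tx, ty, tz)` in mm:
#' `X = R %*% X0 + t`.  In the sagittal acquisition convention, knee
#' flexion is the `gamma` rotation.
#'
#' @param alpha,beta,gamma rotations in degrees.
#' @param tx,ty,tz translation in mm.
#' @return An object of class `pose6`.
#' @export
pose <- function(alpha = 0, beta = 0, gamma = 0, tx = 0, ty = 0, tz = 0) {
  p <- c(alpha = alpha, beta = beta, gamma = gamma,
         tx = tx, ty = ty, tz = tz)
  if (!all(is.finite(p))) stop("pose parameters must be finite")
  structure(as.list(p), class = "pose6")
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf("pose6: rot (%.3g, %.3g, %.3g) deg, trans (%.4g, %.4g, %.4g) mm\n",
              x$alpha, x$beta, x$gamma, x$tx, x$ty, x$tz))
  invisible(x)
}

pose_from_vector <- function(v) {
  pose(v[1], v[2], v[3], v[4], v[5], v[6])
}

pose_to_vector <- function(p) {
  c(p$alpha, p$beta, p$gamma, p$tx, p$ty, p$tz)
}

#' Rotation matrix of a pose
#'
#' `R = Rgamma %*% Rbeta %*% Ralpha` with the elementary rotations about
#' z, y and x respectively; orthonormal with determinant +1.
#'
#' @param p a [pose6].
#' @return `3 x 3` rotation matrix.
#' @export
rotation_matrix <- function(p) {
  a <- p$alpha * pi / 180; b <- p$beta * pi / 180; g <- p$gamma * pi / 180
  Ra <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3L, 3L, byrow = TRUE)
  Rb <- matrix(c(cos(b), 0, sin(b),
                 0, 1, 0,
                 -sin(b), 0, cos(b)), 3L, 3L, byrow = TRUE)
  Rg <- matrix(c(cos(g), -sin(g), 0,
                 sin(g), cos(g), 0,
                 0, 0, 1), 3L, 3L, byrow = TRUE)
  Rg %*% Rb %*% Ra
}

#' Apply a rigid pose to a point set
#'
#' @param X `M x 3` matrix of points (mm).
#' @param p a [pose6].
#' @return Transformed `M x 3` matrix `R X' + t`.
#' @export
apply_pose <- function(X, p) {
  X <- as.matrix(X)
  R <- rotation_matrix(p)
  t(R %*% t(X)) + matrix(c(p$tx, p$ty, p$tz), nrow(X), 3L, byrow = TRUE)
}

# Euler angles (deg) from a Rz Ry Rx rotation matrix
euler_from_matrix <- function(R) {
  beta <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(beta)) > 1e-12) {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    alpha <- atan2(-R[2, 3], R[2, 2])
    gamma <- 0
  }
  c(alpha, beta, gamma) * 180 / pi
}

#' Compose and invert poses
#'
#' `compose_pose(outer, inner)` is the pose equivalent to applying `inner`
#' then `outer`; `invert_pose(p)` is the analytic inverse
#' (`R^T`, `-R^T t`).  Euler angles are re-extracted from the composed
#' matrix under the `Rz Ry Rx` convention.
#'
#' @param outer,inner,p [pose6] objects.
#' @return A [pose6].
#' @export
is_identity_pose <- function(p) {
  all(c(p$alpha, p$beta, p$gamma, p$tx, p$ty, p$tz) == 0)
}

compose_pose <- function(outer, inner) {
  if (is_identity_pose(outer)) return(inner)
  if (is_identity_pose(inner)) return(outer)
  Ro <- rotation_matrix(outer); Ri <- rotation_matrix(inner)
  R <- Ro %*% Ri
  t <- drop(Ro %*% c(inner$tx, inner$ty, inner$tz)) +
    c(outer$tx, outer$ty, outer$tz)
  ang <- euler_from_matrix(R)
  pose(ang[1], ang[2], ang[3], t[1], t[2], t[3])
}

#' @rdname compose_pose
#' @export
invert_pose <- function(p) {
  R <- rotation_matrix(p)
  t <- -drop(t(R) %*% c(p$tx, p$ty, p$tz))
  ang <- euler_from_matrix(t(R))
  pose(ang[1], ang[2], ang[3], t[1], t[2], t[3])
}

#' Perspective projection of 3-D points to pixel coordinates
#'
#' @param X `M x 3` matrix in the camera frame; all `z > 0`.
#' @param cam a [camera_model].
#' @return `M x 2` matrix of (x, y) pixel coordinates (0-based, y down).
#' @export
project_perspective <- function(X, cam) {
  X <- as.matrix(X)
  if (any(X[, 3] <= 1e-9))
    stop("points at or behind the x-ray source (z <= 0)")
  f <- cam$sid / cam$pitch
  cbind(cam$principal_point[1] + f * X[, 1] / X[, 3],
        cam$principal_point[2] + f * X[, 2] / X[, 3])
}
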