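#' RMS error between corresponded point sets
#'
#' `sqrt(mean_i ||a_i - b_i||^2)` over corresponded points, in mm — the
#' reconstruction accuracy measure.
#'
#' @param A,B `n x 3` point matrices (or shape vectors / [tri_mesh]
#'   objects) in corresponded order.
#' @return RMS distance (mm).
#' @export
rms_error <- function(A, B) {
  A <- points_of(A); B <- points_of(B)
  if (nrow(A) != nrow(B)) stop("point sets differ in size")
  sqrt(mean(rowSums((A - B)^2)))
}

points_of <- function(x) {
  if (inherits(x, "tri_mesh")) return(x$vertices)
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  vec_to_vertices(as.numeric(x))
}

#' Per-vertex surface distance map
#'
#' Distance from every vertex of the estimated mesh to the nearest point
#' on the ground-truth surface (one-directional, estimate to truth), plus
#' summary statistics and the symmetric Hausdorff distance as a
#' supplement.  Correspondence is not required.
#'
#' @param est estimated [tri_mesh].
#' @param truth ground-truth [tri_mesh].
#' @return List with `distances` (per est vertex), `mean`, `max`, `p95`
#'   and `hausdorff`.
#' @export
surface_distance_map <- function(est, truth) {
  stopifnot(inherits(est, "tri_mesh"), inherits(truth, "tri_mesh"))
  if (nrow(est$vertices) == 0L || nrow(truth$vertices) == 0L ||
      nrow(truth$faces) == 0L)
    stop("empty mesh")
  d <- surface_dist_cpp(est$vertices, truth$vertices, truth$faces - 1L)
  dr <- surface_dist_cpp(truth$vertices, est$vertices, est$faces - 1L)
  list(distances = d, mean = mean(d), max = max(d),
       p95 = unname(stats::quantile(d, 0.95)),
       hausdorff = max(max(d), max(dr)))
}

#' Per-axis pose error table
#'
#' Mean absolute error and standard deviation of the per-frame pose
#' differences for the three translations (mm) and three rotations
#' (degrees); angular differences are wrapped to `(-180, 180]`.
#'
#' @param fit_poses,truth_poses equal-length lists of [pose6].
#' @return A data.frame of class `pose_error_table` with rows Tx, Ty, Tz,
#'   Rx, Ry, Rz and columns `mae` and `sd`.
#' @export
pose_error_stats <- function(fit_poses, truth_poses) {
  if (length(fit_poses) != length(truth_poses))
    stop("pose lists differ in length")
  Pf <- t(vapply(fit_poses, pose_to_vector, numeric(6)))
  Pt <- t(vapply(truth_poses, pose_to_vector, numeric(6)))
  diff <- Pf - Pt
  wrap <- function(a) ((a + 180) %% 360) - 180
  diff[, 1:3] <- wrap(diff[, 1:3])
  err <- abs(diff)
  out <- data.frame(
    dof = c("Rx", "Ry", "Rz", "Tx", "Ty", "Tz")[c(4:6, 1:3)],
    mae = c(colMeans(err[, 4:6, drop = FALSE]),
            colMeans(err[, 1:3, drop = FALSE])),
    sd = c(apply(err[, 4:6, drop = FALSE], 2, stats::sd),
           apply(err[, 1:3, drop = FALSE], 2, stats::sd)))
  out$dof <- c("Tx", "Ty", "Tz", "Rx", "Ry", "Rz")
  rownames(out) <- out$dof
  class(out) <- c("pose_error_table", "data.frame")
  out
}

#' Leave-one-out generalization comparison of KPCA and PCA models
#'
#' For every held-out shape, both models are trained on the remaining
#' `N - 1` shapes and the held-out shape is reconstructed from its own
#' projection (projection + preimage for the kernel model; projection +
#' linear reconstruction for PCA); the RMS reconstruction error measures
#' pure shape-model generalization (3-D to 3-D), independent of the
#' image pipeline.
#'
#' @param set a [shape_set] with `N >= 10`.
#' @param sigma_grid kernel widths to evaluate; `NA` entries use the
#'   median pairwise distance of each training fold.
#' @param m_grid component counts to evaluate.
#' @param n_neighbors preimage neighborhood size.
#' @param include_pca also evaluate the linear baseline.
#' @return A data.frame with one row per (model, sigma, m): mean and sd
#'   of the LOO RMS error (mm).
#' @export
loo_experiment <- function(set, sigma_grid = NA, m_grid = 5L,
                           n_neighbors = 10L, include_pca = TRUE) {
  stopifnot(inherits(set, "shape_set"))
  N <- length(set$shapes)
  if (N < 10L) stop("need N >= 10 shapes for leave-one-out")
  if (length(sigma_grid) == 0L || length(m_grid) == 0L)
    stop("empty parameter grid")
  X <- shape_matrix(set)
  rows <- list()
  for (sg in sigma_grid) {
    for (m in m_grid) {
      err_k <- err_p <- numeric(N)
      for (i in seq_len(N)) {
        Xtr <- X[-i, , drop = FALSE]
        km <- kpca_ssm(Xtr, sigma = if (is.na(sg)) NULL else sg, m = m)
        th <- drop(predict(km, X[i, , drop = FALSE]))
        xh <- approximate_preimage(km, th, n_neighbors = n_neighbors)
        err_k[i] <- rms_error(xh, X[i, ])
        if (include_pca) {
          pm <- pca_ssm(Xtr, m = m)
          xp <- reconstruct_shape(pm, drop(predict(pm, X[i, , drop = FALSE])))
          err_p[i] <- rms_error(xp, X[i, ])
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(model = "kpca", sigma = sg, m = m,
                   mean_rms = mean(err_k), sd_rms = stats::sd(err_k))
      if (include_pca)
        rows[[length(rows) + 1L]] <-
          data.frame(model = "pca", sigma = NA_real_, m = m,
                     mean_rms = mean(err_p), sd_rms = stats::sd(err_p))
    }
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("model", "sigma", "m")]), , drop = FALSE]
}
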