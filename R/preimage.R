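#' Feature-space distances from a projected point to the training images
#'
#' For a point of the kernel-PCA subspace given by its coordinates `theta`,
#' computes the squared feature-space distance to every (centered) training
#' image, entirely through kernel evaluations and the dual vectors — the
#' explicit feature map is never materialized:
#' `d~2_i = ||P(theta)||^2 - 2 <P(theta), phi(x_i)> + ||phi(x_i)||^2`
#' `      = (sum(theta^2) - 2 * theta . theta_train_i) / N + Kbar_ii`.
#' The `1/N` converts the stored dual normalization
#' (`lambda_k (alpha_k . alpha_k) = 1` with `lambda = eig(Kbar)/N`) to
#' coordinates along unit feature axes.  Because projection and training
#' images are shifted by the same feature mean, these equal the distances
#' between the *uncentered* reconstruction point and the training images,
#' which is what the Gaussian-kernel inversion expects.
#'
#' @param model a [kpca_ssm].
#' @param theta shape parameters, length `m`.
#' @return Numeric vector of `N` nonnegative squared distances (tiny
#'   negative round-off is clamped at 0).
#' @export
feature_space_distances <- function(model, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != model$m)
    stop("theta must have length m = ", model$m)
  N <- nrow(model$training_vectors)
  d2 <- (sum(theta^2) - 2 * drop(model$theta_train %*% theta)) / N +
    diag(model$centered_kernel)
  if (any(d2 < -1e-9 * max(1, sum(theta^2) / N)))
    warning("feature-space distance significantly negative; clamping")
  pmax(unname(d2), 0)
}

#' Invert the Gaussian kernel distance relation
#'
#' Converts a squared feature-space distance to the corresponding
#' input-space distance via
#' `d^2 = -2 sigma^2 * log[(Kii + Kjj - d~2) / 2]`,
#' the exact inverse of the Gaussian kernel relation.  A log argument
#' falling below `clamp_eps` signals an out-of-model query; the value is
#' clamped and flagged (attribute `"clamped"`), and such neighbors are
#' dropped from the preimage system.
#'
#' @param d_tilde_sq squared feature-space distance.
#' @param Kii,Kjj self-kernel values, in `(0, 1]` (1 for the Gaussian
#'   kernel).
#' @param sigma kernel width (mm).
#' @param clamp_eps lower guard for the log argument, in `(0, 0.5)`.
#' @return Input-space distance `d >= 0` (mm) with logical attribute
#'   `clamped`.
#' @export
input_space_distance <- function(d_tilde_sq, Kii, Kjj, sigma,
                                 clamp_eps = 1e-6) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (clamp_eps <= 0 || clamp_eps >= 0.5) stop("clamp_eps out of (0, 0.5)")
  arg <- (Kii + Kjj - d_tilde_sq) / 2
  clamped <- (arg < clamp_eps)
  arg <- pmin(pmax(arg, clamp_eps), 1)
  d <- sqrt(pmax(-2 * sigma^2 * log(arg), 0))
  attr(d, "clamped") <- clamped
  d
}

#' Preimage approximation for the kernel shape model
#'
#' Maps shape parameters `theta` back to a 3-D shape.  The feature-space
#' distances from the projected point to the training images are converted
#' to input-space distances by inverting the Gaussian kernel; the `n`
#' nearest training shapes are selected (their influence drops rapidly with
#' distance); the centered neighbor matrix is factored by SVD and the
#' preimage is the least-squares point reproducing the distances in the
#' local embedding, mapped back through the left singular vectors:
#' `zhat = -1/2 * Lambda^-1 V' (d^2 - d0^2)`, `xhat = U zhat + xbar`.
#'
#' @param model a [kpca_ssm].
#' @param theta shape parameters, length `m`.
#' @param n_neighbors number of neighboring training shapes `n <= N`
#'   (default 10).
#' @param clamp_eps log-argument guard for the kernel inversion; neighbors
#'   whose distance clamps are excluded from the least-squares system
#'   rather than clamped into it.
#' @return Shape vector of length `3 M` (the preimage `xhat`).
#' @export
approximate_preimage <- function(model, theta, n_neighbors = 10L,
                                 clamp_eps = 1e-6) {
  stopifnot(inherits(model, "kpca_ssm"))
  N <- nrow(model$training_vectors)
  n_neighbors <- as.integer(n_neighbors)
  if (n_neighbors < 2L || n_neighbors > N)
    stop("n_neighbors must be in [2, N]")
  d2f <- feature_space_distances(model, theta)
  d <- input_space_distance(d2f, 1, 1, model$sigma, clamp_eps)
  valid <- which(!attr(d, "clamped"))
  if (length(valid) < 2L)
    stop("out-of-model query: fewer than 2 training shapes at finite distance")
  ord <- valid[order(d[valid])]
  nb <- ord[seq_len(min(n_neighbors, length(ord)))]
  Xn <- t(model$training_vectors[nb, , drop = FALSE])   # 3M x n
  xbar <- rowMeans(Xn)
  Xc <- Xn - xbar
  s <- svd(Xc)
  keep <- which(s$d > 1e-10 * max(s$d))
  if (length(keep) == 0L) {
    warning("all preimage neighbors coincide; returning neighbor mean")
    return(xbar)
  }
  U <- s$u[, keep, drop = FALSE]
  sv <- s$d[keep]
  Vt <- t(s$v[, keep, drop = FALSE])
  Z <- sv * Vt                       # rank x n projections z_i
  d0sq <- colSums(Z^2)
  zhat <- -0.5 * (1 / sv) * (Vt %*% (d[nb]^2 - d0sq))
  drop(U %*% zhat + xbar)
}
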