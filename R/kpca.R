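#' Gaussian kernel between two shape vectors
#'
#' `k(a, b) = exp(-||a - b||^2 / (2 sigma^2))`, the radial basis kernel
#' used by the nonlinear shape model.  `sigma` is the kernel width in the
#' same units as the shape-vector norm (mm).
#'
#' @param a,b numeric shape vectors of equal length.
#' @param sigma kernel width, `> 0` (mm).
#' @return Kernel value in `(0, 1]`.
#' @export
gaussian_kernel <- function(a, b, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(a) != length(b)) stop("shape vectors differ in length")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

#' Double-center a kernel matrix
#'
#' Centers the implicit feature map: `Kbar = H K H` with
#' `H = I - 11'/N`, i.e. subtracts row means and column means and adds the
#' grand mean.  Every row and column of the result sums to zero.
#'
#' @param K symmetric `N x N` kernel matrix.
#' @return The centered kernel matrix.
#' @export
center_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  rm <- rowMeans(K); cm <- colMeans(K); g <- mean(K)
  Kb <- K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + g
  (Kb + t(Kb)) / 2
}

#' Fit a kernel-PCA statistical shape model
#'
#' Trains the nonlinear SSM on a corresponded shape population: builds the
#' Gaussian kernel matrix of the flattened training shapes, centers it,
#' solves the dual eigenproblem and normalizes the dual eigenvectors so the
#' corresponding feature-space axes have unit norm
#' (`lambda_k * (alpha_k . alpha_k) = 1`).  Eigenvalues are stored under
#' the convention `lambda = eig(Kbar) / N`; only ratios and the
#' normalization matter downstream.
#'
#' @param set a [shape_set] (assumed pose-normalized, see
#'   [rigid_align_set]), or an `N x 3M` matrix of shape vectors.
#' @param sigma kernel width (mm); default: median pairwise training
#'   distance.
#' @param m number of retained components, `1 <= m <= N - 1`; default:
#'   smallest `m` reaching 95% cumulative kernel variance, capped at 10.
#' @return An object of class `kpca_ssm`.
#' @export
kpca_ssm <- function(set, sigma = NULL, m = NULL) {
  if (inherits(set, "shape_set")) {
    X <- shape_matrix(set)
    faces <- set$faces
    names <- set$names
  } else {
    X <- as.matrix(set)
    faces <- matrix(integer(0), 0L, 3L)
    names <- rownames(X) %||% sprintf("shape%03d", seq_len(nrow(X)))
  }
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 training shapes")
  D <- as.matrix(stats::dist(X))
  if (is.null(sigma)) sigma <- stats::median(D[upper.tri(D)])
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be > 0 (are all training shapes identical?)")
  K <- exp(-D^2 / (2 * sigma^2))
  Kb <- center_kernel(K)
  ev <- eigen(Kb, symmetric = TRUE)
  mu <- ev$values                     # eigenvalues of Kbar, descending
  if (any(mu < -1e-10 * max(abs(mu), 1)))
    stop("centered kernel matrix has significantly negative eigenvalues")
  mu[mu < 0] <- 0
  lambdas_full <- mu / N
  pos <- which(mu > 1e-12 * max(mu))
  if (length(pos) == 0L)
    stop("degenerate model: kernel matrix has numerical rank 0")
  m_max <- min(length(pos), N - 1L)
  if (is.null(m)) {
    cum <- cumsum(mu) / sum(mu)
    m <- min(which(cum >= 0.95)[1], 10L, m_max)
  }
  if (m < 1L || m > N - 1L) stop("m out of range [1, N-1]")
  if (m > m_max) {
    warning(sprintf("reducing m from %d to %d: trailing eigenvalues are numerically zero",
                    m, m_max))
    m <- m_max
  }
  idx <- seq_len(m)
  lambdas <- mu[idx] / N
  # normalize dual vectors: lambda_k * (alpha_k . alpha_k) = 1
  alphas <- sweep(ev$vectors[, idx, drop = FALSE], 2L,
                  sqrt(lambdas), `/`)
  theta_train <- Kb %*% alphas
  obj <- structure(list(
    sigma = sigma, m = m,
    training_vectors = X,
    kernel_matrix = K,
    centered_kernel = Kb,
    alphas = alphas,
    lambdas = lambdas,
    lambdas_full = lambdas_full,
    theta_train = theta_train,
    mean_shape = colMeans(X),
    kernel_row_means = rowMeans(K),
    kernel_grand_mean = mean(K),
    faces = faces, names = names), class = "kpca_ssm")
  obj
}

#' @export
print.kpca_ssm <- function(x, ...) {
  cat(sprintf("Kernel-PCA statistical shape model\n  N = %d training shapes, %d coordinates\n  sigma = %.4g mm, m = %d components\n",
              nrow(x$training_vectors), ncol(x$training_vectors),
              x$sigma, x$m))
  invisible(x)
}

#' @export
summary.kpca_ssm <- function(object, ...) {
  cv <- cumulative_variance(object)
  cat(sprintf("Kernel-PCA SSM: N = %d, sigma = %.4g mm, m = %d\n",
              nrow(object$training_vectors), object$sigma, object$m))
  cat(sprintf("  kernel variance captured by m components: %.1f%%\n",
              100 * cv[object$m]))
  cat("  leading eigenvalues (eig(Kbar)/N):\n")
  print(signif(object$lambdas, 4))
  invisible(object)
}

# centered test kernel values k~(x_i, x) for a single shape vector x
centered_test_kernel <- function(model, x) {
  kx <- vapply(seq_len(nrow(model$training_vectors)), function(i)
    gaussian_kernel(model$training_vectors[i, ], x, model$sigma),
    numeric(1))
  kx - mean(kx) - model$kernel_row_means + model$kernel_grand_mean
}

#' Project shapes onto the kernel-PCA feature subspace
#'
#' Computes the feature-space coordinates
#' `theta_k = sum_i alpha_ik * ktilde(x_i, x)` for new shapes, where
#' `ktilde` centers the test kernel values consistently with training.
#'
#' @param object a [kpca_ssm] model.
#' @param newdata a shape vector, a matrix of shape vectors (one per row),
#'   a [tri_mesh], or a [shape_set].  Defaults to the training shapes.
#' @param ... unused.
#' @return A matrix of shape parameters, one row per shape (`m` columns).
#' @export
predict.kpca_ssm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    out <- object$theta_train
    colnames(out) <- paste0("theta", seq_len(ncol(out)))
    return(out)
  }
  X <- newdata_to_matrix(newdata)
  if (ncol(X) != ncol(object$training_vectors))
    stop("dimension mismatch: expected shape vectors of length ",
         ncol(object$training_vectors))
  out <- t(apply(X, 1L, function(x)
    drop(crossprod(object$alphas, centered_test_kernel(object, x)))))
  if (object$m == 1L) out <- matrix(out, ncol = 1L)
  colnames(out) <- paste0("theta", seq_len(ncol(out)))
  out
}

newdata_to_matrix <- function(newdata) {
  if (inherits(newdata, "shape_set")) return(shape_matrix(newdata))
  if (inherits(newdata, "tri_mesh"))
    return(matrix(flatten_shape(newdata), nrow = 1L))
  if (is.matrix(newdata)) return(newdata)
  matrix(as.numeric(newdata), nrow = 1L)
}

#' Fit a linear-PCA statistical shape model (baseline)
#'
#' Standard eigendecomposition of the vertex-coordinate covariance of the
#' flattened training shapes; the linear baseline the kernel model is
#' compared against.
#'
#' @param set a [shape_set] or `N x 3M` matrix of shape vectors.
#' @param m retained components, `1 <= m <= N - 1`; default `N - 1`.
#' @return An object of class `pca_ssm` with `mean_shape`, orthonormal
#'   `modes` (columns) and `variances`.
#' @export
pca_ssm <- function(set, m = NULL) {
  if (inherits(set, "shape_set")) {
    X <- shape_matrix(set); faces <- set$faces
  } else {
    X <- as.matrix(set); faces <- matrix(integer(0), 0L, 3L)
  }
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 training shapes")
  m_max <- min(N - 1L, ncol(X))
  if (is.null(m)) m <- m_max
  if (m < 1L || m > m_max) stop("m out of range [1, min(N-1, 3M)]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  s <- svd(Xc, nu = 0, nv = m_max)
  variances_full <- s$d[seq_len(m_max)]^2 / (N - 1L)
  structure(list(mean_shape = mu,
                 modes = s$v[, seq_len(m), drop = FALSE],
                 variances = variances_full[seq_len(m)],
                 variances_full = variances_full,
                 m = m, faces = faces), class = "pca_ssm")
}

#' @export
print.pca_ssm <- function(x, ...) {
  cat(sprintf("Linear-PCA statistical shape model: %d coordinates, m = %d modes\n",
              length(x$mean_shape), x$m))
  invisible(x)
}

#' @export
predict.pca_ssm <- function(object, newdata, ...) {
  X <- newdata_to_matrix(newdata)
  out <- sweep(X, 2L, object$mean_shape) %*% object$modes
  colnames(out) <- paste0("theta", seq_len(ncol(out)))
  out
}

#' Reconstruct a shape from model parameters
#'
#' Generic inverse map from shape parameters back to a 3-D shape: the
#' linear reconstruction `mean + modes %*% theta` for [pca_ssm], and the
#' distance-based preimage approximation (see [approximate_preimage]) for
#' [kpca_ssm].
#'
#' @param model a fitted shape model.
#' @param theta numeric parameter vector.
#' @param ... passed to the method (e.g. `n_neighbors` for the kernel
#'   model).
#' @return A shape vector of length `3 M`.
#' @export
reconstruct_shape <- function(model, theta, ...) UseMethod("reconstruct_shape")

#' @rdname reconstruct_shape
#' @export
reconstruct_shape.pca_ssm <- function(model, theta, ...) {
  theta <- as.numeric(theta)
  if (length(theta) > model$m) stop("theta longer than retained modes")
  drop(model$mean_shape +
         model$modes[, seq_along(theta), drop = FALSE] %*% theta)
}

#' @rdname reconstruct_shape
#' @export
reconstruct_shape.kpca_ssm <- function(model, theta, ...) {
  approximate_preimage(model, theta, ...)
}

#' Cumulative variance (compactness) curve of a shape model
#'
#' Fraction of total (kernel) variance captured by the first `k`
#' components, for `k = 1 .. N-1`; the compactness curve used to compare
#' models.
#'
#' @param model a [kpca_ssm] or [pca_ssm].
#' @return Nondecreasing numeric vector of fractions ending at 1.
#' @export
cumulative_variance <- function(model) UseMethod("cumulative_variance")

#' @export
cumulative_variance.kpca_ssm <- function(model) {
  ev <- model$lambdas_full
  cumsum(ev) / sum(ev)
}

#' @export
cumulative_variance.pca_ssm <- function(model) {
  ev <- model$variances_full
  cumsum(ev) / sum(ev)
}

#' Principal-component scatter and bimodality diagnostics
#'
#' Projects the population onto the first two linear-PCA components,
#' summarizes each with a Gaussian fit, and quantifies bimodality of the
#' first component by comparing one- and two-component Gaussian mixture
#' fits (`delta_bic > 0` favors two clusters).  Used to verify that a
#' population is non-Gaussian/clustered, the regime where the kernel model
#' is expected to beat the linear one.
#'
#' @param set a [shape_set] with `N >= 10` shapes, or a matrix of shape
#'   vectors.
#' @return A list with `scores` (PC1/PC2, `N x 2`), `gaussian_fit`
#'   (mean/sd per PC), `delta_bic`, `cluster_means`, `pooled_sd` and the
#'   two-component `classification`.
#' @export
pc_scatter_diagnostics <- function(set) {
  X <- if (inherits(set, "shape_set")) shape_matrix(set) else as.matrix(set)
  if (nrow(X) < 10L) stop("need N >= 10 shapes for distribution diagnostics")
  Xc <- sweep(X, 2L, colMeans(X))
  tv <- sum(Xc^2)
  if (tv < 1e-20) stop("degenerate population: zero shape variance")
  s <- svd(Xc, nu = 2L, nv = 0L)
  scores <- s$u %*% diag(s$d[1:2])
  colnames(scores) <- c("PC1", "PC2")
  fit <- data.frame(pc = c("PC1", "PC2"),
                    mean = colMeans(scores),
                    sd = apply(scores, 2L, stats::sd))
  pc1 <- scores[, 1L]
  m1 <- mclust::Mclust(pc1, G = 1, modelNames = "V", verbose = FALSE)
  m2 <- mclust::Mclust(pc1, G = 2, modelNames = "V", verbose = FALSE)
  delta_bic <- if (is.null(m2)) -Inf else m2$bic - m1$bic
  cl_means <- if (is.null(m2)) c(NA_real_, NA_real_) else m2$parameters$mean
  pooled_sd <- if (is.null(m2)) NA_real_ else
    sqrt(mean(m2$parameters$variance$sigmasq))
  list(scores = scores, gaussian_fit = fit, delta_bic = delta_bic,
       cluster_means = cl_means, pooled_sd = pooled_sd,
       classification = if (is.null(m2)) rep(1L, length(pc1)) else
         m2$classification)
}

#' Plot the compactness curve of a shape model
#'
#' Cumulative fraction of (kernel) variance versus number of components.
#'
#' @param x a fitted [kpca_ssm] or [pca_ssm].
#' @param ... passed to [graphics::plot].
#' @export
plot.kpca_ssm <- function(x, ...) {
  cv <- cumulative_variance(x)
  graphics::plot(seq_along(cv), cv, type = "b", pch = 16,
                 xlab = "components", ylab = "cumulative variance",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.95, lty = 3)
  invisible(x)
}

#' @rdname plot.kpca_ssm
#' @export
plot.pca_ssm <- plot.kpca_ssm
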