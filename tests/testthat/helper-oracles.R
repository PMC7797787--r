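# Independent oracles used to cross-check the implementation paths.

# Explicit empirical-kernel-map embedding: eigendecompose the centered
# kernel, embed training images as rows of V * sqrt(mu), embed a test
# point by its coordinates along every unit feature axis, zero the
# coordinates beyond the retained m, and measure distances explicitly.
# Never shares code with feature_space_distances().
embedding_distances_oracle <- function(model, x) {
  Kb <- model$centered_kernel
  ev <- eigen(Kb, symmetric = TRUE)
  mu <- pmax(ev$values, 0)
  pos <- mu > 1e-12 * max(mu)
  Y <- ev$vectors[, pos, drop = FALSE] %*% diag(sqrt(mu[pos]))
  kx <- vapply(seq_len(nrow(model$training_vectors)), function(i)
    gaussian_kernel(model$training_vectors[i, ], x, model$sigma),
    numeric(1))
  ktil <- kx - mean(kx) - model$kernel_row_means + model$kernel_grand_mean
  coords <- drop(t(ev$vectors[, pos, drop = FALSE]) %*% ktil) / sqrt(mu[pos])
  proj <- coords
  if (length(proj) > model$m) proj[-seq_len(model$m)] <- 0
  colSums((t(Y) - proj)^2)
}

# Fixed-point iterative preimage (the classical Gaussian-kernel scheme):
# z <- sum_i gamma_i k(z, x_i) x_i / sum_i gamma_i k(z, x_i), where the
# gamma_i expand the projected-plus-mean feature point over the training
# images.  Implemented for tests only; independent of the SVD route.
iterative_preimage_oracle <- function(model, theta, z0 = NULL,
                                      iters = 500L, tol = 1e-10) {
  X <- model$training_vectors
  N <- nrow(X)
  alpha_std <- model$alphas / sqrt(N)
  theta_std <- theta / sqrt(N)
  cvec <- drop(alpha_std %*% theta_std)
  gam <- cvec + (1 - sum(cvec)) / N
  z <- z0 %||% model$mean_shape
  for (it in seq_len(iters)) {
    k <- exp(-colSums((t(X) - z)^2) / (2 * model$sigma^2))
    w <- gam * k
    s <- sum(w)
    if (abs(s) < 1e-300) break
    znew <- drop(t(X) %*% w) / s
    if (sqrt(mean((znew - z)^2)) < tol) { z <- znew; break }
    z <- znew
  }
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
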