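test_that("feature-space distances match the explicit embedding oracle", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  N <- nrow(X)
  km <- kpca_ssm(pop, sigma = 50, m = N - 1L)
  # self-distance of a training shape is zero at full rank
  th <- drop(predict(km, X[5, , drop = FALSE]))
  d2 <- feature_space_distances(km, th)
  expect_lt(d2[5], 1e-8)
  expect_true(all(d2 >= 0))
  expect_equal(d2, embedding_distances_oracle(km, X[5, ]), tolerance = 1e-8)
  # truncated model and the feature-space mean (theta = 0)
  km3 <- kpca_ssm(pop, sigma = 50, m = 3)
  th3 <- drop(predict(km3, X[5, , drop = FALSE]))
  expect_equal(feature_space_distances(km3, th3),
               embedding_distances_oracle(km3, X[5, ]), tolerance = 1e-8)
  expect_equal(feature_space_distances(km3, rep(0, 3)),
               {
                 # oracle for theta = 0: distances to the origin of the
                 # retained subspace = full embedding norms
                 Kb <- km3$centered_kernel
                 ev <- eigen(Kb, symmetric = TRUE)
                 mu <- pmax(ev$values, 0)
                 pos <- mu > 1e-12 * max(mu)
                 Y <- ev$vectors[, pos] %*% diag(sqrt(mu[pos]))
                 rowSums(Y^2)
               }, tolerance = 1e-8)
  expect_error(feature_space_distances(km3, rep(0, 4)), "length m")
})

test_that("the Gaussian kernel distance relation inverts exactly", {
  expect_equal(as.numeric(input_space_distance(0, 1, 1, 30)), 0)
  # planted distance round-trip
  d0 <- 17.3; sigma <- 40
  dt2 <- 2 - 2 * exp(-d0^2 / (2 * sigma^2))
  d <- input_space_distance(dt2, 1, 1, sigma)
  expect_equal(as.numeric(d), d0, tolerance = 1e-9)
  expect_false(attr(d, "clamped"))
  # out-of-model queries clamp and flag
  d2 <- input_space_distance(2.2, 1, 1, sigma)
  expect_true(attr(d2, "clamped"))
  expect_error(input_space_distance(0.1, 1, 1, -1), "sigma")
  expect_error(input_space_distance(0.1, 1, 1, 30, clamp_eps = 0.7),
               "clamp_eps")
})

test_that("training shapes are recovered from their own projections", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  km <- kpca_ssm(pop, sigma = 50, m = nrow(X) - 1L)
  scale <- population_scale(pop)
  for (j in c(1, 5, 9)) {
    th <- drop(predict(km, X[j, , drop = FALSE]))
    xh <- approximate_preimage(km, th, n_neighbors = 10)
    expect_lt(rms_error(xh, X[j, ]) / scale, 0.01)
  }
  expect_error(approximate_preimage(km, rep(0, km$m), n_neighbors = 1),
               "n_neighbors")
})

test_that("coincident neighbors degrade gracefully to their mean", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  q <- X[1, ]
  Xdup <- rbind(matrix(rep(q, 10), 10, byrow = TRUE), X[2:3, ])
  km <- kpca_ssm(Xdup, sigma = 50, m = 2)
  th <- drop(predict(km, matrix(q, 1)))
  expect_warning(xh <- approximate_preimage(km, th, n_neighbors = 10),
                 "coincide")
  expect_equal(xh, unname(q), tolerance = 1e-8)
})

test_that("the SVD preimage agrees with the iterative fixed-point oracle", {
  pop <- phantom_pop()
  km <- kpca_ssm(pop, m = 5)
  box <- 2 * sqrt(km$lambdas)
  scale <- population_scale(pop)
  set.seed(7)
  for (r in 1:8) {
    th <- runif(5, -1, 1) * box
    xh <- approximate_preimage(km, th, n_neighbors = 10)
    xi <- iterative_preimage_oracle(km, th, z0 = xh)
    expect_lt(rms_error(xh, xi) / scale, 0.05)
  }
})

test_that("the preimage is translation-equivariant and lies in the neighbor span", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  km <- kpca_ssm(X, sigma = 50, m = 4)
  th <- drop(predict(km, X[2, , drop = FALSE]))
  xh <- approximate_preimage(km, th, n_neighbors = 6)
  # translate the whole training set
  t3 <- rep(c(4, -7, 11), ncol(X) / 3)
  kmT <- kpca_ssm(sweep(X, 2, -t3), sigma = 50, m = 4)
  thT <- drop(predict(kmT, matrix(X[2, ] + t3, 1)))
  xhT <- approximate_preimage(kmT, thT, n_neighbors = 6)
  expect_lt(max(abs(xhT - (xh + t3))), 1e-6)
  # affine-span property: the preimage lies in the span of its neighbors
  d <- input_space_distance(feature_space_distances(km, th), 1, 1, km$sigma)
  nb <- order(d)[1:6]
  Xn <- t(X[nb, ]); xbar <- rowMeans(Xn)
  B <- svd(Xn - xbar)$u[, 1:5]
  resid <- (xh - xbar) - B %*% crossprod(B, xh - xbar)
  expect_lt(max(abs(resid)), 1e-8)
})
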