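test_that("the Gaussian kernel matches its closed form", {
  x <- c(1, 2, 3)
  expect_identical(gaussian_kernel(x, x, 5), 1)
  # ||a - b||^2 = 2 sigma^2  ->  exp(-1)
  sigma <- 3
  a <- c(0, 0); b <- c(sqrt(2) * sigma, 0)
  expect_equal(gaussian_kernel(a, b, sigma), exp(-1), tolerance = 1e-12)
  set.seed(2)
  u <- rnorm(7); v <- rnorm(7)
  expect_equal(gaussian_kernel(u, v, 2.5),
               exp(-sum((u - v)^2) / (2 * 2.5^2)), tolerance = 1e-15)
  expect_identical(gaussian_kernel(u, v, 2.5), gaussian_kernel(v, u, 2.5))
  expect_error(gaussian_kernel(u, v, 0), "sigma")
})

test_that("kernel centering matches the closed form and is idempotent", {
  a <- 0.37
  K <- matrix(c(1, a, a, 1), 2)
  expect_equal(center_kernel(K),
               ((1 - a) / 2) * matrix(c(1, -1, -1, 1), 2),
               tolerance = 1e-14)
  set.seed(3)
  X <- matrix(rnorm(20), 5)
  K5 <- exp(-as.matrix(dist(X))^2 / 2)
  Kb <- center_kernel(K5)
  expect_lt(max(abs(rowSums(Kb))), 1e-9)
  expect_lt(max(abs(colSums(Kb))), 1e-9)
  expect_lt(max(abs(center_kernel(Kb) - Kb)), 1e-12)
  expect_equal(center_kernel(matrix(1, 4, 4)), matrix(0, 4, 4))
  expect_error(center_kernel(matrix(1, 2, 3)), "square")
})

test_that("kernel model invariants hold after fitting, incl. the N = 2 closed form", {
  pop <- phantom_pop_small()
  km <- kpca_ssm(pop, sigma = 50, m = 6)
  K <- km$kernel_matrix
  expect_true(isSymmetric(K, tol = 1e-12))
  expect_true(all(diag(K) == 1))
  expect_true(all(K > 0 & K <= 1))
  expect_lt(max(abs(rowSums(km$centered_kernel))), 1e-9)
  expect_true(all(diff(km$lambdas) <= 1e-12))
  expect_true(all(km$lambdas_full >= -1e-10))
  # normalization lambda_k (alpha_k . alpha_k) = 1
  expect_lt(max(abs(km$lambdas * colSums(km$alphas^2) - 1)), 1e-8)
  # spectral conservation: sum of eig(Kbar)/N equals trace(Kbar)/N
  expect_equal(sum(km$lambdas_full),
               sum(diag(km$centered_kernel)) / nrow(K), tolerance = 1e-9)
  # N = 2: the single eigenvalue is (1 - k(x1, x2)) / 2
  X2 <- shape_mat(pop)[1:2, ]
  km2 <- kpca_ssm(X2, sigma = 50, m = 1)
  k12 <- gaussian_kernel(X2[1, ], X2[2, ], 50)
  expect_equal(km2$lambdas, (1 - k12) / 2, tolerance = 1e-12)
  # identical training shapes are degenerate
  expect_error(kpca_ssm(X2[c(1, 1), ], sigma = 50, m = 1), "sigma|degenerate")
  expect_error(kpca_ssm(pop, sigma = 50, m = 40), "out of range")
})

test_that("projections reproduce the centered kernel spectrally", {
  pop <- phantom_pop_small()
  N <- length(pop)
  km <- kpca_ssm(pop, sigma = 50, m = N - 1L)
  th <- predict(km)
  expect_lt(norm(km$centered_kernel - th %*% t(th) / N, "F"), 1e-6)
  # projecting a training shape reproduces its training row
  X <- shape_mat(pop)
  expect_equal(unname(drop(predict(km, X[4, , drop = FALSE]))),
               unname(km$theta_train[4, ]), tolerance = 1e-9)
  # duplicated query shapes give identical projections
  two <- predict(km, X[c(7, 7), ])
  expect_identical(two[1, ], two[2, ])
  expect_error(predict(km, numeric(5)), "dimension mismatch")
})

test_that("the linear baseline is complete at m = N - 1 and behaves at m = 1", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  pm <- pca_ssm(pop)
  expect_lt(max(abs(crossprod(pm$modes) - diag(ncol(pm$modes)))), 1e-8)
  expect_true(all(diff(pm$variances) <= 1e-12))
  rec <- reconstruct_shape(pm, drop(predict(pm, X[3, , drop = FALSE])))
  expect_lt(rms_error(rec, X[3, ]) / population_scale(pop), 1e-6)
  expect_equal(reconstruct_shape(pm, rep(0, pm$m)), pm$mean_shape)
  # two shapes give one mode along their difference
  pm2 <- pca_ssm(X[1:2, ], m = 1)
  d <- X[1, ] - X[2, ]
  expect_gt(abs(sum(pm2$modes[, 1] * d / sqrt(sum(d^2)))), 1 - 1e-9)
})

test_that("cumulative variance curves are monotone, end at 1, and equal eigenvalues split evenly", {
  pop <- phantom_pop_small()
  for (model in list(kpca_ssm(pop, sigma = 50, m = 4), pca_ssm(pop))) {
    cv <- cumulative_variance(model)
    expect_true(all(diff(cv) >= -1e-12))
    expect_equal(cv[length(cv)], 1, tolerance = 1e-9)
  }
  # two equal variances -> (0.5, 1)
  X <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(cumulative_variance(pca_ssm(X)), c(0.5, 1), tolerance = 1e-12)
})

test_that("a huge kernel width reproduces the linear model (linear limit)", {
  pop <- phantom_pop()
  X <- shape_mat(pop)
  D <- stats::dist(X)
  km <- kpca_ssm(pop, sigma = 100 * max(D), m = 3)
  pm <- pca_ssm(pop, m = 3)
  r <- stats::cor(predict(km)[, 1], predict(pm, X)[, 1])
  expect_gt(abs(r), 0.99)
})

test_that("distribution diagnostics separate clustered from Gaussian populations", {
  # a single Gaussian cloud should not look bimodal
  set.seed(5)
  G <- matrix(rnorm(30 * 12), 30, 12)
  dg <- pc_scatter_diagnostics(G)
  expect_lt(dg$delta_bic, 10)
  # the two-cluster phantom population must
  dp <- pc_scatter_diagnostics(phantom_pop())
  expect_gt(dp$delta_bic, 10)
  expect_gt(abs(diff(dp$cluster_means)) / dp$pooled_sd, 2)
  expect_error(pc_scatter_diagnostics(matrix(1, 12, 6)), "degenerate")
  expect_error(pc_scatter_diagnostics(G[1:5, ]), "N >= 10")
})
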