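test_that("the RMS error matches hand arithmetic and behaves as a metric", {
  A <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_equal(rms_error(A, A), 0)
  expect_equal(rms_error(A, A + matrix(c(1, 0, 0), 2, 3, byrow = TRUE)), 1)
  B <- rbind(c(1, 0, 0), c(1, 2, 1))
  expect_equal(rms_error(A, B), 1)
  expect_error(rms_error(A, B[1, , drop = FALSE]), "size")
  # symmetry, identity and triangle inequality on random triples
  set.seed(14)
  for (k in 1:5) {
    P <- matrix(rnorm(15), 5); Q <- matrix(rnorm(15), 5)
    R <- matrix(rnorm(15), 5)
    expect_equal(rms_error(P, Q), rms_error(Q, P))
    expect_lte(rms_error(P, R), rms_error(P, Q) + rms_error(Q, R) + 1e-12)
  }
})

test_that("surface distance maps recover analytic offsets", {
  s <- sphere_mesh(20, 24)
  expect_equal(surface_distance_map(s, s)$max, 0, tolerance = 1e-9)
  # inflating a sphere by 1 mm along its normals gives ~1 mm everywhere
  s2 <- tri_mesh(s$vertices * 21 / 20, s$faces)
  sd <- surface_distance_map(s2, s)
  expect_equal(sd$mean, 1, tolerance = 0.05)
  expect_equal(sd$p95, 1, tolerance = 0.1)
  expect_gte(sd$hausdorff, sd$max)
  empty <- tri_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(surface_distance_map(s, empty), "empty")
})

test_that("pose error tables summarize per-axis differences with wrapping", {
  truth <- list(pose(0, 0, 10, 1, 2, 700), pose(0, 0, 40, 1, 2, 700))
  expect_true(all(pose_error_stats(truth, truth)$mae == 0))
  off <- lapply(truth, function(p)
    pose(p$alpha, p$beta, p$gamma + 2, p$tx, p$ty, p$tz))
  tab <- pose_error_stats(off, truth)
  expect_equal(tab["Rz", "mae"], 2)
  expect_equal(tab["Rz", "sd"], 0)
  # angle wrapping: 359 vs 1 degree differ by 2, not 358
  a <- list(pose(gamma = 359)); b <- list(pose(gamma = 1))
  expect_equal(pose_error_stats(a, b)["Rz", "mae"], 2)
  # random offsets match direct computation
  set.seed(15)
  offs <- matrix(rnorm(12, 0, 3), 2)
  fit <- lapply(1:2, function(i) {
    p <- truth[[i]]
    pose(p$alpha + offs[i, 1], p$beta + offs[i, 2], p$gamma + offs[i, 3],
         p$tx + offs[i, 4], p$ty + offs[i, 5], p$tz + offs[i, 6])
  })
  tab2 <- pose_error_stats(fit, truth)
  expect_equal(tab2$mae, colMeans(abs(offs))[c(4:6, 1:3)],
               tolerance = 1e-12)
  expect_error(pose_error_stats(truth, truth[1]), "length")
})

test_that("the leave-one-out experiment runs deterministically on a small set", {
  pop <- phantom_pop_small()
  tab <- loo_experiment(pop, sigma_grid = NA, m_grid = 3L, n_neighbors = 6)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$mean_rms > 0))
  tab2 <- loo_experiment(pop, sigma_grid = NA, m_grid = 3L, n_neighbors = 6)
  expect_identical(tab$mean_rms, tab2$mean_rms)
  # resubstitution control: a full-rank model reconstructs members of its
  # own training set almost exactly
  X <- shape_mat(pop)
  km <- kpca_ssm(pop, sigma = 50, m = nrow(X) - 1L)
  th <- drop(predict(km, X[6, , drop = FALSE]))
  expect_lt(rms_error(approximate_preimage(km, th), X[6, ]) /
              population_scale(pop), 1e-3)
  expect_error(loo_experiment(pop, sigma_grid = numeric(0)), "grid")
})
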