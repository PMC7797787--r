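test_that("the neighbor mask excludes exactly the other bone's silhouette", {
  expect_true(all(neighbor_mask(NULL, dim = c(4, 5))))
  sil <- matrix(FALSE, 4, 6); sil[, 1:3] <- TRUE
  u <- neighbor_mask(sil)
  expect_identical(u, !sil)
  full <- neighbor_mask(matrix(TRUE, 2, 2))
  expect_true(isTRUE(attr(full, "degenerate")))
})

test_that("the edge score counts the unmasked model-edge overlap fraction", {
  C <- matrix(FALSE, 10, 10); C[5, 2:9] <- TRUE
  expect_equal(edge_score(C, C), 1)
  D <- matrix(FALSE, 10, 10); D[8, 2:9] <- TRUE
  expect_equal(edge_score(C, D), 0)
  half <- C; half[5, 2:5] <- FALSE   # image edges cover half the model edge
  expect_equal(edge_score(half, C), 0.5)
  expect_error(edge_score(C, matrix(FALSE, 10, 10)), "empty model edge")
  expect_error(edge_score(C, D[1:5, ]), "shape")
})

test_that("the region score is affine-invariant and rejects noise", {
  set.seed(11)
  base <- conv_sep_smooth(matrix(runif(60 * 80), 60, 80))
  # I2 = a I1 + b scores 1 (squared local correlation)
  expect_equal(region_score(base, 0.4 * base + 0.3), 1, tolerance = 1e-6)
  # independent white noise scores low
  noise <- matrix(runif(60 * 80), 60, 80)
  expect_lt(region_score(base, noise), 0.2)
  # both images constant: degenerate, defined as 0
  z <- region_score(matrix(0.5, 20, 20), matrix(0.7, 20, 20))
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("the homogeneity score vanishes iff the contour separates homogeneous regions", {
  img <- matrix(0.2, 60, 60); img[, 31:60] <- 0.8
  sil <- matrix(FALSE, 60, 60); sil[, 31:60] <- TRUE
  expect_equal(homogeneity_score(img, sil), 0, tolerance = 1e-12)
  # displacing the contour mixes the regions
  sil5 <- matrix(FALSE, 60, 60); sil5[, 26:60] <- TRUE
  expect_gt(homogeneity_score(img, sil5), 0.01)
  # a uniform image is homogeneous under any contour
  expect_equal(homogeneity_score(matrix(0.5, 60, 60), sil), 0,
               tolerance = 1e-12)
  expect_error(homogeneity_score(img, matrix(FALSE, 60, 60)), "contour")
})

test_that("the total energy is the exact weighted combination", {
  w1 <- energy_weights(c1 = 1.5, c2 = 1, c3 = 1, c4 = 1)
  e <- total_energy(1, 1, 0, 0, w1)
  expect_equal(e$E, -2.5)
  w2 <- energy_weights(c1 = 2, c2 = 1, c3 = 1, c4 = 1)
  expect_equal(total_energy(0.5, 0.5, 0.1, 0, w2)$E, -1.4)
  # a collision dominates every other term
  e3 <- total_energy(1, 1, 0, 1e6, w2)
  expect_gt(e3$E, 0)
  expect_error(energy_weights(c1 = 1, c2 = 2), "c1")
  expect_error(energy_weights(c4 = 0, big_C = 1), "big_C")
})

test_that("masked pixels contribute to neither the edge nor the region score", {
  set.seed(12)
  I1 <- conv_sep_smooth(matrix(runif(50 * 50), 50, 50))
  I2 <- conv_sep_smooth(matrix(runif(50 * 50), 50, 50))
  C1 <- I1 > 0.6
  C2 <- I2 > 0.6
  u <- matrix(TRUE, 50, 50); u[, 1:20] <- FALSE
  ee <- edge_score(C1, C2, u)
  er <- region_score(I1, I2, u)
  # paint the masked region with fresh noise
  I1b <- I1; I1b[, 1:20] <- runif(50 * 20)
  C1b <- C1; C1b[, 1:20] <- I1b[, 1:20] > 0.5
  expect_equal(edge_score(C1b, C2, u), ee, tolerance = 1e-12)
  expect_equal(region_score(I1b, I2, u), er, tolerance = 1e-12)
})
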