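test_that("thickness render of a sphere matches the analytic chord and area", {
  s <- sphere_mesh(20, 28)
  cam <- default_camera_test()
  r <- render_model_image(s, pose(tz = 700), cam)
  # chord through the centre = diameter (faceted mesh slightly under)
  expect_equal(r$thickness[120, 160], 40, tolerance = 0.02)
  # silhouette area ~ pi (r f / (z pitch))^2
  pred <- pi * (20 * 1000 / (700 * 0.8))^2
  expect_lt(abs(sum(r$silhouette) - pred) / pred, 0.03)
  expect_false(r$empty)
  # determinism
  r2 <- render_model_image(s, pose(tz = 700), cam)
  expect_identical(r2$thickness, r$thickness)
  # moving away shrinks the silhouette monotonically
  areas <- vapply(c(600, 700, 850, 1000), function(z)
    sum(render_model_image(s, pose(tz = z), cam)$silhouette), numeric(1))
  expect_true(all(diff(areas) < 0))
  # fully off-screen is flagged, behind the source errors
  off <- render_model_image(s, pose(tx = 4000, tz = 700), cam)
  expect_true(off$empty)
  expect_error(render_model_image(s, pose(tz = -5), cam), "behind")
})

test_that("edge extraction finds step edges and ignores flat images", {
  img <- matrix(0, 60, 80)
  img[, 41:80] <- 1
  C <- compute_edge_image(img, edge_config(bilateral_sigma_s = 1,
                                           bilateral_sigma_r = 0.5))
  cols <- which(colSums(C) > 0)
  expect_true(all(cols >= 39 & cols <= 42))
  expect_gt(sum(C), 30)
  expect_equal(sum(compute_edge_image(matrix(0.5, 40, 40))), 0)
})

test_that("a noisy disk yields a closed ring of edge pixels", {
  R_px <- 35
  yy <- matrix(seq_len(240), 240, 320)
  xx <- matrix(seq_len(320), 240, 320, byrow = TRUE)
  disk <- 0.8 * (sqrt((yy - 120)^2 + (xx - 160)^2) < R_px)
  set.seed(8)
  img <- pmin(pmax(disk + matrix(rnorm(length(disk), 0, 0.02), 240), 0), 1)
  C <- compute_edge_image(img)
  expect_lt(abs(sum(C) - 2 * pi * R_px) / (2 * pi * R_px), 0.25)
  # the ring is closed: every edge pixel lies near the circle
  idx <- which(C, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - 120)^2 + (idx[, 2] - 160)^2)
  expect_true(all(abs(d - R_px) < 4))
})

test_that("grayscale images round-trip through PNG and TIFF", {
  set.seed(9)
  img <- matrix(runif(120 * 160), 120, 160)
  for (ext in c(".png", ".tiff")) {
    path <- withr::local_tempfile(fileext = ext)
    write_image(img, path)
    img2 <- read_image(path)
    expect_equal(dim(img2), dim(img))
    expect_lt(max(abs(img2 - img)), 1 / 255)  # 8/16-bit quantization
  }
})

test_that("frames validate their dimensions against the camera", {
  cam <- camera_model(1000, 0.8, c(40L, 30L))
  img <- matrix(0.5, 30, 40)
  fr <- fluoro_frame(img, cam)
  expect_s3_class(fr, "fluoro_frame")
  expect_error(fluoro_frame(matrix(0.5, 40, 30), cam), "dimensions")
})
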