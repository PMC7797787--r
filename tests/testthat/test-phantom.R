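test_that("bone templates are watertight, outward-wound, deterministic meshes", {
  for (kind in c("femur-like", "tibia-like")) {
    m <- make_template(kind, 600)
    expect_gte(nrow(m$vertices), 450)
    expect_lte(nrow(m$vertices), 800)
    # watertight: every edge shared by exactly two faces
    ed <- rbind(m$faces[, 1:2], m$faces[, 2:3], m$faces[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    expect_true(all(table(key) == 2L))
    # Euler characteristic of a closed genus-0 surface
    expect_identical(nrow(m$vertices) - length(unique(key)) + nrow(m$faces),
                     2L)
    # outward winding: positive enclosed volume
    V <- m$vertices; F <- m$faces
    v1 <- V[F[, 1], ]; v2 <- V[F[, 2], ]; v3 <- V[F[, 3], ]
    vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
                 v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
                 v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
    expect_gt(vol, 0)
    expect_identical(make_template(kind, 600)$vertices, m$vertices)
  }
  expect_error(make_template("femur-like", 100), "resolution")
})

test_that("population sampling is deterministic, topology-preserving and clustered", {
  cfg <- phantom_config(n_shapes = 12, resolution = 420, seed = 4)
  a <- sample_population(cfg)
  b <- sample_population(cfg)
  expect_identical(shape_mat(a), shape_mat(b))
  expect_true(all(vapply(a$shapes, function(s)
    identical(s$faces, a$faces), logical(1))))
  # zero amplitudes reproduce the template exactly
  cfg0 <- phantom_config(n_shapes = 4, resolution = 420,
                         morph_sd = 0, condyle_ratio_amp = 0, twist_gain = 0,
                         ridge_amp = 0, shaft_bow_amp = 0,
                         width_scale_sd = 0, depth_scale_sd = 0,
                         sine_amp = 0, noise_sd = 0)
  p0 <- sample_population(cfg0)
  tmpl <- make_template(cfg0$kind, cfg0$resolution, cfg0$scale)
  expect_equal(p0$shapes[[1]]$vertices, tmpl$vertices, tolerance = 1e-12)
  expect_equal(p0$shapes[[4]]$vertices, tmpl$vertices, tolerance = 1e-12)
  # the population mean differs from both cluster centroids
  pop <- phantom_pop()
  cl <- attr(pop, "cluster")
  X <- shape_mat(pop)
  mu <- colMeans(X)
  for (k in 1:2)
    expect_gt(rms_error(colMeans(X[cl == k, , drop = FALSE]), mu), 0.5)
  expect_error(phantom_config(n_shapes = 2), "n_shapes")
  expect_error(phantom_config(cluster_fraction = 1), "cluster_fraction")
})

test_that("simulated sequences store self-consistent ground truth", {
  pop <- phantom_pop_small()
  shape <- pop$shapes[[1]]
  cam <- camera_model(1000, 320 * 0.8 / 160, c(160L, 120L))
  seqn <- simulate_sequence(shape, trajectory_config(n_frames = 3),
                            cam = cam, noise_sd = 0, seed = 2)
  expect_length(seqn$views[[1]]$frames, 3L)
  expect_length(seqn$true_poses, 3L)
  # with zero noise the stored image is exactly the truth render, and the
  # edge score of the true configuration is essentially perfect
  for (i in 1:3) {
    r <- render_model_image(shape, seqn$true_poses[[i]], cam)
    expect_identical(seqn$views[[1]]$frames[[i]]$image, r$image)
    e <- frame_energy(seqn$views[[1]]$frames[[i]], r)
    expect_gte(e$Ee, 0.95)
  }
  # determinism
  seqn2 <- simulate_sequence(shape, trajectory_config(n_frames = 3),
                             cam = cam, noise_sd = 0, seed = 2)
  expect_identical(seqn2$views[[1]]$frames[[2]]$image,
                   seqn$views[[1]]$frames[[2]]$image)
  # a trajectory leaving the detector is an error
  wild <- trajectory_config(n_frames = 2, flexion = c(0, 30), distance = 150)
  expect_error(simulate_sequence(shape, wild, cam = cam, seed = 2),
               "field of view")
})

test_that("two-bone scenes respect the articular gap at ground truth", {
  femur <- make_template("femur-like", 420)
  tibia <- make_template("tibia-like", 420)
  js <- simulate_joint_sequence(femur, tibia,
                                trajectory_config(n_frames = 3,
                                                  flexion = c(0, 40)),
                                gap = 4, noise_sd = 0, seed = 6)
  expect_length(js$views[[1]]$frames, 3L)
  expect_false(meshes_intersect(femur, tibia, js$femur_poses[[1]],
                                js$tibia_poses[[1]]))
  # zero/negative gap produces contact or overlap at reference
  js0 <- simulate_joint_sequence(femur, tibia,
                                 trajectory_config(n_frames = 1,
                                                   flexion = c(0, 0),
                                                   perturb_mm = 0),
                                 gap = -2, noise_sd = 0, seed = 6)
  expect_true(meshes_intersect(femur, tibia, js0$femur_poses[[1]],
                               js0$tibia_poses[[1]]))
})
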