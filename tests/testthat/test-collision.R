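# two tall block meshes stacked along y (long axis y), for constructed
# geometry tests; only the two horizontal sheets are meshed
make_plate <- function(y, nx = 6, nz = 6, w = 8, label = NULL, thick = 20) {
  gx <- seq(-w / 2, w / 2, length.out = nx)
  gz <- seq(-w / 2, w / 2, length.out = nz)
  top <- as.matrix(expand.grid(x = gx, y = y, z = gz))[, c("x", "y", "z")]
  bot <- top; bot[, 2] <- y + thick
  V <- rbind(top, bot)
  idx <- function(i, j) (j - 1L) * nx + i
  faces <- list()
  for (j in 1:(nz - 1)) for (i in 1:(nx - 1)) {
    a <- idx(i, j); b <- idx(i + 1, j); c_ <- idx(i, j + 1); d <- idx(i + 1, j + 1)
    faces[[length(faces) + 1]] <- c(a, b, c_)
    faces[[length(faces) + 1]] <- c(b, d, c_)
    n0 <- nx * nz
    faces[[length(faces) + 1]] <- c(a, c_, b) + n0
    faces[[length(faces) + 1]] <- c(b, c_, d) + n0
  }
  tri_mesh(V, do.call(rbind, faces), anatomy = label)
}

test_that("contact patches on stacked plates pair vertically aligned vertices", {
  femur <- make_plate(-26, label = "femur-like")  # above (y down in image)
  tibia <- make_plate(4, label = "tibia-like")    # below, top sheet at y = 4
  geom <- pair_contact_patches(femur, tibia, top_frac = 0.2,
                               max_pair_frac = 1)
  Vf <- femur$vertices; Vt <- tibia$vertices
  # every pair must be vertically aligned (same x, z)
  dxz <- Vf[geom$condyle_vertex_ids, c(1, 3), drop = FALSE] -
    Vt[geom$plateau_vertex_ids, c(1, 3), drop = FALSE]
  expect_lt(max(abs(dxz)), 1e-9)
  expect_equal(sqrt(sum(geom$bottom_plane$normal^2)), 1, tolerance = 1e-9)
  # swapping femur and tibia fails the orientation check
  expect_error(pair_contact_patches(tibia, femur), "swapped|orientation")
})

test_that("the paired-vertex test detects interpenetration with the stated tolerance", {
  femur <- make_plate(-26, label = "femur-like")
  tibia <- make_plate(4, label = "tibia-like")
  geom <- pair_contact_patches(femur, tibia, top_frac = 0.2, max_pair_frac = 1)
  # condyles 0.5 mm above the plateau (reference gap is 10 mm): separated
  expect_identical(detect_collision(geom, femur, tibia,
                                    pose(ty = 9.5), pose()), 0L)
  # condyles pushed 1 mm below the plateau: collision
  expect_identical(detect_collision(geom, femur, tibia,
                                    pose(ty = 11), pose()), 1L)
  # moving both bones rigidly together never changes the outcome
  g <- pose(12, -7, 33, 5, -4, 8)
  for (ty in c(9, 11)) {
    a <- detect_collision(geom, femur, tibia, pose(ty = ty), pose())
    b <- detect_collision(geom, femur, tibia,
                          compose_pose(g, pose(ty = ty)), compose_pose(g, pose()))
    expect_identical(a, b)
  }
  expect_identical(collision_score(0), 0)
  expect_identical(collision_score(1, 1e6), 1e6)
})

test_that("the fast test agrees with the brute-force mesh-intersection oracle", {
  femur <- make_template("femur-like", 600)
  tibia <- make_template("tibia-like", 600)
  js <- simulate_joint_sequence(femur, tibia,
                                trajectory_config(n_frames = 4,
                                                  flexion = c(0, 60)),
                                gap = 4, noise_sd = 0, seed = 5)
  geom <- pair_contact_patches(femur, tibia, js$femur_poses[[1]],
                               js$tibia_poses[[1]])
  # ground truth keeps the joint space open throughout the sweep
  H <- vapply(1:4, function(i)
    detect_collision(geom, femur, tibia, js$femur_poses[[i]],
                     js$tibia_poses[[i]]), integer(1))
  expect_identical(H, rep(0L, 4))
  set.seed(13)
  agree <- 0L
  for (k in 1:20) {
    fp <- js$femur_poses[[sample(1:4, 1)]]
    dy <- if (runif(1) < 0.5) runif(1, -8, -1) else runif(1, 6, 10)
    fp2 <- pose(fp$alpha, fp$beta, fp$gamma + runif(1, -5, 5),
                fp$tx + runif(1, -2, 2), fp$ty + dy, fp$tz + runif(1, -2, 2))
    fast <- detect_collision(geom, femur, tibia, fp2, js$tibia_poses[[1]],
                             tol = 0.1)
    slow <- as.integer(meshes_intersect(femur, tibia, fp2,
                                        js$tibia_poses[[1]], tol = -0.1))
    agree <- agree + (fast == slow)
  }
  expect_gte(agree, 19L)
})
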