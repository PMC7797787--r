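test_that("pattern search minimizes standard test functions", {
  cfg <- optimizer_config(mesh_tol = 1e-6, max_eval = 500L)
  quad <- pattern_search(function(x) (x - 2)^2, 0, step = 1, cfg = cfg)
  expect_lt(abs(quad$par - 2), 1e-4)
  expect_true(quad$converged)
  # 2-D Rosenbrock from (-1, 1)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  cfg2 <- optimizer_config(mesh_tol = 1e-9, max_eval = 5000L)
  rb <- pattern_search(rosen, c(-1, 1), step = c(0.5, 0.5), cfg = cfg2)
  expect_lt(rb$value, 1e-3)
  # constant objective returns the start after contracting to tolerance
  const <- pattern_search(function(x) 1, c(3, 4), step = 1,
                          cfg = optimizer_config(max_eval = 200))
  expect_equal(const$par, c(3, 4))
  expect_true(const$converged)
  expect_error(pattern_search(function(x) NaN, 0, 1), "finite")
  # trace of accepted values never increases
  expect_true(all(diff(rb$trace) <= 0))
})

test_that("pattern search respects bounds and is deterministic under a seed", {
  f <- function(x) sum(x^2)
  cfg <- optimizer_config(mesh_tol = 1e-4, max_eval = 300,
                          shuffle = TRUE, seed = 7L)
  a <- pattern_search(f, c(2, 3), step = 1, lower = 0.5, upper = 5, cfg = cfg)
  expect_error(pattern_search(f, c(6, 6), step = 1, lower = 0, upper = 5),
               "bounds")
  b <- pattern_search(f, c(2, 3), step = 1, lower = 0.5, upper = 5, cfg = cfg)
  expect_identical(a$par, b$par)
  expect_gte(min(a$par), 0.5)
})

test_that("stage 1 recovers perturbed poses on a noiseless frame", {
  pop <- phantom_pop_small()
  shape <- pop$shapes[[2]]
  cam <- camera_model(1000, 320 * 0.8 / 160, c(160L, 120L))
  seqn <- simulate_sequence(shape, trajectory_config(n_frames = 1,
                                                     flexion = c(30, 30)),
                            cam = cam, noise_sd = 0, seed = 3)
  tp <- seqn$true_poses[[1]]
  opt <- optimizer_config(max_eval = 220L)
  # starting at the truth stays at the truth
  s0 <- estimate_pose_stage1(seqn, shape, seqn$true_poses, opt = opt)
  pe0 <- pose_error_stats(s0$poses, seqn$true_poses)
  expect_lt(pe0["Rz", "mae"], 0.5)
  expect_lt(mean(pe0[c("Tx", "Ty"), "mae"]), 0.5)
  # in-plane perturbation of +-5 mm / +-5 deg is recovered
  init <- pose(tp$alpha, tp$beta, tp$gamma + 5, tp$tx - 5, tp$ty + 5, tp$tz)
  s1 <- estimate_pose_stage1(seqn, shape, list(init), opt = opt)
  pe <- pose_error_stats(s1$poses, seqn$true_poses)
  expect_lt(pe["Rz", "mae"], 1)
  expect_lt(mean(pe[c("Tx", "Ty"), "mae"]), 1)
  # an off-screen init names the offending frame
  bad <- pose(tp$alpha, tp$beta, tp$gamma, tp$tx + 4000, tp$ty, tp$tz)
  expect_error(estimate_pose_stage1(seqn, shape, list(bad), opt = opt),
               "frame 1")
})

test_that("stage 2 does not increase the energy from the truth's projection", {
  pop <- phantom_pop_small()
  X <- shape_mat(pop)
  hold <- 2
  model <- kpca_ssm(shape_set(pop$shapes[-hold]), m = 3)
  cam <- camera_model(1000, 320 * 0.8 / 160, c(160L, 120L))
  seqn <- simulate_sequence(pop$shapes[[hold]],
                            trajectory_config(n_frames = 1,
                                              flexion = c(20, 20)),
                            cam = cam, noise_sd = 0, seed = 3)
  th0 <- drop(predict(model, X[hold, , drop = FALSE]))
  views <- fluoroshape:::prep_views(seqn$views, energy_config())
  E0 <- fluoroshape:::candidate_energy(
    unflatten_shape(approximate_preimage(model, th0), model$faces),
    seqn$true_poses[[1]], views, 1, energy_weights(), energy_config())
  opt <- optimizer_config(max_eval = 60L, multi_start = FALSE)
  s2 <- estimate_shape_stage2(seqn, seqn$true_poses, model, th0, opt = opt)
  expect_lte(s2$value, E0 + 1e-12)
  # a model cannot be requested with zero components
  expect_error(kpca_ssm(shape_set(pop$shapes[-hold]), m = 0), "out of range")
})
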