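#' Optimizer configuration
#'
#' Settings of the generalized pattern-search minimizer and of the outer
#' alternation between pose and shape stages.  Step sizes are expressed as
#' a per-parameter scale vector times a global mesh multiplier that starts
#' at 1, doubles on success (capped), halves on failure, and terminates the
#' search when it falls below `mesh_tol`.
#'
#' @param pose_step initial step sizes for the six pose parameters
#'   (deg, deg, deg, mm, mm, mm).
#' @param theta_step_frac initial shape step as a fraction of the
#'   per-component training spread.
#' @param contraction,expansion mesh contraction/expansion factors.
#' @param mesh_max upper cap of the mesh multiplier; the default of 1
#'   disables expansion (pure contracting search), which proved far more
#'   reliable on the plateau-like similarity landscape than aggressive
#'   expansion.
#' @param mesh_tol termination threshold of the mesh multiplier.
#' @param max_eval function-evaluation budget per pattern-search call.
#' @param pose_box half-widths of the pose search box around the
#'   starting point (deg, deg, deg, mm, mm, mm); the wide `tz` entry
#'   reflects the weak observability of out-of-plane translation in a
#'   single view.
#' @param theta_bound_sd shape-parameter box half-width in training-sd
#'   units.
#' @param max_alternations maximum outer pose/shape alternations.
#' @param outer_tol outer convergence tolerance on the total-energy drop.
#' @param shape_frames use every k-th frame in the shape stage (default
#'   every frame).
#' @param joint_refine after each shape stage, refine the shape
#'   parameters jointly with one shared bone-frame pose offset applied to
#'   all frames.  Shape modes that resemble a rigid motion (an axial
#'   torsion is locally close to a rotation) make the alternating scheme
#'   converge to a biased pose/shape pair; the joint move crosses that
#'   ravine.
#' @param coarse_offsets offsets of the coarse per-frame grid search over
#'   flexion and in-plane translation run before the pattern search in
#'   the pose stage (`gamma` in degrees, `txy` in mm); guards against
#'   per-frame local minima when the initial pose is several degrees or
#'   millimetres off.  Set entries to `0` to disable.
#' @param multi_start start the shape stage from the feature-space mean
#'   *and* from each morphotype centroid of the training projections
#'   (2-means), keeping the best result.  In clustered populations the
#'   mean lies in the inter-cluster gap, where the preimage is poorly
#'   conditioned and the energy has a spurious local minimum.
#' @param shuffle randomize the polling order (seeded); default is the
#'   deterministic coordinate order.
#' @param seed RNG seed for the optional polling shuffle.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(pose_step = c(2, 2, 2, 2, 2, 2),
                             theta_step_frac = 0.5,
                             contraction = 0.5, expansion = 2,
                             mesh_max = 1, mesh_tol = 0.05,
                             max_eval = 300L,
                             pose_box = c(15, 15, 25, 20, 20, 60),
                             theta_bound_sd = 3,
                             max_alternations = 3L,
                             outer_tol = 1e-3,
                             shape_frames = 1L,
                             joint_refine = TRUE,
                             coarse_offsets = list(gamma = c(-6, -3, 0, 3, 6),
                                                   txy = c(-3, 0, 3)),
                             multi_start = TRUE,
                             shuffle = FALSE, seed = NULL) {
  stopifnot(all(pose_step > 0), contraction > 0, contraction < 1,
            expansion > 1, mesh_tol > 0, max_eval >= 1,
            length(pose_box) == 6L, all(pose_box > 0))
  structure(list(pose_step = pose_step,
                 theta_step_frac = theta_step_frac,
                 contraction = contraction, expansion = expansion,
                 mesh_max = mesh_max, mesh_tol = mesh_tol,
                 max_eval = as.integer(max_eval),
                 pose_box = pose_box,
                 theta_bound_sd = theta_bound_sd,
                 max_alternations = as.integer(max_alternations),
                 outer_tol = outer_tol,
                 shape_frames = as.integer(shape_frames),
                 joint_refine = isTRUE(joint_refine),
                 coarse_offsets = coarse_offsets,
                 multi_start = isTRUE(multi_start),
                 shuffle = isTRUE(shuffle), seed = seed),
            class = "optimizer_config")
}

#' Generalized pattern-search minimization
#'
#' Derivative-free coordinate-poll pattern search: at each iteration the
#' objective is compared over trial points `x +/- mesh * step_i * e_i`;
#' the first improving point is accepted and the mesh expands, otherwise
#' the mesh contracts.  Applicable to non-smooth objectives; deterministic
#' given the seed.
#'
#' @param f objective function of a numeric vector; must be finite at
#'   `x0`.
#' @param x0 starting point.
#' @param step per-parameter initial step sizes (same length as `x0`).
#' @param lower,upper box bounds (recycled scalars allowed).
#' @param cfg an [optimizer_config] (controls contraction/expansion,
#'   budget, termination and polling order).
#' @param poll_order integer permutation fixing the coordinate polling
#'   order (default: natural order).
#' @return List with `par`, `value`, `trace` (accepted objective values),
#'   `evals` and `converged`.
#' @export
pattern_search <- function(f, x0, step, lower = -Inf, upper = Inf,
                           cfg = optimizer_config(), poll_order = NULL) {
  x <- as.numeric(x0)
  d <- length(x)
  step <- rep_len(as.numeric(step), d)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(x < lower | x > upper)) stop("x0 outside bounds")
  fx <- f(x)
  if (!is.finite(fx)) stop("objective not finite at the starting point")
  evals <- 1L
  mesh <- 1
  trace <- fx
  order_base <- poll_order %||% seq_len(d)
  repeat {
    if (mesh < cfg$mesh_tol || evals >= cfg$max_eval) break
    improved <- FALSE
    ord <- if (cfg$shuffle) with_seed(cfg$seed %||% 0L + evals,
                                      sample(order_base)) else order_base
    for (i in ord) {
      for (s in c(1, -1)) {
        xt <- x
        xt[i] <- min(max(x[i] + s * mesh * step[i], lower[i]), upper[i])
        if (xt[i] == x[i]) next
        ft <- f(xt)
        evals <- evals + 1L
        if (is.finite(ft) && ft < fx) {
          x <- xt; fx <- ft
          trace <- c(trace, fx)
          improved <- TRUE
          break
        }
        if (evals >= cfg$max_eval) break
      }
      if (improved || evals >= cfg$max_eval) break
    }
    mesh <- if (improved) min(mesh * cfg$expansion, cfg$mesh_max)
            else mesh * cfg$contraction
  }
  list(par = x, value = fx, trace = trace, evals = evals,
       converged = mesh < cfg$mesh_tol)
}

#' A projection view: camera, frames and view transform
#'
#' A view bundles the frames observed by one camera together with the
#' rigid transform mapping world coordinates (the first camera's frame)
#' into this camera's frame.  Single-plane sequences use one view with the
#' identity transform; a biplane setup adds an orthogonal second view.
#'
#' @param cam a [camera_model].
#' @param frames list of [fluoro_frame] objects.
#' @param view_pose a [pose6] mapping world to this camera's coordinates.
#' @return An object of class `fluoro_view`.
#' @export
fluoro_view <- function(cam, frames, view_pose = pose()) {
  stopifnot(inherits(cam, "camera_model"),
            all(vapply(frames, inherits, logical(1), "fluoro_frame")))
  structure(list(camera = cam, frames = frames, view_pose = view_pose),
            class = "fluoro_view")
}

as_views <- function(x) {
  if (inherits(x, "fluoro_view")) return(list(x))
  if (inherits(x, "synthetic_sequence")) return(x$views)
  if (is.list(x) && length(x) && inherits(x[[1]], "fluoro_frame"))
    return(list(fluoro_view(x[[1]]$camera, x)))
  if (is.list(x) && length(x) && inherits(x[[1]], "fluoro_view"))
    return(x)
  stop("cannot interpret frames/views argument")
}

render_in_view <- function(mesh, p, view) {
  render_model_image(mesh, compose_pose(view$view_pose, p), view$camera)
}

# attach the tolerance-dilated observed edge image to every frame so the
# optimization loop does not redo the dilation per candidate
prep_views <- function(views, ecfg) {
  if (isTRUE(attr(views, "prepped"))) return(views)
  out <- lapply(views, function(v) {
    v$frames <- lapply(v$frames, function(fr) {
      C1 <- fr$edge_image
      for (i in seq_len(ecfg$edge_tol_px)) C1 <- dilate8(C1)
      fr$edge_dil <- C1
      fr
    })
    v
  })
  attr(out, "prepped") <- TRUE
  out
}

# poll the observable degrees of freedom first: flexion and the in-plane
# translations carry most of the single-view signal
POSE_POLL_ORDER <- c(3L, 4L, 5L, 6L, 1L, 2L)

# total candidate energy of pose p for frame index i across views
candidate_energy <- function(mesh, p, views, i, weights, ecfg,
                             other_sil = NULL, H1 = 0) {
  E <- 0
  for (v in seq_along(views)) {
    r <- tryCatch(render_in_view(mesh, p, views[[v]]),
                  error = function(e) NULL)
    if (is.null(r)) return(Inf)
    os <- if (is.null(other_sil)) NULL else other_sil[[v]][[i]]
    E <- E + frame_energy(views[[v]]$frames[[i]], r, weights, ecfg,
                          other_silhouette = os, collision = H1)$E
  }
  E
}

#' Stage 1: per-frame rigid pose estimation with a fixed shape
#'
#' Minimizes the hybrid energy over the six pose parameters for each
#' frame while the shape is held fixed; when a single initial pose is
#' given, each subsequent frame is initialized from the previous frame's
#' solution.
#'
#' @param views frames to fit: a [fluoro_view], list of views, list of
#'   frames, or a `synthetic_sequence`.
#' @param mesh the fixed candidate shape ([tri_mesh]).
#' @param init_poses a single [pose6] or a list of per-frame poses.
#' @param weights an [energy_weights].
#' @param opt an [optimizer_config].
#' @param ecfg an [energy_config].
#' @param other_sil optional per-view list of per-frame neighboring-bone
#'   silhouettes (masks).
#' @param collision_fn optional function `(pose) -> {0, 1}` giving the
#'   collision indicator of a candidate pose.
#' @return List with `poses` (per frame), `energies` and `evals`.
#' @export
estimate_pose_stage1 <- function(views, mesh, init_poses,
                                 weights = energy_weights(),
                                 opt = optimizer_config(),
                                 ecfg = energy_config(),
                                 other_sil = NULL, collision_fn = NULL) {
  views <- prep_views(as_views(views), ecfg)
  nF <- length(views[[1]]$frames)
  single_init <- inherits(init_poses, "pose6")
  if (!single_init && length(init_poses) != nF)
    stop("init_poses must be one pose or one per frame")
  poses <- vector("list", nF)
  energies <- numeric(nF)
  evals <- 0L
  prev <- NULL
  for (i in seq_len(nF)) {
    p0 <- if (single_init) (prev %||% init_poses) else init_poses[[i]]
    r0 <- tryCatch(render_in_view(mesh, p0, views[[1]]),
                   error = function(e) NULL)
    if (is.null(r0) || r0$empty)
      stop(sprintf("empty silhouette at the initial pose of frame %d", i))
    obj <- function(pv) {
      p <- pose_from_vector(pv)
      H1 <- if (is.null(collision_fn)) 0 else collision_fn(p)
      candidate_energy(mesh, p, views, i, weights, ecfg, other_sil, H1)
    }
    x0 <- pose_to_vector(p0)
    co <- opt$coarse_offsets
    if (!is.null(co) && (length(co$gamma) > 1L || length(co$txy) > 1L)) {
      # coarse flexion / in-plane grid around the init
      bestx <- x0; bestf <- obj(x0); evals <- evals + 1L
      for (dg in co$gamma) for (dx in co$txy) for (dy in co$txy) {
        if (dg == 0 && dx == 0 && dy == 0) next
        xt <- x0 + c(0, 0, dg, dx, dy, 0)
        ft <- obj(xt)
        evals <- evals + 1L
        if (is.finite(ft) && ft < bestf) { bestf <- ft; bestx <- xt }
      }
      x0 <- bestx
    }
    ps <- pattern_search(obj, x0, opt$pose_step,
                         lower = x0 - opt$pose_box,
                         upper = x0 + opt$pose_box,
                         cfg = opt, poll_order = POSE_POLL_ORDER)
    poses[[i]] <- pose_from_vector(ps$par)
    energies[i] <- ps$value
    evals <- evals + ps$evals
    prev <- poses[[i]]
  }
  list(poses = poses, energies = energies, evals = evals)
}

theta_sd <- function(model) sqrt(pmax(nrow(model$training_vectors) *
                                        model$lambdas, 1e-12))

#' Stage 2: shape estimation with fixed per-frame poses
#'
#' Minimizes the sum of per-frame hybrid energies over the shape
#' parameters `theta`; the preimage is evaluated once per candidate and
#' rendered into every (subsampled) frame.  `theta` is box-bounded to
#' +/- `theta_bound_sd` training standard deviations per component.
#'
#' @inheritParams estimate_pose_stage1
#' @param poses fixed per-frame poses from stage 1.
#' @param model a [kpca_ssm].
#' @param theta0 starting shape parameters (default: the zero vector, the
#'   feature-space mean).
#' @param n_neighbors preimage neighborhood size.
#' @return List with `theta`, `value` (total energy) and `evals`.
#' @export
estimate_shape_stage2 <- function(views, poses, model, theta0 = NULL,
                                  weights = energy_weights(),
                                  opt = optimizer_config(),
                                  ecfg = energy_config(),
                                  other_sil = NULL, collision_fn = NULL,
                                  n_neighbors = 10L) {
  views <- prep_views(as_views(views), ecfg)
  n_neighbors <- min(n_neighbors, nrow(model$training_vectors))
  if (model$m < 1L) stop("model must retain at least one component")
  theta0 <- theta0 %||% rep(0, model$m)
  sds <- theta_sd(model)
  frame_idx <- seq(1L, length(poses), by = opt$shape_frames)
  obj <- function(theta) {
    v <- tryCatch(approximate_preimage(model, theta,
                                       n_neighbors = n_neighbors),
                  error = function(e) NULL)
    if (is.null(v)) return(Inf)   # degenerate preimage: reject candidate
    mesh <- unflatten_shape(v, model$faces)
    E <- 0
    for (i in frame_idx) {
      H1 <- if (is.null(collision_fn)) 0 else collision_fn(mesh, poses[[i]], i)
      E <- E + candidate_energy(mesh, poses[[i]], views, i, weights, ecfg,
                                other_sil, H1)
    }
    E
  }
  starts <- list(theta0)
  if (opt$multi_start) {
    km <- with_seed(91L, stats::kmeans(model$theta_train, centers = 2L,
                                       nstart = 5L))
    starts <- c(starts, lapply(1:2, function(k)
      pmin(pmax(km$centers[k, ], -opt$theta_bound_sd * sds),
           opt$theta_bound_sd * sds)))
  }
  budget <- max(20L, opt$max_eval %/% length(starts))
  opt_s <- opt; opt_s$max_eval <- budget
  best <- NULL
  evals <- 0L
  for (s0 in starts) {
    ps <- pattern_search(obj, s0, opt$theta_step_frac * sds,
                         lower = -opt$theta_bound_sd * sds,
                         upper = opt$theta_bound_sd * sds, cfg = opt_s)
    evals <- evals + ps$evals
    if (is.null(best) || ps$value < best$value) best <- ps
  }
  list(theta = best$par, value = best$value, evals = evals)
}

# joint refinement over (theta, one shared bone-frame pose offset):
# crosses the ravine between rotation-like shape modes and the rigid
# pose.  Seeded from the current theta and from each morphotype centroid
# of the training projections — from a centroid seed the shared offset
# coordinate immediately absorbs the pose bias that otherwise makes the
# centroid look poor, which plain alternation can never discover.
refine_joint <- function(views, poses, model, theta, weights, opt, ecfg,
                         n_neighbors) {
  m <- model$m
  sds <- theta_sd(model)
  frame_idx <- seq(1L, length(poses), by = opt$shape_frames)
  obj <- function(x) {
    th <- x[seq_len(m)]
    dp <- pose_from_vector(x[m + 1:6])
    v <- tryCatch(approximate_preimage(model, th,
                                       n_neighbors = n_neighbors),
                  error = function(e) NULL)
    if (is.null(v)) return(Inf)
    mesh <- unflatten_shape(v, model$faces)
    E <- 0
    for (i in frame_idx)
      E <- E + candidate_energy(mesh, compose_pose(poses[[i]], dp), views,
                                i, weights, ecfg)
    E
  }
  starts <- list(theta)
  if (opt$multi_start) {
    km <- with_seed(91L, stats::kmeans(model$theta_train, centers = 2L,
                                       nstart = 5L))
    starts <- c(starts, lapply(1:2, function(k)
      pmin(pmax(km$centers[k, ], -opt$theta_bound_sd * sds),
           opt$theta_bound_sd * sds)))
  }
  opt_s <- opt
  opt_s$max_eval <- max(30L, opt$max_eval %/% length(starts))
  best <- NULL
  evals <- 0L
  for (s0 in starts) {
    ps <- pattern_search(obj, c(s0, rep(0, 6)),
                         c(opt$theta_step_frac * sds, opt$pose_step),
                         lower = c(-opt$theta_bound_sd * sds, -opt$pose_box / 2),
                         upper = c(opt$theta_bound_sd * sds, opt$pose_box / 2),
                         cfg = opt_s)
    evals <- evals + ps$evals
    if (is.null(best) || ps$value < best$value) best <- ps
  }
  dp <- pose_from_vector(best$par[m + 1:6])
  list(theta = best$par[seq_len(m)],
       poses = lapply(poses, compose_pose, inner = dp),
       value = best$value, evals = evals)
}

#' Reconstruct shape and per-frame pose from a projection sequence
#'
#' The full two-stage alternating scheme: stage 1 rigidly aligns the
#' current shape estimate (initially the model mean, `theta = 0`) to every
#' frame; stage 2 optimizes one shared shape over all frames with poses
#' fixed; the stages alternate until the total energy stops improving or
#' the alternation budget is exhausted.  Multiple views are fitted
#' jointly by summing their energies.
#'
#' @param model a [kpca_ssm].
#' @param views a [fluoro_view], list of views, list of frames, or a
#'   `synthetic_sequence`.
#' @param init a single initial [pose6] or a per-frame list.
#' @param weights an [energy_weights].
#' @param opt an [optimizer_config].
#' @param ecfg an [energy_config].
#' @param n_neighbors preimage neighborhood size.
#' @return An object of class `sequence_fit`: `theta`, `poses`,
#'   `energy_trace` (outer alternations), per-frame `energies`,
#'   `converged`, and the reconstructed `mesh`.
#' @export
reconstruct_sequence <- function(model, views, init,
                                 weights = energy_weights(),
                                 opt = optimizer_config(),
                                 ecfg = energy_config(),
                                 n_neighbors = 10L) {
  views <- prep_views(as_views(views), ecfg)
  n_neighbors <- min(n_neighbors, nrow(model$training_vectors))
  theta <- rep(0, model$m)
  if (opt$multi_start) {
    # basin selection: clustered populations put the model mean in the
    # inter-cluster gap, so the morphotype centroids are tried as
    # alternative starting shapes, each scored by rigidly fitting a
    # small frame subset
    km <- with_seed(91L, stats::kmeans(model$theta_train, centers = 2L,
                                       nstart = 5L))
    cand <- list(theta, km$centers[1, ], km$centers[2, ])
    nF <- length(views[[1]]$frames)
    sub <- unique(round(seq(1L, nF, length.out = min(3L, nF))))
    sub_views <- lapply(views, function(v) {
      v$frames <- v$frames[sub]; v
    })
    attr(sub_views, "prepped") <- TRUE
    sub_init <- if (inherits(init, "pose6")) init else init[sub]
    scores <- vapply(cand, function(th) {
      msh <- unflatten_shape(approximate_preimage(model, th,
                                                  n_neighbors = n_neighbors),
                             model$faces)
      s <- tryCatch(estimate_pose_stage1(sub_views, msh, sub_init,
                                         weights, opt, ecfg),
                    error = function(e) NULL)
      if (is.null(s)) Inf else sum(s$energies)
    }, numeric(1))
    theta <- cand[[which.min(scores)]]
  }
  mesh <- unflatten_shape(approximate_preimage(model, theta,
                                               n_neighbors = n_neighbors),
                          model$faces)
  poses <- init
  trace <- numeric(0)
  best <- Inf
  converged <- FALSE
  for (it in seq_len(opt$max_alternations)) {
    s1 <- estimate_pose_stage1(views, mesh, poses, weights, opt, ecfg)
    poses <- s1$poses
    s2 <- estimate_shape_stage2(views, poses, model, theta, weights, opt,
                                ecfg, n_neighbors = n_neighbors)
    theta <- s2$theta
    value <- s2$value
    if (opt$joint_refine) {
      jr <- refine_joint(views, poses, model, theta, weights, opt, ecfg,
                         n_neighbors)
      theta <- jr$theta
      poses <- jr$poses
      value <- jr$value
    }
    mesh <- unflatten_shape(approximate_preimage(model, theta,
                                                 n_neighbors = n_neighbors),
                            model$faces)
    trace <- c(trace, value)
    if (is.finite(best) && best - value < opt$outer_tol) {
      converged <- TRUE
      best <- min(best, value)
      break
    }
    best <- value
  }
  # final pose polish with the final shape
  s1 <- estimate_pose_stage1(views, mesh, poses, weights, opt, ecfg)
  structure(list(theta = theta, poses = s1$poses,
                 energies = s1$energies, energy_trace = trace,
                 converged = converged, mesh = mesh, model = model),
            class = "sequence_fit")
}

#' @export
print.sequence_fit <- function(x, ...) {
  cat(sprintf("sequence_fit: %d frames, m = %d shape parameters, total E = %.4g%s\n",
              length(x$poses), length(x$theta), sum(x$energies),
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.sequence_fit <- function(object, ...) {
  print(object)
  cat("theta:", paste(signif(object$theta, 4), collapse = " "), "\n")
  pm <- t(vapply(object$poses, pose_to_vector, numeric(6)))
  colnames(pm) <- c("alpha", "beta", "gamma", "tx", "ty", "tz")
  cat("per-frame poses:\n")
  print(round(pm, 3))
  invisible(object)
}

#' @export
coef.sequence_fit <- function(object, ...) {
  pm <- t(vapply(object$poses, pose_to_vector, numeric(6)))
  colnames(pm) <- c("alpha", "beta", "gamma", "tx", "ty", "tz")
  list(theta = object$theta, poses = pm)
}

#' Joint multi-body reconstruction of femur and tibia
#'
#' Round-robin extension of [reconstruct_sequence] for two articulating
#' bones: in every alternation each bone's pose and shape are optimized
#' with the *other* bone's current silhouette masking its edge/region
#' scores and the paired-patch collision penalty discouraging
#' interpenetration.
#'
#' @param femur_model,tibia_model [kpca_ssm] models of the two bones.
#' @param views shared views (each frame shows both bones).
#' @param init_femur,init_tibia initial per-frame poses (or single poses).
#' @param geom optional precomputed [pair_contact_patches] geometry;
#'   built from the model mean shapes at the frame-1 initial poses when
#'   `NULL`.
#' @param weights,opt,ecfg,n_neighbors as in [reconstruct_sequence].
#' @param collision_tol contact tolerance (mm).
#' @return Named list of two `sequence_fit` objects (`femur`, `tibia`)
#'   plus the collision `geom` and per-frame final `H1` indicators.
#' @export
reconstruct_joint <- function(femur_model, tibia_model, views,
                              init_femur, init_tibia, geom = NULL,
                              weights = energy_weights(),
                              opt = optimizer_config(),
                              ecfg = energy_config(),
                              n_neighbors = 10L, collision_tol = 0.1) {
  views <- prep_views(as_views(views), ecfg)
  n_neighbors <- min(n_neighbors, nrow(femur_model$training_vectors),
                     nrow(tibia_model$training_vectors))
  nF <- length(views[[1]]$frames)
  expand_init <- function(init) {
    if (inherits(init, "pose6")) rep(list(init), nF) else init
  }
  state <- list(
    femur = list(model = femur_model, theta = rep(0, femur_model$m),
                 poses = expand_init(init_femur)),
    tibia = list(model = tibia_model, theta = rep(0, tibia_model$m),
                 poses = expand_init(init_tibia)))
  for (b in names(state))
    state[[b]]$mesh <- unflatten_shape(
      approximate_preimage(state[[b]]$model, state[[b]]$theta,
                           n_neighbors = n_neighbors),
      state[[b]]$model$faces)
  if (is.null(geom))
    geom <- pair_contact_patches(state$femur$mesh, state$tibia$mesh,
                                 state$femur$poses[[1]],
                                 state$tibia$poses[[1]])
  other <- c(femur = "tibia", tibia = "femur")
  sil_of <- function(b) {
    lapply(views, function(v)
      lapply(seq_len(nF), function(i)
        tryCatch(render_in_view(state[[b]]$mesh, state[[b]]$poses[[i]],
                                v)$silhouette,
                 error = function(e) NULL)))
  }
  trace <- list(femur = numeric(0), tibia = numeric(0))
  for (it in seq_len(opt$max_alternations)) {
    for (b in names(state)) {
      o <- other[[b]]
      os <- sil_of(o)
      # per-frame collision compares against the other bone in the same
      # frame, so stage 1 is unrolled here with a per-frame closure
      s1poses <- vector("list", nF)
      energies <- numeric(nF)
      for (i in seq_len(nF)) {
        obj <- function(pv) {
          p <- pose_from_vector(pv)
          H1 <- if (b == "femur")
            detect_collision(geom, state$femur$mesh, state$tibia$mesh,
                             p, state$tibia$poses[[i]], collision_tol)
          else
            detect_collision(geom, state$femur$mesh, state$tibia$mesh,
                             state$femur$poses[[i]], p, collision_tol)
          candidate_energy(state[[b]]$mesh, p, views, i, weights, ecfg,
                           os, H1)
        }
        x0 <- pose_to_vector(state[[b]]$poses[[i]])
        ps <- pattern_search(obj, x0, opt$pose_step,
                             lower = x0 - opt$pose_box,
                             upper = x0 + opt$pose_box,
                             cfg = opt, poll_order = POSE_POLL_ORDER)
        s1poses[[i]] <- pose_from_vector(ps$par)
        energies[i] <- ps$value
      }
      state[[b]]$poses <- s1poses
      cfn_shape <- local({
        bb <- b
        function(mesh, p, i) {
          if (bb == "femur")
            detect_collision(geom, mesh, state$tibia$mesh,
                             p, state$tibia$poses[[i]], collision_tol)
          else
            detect_collision(geom, state$femur$mesh, mesh,
                             state$femur$poses[[i]], p, collision_tol)
        }
      })
      s2 <- estimate_shape_stage2(views, state[[b]]$poses, state[[b]]$model,
                                  state[[b]]$theta, weights, opt, ecfg,
                                  other_sil = os, collision_fn = cfn_shape,
                                  n_neighbors = n_neighbors)
      state[[b]]$theta <- s2$theta
      state[[b]]$mesh <- unflatten_shape(
        approximate_preimage(state[[b]]$model, s2$theta,
                             n_neighbors = n_neighbors),
        state[[b]]$model$faces)
      trace[[b]] <- c(trace[[b]], s2$value)
    }
  }
  H1_final <- vapply(seq_len(nF), function(i)
    detect_collision(geom, state$femur$mesh, state$tibia$mesh,
                     state$femur$poses[[i]], state$tibia$poses[[i]],
                     collision_tol), integer(1))
  fits <- lapply(names(state), function(b)
    structure(list(theta = state[[b]]$theta, poses = state[[b]]$poses,
                   energies = rep(NA_real_, nF),
                   energy_trace = trace[[b]],
                   converged = TRUE, mesh = state[[b]]$mesh,
                   model = state[[b]]$model), class = "sequence_fit"))
  names(fits) <- names(state)
  c(fits, list(geom = geom, H1 = H1_final))
}

#' Plot a sequence fit: energy trace and flexion curve
#'
#' @param x a `sequence_fit`.
#' @param ... unused.
#' @export
plot.sequence_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$energy_trace), x$energy_trace, type = "b",
                 pch = 16, xlab = "alternation", ylab = "total energy")
  gamma <- vapply(x$poses, function(p) p$gamma, numeric(1))
  graphics::plot(seq_along(gamma), gamma, type = "b", pch = 16,
                 xlab = "frame", ylab = "flexion (deg)")
  invisible(x)
}
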