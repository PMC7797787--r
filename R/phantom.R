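# ---- stylized bone templates ----------------------------------------------

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Stylized bone template mesh
#'
#' Builds a watertight, consistently outward-wound, fixed-topology
#' triangle mesh emulating a distal femur (shaft plus two condylar
#' bulges) or a proximal tibia (shaft plus a widened plateau rim).  The
#' mesh is a deformed latitude-longitude sphere, star-shaped about the
#' origin, with the long axis along y; the articulating end (femoral
#' condyles / tibial plateau) points along `+y` for the femur and `-y`
#' for the tibia so that a knee scene stacks naturally in image
#' coordinates (y down).
#'
#' @param kind `"femur-like"` or `"tibia-like"`.
#' @param resolution requested vertex count, 300-2000.
#' @param scale characteristic half-length (mm); default 60.
#' @return A [tri_mesh] carrying the `anatomy` label.
#' @export
make_template <- function(kind = c("femur-like", "tibia-like"),
                          resolution = 800L, scale = 60) {
  kind <- match.arg(kind)
  resolution <- as.integer(resolution)
  if (resolution < 300L || resolution > 2000L)
    stop("resolution out of the supported 300-2000 vertex range")
  n_u <- max(8L, round(sqrt(resolution)))
  n_v <- max(6L, round((resolution - 2L) / n_u))
  phi <- 2 * pi * (seq_len(n_u) - 1L) / n_u
  theta <- pi * seq_len(n_v) / (n_v + 1L)
  grid <- expand.grid(phi = phi, theta = theta)
  # unit directions; latitude measured from +y (articulating end of the
  # femur template), so theta = 0 is +y and theta = pi is -y
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                cos(grid$theta),
                sin(grid$theta) * sin(grid$phi))
  dirs <- rbind(c(0, 1, 0), dirs, c(0, -1, 0))
  rho <- template_radius(dirs, kind, scale)
  V <- dirs * rho
  F <- lonlat_faces(n_u, n_v)
  m <- tri_mesh(V, F, anatomy = kind)
  orient_outward(m)
}

template_radius <- function(dirs, kind, scale) {
  angle_to <- function(d) {
    dn <- d / sqrt(sum(d^2))
    acos(pmin(pmax(dirs %*% dn, -1), 1))
  }
  if (kind == "femur-like") {
    a <- scale * c(0.24, 0.50, 0.24)
    rho <- 1 / sqrt((dirs[, 1] / a[1])^2 + (dirs[, 2] / a[2])^2 +
                      (dirs[, 3] / a[3])^2)
    # two condylar bulges at the +y (distal-in-image) end, offset in +/-x
    for (sx in c(1, -1)) {
      psi <- angle_to(c(sx * 0.50, 1, 0.35))
      rho <- rho + 0.13 * scale * exp(-psi^2 / (2 * 0.45^2))
    }
  } else {
    a <- scale * c(0.22, 0.46, 0.22)
    rho <- 1 / sqrt((dirs[, 1] / a[1])^2 + (dirs[, 2] / a[2])^2 +
                      (dirs[, 3] / a[3])^2)
    # widened plateau rim near the -y (up-in-image) end
    psi_top <- acos(pmin(pmax(-dirs[, 2], -1), 1))
    rho <- rho * (1 + 0.40 * exp(-(psi_top - 0.55)^2 / (2 * 0.35^2)))
  }
  as.numeric(rho)
}

lonlat_faces <- function(n_u, n_v) {
  idx <- function(i, j) 1L + (j - 1L) * n_u + (i %% n_u) + 1L  # 1-based
  faces <- list()
  top <- 1L
  bottom <- n_u * n_v + 2L
  for (i in 0:(n_u - 1L))
    faces[[length(faces) + 1L]] <- c(top, idx(i, 1L), idx(i + 1L, 1L))
  for (j in 1:(n_v - 1L))
    for (i in 0:(n_u - 1L)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c_ <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(b, c_, d)
    }
  for (i in 0:(n_u - 1L))
    faces[[length(faces) + 1L]] <- c(bottom, idx(i + 1L, n_v), idx(i, n_v))
  do.call(rbind, faces)
}

# flip winding if the enclosed signed volume is negative
orient_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], ]; v2 <- V[F[, 2], ]; v3 <- V[F[, 3], ]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
               v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
               v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  if (vol < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

# ---- shape population ------------------------------------------------------

#' Phantom population configuration
#'
#' Parameters of the synthetic corresponded shape population.  Shapes are
#' organized along a single bimodal morphotype axis: the two clusters sit
#' at latent values -1 and +1 (within-cluster spread `morph_sd`), and the
#' latent drives three coupled anatomical features — a mirrored condylar
#' asymmetry, an axial torsion of the articulating end, and a localized
#' condylar ridge whose azimuth migrates around the bone.  The migrating
#' ridge and the torsion are trigonometric in the latent, so the
#' population lies on a genuinely curved (nonlinear, non-Gaussian,
#' two-cluster) manifold, which is the regime that motivates a kernel
#' shape model.  Smaller independent factors (shaft bow, width/depth
#' scaling, low-frequency displacement patterns shared across the
#' population) and a small iid vertex jitter emulate residual atlas
#' variation and correspondence noise.
#'
#' @param n_shapes population size, `>= 4`.
#' @param cluster_fraction fraction of shapes in the first morphotype
#'   cluster, in (0, 1).
#' @param scale characteristic bone half-length (mm).
#' @param kind template kind, `"femur-like"` or `"tibia-like"`.
#' @param resolution template vertex count.
#' @param morph_sd within-cluster sd of the morphotype latent (cluster
#'   centers at -1 and +1).
#' @param condyle_ratio_amp condyle-asymmetry amplitude per unit latent
#'   (fractional radial scaling; mirrored between the clusters).
#' @param twist_gain axial torsion (degrees) per unit latent.
#' @param ridge_amp amplitude (mm) of the localized condylar ridge.
#' @param ridge_migration azimuthal migration of the ridge (degrees per
#'   unit latent).
#' @param ridge_width angular width (radians) of the ridge bump.
#' @param shaft_bow_amp shaft bowing sd (mm).
#' @param width_scale_sd,depth_scale_sd log-sd of global width/depth
#'   scaling.
#' @param sine_amp per-axis amplitude sd (mm) of the low-frequency
#'   displacement patterns; the spatial patterns are shared by the whole
#'   population (drawn once per seed) and only their amplitudes vary per
#'   shape.
#' @param noise_sd iid vertex (correspondence) noise sd (mm).
#' @param seed RNG seed; populations are deterministic per seed.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_shapes = 40L, cluster_fraction = 0.5,
                           scale = 60, kind = "femur-like",
                           resolution = 800L,
                           morph_sd = 0.35,
                           condyle_ratio_amp = 0.10,
                           twist_gain = 10,
                           ridge_amp = 7, ridge_migration = 60,
                           ridge_width = 0.35,
                           shaft_bow_amp = 1,
                           width_scale_sd = 0.03, depth_scale_sd = 0.03,
                           sine_amp = 0.5, noise_sd = 0.1, seed = 1L) {
  n_shapes <- as.integer(n_shapes)
  if (n_shapes < 4L) stop("n_shapes must be >= 4")
  if (cluster_fraction <= 0 || cluster_fraction >= 1)
    stop("cluster_fraction must be in (0, 1)")
  amps <- c(morph_sd, condyle_ratio_amp, twist_gain, ridge_amp,
            ridge_width, shaft_bow_amp, width_scale_sd,
            depth_scale_sd, sine_amp, noise_sd)
  if (any(amps < 0)) stop("amplitudes must be nonnegative")
  structure(list(n_shapes = n_shapes, cluster_fraction = cluster_fraction,
                 scale = scale, kind = kind,
                 resolution = as.integer(resolution),
                 morph_sd = morph_sd,
                 condyle_ratio_amp = condyle_ratio_amp,
                 twist_gain = twist_gain,
                 ridge_amp = ridge_amp,
                 ridge_migration = ridge_migration,
                 ridge_width = ridge_width,
                 shaft_bow_amp = shaft_bow_amp,
                 width_scale_sd = width_scale_sd,
                 depth_scale_sd = depth_scale_sd,
                 sine_amp = sine_amp, noise_sd = noise_sd,
                 seed = seed), class = "phantom_config")
}

#' Sample a synthetic corresponded shape population
#'
#' Deforms the shared template with per-shape smooth fields driven by the
#' bimodal morphotype latent (mirrored condylar asymmetry, axial torsion,
#' migrating condylar ridge) plus independent shaft bowing, width/depth
#' scaling, population-shared low-frequency displacement patterns and
#' small iid vertex noise.  All shapes share the template topology
#' exactly.
#'
#' @param cfg a [phantom_config].
#' @return A [shape_set] with attribute `cluster` (per-shape cluster
#'   labels 1/2).
#' @export
sample_population <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  template <- make_template(cfg$kind, cfg$resolution, cfg$scale)
  V0 <- template$vertices
  distal_sign <- if (cfg$kind == "femur-like") 1 else -1
  n1 <- ceiling(cfg$cluster_fraction * cfg$n_shapes)
  clusters <- rep(c(1L, 2L), c(n1, cfg$n_shapes - n1))
  with_seed(cfg$seed, {
    # population-shared sinusoidal displacement patterns (one per axis)
    patterns <- lapply(1:3, function(d) {
      k <- rnorm(3); k <- k / sqrt(sum(k^2))
      list(k = k, lambda = runif(1, 0.8, 1.6) * cfg$scale,
           phase = runif(1, 0, 2 * pi))
    })
    shapes <- vector("list", cfg$n_shapes)
    for (s in seq_len(cfg$n_shapes)) {
      for (try in 1:5) {
        V <- deform_template(V0, cfg, distal_sign,
                             sign = c(1, -1)[clusters[s]], patterns)
        ok <- all(is.finite(V)) &&
          min(sqrt(rowSums(V^2))) > 0.05 * cfg$scale
        if (ok) break
      }
      if (!ok) stop("failed to sample a valid shape after 5 retries")
      shapes[[s]] <- tri_mesh(V, template$faces, template$anatomy)
    }
    out <- shape_set(shapes)
  })
  attr(out, "cluster") <- clusters
  attr(out, "template") <- template
  out
}

deform_template <- function(V0, cfg, distal_sign, sign, patterns) {
  scale <- cfg$scale
  V <- V0
  # bimodal morphotype latent: cluster centers at -1 / +1
  t_lat <- sign + rnorm(1, 0, cfg$morph_sd)
  # mirrored condyle asymmetry: radial scaling on the +/-x sides of the
  # articulating (distal_sign * y) end, proportional to the latent
  side <- tanh(V0[, 1] / (0.15 * scale))
  distal <- exp(-((V0[, 2] - distal_sign * 0.45 * scale)^2) /
                  (2 * (0.3 * scale)^2))
  V <- V * (1 + cfg$condyle_ratio_amp * t_lat * side * distal)
  # migrating condylar ridge: a localized radial bulge near the
  # articulating end whose azimuth rotates with the latent — a moving
  # feature spreads over many linear modes, the population's main
  # nonlinearity
  eta <- cfg$ridge_migration * t_lat * pi / 180
  dir <- c(sin(eta) * 0.7, 0.6 * distal_sign, cos(eta) * 0.7)
  dir <- dir / sqrt(sum(dir^2))
  u <- V0 / sqrt(rowSums(V0^2))
  psi <- acos(pmin(pmax(u %*% dir, -1), 1))
  V <- V * as.numeric(1 + (cfg$ridge_amp / scale) *
                        exp(-psi^2 / (2 * cfg$ridge_width^2)))
  # axial torsion: cross-sections rotate about the long axis by an angle
  # growing toward the articulating end (trigonometric in the latent)
  tau <- cfg$twist_gain * t_lat * pi / 180
  yr0 <- (distal_sign * V0[, 2] - min(distal_sign * V0[, 2])) /
    diff(range(V0[, 2]))
  ang <- tau * yr0
  x <- V[, 1] * cos(ang) - V[, 3] * sin(ang)
  z <- V[, 1] * sin(ang) + V[, 3] * cos(ang)
  V[, 1] <- x; V[, 3] <- z
  # shaft bow: in-plane bending along the long axis
  bow <- rnorm(1, 0, cfg$shaft_bow_amp)
  yr <- (V0[, 2] - min(V0[, 2])) / diff(range(V0[, 2]))
  V[, 1] <- V[, 1] + bow * sin(pi * yr)
  # global width/depth scaling
  V[, 1] <- V[, 1] * exp(rnorm(1, 0, cfg$width_scale_sd))
  V[, 3] <- V[, 3] * exp(rnorm(1, 0, cfg$depth_scale_sd))
  # population-shared low-frequency displacement patterns with
  # per-shape amplitudes
  for (d in 1:3) {
    p <- patterns[[d]]
    V[, d] <- V[, d] + rnorm(1, 0, cfg$sine_amp) *
      sin(2 * pi * (V0 %*% p$k) / p$lambda + p$phase)
  }
  V + matrix(rnorm(length(V), 0, cfg$noise_sd), nrow(V), 3L)
}

# ---- synthetic projection sequences ---------------------------------------

#' Trajectory configuration for a deep-knee-bend-like sweep
#'
#' @param n_frames number of frames.
#' @param flexion start/end flexion angle (degrees) about the
#'   medial-lateral (z) axis.
#' @param distance nominal source-to-object distance (mm).
#' @param perturb_deg,perturb_mm uniform perturbation half-widths applied
#'   to the non-flexion degrees of freedom per frame.
#' @return A list of class `trajectory_config`.
#' @export
trajectory_config <- function(n_frames = 8L, flexion = c(0, 120),
                              distance = 700, perturb_deg = 1,
                              perturb_mm = 1) {
  structure(list(n_frames = as.integer(n_frames), flexion = flexion,
                 distance = distance, perturb_deg = perturb_deg,
                 perturb_mm = perturb_mm), class = "trajectory_config")
}

default_camera <- function() camera_model(1000, 0.8, c(320L, 240L))

#' Simulate a ground-truthed projection sequence
#'
#' Renders the given shape along a flexion sweep with small random
#' perturbations on the other degrees of freedom, adds Gaussian pixel
#' noise, and precomputes edge images.  The ground-truth shape and
#' per-frame poses are stored with the frames; with zero noise,
#' re-rendering the truth reproduces the images exactly.
#'
#' @param shape a [tri_mesh] (the true bone).
#' @param traj a [trajectory_config].
#' @param cam a [camera_model]; default: 1000 mm SID, 0.8 mm pixels,
#'   320x240.
#' @param noise_sd Gaussian pixel-noise sd (intensity units).
#' @param seed RNG seed.
#' @param biplane add a second, orthogonal (AP-like) view rotated 90
#'   degrees about the proximal-distal axis around the object center.
#' @param edge_cfg an [edge_config] for the frame edge images.
#' @return An object of class `synthetic_sequence` with `views` (list of
#'   [fluoro_view]), `true_poses`, `true_shape` and `camera`.
#' @export
simulate_sequence <- function(shape, traj = trajectory_config(),
                              cam = default_camera(), noise_sd = 0.01,
                              seed = 1L, biplane = FALSE,
                              edge_cfg = edge_config()) {
  stopifnot(inherits(shape, "tri_mesh"), inherits(traj, "trajectory_config"))
  nF <- traj$n_frames
  with_seed(seed, {
    gamma <- seq(traj$flexion[1], traj$flexion[2], length.out = nF)
    poses <- lapply(seq_len(nF), function(i)
      pose(alpha = runif(1, -traj$perturb_deg, traj$perturb_deg),
           beta = runif(1, -traj$perturb_deg, traj$perturb_deg),
           gamma = gamma[i],
           tx = runif(1, -traj$perturb_mm, traj$perturb_mm),
           ty = runif(1, -traj$perturb_mm, traj$perturb_mm),
           tz = traj$distance + runif(1, -traj$perturb_mm, traj$perturb_mm)))
    view_poses <- list(pose())
    if (biplane) {
      c0 <- c(0, 0, traj$distance)
      R <- rotation_matrix(pose(beta = 90))
      t2 <- c0 - drop(R %*% c0)
      ang <- euler_from_matrix(R)
      view_poses[[2]] <- pose(ang[1], ang[2], ang[3], t2[1], t2[2], t2[3])
    }
    views <- lapply(view_poses, function(vp) {
      frames <- lapply(seq_len(nF), function(i) {
        r <- render_model_image(shape, compose_pose(vp, poses[[i]]), cam)
        if (r$empty) stop(sprintf("trajectory exits the field of view at frame %d", i))
        px <- project_perspective(
          apply_pose(shape$vertices, compose_pose(vp, poses[[i]])), cam)
        if (any(px[, 1] < 0 | px[, 1] > cam$image_size[1] - 1 |
                  px[, 2] < 0 | px[, 2] > cam$image_size[2] - 1))
          stop(sprintf("trajectory exits the field of view at frame %d", i))
        img <- r$image
        if (noise_sd > 0)
          img <- pmin(pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img)), 0), 1)
        fluoro_frame(img, cam, edge_cfg = edge_cfg)
      })
      fluoro_view(cam, frames, vp)
    })
  })
  structure(list(views = views, true_poses = poses, true_shape = shape,
                 camera = cam), class = "synthetic_sequence")
}

#' @export
print.synthetic_sequence <- function(x, ...) {
  cat(sprintf("synthetic_sequence: %d view(s) x %d frames, %dx%d px\n",
              length(x$views), length(x$true_poses),
              x$camera$image_size[1], x$camera$image_size[2]))
  invisible(x)
}

#' Simulate a two-bone (femur + tibia) joint sequence
#'
#' Places a femur above a tibia with a configurable articular gap, keeps
#' the tibia nearly still, and flexes the femur about the joint center
#' through the trajectory's flexion sweep.  Each frame shows both bones
#' (summed thickness).  Ground-truth poses for both bones are stored.
#'
#' @param femur,tibia [tri_mesh] objects (femoral condyles pointing `+y`,
#'   tibial plateau `-y`, as built by [make_template]).
#' @param traj a [trajectory_config] (flexion sweep of the femur).
#' @param cam a [camera_model].
#' @param gap articular gap at reference (mm); zero or negative produces
#'   contact/overlap, used for collision tests.
#' @param noise_sd Gaussian pixel-noise sd.
#' @param seed RNG seed.
#' @param edge_cfg an [edge_config].
#' @return A list of class `synthetic_joint_sequence` with `views`,
#'   `femur_poses`, `tibia_poses`, the meshes and the camera.
#' @export
simulate_joint_sequence <- function(femur, tibia,
                                    traj = trajectory_config(flexion = c(0, 60)),
                                    cam = default_camera(), gap = 4,
                                    noise_sd = 0.01, seed = 1L,
                                    edge_cfg = edge_config()) {
  z0 <- traj$distance
  fy_max <- max(femur$vertices[, 2])   # condyle tip (+y, down in image)
  ty_min <- min(tibia$vertices[, 2])   # plateau tip (-y, up in image)
  # reference placement: femur condyles end `gap` mm above the plateau
  femur_ty <- -fy_max - gap / 2
  tibia_ty <- -ty_min + gap / 2
  # flexion center: centroid of the condylar mass (knees flex about the
  # condylar arc center, which keeps the articular surface in place)
  cond <- femur$vertices[femur$vertices[, 2] > 0.6 * fy_max, , drop = FALSE]
  joint_center <- colMeans(cond) + c(0, femur_ty, z0)
  nF <- traj$n_frames
  with_seed(seed, {
    gamma <- seq(traj$flexion[1], traj$flexion[2], length.out = nF)
    femur_poses <- lapply(seq_len(nF), function(i) {
      R <- rotation_matrix(pose(gamma = gamma[i]))
      p0 <- c(0, femur_ty, z0)
      t <- drop(R %*% p0) + joint_center - drop(R %*% joint_center)
      ang <- euler_from_matrix(R)
      pose(ang[1], ang[2], ang[3],
           t[1] + runif(1, -traj$perturb_mm, traj$perturb_mm),
           t[2] + runif(1, -traj$perturb_mm, traj$perturb_mm),
           t[3])
    })
    tibia_poses <- lapply(seq_len(nF), function(i)
      pose(gamma = runif(1, -traj$perturb_deg, traj$perturb_deg),
           tx = runif(1, -traj$perturb_mm, traj$perturb_mm),
           ty = tibia_ty + runif(1, -traj$perturb_mm, traj$perturb_mm),
           tz = z0))
    frames <- lapply(seq_len(nF), function(i) {
      rf <- render_model_image(femur, femur_poses[[i]], cam)
      rt <- render_model_image(tibia, tibia_poses[[i]], cam)
      if (rf$empty || rt$empty)
        stop(sprintf("trajectory exits the field of view at frame %d", i))
      thick <- rf$thickness + rt$thickness
      img <- thick / max(thick)
      if (noise_sd > 0)
        img <- pmin(pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                                      nrow(img)), 0), 1)
      fluoro_frame(img, cam, edge_cfg = edge_cfg)
    })
  })
  structure(list(views = list(fluoro_view(cam, frames)),
                 femur_poses = femur_poses, tibia_poses = tibia_poses,
                 femur = femur, tibia = tibia, camera = cam),
            class = "synthetic_joint_sequence")
}
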