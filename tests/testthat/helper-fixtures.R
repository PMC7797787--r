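# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

cache_fx <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, expr, envir = .fx)
  get(name, envir = .fx)
}

# closed unit-sphere-topology mesh with radius r, for analytic render tests
sphere_mesh <- function(r = 20, n = 28) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  theta <- pi * seq_len(n) / (n + 1)
  g <- expand.grid(phi = phi, theta = theta)
  dirs <- cbind(sin(g$theta) * cos(g$phi), cos(g$theta),
                sin(g$theta) * sin(g$phi))
  dirs <- rbind(c(0, 1, 0), dirs, c(0, -1, 0))
  m <- tri_mesh(dirs * r, fluoroshape:::lonlat_faces(n, n))
  fluoroshape:::orient_outward(m)
}

# the default phantom population of the study conditions (N = 40)
phantom_pop <- function() {
  cache_fx("pop40", rigid_align_set(sample_population(phantom_config())))
}

# a small, fast population for unit tests
phantom_pop_small <- function() {
  cache_fx("pop12", rigid_align_set(sample_population(
    phantom_config(n_shapes = 12, resolution = 420, seed = 4))))
}

shape_mat <- function(set) fluoroshape:::shape_matrix(set)

# population scale: RMS vertex distance of shapes to the population mean,
# population scale: mean centroid size (RMS vertex distance to the shape
# centroid), the standard yardstick for "percent of scale" statements
population_scale <- function(set) {
  mean(vapply(set$shapes, function(s) {
    V <- s$vertices
    sqrt(mean(rowSums(sweep(V, 2L, colMeans(V))^2)))
  }, numeric(1)))
}

default_camera_test <- function() camera_model(1000, 0.8, c(320L, 240L))

# smooth a random texture (Gaussian blur) so local correlations are defined
conv_sep_smooth <- function(m) {
  k <- fluoroshape:::gaussian_kernel_1d(2)
  fluoroshape:::conv_sep_cpp(m, k, k)
}
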