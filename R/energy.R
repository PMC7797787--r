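#' Hybrid-energy weights
#'
#' Weights of the four similarity terms.  The edge score must dominate the
#' intensity score (`c1 > c2`), and the collision weight times `big_C`
#' must exceed any attainable `|c1 Ee + c2 Er|` so a collision is always
#' decisive.
#'
#' @param c1,c2,c3,c4 nonnegative term weights (edge, region, homogeneity,
#'   collision).
#' @param big_C large positive collision constant.
#' @return A list of class `energy_weights`.
#' @export
energy_weights <- function(c1 = 2, c2 = 1, c3 = 0.5, c4 = 1, big_C = 1e6) {
  if (any(c(c1, c2, c3, c4) < 0)) stop("weights must be nonnegative")
  if (c1 <= c2) stop("edge weight c1 must exceed intensity weight c2")
  if (c4 * big_C <= c1 + c2)
    stop("c4 * big_C must exceed the maximum attainable c1*Ee + c2*Er")
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, big_C = big_C),
            class = "energy_weights")
}

#' Region-score and homogeneity configuration
#'
#' @param window odd window size (px) of the Gaussian-weighted local
#'   cross-correlation.
#' @param window_sigma Gaussian window width (px).
#' @param var_floor minimum local variance for a neighborhood to count.
#' @param band_halfwidth half-width (px) of the contour-adjacent bands of
#'   the homogeneity score.
#' @param mad_radius window radius (px) of the homogeneity neighborhoods.
#' @param edge_tol_px matching tolerance (px) between the observed edge
#'   image and the projected model contour: the observed edges are
#'   dilated this many times before the overlap is counted,
#'   compensating the half-pixel offset between a silhouette boundary
#'   and the gradient-maximum edge position.
#' @param squared_lcc if `TRUE` (default, as the energy is defined) use the
#'   squared local correlation (sign-insensitive); `FALSE` uses the signed
#'   correlation.
#' @return A list of class `energy_config`.
#' @export
energy_config <- function(window = 5L, window_sigma = 1.5,
                          var_floor = 1e-6, band_halfwidth = 3L,
                          mad_radius = 2L, edge_tol_px = 1L,
                          squared_lcc = TRUE) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  structure(list(window = window, window_sigma = window_sigma,
                 var_floor = var_floor,
                 band_halfwidth = as.integer(band_halfwidth),
                 mad_radius = as.integer(mad_radius),
                 edge_tol_px = as.integer(edge_tol_px),
                 squared_lcc = isTRUE(squared_lcc)),
            class = "energy_config")
}

#' Mask of pixels not covered by neighboring bones
#'
#' Pixels whose projection falls inside a neighboring bone's silhouette
#' are excluded (`u = 0`) from the edge and region scores; all other
#' pixels have `u = 1`.
#'
#' @param other_bone_silhouette logical matrix (or `NULL` for no
#'   neighbor).
#' @param dim image dimensions `c(nrow, ncol)`, used when the silhouette
#'   is `NULL`.
#' @return Logical mask matrix `u`.
#' @export
neighbor_mask <- function(other_bone_silhouette = NULL, dim = NULL) {
  if (is.null(other_bone_silhouette)) {
    if (is.null(dim)) stop("dim required when no silhouette is given")
    return(matrix(TRUE, dim[1], dim[2]))
  }
  u <- !other_bone_silhouette
  if (!any(u)) attr(u, "degenerate") <- TRUE
  u
}

#' Edge score: fraction of model-edge pixels on image edges
#'
#' `Ee = sum(C1 * C2 * u) / sum(C2 * u)`, in `[0, 1]`; equals 1 exactly
#' when every unmasked model-edge pixel lies on an image edge.
#'
#' @param C1 binary image edge matrix (observed frame).
#' @param C2 binary model edge matrix (projected contour).
#' @param u logical mask from [neighbor_mask].
#' @return Edge score in `[0, 1]`.
#' @export
edge_score <- function(C1, C2, u = NULL) {
  if (!identical(dim(C1), dim(C2))) stop("edge images differ in shape")
  if (is.null(u)) u <- matrix(TRUE, nrow(C1), ncol(C1))
  denom <- sum(C2 & u)
  if (denom == 0) stop("empty model edge set under the mask")
  sum(C1 & C2 & u) / denom
}

#' Region score: masked local cross-correlation of intensities
#'
#' Gaussian-windowed local correlation between the observed image and the
#' rendered model image, squared by default (invariant to local affine
#' intensity maps `I2 = a I1 + b`), averaged over unmasked pixels whose
#' local variances exceed the floor.  Masked pixels contribute neither as
#' centers nor as neighbors.
#'
#' @param I1 observed intensity matrix.
#' @param I2 rendered model intensity matrix.
#' @param u logical mask from [neighbor_mask].
#' @param cfg an [energy_config].
#' @return Score in `[0, 1]`; 0 with attribute `degenerate` when no valid
#'   neighborhood exists.
#' @export
region_score <- function(I1, I2, u = NULL, cfg = energy_config()) {
  if (!identical(dim(I1), dim(I2))) stop("images differ in shape")
  if (is.null(u)) u <- matrix(TRUE, nrow(I1), ncol(I1))
  w <- gaussian_kernel_1d(cfg$window_sigma, (cfg$window - 1L) / 2L)
  um <- u * 1
  cw <- function(m) conv_sep_cpp(m, w, w)
  ninv <- 1 / pmax(cw(um), 1e-12)
  m1 <- cw(um * I1) * ninv
  m2 <- cw(um * I2) * ninv
  v1 <- cw(um * I1 * I1) * ninv - m1 * m1
  v2 <- cw(um * I2 * I2) * ninv - m2 * m2
  cv <- cw(um * I1 * I2) * ninv - m1 * m2
  valid <- u & (v1 > cfg$var_floor) & (v2 > cfg$var_floor)
  if (!any(valid)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rho <- cv[valid] / sqrt(v1[valid] * v2[valid])
  rho <- pmin(pmax(rho, -1), 1)
  if (cfg$squared_lcc) mean(rho^2) else mean(pmax(rho, 0))
}

#' Homogeneity score along the projected contour
#'
#' Mean absolute deviation of the observed intensities in neighborhoods
#' adjacent to the projected model contour, computed separately for the
#' interior and exterior bands and summed.  The score is minimal (0) when
#' the contour separates two homogeneous regions.
#'
#' @param I1 observed intensity matrix.
#' @param silhouette logical matrix of the projected model interior.
#' @param C2 logical model contour matrix (defaults to the silhouette
#'   boundary).
#' @param cfg an [energy_config].
#' @return Nonnegative homogeneity score.
#' @export
homogeneity_score <- function(I1, silhouette, C2 = NULL,
                              cfg = energy_config()) {
  if (!identical(dim(I1), dim(silhouette))) stop("images differ in shape")
  if (is.null(C2)) C2 <- silhouette_boundary(silhouette)
  if (!any(C2)) stop("empty model contour")
  k <- cfg$band_halfwidth
  grown <- C2
  for (i in seq_len(k - 1L)) grown <- dilate8(grown)
  band_in <- grown & silhouette
  band_out <- dilate8(grown) & !silhouette
  band <- matrix(0L, nrow(I1), ncol(I1))
  band[band_in] <- 1L
  band[band_out] <- 2L
  inside <- matrix(0L, nrow(I1), ncol(I1))
  inside[silhouette] <- 1L
  st <- band_mad_cpp(I1, inside, band, cfg$mad_radius)
  s_in <- if (st[2] > 0) st[1] / st[2] else 0
  s_out <- if (st[4] > 0) st[3] / st[4] else 0
  s_in + s_out
}

#' Combine term scores into the hybrid energy
#'
#' `E = -[c1 Ee + c2 Er - c3 Eh - c4 Ec]`; lower is better.  The edge and
#' region scores reward agreement, the homogeneity score and the collision
#' penalty raise the energy.
#'
#' @param Ee,Er,Eh edge, region and homogeneity scores.
#' @param Ec collision score (`0` or `big_C`).
#' @param weights an [energy_weights].
#' @param masked_fraction fraction of pixels masked out by neighboring
#'   bones (bookkeeping only).
#' @return An object of class `energy_report` with the per-term values and
#'   the total `E`.
#' @export
total_energy <- function(Ee, Er, Eh, Ec = 0,
                         weights = energy_weights(),
                         masked_fraction = 0) {
  E <- -(weights$c1 * Ee + weights$c2 * Er - weights$c3 * Eh -
           weights$c4 * Ec)
  structure(list(Ee = as.numeric(Ee), Er = as.numeric(Er),
                 Eh = as.numeric(Eh), Ec = as.numeric(Ec),
                 E = E, masked_fraction = masked_fraction,
                 weights = weights),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("energy_report: E = %.6g (Ee %.3f, Er %.3f, Eh %.4f, Ec %.3g)\n",
              x$E, x$Ee, x$Er, x$Eh, x$Ec))
  invisible(x)
}

#' @export
format.energy_report <- function(x, ...) {
  jsonlite::toJSON(x[c("Ee", "Er", "Eh", "Ec", "E", "masked_fraction")],
                   auto_unbox = TRUE, digits = NA)
}

#' Evaluate the hybrid energy of a candidate render against a frame
#'
#' Convenience wrapper computing all four terms of one (shape, pose)
#' candidate against one frame, with optional neighbor masking and a
#' precomputed collision indicator.
#'
#' @param frame a [fluoro_frame].
#' @param render a [model_render] of the candidate.
#' @param weights an [energy_weights].
#' @param cfg an [energy_config].
#' @param other_silhouette logical silhouette of the neighboring bone (or
#'   `NULL`).
#' @param collision collision indicator `H1` in `{0, 1}`.
#' @return An `energy_report`.
#' @export
frame_energy <- function(frame, render, weights = energy_weights(),
                         cfg = energy_config(), other_silhouette = NULL,
                         collision = 0) {
  u <- neighbor_mask(other_silhouette, dim = dim(frame$image))
  if (render$empty || !any(render$edge & u))
    return(total_energy(0, 0, 0, collision * weights$big_C, weights,
                        masked_fraction = mean(!u)))
  C1 <- frame$edge_dil
  if (is.null(C1)) {
    C1 <- frame$edge_image
    for (i in seq_len(cfg$edge_tol_px)) C1 <- dilate8(C1)
  }
  Ee <- edge_score(C1, render$edge, u)
  Er <- region_score(frame$image, render$image, u, cfg)
  Eh <- homogeneity_score(frame$image, render$silhouette, render$edge, cfg)
  total_energy(Ee, Er, Eh, collision * weights$big_C, weights,
               masked_fraction = mean(!u))
}
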