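# ---- image helpers --------------------------------------------------------

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

dilate8 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_mat(m, dy, dx, FALSE)
  }
  out
}

erode4 <- function(m) {
  m & shift_mat(m, 1, 0, FALSE) & shift_mat(m, -1, 0, FALSE) &
    shift_mat(m, 0, 1, FALSE) & shift_mat(m, 0, -1, FALSE)
}

# one-pixel-wide interior boundary of a binary silhouette
silhouette_boundary <- function(sil) sil & !erode4(sil)

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Read / write a grayscale image (PNG or TIFF)
#'
#' Images are `height x width` numeric matrices with intensities in
#' `[0, 1]`; color inputs are converted by channel averaging.
#'
#' @param path image file path (`.png`, `.tif`/`.tiff`).
#' @return `read_image`: intensity matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3])],
                                           c(1, 2), mean)
  img <- pmin(pmax(img, 0), 1)
  img
}

#' @rdname read_image
#' @param img intensity matrix in `[0, 1]`.
#' @export
write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         stop("unsupported image format: ", ext))
  invisible(path)
}

# ---- model rendering -------------------------------------------------------

#' Render a posed mesh as a thickness image
#'
#' Projects a closed triangle mesh through the perspective camera and
#' accumulates, per pixel, the chord length of the x-ray through the mesh
#' (signed ray-triangle crossings).  The thickness image approximates
#' radiographic attenuation structure without a full digitally
#' reconstructed radiograph; it is normalized to `[0, 1]` for the
#' intensity scores.  The model edge image is the one-pixel-wide boundary
#' of the silhouette (pixels with positive thickness).
#'
#' @param mesh a watertight, consistently outward-wound [tri_mesh].
#' @param p a [pose6] placing the mesh in the camera frame.
#' @param cam a [camera_model].
#' @return An object of class `model_render`: list with `image`
#'   (normalized), `thickness` (mm), `silhouette` and `edge` (logical
#'   matrices) and `empty` (TRUE when the mesh projects entirely
#'   off-screen).
#' @export
render_model_image <- function(mesh, p, cam) {
  stopifnot(inherits(mesh, "tri_mesh"))
  V <- apply_pose(mesh$vertices, p)
  if (any(V[, 3] <= 1e-6))
    stop("posed mesh at or behind the x-ray source")
  thick <- render_thickness_cpp(V, mesh$faces - 1L,
                                cam$sid, cam$pitch,
                                cam$principal_point[1],
                                cam$principal_point[2],
                                cam$image_size[1], cam$image_size[2])
  sil <- thick > 1e-9
  empty <- !any(sil)
  mx <- max(thick)
  img <- if (mx > 0) thick / mx else thick
  structure(list(image = img, thickness = thick, silhouette = sil,
                 edge = silhouette_boundary(sil), empty = empty),
            class = "model_render")
}

#' @export
print.model_render <- function(x, ...) {
  cat(sprintf("model_render: %dx%d px, silhouette %d px%s\n",
              ncol(x$image), nrow(x$image), sum(x$silhouette),
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

# ---- edge extraction -------------------------------------------------------

#' Edge-extraction configuration
#'
#' Bilateral pre-filter (spatial and range widths) followed by a Canny
#' detector with hysteresis thresholds given as fractions of the maximum
#' gradient magnitude.
#'
#' @param bilateral_sigma_s spatial width of the bilateral filter (px).
#' @param bilateral_sigma_r range (intensity) width of the bilateral
#'   filter.
#' @param bilateral_radius window radius (px).
#' @param canny_low,canny_high hysteresis thresholds, fractions of the
#'   gradient maximum.
#' @return A list of class `edge_config`.
#' @export
edge_config <- function(bilateral_sigma_s = 3, bilateral_sigma_r = 0.1,
                        bilateral_radius = ceiling(2 * bilateral_sigma_s),
                        canny_low = 0.1, canny_high = 0.2) {
  stopifnot(bilateral_sigma_s > 0, bilateral_sigma_r > 0,
            canny_low > 0, canny_high >= canny_low)
  structure(list(bilateral_sigma_s = bilateral_sigma_s,
                 bilateral_sigma_r = bilateral_sigma_r,
                 bilateral_radius = as.integer(bilateral_radius),
                 canny_low = canny_low, canny_high = canny_high),
            class = "edge_config")
}

#' Extract a binary edge image (bilateral filter + Canny)
#'
#' Deterministic for a fixed configuration.  A constant image yields an
#' empty (all `FALSE`) edge image.
#'
#' @param image intensity matrix in `[0, 1]`.
#' @param cfg an [edge_config].
#' @return Logical matrix of edge pixels.
#' @export
compute_edge_image <- function(image, cfg = edge_config()) {
  stopifnot(inherits(cfg, "edge_config"))
  sm <- bilateral_cpp(image, cfg$bilateral_sigma_s, cfg$bilateral_sigma_r,
                      cfg$bilateral_radius)
  # Sobel gradients (y down): separable [1 2 1] smoothing x [-1 0 1] diff
  gx <- conv_sep_cpp(sm, c(1, 2, 1) / 4, c(-1, 0, 1))
  gy <- conv_sep_cpp(sm, c(-1, 0, 1), c(1, 2, 1) / 4)
  g <- sqrt(gx^2 + gy^2)
  gm <- max(g)
  if (gm <= 0) return(matrix(FALSE, nrow(image), ncol(image)))
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  bin <- round(ang / (pi / 4)) %% 4
  nms <- matrix(FALSE, nrow(g), ncol(g))
  steps <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (b in 0:3) {
    s <- steps[[b + 1]]
    n1 <- shift_mat(g, s[1], s[2], 0)
    n2 <- shift_mat(g, -s[1], -s[2], 0)
    nms <- nms | (bin == b & g >= n1 & g > n2)
  }
  strong <- nms & (g >= cfg$canny_high * gm)
  weak <- nms & (g >= cfg$canny_low * gm)
  # hysteresis: grow strong edges through connected weak pixels
  repeat {
    grown <- strong | (weak & dilate8(strong))
    if (identical(grown, strong)) break
    strong <- grown
  }
  strong
}

#' A single projection frame
#'
#' Bundles one grayscale image, its binary edge image and the camera it
#' was acquired with.
#'
#' @param image intensity matrix in `[0, 1]`, dimensions matching
#'   `cam$image_size` (height rows, width columns).
#' @param cam a [camera_model].
#' @param edge_image optional precomputed logical edge matrix; computed
#'   with [compute_edge_image] when `NULL`.
#' @param edge_cfg an [edge_config] used when computing edges.
#' @return An object of class `fluoro_frame`.
#' @export
fluoro_frame <- function(image, cam, edge_image = NULL,
                         edge_cfg = edge_config()) {
  stopifnot(inherits(cam, "camera_model"))
  image <- as.matrix(image)
  if (nrow(image) != cam$image_size[2] || ncol(image) != cam$image_size[1])
    stop("image dimensions do not match camera image_size")
  if (is.null(edge_image)) edge_image <- compute_edge_image(image, edge_cfg)
  if (!identical(dim(edge_image), dim(image)))
    stop("edge image dimensions do not match image")
  structure(list(image = image, edge_image = edge_image, camera = cam),
            class = "fluoro_frame")
}

#' @export
print.fluoro_frame <- function(x, ...) {
  cat(sprintf("fluoro_frame: %dx%d px, %d edge px\n",
              ncol(x$image), nrow(x$image), sum(x$edge_image)))
  invisible(x)
}
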