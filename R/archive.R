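#' Save / load a fitted kernel shape model (plain-text archive)
#'
#' Serializes a [kpca_ssm] to a single JSON file (arrays plus metadata:
#' kernel width, component count, shape-vector layout, face list), so
#' models survive across sessions and tools without binary formats.
#'
#' @param model a [kpca_ssm].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_kpca_model <- function(model, path) {
  stopifnot(inherits(model, "kpca_ssm"))
  obj <- list(
    format = "fluoroshape-kpca-1",
    layout = "x1 y1 z1 ... xM yM zM",
    sigma = model$sigma, m = model$m,
    training_vectors = model$training_vectors,
    faces = model$faces,
    names = model$names)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_kpca_model
#' @return `load_kpca_model`: the refitted [kpca_ssm] (the eigensystem is
#'   recomputed from the stored training vectors, which is cheap and keeps
#'   the archive small and exact).
#' @export
load_kpca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "fluoroshape-kpca-1"))
    stop("not a fluoroshape model archive: ", path)
  X <- matrix(as.numeric(obj$training_vectors),
              nrow = nrow(obj$training_vectors))
  model <- kpca_ssm(X, sigma = obj$sigma, m = obj$m)
  model$faces <- matrix(as.integer(obj$faces), ncol = 3L)
  model$names <- obj$names
  model
}
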