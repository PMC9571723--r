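# Per-pixel class masks. The pipeline consumes masks produced by any
# external segmenter (or by the synthetic scene generator); classes are
# 0 background/excluded, 1 water, 2 waterwheel, 3 checkerboard, 4 foam.

#' Class codes used in segmentation masks
#' @export
MASK_CLASSES <- c(background = 0L, water = 1L, waterwheel = 2L,
                  checkerboard = 3L, foam = 4L)

#' Construct a class mask
#'
#' @param labels integer matrix (H x W) of class labels in `0..4`.
#' @return object of class `class_mask`.
#' @export
class_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), MASK_CLASSES)
  if (length(bad))
    stop("mask contains labels outside 0..4: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, classes = MASK_CLASSES),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  tab <- table(factor(x$labels, levels = MASK_CLASSES,
                      labels = names(MASK_CLASSES)))
  cat("class mask ", nrow(x$labels), "x", ncol(x$labels), " px; ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a class mask as a single-channel PNG
#'
#' Masks are stored losslessly as 8-bit grayscale PNG where the pixel value
#' is the class label itself (file suffix convention: `.mask.png`).
#'
#' @param path PNG file path.
#' @param expected_shape optional `c(H, W)`; a mismatch is an error.
#' @param mask a `class_mask`.
#' @return `load_mask` returns a `class_mask`.
#' @export
load_mask <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  labels <- round(x * 255)
  if (!is.null(expected_shape) &&
      !identical(dim(labels), as.integer(expected_shape)))
    stop("mask shape ", paste(dim(labels), collapse = "x"),
         " does not match expected ", paste(expected_shape, collapse = "x"))
  class_mask(labels)
}

#' @rdname load_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "class_mask"))
  png::writePNG(mask$labels / 255, path)
  invisible(path)
}

#' Connected foam components and their contours
#'
#' Labels the foam class with 8-connectivity and extracts, for each
#' component, its pixel coordinates and contour pixels (foam pixels with at
#' least one 4-neighbor outside the component, or on the image border).
#' Distances from candidate patches are measured to these contour pixels.
#'
#' @param mask a `class_mask`.
#' @return object of class `foam_components`: list with `K` and
#'   `components`, each `list(pixels, contour)` of n x 2 (x, y) matrices in
#'   0-based pixel-center coordinates.
#' @export
foam_components <- function(mask) {
  stopifnot(inherits(mask, "class_mask"))
  foam <- mask$labels == MASK_CLASSES[["foam"]]
  lab <- label_components(foam)
  K <- max(lab)
  Hh <- nrow(foam); Ww <- ncol(foam)
  # contour: foam pixel with any 4-neighbor that is not foam (or border)
  pad <- matrix(FALSE, Hh + 2L, Ww + 2L)
  pad[2:(Hh + 1L), 2:(Ww + 1L)] <- foam
  interior <- pad[1:Hh, 2:(Ww + 1L)] & pad[3:(Hh + 2L), 2:(Ww + 1L)] &
              pad[2:(Hh + 1L), 1:Ww] & pad[2:(Hh + 1L), 3:(Ww + 2L)]
  contour <- foam & !interior
  comps <- vector("list", K)
  if (K > 0L) {
    for (k in seq_len(K)) {
      idx <- which(lab == k)
      cidx <- idx[contour[idx]]
      comps[[k]] <- list(
        pixels = cbind(x = (idx - 1L) %/% Hh, y = (idx - 1L) %% Hh),
        contour = cbind(x = (cidx - 1L) %/% Hh, y = (cidx - 1L) %% Hh))
    }
  }
  structure(list(K = K, components = comps, shape = c(Hh, Ww)),
            class = "foam_components")
}
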