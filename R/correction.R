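# Least-squares estimation of the 3x3 Lab-space correction matrix from the
# 24 measured vs. reference block colors, and its per-pixel application.

#' Pair measured and reference block colors
#'
#' @param measured 24 x 3 matrix of Lab colors measured from the imaged
#'   checkerboard blocks.
#' @param reference 24 x 3 matrix of ground-truth Lab colors (from the
#'   layout's printed RGB values), index-aligned with `measured`.
#' @return an object of class `block_correspondence`.
#' @export
block_correspondence <- function(measured, reference) {
  measured <- as.matrix(measured); reference <- as.matrix(reference)
  if (!identical(dim(measured), c(24L, 3L)) ||
      !identical(dim(reference), c(24L, 3L)))
    stop("measured and reference must both be 24 x 3 Lab matrices")
  structure(list(measured = measured, reference = reference),
            class = "block_correspondence")
}

#' Build the stacked least-squares system for the correction matrix
#'
#' Each block contributes three rows in block-diagonal form: row 3i+1 carries
#' the measured Lab triple in columns 1..3, row 3i+2 in columns 4..6, row
#' 3i+3 in columns 7..9, so that `A %*% m = d` with `m` the row-major
#' flattening of the 3x3 matrix and `d` the stacked reference Lab triples.
#'
#' @param corr a [block_correspondence()].
#' @return list with `A` (72 x 9) and `d` (length 72).
#' @export
build_lsq_system <- function(corr) {
  stopifnot(inherits(corr, "block_correspondence"))
  n <- nrow(corr$measured)
  A <- matrix(0, 3 * n, 9)
  for (i in seq_len(n)) {
    v <- corr$measured[i, ]
    A[3 * i - 2, 1:3] <- v
    A[3 * i - 1, 4:6] <- v
    A[3 * i,     7:9] <- v
  }
  list(A = A, d = as.numeric(t(corr$reference)))
}

#' Estimate the Lab correction matrix
#'
#' Solves the stacked system by the normal-equation pseudo-inverse
#' \eqn{m = (A^T A)^{-1} A^T d} and reshapes `m` into the 3x3 matrix `M`
#' acting on Lab column vectors. The residual reported is the root mean
#' square Lab distance of the corrected blocks from their references.
#'
#' @param corr a [block_correspondence()].
#' @return an object of class `correction_model`: list with `M` (3x3) and
#'   `residual`.
#' @export
estimate_correction <- function(corr) {
  sys <- build_lsq_system(corr)
  qrA <- qr(sys$A)
  if (qrA$rank < 9L)
    .aqua_stop(paste0("design matrix rank ", qrA$rank,
                      " < 9: block colors do not span Lab space"),
               "estimation_error")
  m <- solve(crossprod(sys$A), crossprod(sys$A, sys$d))
  M <- matrix(m, 3, 3, byrow = TRUE)
  corrected <- corr$measured %*% t(M)
  residual <- sqrt(mean(rowSums((corrected - corr$reference)^2)))
  structure(list(M = M, residual = residual), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat("Lab correction matrix (RMS block residual ",
      format(x$residual, digits = 4), "):\n", sep = "")
  print(round(x$M, 5))
  invisible(x)
}

#' Apply a correction model to an image
#'
#' Converts every pixel to Lab, left-multiplies by the model matrix, and
#' converts back to RGB. Gamut clamping happens only at the final RGB stage.
#'
#' @param img H x W x 3 image array in \eqn{[0, 255]}.
#' @param model a `correction_model`.
#' @param round logical; round output channels to integers.
#' @return corrected image array, same dimensions.
#' @export
apply_correction <- function(img, model, round = TRUE) {
  .check_image(img)
  stopifnot(inherits(model, "correction_model"))
  d <- dim(img)
  px <- matrix(img, ncol = 3L)
  lab <- rgb_to_lab(px)
  rgb <- lab_to_rgb(lab %*% t(model$M), round = round)
  array(rgb, d)
}

#' Correct an image against its embedded checkerboard
#'
#' End-to-end color correction: detect the fiducial markers, estimate the
#' ROI homography, measure the 24 block colors, estimate the Lab correction
#' matrix against the layout's reference colors, and apply it to the whole
#' frame.
#'
#' @param img H x W x 3 image array in \eqn{[0, 255]}.
#' @param layout a [checkerboard_layout()].
#' @return list with `image` (corrected array), `model`
#'   (`correction_model`), `blocks` (24 x 3 measured RGB), `homography`.
#' @export
correct_image <- function(img, layout = checkerboard_layout()) {
  markers <- detect_markers(img)
  H <- estimate_roi_homography(markers, layout)
  blocks <- extract_block_colors(img, H, layout)
  corr <- block_correspondence(rgb_to_lab(blocks), layout_ref_lab(layout))
  model <- estimate_correction(corr)
  list(image = apply_correction(img, model), model = model,
       blocks = blocks, homography = H)
}

#' Serialize / restore a correction model as JSON
#'
#' @param model a `correction_model`.
#' @param path JSON file path.
#' @return `read_correction_model` returns the model.
#' @export
write_correction_model <- function(model, path) {
  jsonlite::write_json(list(M = as.numeric(t(model$M)),
                            residual = model$residual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_correction_model
#' @export
read_correction_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(M = matrix(x$M, 3, 3, byrow = TRUE),
                 residual = x$residual), class = "correction_model")
}
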