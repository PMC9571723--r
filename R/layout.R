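# Canonical checkerboard geometry and the 24 reference colors.

# The 24 reference colors of the printed checkerboard, in reading order
# (grid row-major: 4 rows x 6 columns).
.REF_COLORS <- matrix(c(
  111,  77,  71,   189, 149, 132,    93, 116, 151,    86, 106,  67,
  118, 123, 164,    92, 181, 170,   206, 121,  37,    50,  85, 164,
  172,  75,  85,    88,  62, 103,   164, 201, 100,   212, 149,  55,
   20,  46, 123,    67, 140,  76,   162,  46,  55,   205, 185,   0,
  194,  83, 145,    47, 144, 170,   229, 225, 230,   201, 201, 200,
  158, 161, 162,   118, 119, 123,    83,  86,  90,    55,  58,  54),
  ncol = 3, byrow = TRUE)
colnames(.REF_COLORS) <- c("R", "G", "B")

#' Canonical checkerboard layout
#'
#' Describes the printed reference board: a 4 x 6 grid of 24 known colors
#' normalized to a 200 x 200 pixel region of interest (ROI), with four square
#' fiducial markers just outside the ROI corners. Marker ids 0, 1, 2, 3 sit at
#' the top-left, top-right, bottom-right and bottom-left corners respectively;
#' this id-to-corner assignment is the convention shared by the synthetic
#' renderer and the detector.
#'
#' All geometry is expressed in ROI coordinates: the color grid occupies
#' \eqn{[0, 200]^2}; marker squares (side `marker_side`) sit `marker_margin`
#' outside the grid, and a white quiet zone extends to `canvas`.
#'
#' @param roi_size side of the normalized ROI in pixels (default 200).
#' @param marker_side,marker_margin fiducial square side and gap to the ROI,
#'   in ROI units.
#' @param marker_ids integer ids (from the 50-id dictionary) at TL, TR, BR,
#'   BL.
#' @param sample_frac central fraction of each cell averaged when measuring
#'   block colors (default 0.5, i.e. the middle 50% x 50% window, avoiding
#'   bleed at cell borders).
#' @return an object of class `checkerboard_layout`.
#' @export
checkerboard_layout <- function(roi_size = 200, marker_side = 48,
                                marker_margin = 12, marker_ids = 0:3,
                                sample_frac = 0.5) {
  stopifnot(roi_size > 0, marker_side > 0, marker_margin >= 0,
            length(marker_ids) == 4L, sample_frac > 0, sample_frac <= 1)
  s <- marker_side; m <- marker_margin; R <- roi_size
  # top-left corner of each marker square, order TL, TR, BR, BL
  origins <- rbind(c(-m - s, -m - s), c(R + m, -m - s),
                   c(R + m, R + m), c(-m - s, R + m))
  corners <- lapply(seq_len(4), function(k) {
    o <- origins[k, ]
    rbind(o, o + c(s, 0), o + c(s, s), o + c(0, s))  # TL TR BR BL
  })
  pad <- 20
  structure(list(
    roi_size = R, nrow = 4L, ncol = 6L,
    ref_rgb = .REF_COLORS,
    marker_side = s, marker_margin = m,
    marker_ids = as.integer(marker_ids),
    marker_corners = corners,          # ROI coords, per id slot TL,TR,BR,BL
    canvas = c(-m - s - pad, R + m + s + pad),
    sample_frac = sample_frac
  ), class = "checkerboard_layout")
}

#' @export
print.checkerboard_layout <- function(x, ...) {
  cat("checkerboard layout: ", x$nrow, "x", x$ncol, " blocks, ROI ",
      x$roi_size, "x", x$roi_size, " px, marker ids ",
      paste(x$marker_ids, collapse = "/"), " (TL/TR/BR/BL)\n", sep = "")
  invisible(x)
}

# Reference Lab values of the 24 blocks.
layout_ref_lab <- function(layout) rgb_to_lab(layout$ref_rgb)

# Cell rectangle (x0, y0, x1, y1) in ROI coords for block i (row-major).
.cell_rect <- function(layout, i) {
  r <- (i - 1L) %/% layout$ncol
  c <- (i - 1L) %% layout$ncol
  cw <- layout$roi_size / layout$ncol
  ch <- layout$roi_size / layout$nrow
  c(c * cw, r * ch, (c + 1) * cw, (r + 1) * ch)
}

#' Export measured block colors as CSV
#'
#' @param blocks 24 x 3 matrix of block mean RGB values.
#' @param path output CSV path (columns index, R, G, B).
#' @export
write_block_colors <- function(blocks, path) {
  df <- data.frame(index = seq_len(nrow(blocks)),
                   R = blocks[, 1], G = blocks[, 2], B = blocks[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
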