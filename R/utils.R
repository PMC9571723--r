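# Shared low-level helpers: image containers, geometry, labeling, conditions.
#
# Image convention: numeric array H x W x 3 with channel values in [0, 255].
# A point (x, y) has x growing rightwards (columns) and y downwards (rows),
# 0-based, referring to pixel centers: pixel [i, j] (1-based array indices)
# has center (x, y) = (j - 1, i - 1).

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.aqua_stop <- function(msg, class, ...) {
  stop(structure(class = c(class, "aquacolor_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

.check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an H x W x 3 array")
  invisible(img)
}

# ITU-R BT.601 luma, returned as an H x W matrix in [0, 255] (not rounded).
luma <- function(img) {
  .check_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read and write RGB images
#'
#' Images are plain numeric arrays of shape H x W x 3 with channels in
#' \eqn{[0, 255]}. Only PNG is supported (lossless, the format the synthetic
#' generator writes).
#'
#' @param path file path of a PNG image.
#' @param img H x W x 3 array, channels in \eqn{[0, 255]}.
#' @return `read_image` returns the image array; `write_image` returns `path`
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  .check_image(img)
  png::writePNG(.clamp(img, 0, 255) / 255, path)
  invisible(path)
}

## ---- homography geometry ----------------------------------------------

# Apply a 3x3 homography to an n x 2 point matrix.
apply_homography <- function(H, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  p <- cbind(pts, 1) %*% t(H)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

# Direct linear transform with Hartley normalization.
# Maps src (n x 2) -> dst (n x 2); returns 3x3 H with H[3,3] scaled to 1
# when possible. Degenerate configurations raise a localization error.
homography_dlt <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2L)
  dst <- matrix(as.numeric(dst), ncol = 2L)
  n <- nrow(src)
  if (n < 4L || nrow(dst) != n)
    .aqua_stop("need at least 4 point correspondences", "localization_error")

  norm_t <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(T = T, p = apply_homography(T, p))
  }
  ns <- norm_t(src); nd <- norm_t(dst)
  x <- ns$p[, 1]; y <- ns$p[, 2]; u <- nd$p[, 1]; v <- nd$p[, 2]
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  sv <- svd(A, nu = 0, nv = 9)
  # collinear / degenerate points leave a >1 dimensional null space
  if (sv$d[8] < 1e-8 * sv$d[1])
    .aqua_stop("degenerate point configuration for homography estimation",
               "localization_error")
  H <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(det(H)) < 1e-12)
    .aqua_stop("estimated homography is singular", "localization_error")
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

# Bilinear sampling of a single-channel matrix at (x, y) point vectors
# (0-based pixel-center coords); coordinates are clamped to the image.
bilinear_sample <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  x <- .clamp(x, 0, W - 1); y <- .clamp(y, 0, H - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + H * x0; i10 <- y0 + 1 + H * x1
  i01 <- y1 + 1 + H * x0; i11 <- y1 + 1 + H * x1
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

#' Warp an image through a homography
#'
#' Resamples `img` into an `out_w` x `out_h` canvas such that output pixel
#' (x, y) takes the value of the input at \eqn{H^{-1}(x, y)} (bilinear
#' interpolation, border clamp). `H` maps image coordinates to output
#' coordinates, the direction the ROI-normalization homography is estimated
#' in.
#'
#' @param img H x W x 3 image array.
#' @param H 3x3 homography, image -> output frame.
#' @param out_w,out_h output size in pixels.
#' @return an `out_h` x `out_w` x 3 image array.
#' @export
warp_perspective <- function(img, H, out_w, out_h) {
  .check_image(img)
  Hi <- solve(H)
  g <- expand.grid(x = seq_len(out_w) - 1, y = seq_len(out_h) - 1)
  src <- apply_homography(Hi, cbind(g$x, g$y))
  out <- array(0, c(out_h, out_w, 3))
  for (ch in 1:3) {
    v <- bilinear_sample(img[, , ch], src[, 1], src[, 2])
    out[, , ch] <- matrix(v, nrow = out_h, byrow = TRUE)
  }
  out
}

## ---- connected components ---------------------------------------------

# 8-connected labeling of a logical matrix via row runs + union-find.
# Returns an integer matrix; background 0, components 1..K.
label_components <- function(bin) {
  bin <- bin != 0
  H <- nrow(bin); W <- ncol(bin)
  out <- matrix(0L, H, W)
  # row runs (over columns) per row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  row_first <- integer(H + 1L)  # index of first run of each row
  for (i in seq_len(H)) {
    row_first[i] <- length(run_row) + 1L
    r <- rle(bin[i, ])
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      run_row <- c(run_row, rep.int(i, sum(keep)))
      run_s <- c(run_s, starts[keep])
      run_e <- c(run_e, ends[keep])
    }
  }
  row_first[H + 1L] <- length(run_row) + 1L
  nr <- length(run_row)
  if (nr == 0L) return(out)

  parent <- seq_len(nr)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (i in seq_len(H)[-1]) {
    if (row_first[i] > row_first[i + 1L] - 1L) next       # no runs in row i
    if (row_first[i - 1L] > row_first[i] - 1L) next       # none in row i-1
    a_idx <- row_first[i]:(row_first[i + 1L] - 1L)
    b_idx <- row_first[i - 1L]:(row_first[i] - 1L)
    for (a in a_idx) {
      for (b in b_idx) {
        # 8-connectivity: column ranges may touch diagonally (+/- 1)
        if (run_s[a] <= run_e[b] + 1L && run_e[a] >= run_s[b] - 1L) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  labels <- match(roots, unique(roots))
  for (k in seq_len(nr)) {
    out[run_row[k], run_s[k]:run_e[k]] <- labels[k]
  }
  out
}
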