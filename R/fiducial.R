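# Square fiducial markers: a 4x4-bit, 50-id dictionary, plus detection and
# decoding. Markers are 6x6 modules: a black outer border enclosing the 4x4
# payload (bit 1 = white module). Ids and bit patterns are fixed by a
# deterministic generation procedure, so renderer and detector always agree.

.fiducial_env <- new.env(parent = emptyenv())

.rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

.bits_to_code <- function(bits) sum(as.integer(bits) * 2^(seq_along(bits) - 1))

.mat_to_code <- function(m) .bits_to_code(as.integer(t(m)))  # row-major

#' The 4x4 fiducial marker dictionary
#'
#' Fifty 16-bit marker payloads generated deterministically: candidate codes
#' are scanned in a fixed order and accepted when every rotation keeps a
#' Hamming distance of at least 4 from every rotation of every previously
#' accepted code, and the four rotations of the code itself are mutually at
#' distance >= 4 (so orientation is unambiguous). This mirrors how standard
#' small fiducial dictionaries are constructed.
#'
#' @return list with `bits` (list of 4x4 0/1 matrices, ids 0..49) and
#'   `lookup` (named integer vector mapping the 16-bit code of any rotation
#'   to `4 * id + rotation`).
#' @export
fiducial_dictionary <- function() {
  if (!is.null(.fiducial_env$dict)) return(.fiducial_env$dict)
  target <- 50L
  accepted <- list()          # canonical 16-bit vectors
  accepted_rots <- list()     # list of 4 x 16 matrices (all rotations)
  bits_of <- function(code) as.integer(bitwAnd(bitwShiftR(code, 0:15), 1L))
  rotations <- function(b) {
    m <- matrix(b, 4, 4, byrow = TRUE)
    out <- matrix(0L, 4, 16)
    for (r in 1:4) {
      out[r, ] <- as.integer(t(m))
      m <- .rot_cw(m)
    }
    out
  }
  cand <- 0L
  while (length(accepted) < target && cand < 65536L) {
    b <- bits_of(cand)
    rots <- rotations(b)
    self_d <- c(sum(rots[1, ] != rots[2, ]), sum(rots[1, ] != rots[3, ]),
                sum(rots[1, ] != rots[4, ]), sum(rots[2, ] != rots[3, ]),
                sum(rots[2, ] != rots[4, ]), sum(rots[3, ] != rots[4, ]))
    ok <- all(self_d >= 4)
    if (ok && length(accepted_rots)) {
      for (ar in accepted_rots) {
        # min distance between any rotation pair across the two codes
        dmin <- min(vapply(1:4, function(i)
          min(colSums(t(ar) != rots[i, ])), numeric(1)))
        if (dmin < 4) { ok <- FALSE; break }
      }
    }
    if (ok) {
      accepted[[length(accepted) + 1L]] <- b
      accepted_rots[[length(accepted_rots) + 1L]] <- rots
    }
    cand <- cand + 1L
  }
  lookup <- integer(0)
  bits <- vector("list", length(accepted))
  for (id0 in seq_along(accepted) - 1L) {
    rots <- accepted_rots[[id0 + 1L]]
    bits[[id0 + 1L]] <- matrix(accepted[[id0 + 1L]], 4, 4, byrow = TRUE)
    for (r in 0:3) {
      code <- .bits_to_code(rots[r + 1L, ])
      lookup[as.character(code)] <- 4L * id0 + r
    }
  }
  .fiducial_env$dict <- list(bits = bits, lookup = lookup)
  .fiducial_env$dict
}

# Module color (0 black / 1 white) of marker `id` at module row i, col j
# (1-based, 6x6 including border).
marker_module <- function(id, i, j) {
  dict <- fiducial_dictionary()
  border <- i == 1L | i == 6L | j == 1L | j == 6L
  out <- integer(length(border))
  inner <- !border
  if (any(inner)) {
    b <- dict$bits[[id + 1L]]
    out[inner] <- b[cbind(i[inner] - 1L, j[inner] - 1L)]
  }
  out[border] <- 0L
  out
}

## ---- quad corner extraction -------------------------------------------

# Distance of points to the (infinite) line through p and q.
.line_dist <- function(pts, p, q) {
  d <- q - p
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(sqrt(rowSums(sweep(pts, 2, p)^2)))
  abs((pts[, 1] - p[1]) * d[2] - (pts[, 2] - p[2]) * d[1]) / nrm
}

# Fit 4 corners to a convex blob given its pixel coordinates (n x 2, x/y).
# Strategy: convex hull; the farthest point pair gives two opposite corners;
# the farthest hull point from that diagonal on each side gives the other
# two; each corner is then refined by total-least-squares line fits to the
# hull points of the adjacent edges.
.quad_corners <- function(pts) {
  hull <- pts[chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 4L) return(NULL)
  D <- as.matrix(dist(hull))
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  i <- min(ij); j <- max(ij)
  side <- (hull[, 1] - hull[i, 1]) * (hull[j, 2] - hull[i, 2]) -
          (hull[, 2] - hull[i, 2]) * (hull[j, 1] - hull[i, 1])
  dd <- .line_dist(hull, hull[i, ], hull[j, ])
  dd_a <- dd; dd_a[side <= 0] <- -1
  dd_b <- dd; dd_b[side > 0] <- -1
  a <- which.max(dd_a); b <- which.max(dd_b)
  if (dd_a[a] <= 0.5 || dd_b[b] <= 0.5) return(NULL)  # degenerate / thin
  idx <- c(i, a, j, b)
  # order the 4 corners along the hull to get a consistent winding
  idx <- idx[order(match(idx, seq_len(nh)))]
  quad <- hull[idx, , drop = FALSE]
  # enforce clockwise-as-viewed winding: in y-down image coords this is a
  # positive shoelace sum
  area2 <- sum(quad[, 1] * quad[c(2:4, 1), 2] - quad[c(2:4, 1), 1] * quad[, 2])
  if (area2 < 0) quad <- quad[c(1, 4, 3, 2), , drop = FALSE]
  .refine_quad(quad, hull)
}

# Refine quad corners by fitting a TLS line to hull points nearest each edge
# and intersecting adjacent lines.
.refine_quad <- function(quad, hull) {
  edges <- lapply(1:4, function(k) rbind(quad[k, ], quad[k %% 4 + 1, ]))
  dmat <- vapply(edges, function(e) .line_dist(hull, e[1, ], e[2, ]),
                 numeric(nrow(hull)))
  assign <- max.col(-dmat)
  lines <- vector("list", 4L)
  for (k in 1:4) {
    p <- hull[assign == k, , drop = FALSE]
    if (nrow(p) < 2L) {
      e <- edges[[k]]
      ctr <- colMeans(e); d <- e[2, ] - e[1, ]
    } else {
      ctr <- colMeans(p)
      cm <- sweep(p, 2, ctr)
      d <- svd(cm, nu = 0, nv = 2)$v[, 1]
    }
    lines[[k]] <- list(p = ctr, d = d / sqrt(sum(d^2)))
  }
  out <- matrix(0, 4, 2)
  for (k in 1:4) {
    l1 <- lines[[(k - 2) %% 4 + 1]]; l2 <- lines[[k]]
    A <- cbind(l1$d, -l2$d)
    if (abs(det(A)) < 1e-9) return(NULL)   # parallel edges: not a quad
    t1 <- solve(A, l2$p - l1$p)[1]
    out[k, ] <- l1$p + t1 * l1$d
  }
  out
}

## ---- detection ---------------------------------------------------------

.otsu_threshold <- function(g) {
  h <- tabulate(pmin(pmax(floor(g) + 1L, 1L), 256L), nbins = 256L)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mt <- mu[256]
  sb <- (mt * w - mu)^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1L
}

#' Detect square fiducial markers in an image
#'
#' Finds dark quadrilateral candidates by thresholding and 8-connected
#' labeling, fits and refines their four corners, and decodes the 4x4 payload
#' against the 50-id dictionary over all four rotations. Only exact payload
#' matches are returned. Corners are reported in the marker's canonical order
#' (top-left, top-right, bottom-right, bottom-left as the marker was
#' designed), which makes the detection orientation-aware.
#'
#' @param img H x W x 3 image array in \eqn{[0, 255]}.
#' @param min_side minimum marker side length in pixels considered.
#' @return list of detections, each `list(id, corners)` with `corners` a
#'   4 x 2 matrix of (x, y) image coordinates. Empty list when nothing is
#'   found.
#' @export
detect_markers <- function(img, min_side = 8) {
  .check_image(img)
  g <- luma(img)
  H <- nrow(g); W <- ncol(g)
  thr <- .otsu_threshold(g)
  dict <- fiducial_dictionary()
  found <- list()
  for (th in unique(c(thr, 128, 80))) {
    dark <- g < th
    lab <- label_components(dark)
    K <- max(lab)
    if (K == 0L) next
    sizes <- tabulate(lab, nbins = K)
    min_area <- (min_side * 0.5)^2 * 4   # border ring area lower bound
    cand_ids <- which(sizes >= min_area & sizes <= 0.25 * H * W)
    for (k in cand_ids) {
      idx <- which(lab == k)
      ys <- (idx - 1L) %% H; xs <- (idx - 1L) %/% H
      bw <- diff(range(xs)); bh <- diff(range(ys))
      if (bw < min_side || bh < min_side) next
      if (bw > 4 * bh || bh > 4 * bw) next
      quad <- .quad_corners(cbind(xs, ys))
      if (is.null(quad)) next
      dec <- .decode_marker(g, quad, dict)
      if (!is.null(dec)) found[[length(found) + 1L]] <- dec
    }
    if (length(found)) break
  }
  # deduplicate by id, keep first
  if (length(found)) {
    ids <- vapply(found, `[[`, integer(1), "id")
    found <- found[!duplicated(ids)]
  }
  found
}

# Decode the payload inside a quad (corners clockwise). Returns
# list(id, corners) with corners rotated into canonical order, or NULL.
.decode_marker <- function(gray, quad, dict) {
  Hm <- tryCatch(
    homography_dlt(rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6)), quad),
    error = function(e) NULL)
  if (is.null(Hm)) return(NULL)
  cells <- expand.grid(j = 1:6, i = 1:6)
  pts <- apply_homography(Hm, cbind(cells$j - 0.5, cells$i - 0.5))
  v <- bilinear_sample(gray, pts[, 1], pts[, 2])
  cutoff <- (min(v) + max(v)) / 2
  if (max(v) - min(v) < 30) return(NULL)   # no contrast: not a marker
  bitmat <- matrix(as.integer(v > cutoff), 6, 6, byrow = TRUE)
  if (any(bitmat[c(1, 6), ] != 0L) || any(bitmat[, c(1, 6)] != 0L))
    return(NULL)                           # border must be fully black
  B <- bitmat[2:5, 2:5]
  for (r in 0:3) {
    m <- B
    if (r > 0) for (s in seq_len(r)) m <- .rot_cw(m)
    hit <- dict$lookup[as.character(.mat_to_code(m))]
    if (!is.na(hit) && hit %% 4L == 0L) {
      id <- hit %/% 4L
      corners <- quad[((0:3 - r) %% 4) + 1, , drop = FALSE]
      return(list(id = id, corners = corners))
    }
  }
  NULL
}

#' Estimate the ROI-normalizing homography from marker detections
#'
#' Uses the known canonical positions of the four board markers (in ROI
#' coordinates) as point correspondences and estimates the homography that
#' maps image coordinates onto the canonical 200 x 200 ROI by the direct
#' linear transform. Markers whose ids are not part of the layout are
#' ignored; at least four corresponding points (one full marker) are
#' required, and three visible markers are plenty.
#'
#' @param markers list of detections from [detect_markers()].
#' @param layout a [checkerboard_layout()].
#' @return 3x3 homography matrix mapping image -> ROI coordinates.
#' @export
estimate_roi_homography <- function(markers, layout) {
  src <- NULL; dst <- NULL
  for (m in markers) {
    slot <- match(m$id, layout$marker_ids)
    if (is.na(slot)) next
    src <- rbind(src, m$corners)
    dst <- rbind(dst, layout$marker_corners[[slot]])
  }
  if (is.null(src) || nrow(src) < 4L)
    .aqua_stop("checkerboard not localized: fewer than 4 marker corner correspondences",
               "localization_error")
  homography_dlt(src, dst)
}

#' Measure the 24 block colors of a localized checkerboard
#'
#' Warps the image into the canonical ROI (200 x 200 by default) and averages
#' the central window of each of the 24 cells, returning the mean colors in
#' the layout's row-major reading order.
#'
#' @param img H x W x 3 image array.
#' @param H 3x3 homography from [estimate_roi_homography()].
#' @param layout a [checkerboard_layout()].
#' @return 24 x 3 matrix of mean RGB values in \eqn{[0, 255]}.
#' @export
extract_block_colors <- function(img, H, layout) {
  roi <- warp_perspective(img, H, layout$roi_size, layout$roi_size)
  n <- layout$nrow * layout$ncol
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    rect <- .cell_rect(layout, i)
    cx <- (rect[1] + rect[3]) / 2; cy <- (rect[2] + rect[4]) / 2
    hw <- (rect[3] - rect[1]) * layout$sample_frac / 2
    hh <- (rect[4] - rect[2]) * layout$sample_frac / 2
    cols <- which(seq_len(ncol(roi[, , 1])) - 0.5 >= cx - hw &
                  seq_len(ncol(roi[, , 1])) - 0.5 <= cx + hw)
    rows <- which(seq_len(nrow(roi[, , 1])) - 0.5 >= cy - hh &
                  seq_len(nrow(roi[, , 1])) - 0.5 <= cy + hh)
    if (!length(rows) || !length(cols))
      .aqua_stop("empty sampling window for block ", "extraction_error")
    for (ch in 1:3) out[i, ch] <- mean(roi[rows, cols, ch])
  }
  colnames(out) <- c("R", "G", "B")
  out
}
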