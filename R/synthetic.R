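# Synthetic pond scenes with exact ground truth: a water field of a known
# color code, foam blobs, a waterwheel, and the reference checkerboard
# embedded under a known placement homography and a known invertible Lab
# distortion. Every pipeline stage can be exercised against these scenes
# without field data.

#' Specification of a synthetic pond scene
#'
#' Defaults describe the nominal study conditions: a 480 x 360 frame, green
#' water (code 001-003) with a gentle Lab gradient, three foam blobs, a
#' striped waterwheel on the right, the checkerboard placed in the upper
#' left, identity color distortion and per-channel Gaussian sensor noise of
#' 2 gray levels.
#'
#' @param W,H frame size in pixels (each at least 200).
#' @param water_code full water-color code of the rendered water.
#' @param gradient_amp peak-to-center amplitude of the spatial water color
#'   gradient, in L units.
#' @param n_foam number of disjoint foam blobs (may be 0).
#' @param foam_radius range of foam ellipse semi-axes, pixels.
#' @param waterwheel pixel rect `c(x1, y1, x2, y2)` (0-based half-open) or
#'   `NULL` for none; default scales with the frame.
#' @param board_homography 3x3 matrix mapping board coordinates (the
#'   layout's canvas frame) into the image, or `NULL` for the default
#'   upper-left similarity placement.
#' @param board logical; embed the checkerboard at all.
#' @param occlude_markers integer ids of board markers to paint over (for
#'   occlusion tests).
#' @param distortion invertible 3x3 Lab matrix applied to the whole frame
#'   (the "true" color distortion the correction stage must undo).
#' @param noise_sd per-channel Gaussian noise standard deviation (gray
#'   levels).
#' @param seed RNG seed; scenes are bit-reproducible given the spec.
#' @param layout a [checkerboard_layout()].
#' @param palette a [palette_config()] supplying the water color.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(W = 480L, H = 360L, water_code = "001-003",
                       gradient_amp = 4, n_foam = 3L,
                       foam_radius = c(6, 14), waterwheel = NULL,
                       board_homography = NULL, board = TRUE,
                       occlude_markers = integer(0),
                       distortion = diag(3), noise_sd = 2, seed = 1L,
                       layout = checkerboard_layout(),
                       palette = palette_config()) {
  stopifnot(W >= 200, H >= 200, water_code %in% palette$codes,
            n_foam >= 0, length(foam_radius) == 2L,
            identical(dim(distortion), c(3L, 3L)))
  if (abs(det(distortion)) < 1e-8) stop("distortion matrix must be invertible")
  if (is.null(waterwheel))
    waterwheel <- round(c(0.72 * W, 0.42 * H, 0.95 * W, 0.56 * H))
  if (is.null(board_homography) && board) {
    side <- round(0.52 * min(W, H))
    sc <- side / diff(layout$canvas)
    board_homography <- matrix(c(sc, 0, round(0.03 * W) - sc * layout$canvas[1],
                                 0, sc, round(0.02 * H) - sc * layout$canvas[1],
                                 0, 0, 1), 3, 3, byrow = TRUE)
  }
  structure(list(W = as.integer(W), H = as.integer(H),
                 water_code = water_code, gradient_amp = gradient_amp,
                 n_foam = as.integer(n_foam), foam_radius = foam_radius,
                 waterwheel = waterwheel,
                 board_homography = board_homography, board = board,
                 occlude_markers = as.integer(occlude_markers),
                 distortion = distortion, noise_sd = noise_sd,
                 seed = as.integer(seed), layout = layout,
                 palette = palette),
            class = "scene_spec")
}

# Board color at board-frame points (vectorized). Returns n x 3 RGB plus a
# logical inside-canvas flag.
.board_color <- function(bx, by, layout) {
  n <- length(bx)
  col <- matrix(250, n, 3)   # board background (near-white print margin)
  R <- layout$roi_size
  cw <- R / layout$ncol; ch <- R / layout$nrow
  in_grid <- bx >= 0 & bx < R & by >= 0 & by < R
  if (any(in_grid)) {
    cc <- pmin(floor(bx[in_grid] / cw), layout$ncol - 1)
    rr <- pmin(floor(by[in_grid] / ch), layout$nrow - 1)
    idx <- rr * layout$ncol + cc + 1
    col[in_grid, ] <- layout$ref_rgb[idx, , drop = FALSE]
  }
  s <- layout$marker_side
  for (k in seq_len(4)) {
    o <- layout$marker_corners[[k]][1, ]   # TL corner of the marker square
    inm <- bx >= o[1] & bx < o[1] + s & by >= o[2] & by < o[2] + s
    if (!any(inm)) next
    mi <- pmin(floor((by[inm] - o[2]) / s * 6), 5) + 1L
    mj <- pmin(floor((bx[inm] - o[1]) / s * 6), 5) + 1L
    bits <- marker_module(layout$marker_ids[k], mi, mj)
    col[inm, ] <- matrix(ifelse(rep(bits, 3) == 1L, 252, 3), ncol = 3)
  }
  col
}

#' Render a synthetic scene
#'
#' Renders the water field, waterwheel, foam blobs and (optionally) the
#' checkerboard, passes the whole frame through the spec's Lab distortion,
#' adds Gaussian noise, and returns the 8-bit image together with the exact
#' class mask and the spec as ground truth. Rendering is nearest-neighbor
#' (no anti-aliasing), so mask boundaries are exact.
#'
#' @param spec a [scene_spec()].
#' @return object of class `scene_bundle`: list with `image`, `mask`
#'   (a `class_mask`), `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  W <- spec$W; H <- spec$H
  xx <- matrix(rep(0:(W - 1), each = H), H, W)
  yy <- matrix(rep(0:(H - 1), W), H, W)

  # water field: palette color with a smooth Lab gradient
  base <- spec$palette$centroids[match(spec$water_code, spec$palette$codes), ]
  g <- spec$gradient_amp
  lab <- cbind(as.vector(base[1] + g * (yy / H - 0.5) * 2 +
                           0.4 * g * (xx / W - 0.5)),
               as.vector(base[2] + 0.2 * g * (xx / W - 0.5) * 2),
               as.vector(base[3] + 0.2 * g * (yy / H - 0.5) * 2))
  px <- lab_to_rgb(lab, round = FALSE)
  img <- array(px, c(H, W, 3))
  labels <- matrix(MASK_CLASSES[["water"]], H, W)

  # waterwheel: dark striped rectangle
  ww <- spec$waterwheel
  if (!is.null(ww)) {
    rows <- (ww[2] + 1):ww[4]; cols <- (ww[1] + 1):ww[3]
    stripe <- ((rows - 1) %/% 6) %% 2 == 0
    for (ch in 1:3) {
      block <- matrix(c(62, 64, 70)[ch], length(rows), length(cols))
      block[stripe, ] <- block[stripe, ] + 35
      img[rows, cols, ch] <- block
    }
    labels[rows, cols] <- MASK_CLASSES[["waterwheel"]]
  }

  # checkerboard under the placement homography (inverse-mapped, nearest)
  if (spec$board) {
    Hb <- spec$board_homography
    inv <- solve(Hb)
    bpts <- apply_homography(inv, cbind(as.vector(xx), as.vector(yy)))
    cv <- spec$layout$canvas
    inside <- bpts[, 1] >= cv[1] & bpts[, 1] <= cv[2] &
              bpts[, 2] >= cv[1] & bpts[, 2] <= cv[2]
    if (!any(inside)) stop("checkerboard placement falls outside the frame")
    bc <- .board_color(bpts[inside, 1], bpts[inside, 2], spec$layout)
    lin <- which(inside)
    if (!is.null(ww)) {
      ww_hit <- xx[lin] >= ww[1] & xx[lin] < ww[3] &
                yy[lin] >= ww[2] & yy[lin] < ww[4]
      if (any(ww_hit)) stop("checkerboard placement overlaps the waterwheel")
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[lin] <- bc[, ch]
      img[, , ch] <- plane
    }
    labels[lin] <- MASK_CLASSES[["checkerboard"]]
    # optional occlusion: paint selected markers with the water color
    for (id in spec$occlude_markers) {
      slot <- match(id, spec$layout$marker_ids)
      if (is.na(slot)) next
      mc <- spec$layout$marker_corners[[slot]]
      pad <- 4
      tl <- mc[1, ] - pad; br <- mc[3, ] + pad
      hit <- inside & bpts[, 1] >= tl[1] & bpts[, 1] <= br[1] &
                      bpts[, 2] >= tl[2] & bpts[, 2] <= br[2]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[which(hit)] <- lab_to_rgb(matrix(base, 1), round = FALSE)[ch]
        img[, , ch] <- plane
      }
    }
  }

  # foam blobs: bright ellipses in the lower two-thirds of the water
  placed <- list()
  if (spec$n_foam > 0L) {
    for (k in seq_len(spec$n_foam)) {
      ok <- FALSE
      for (try in seq_len(300)) {
        rx <- runif(1, spec$foam_radius[1], spec$foam_radius[2])
        ry <- runif(1, spec$foam_radius[1], spec$foam_radius[2])
        cx <- runif(1, rx + 2, W - rx - 3)
        cy <- runif(1, H / 3 + ry + 2, H - ry - 3)
        # bounding box (expanded: blobs must stay 8-disconnected)
        bb <- c(cx - rx - 2, cy - ry - 2, cx + rx + 2, cy + ry + 2)
        clash <- any(vapply(placed, function(p)
          bb[1] <= p[3] && bb[3] >= p[1] && bb[2] <= p[4] && bb[4] >= p[2],
          logical(1)))
        if (clash) next
        sel <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
        if (!any(sel)) next
        if (any(labels[sel] != MASK_CLASSES[["water"]])) next
        shade <- 228 + 18 * ((yy[sel] - cy) / ry)   # lit top, shaded bottom
        img[, , 1][sel] <- shade; img[, , 2][sel] <- shade + 2
        img[, , 3][sel] <- shade + 4
        labels[sel] <- MASK_CLASSES[["foam"]]
        placed[[length(placed) + 1L]] <- bb
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place foam blob ", k,
                    " without touching other objects")
    }
  }

  # global color distortion in Lab, then sensor noise
  if (!isTRUE(all.equal(spec$distortion, diag(3)))) {
    lab <- rgb_to_lab(.clamp(matrix(img, ncol = 3L), 0, 255))
    img <- array(lab_to_rgb(lab %*% t(spec$distortion), round = FALSE),
                 c(H, W, 3))
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- round(.clamp(img, 0, 255))

  structure(list(image = img, mask = class_mask(labels), spec = spec),
            class = "scene_bundle")
}

#' Write a scene bundle to disk
#'
#' Writes `<stem>.png` (image), `<stem>.mask.png` (class mask) and
#' `<stem>.truth.json` (water code, distortion, seed) into `dir`.
#'
#' @param bundle a `scene_bundle`.
#' @param dir output directory (created if needed).
#' @param stem file stem (default "scene").
#' @return the image path, invisibly.
#' @export
write_scene_bundle <- function(bundle, dir, stem = "scene") {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  write_image(bundle$image, img_path)
  write_mask(bundle$mask, file.path(dir, paste0(stem, ".mask.png")))
  truth <- list(water_code = bundle$spec$water_code,
                distortion = as.numeric(t(bundle$spec$distortion)),
                noise_sd = bundle$spec$noise_sd,
                seed = bundle$spec$seed)
  jsonlite::write_json(truth, file.path(dir, paste0(stem, ".truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(img_path)
}

#' Generate a labeled synthetic patch dataset
#'
#' For each of the 19 water-color codes, renders `n_per_class` square
#' patches at the class centroid color with a random-direction lightness
#' gradient and i.i.d. Gaussian channel noise. Deterministic under `seed`.
#'
#' @param palette a [palette_config()].
#' @param n_per_class patches per class.
#' @param noise_sd Gaussian channel noise (gray levels, default 8).
#' @param seed RNG seed.
#' @param w patch side in pixels (default 24).
#' @param gradient_amp maximum gradient amplitude in L units (default 3).
#' @return list with `patches` (list of w x w x 3 arrays) and `labels`
#'   (full code strings), class-balanced and interleaved by class.
#' @export
make_patch_dataset <- function(palette = palette_config(),
                               n_per_class = 200L, noise_sd = 8, seed = 1L,
                               w = 24L, gradient_amp = 3) {
  set.seed(seed)
  xx <- matrix(rep(0:(w - 1), each = w), w, w)
  yy <- matrix(rep(0:(w - 1), w), w, w)
  patches <- vector("list", 19L * n_per_class)
  labels <- character(19L * n_per_class)
  i <- 0L
  for (cls in seq_len(19)) {
    base <- palette$centroids[cls, ]
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      th <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0, gradient_amp)
      gfield <- amp * (cos(th) * (xx / w - 0.5) + sin(th) * (yy / w - 0.5)) * 2
      lab <- cbind(base[1] + as.vector(gfield), base[2], base[3])
      px <- lab_to_rgb(lab, round = FALSE) +
        matrix(rnorm(3 * w * w, 0, noise_sd), ncol = 3)
      patches[[i]] <- array(round(.clamp(px, 0, 255)), c(w, w, 3))
      labels[i] <- palette$codes[cls]
    }
  }
  list(patches = patches, labels = labels)
}

#' Write a patch dataset as a class-directory tree
#'
#' Layout: `dir/<full code>/0001.png`, one PNG per patch.
#'
#' @param ds dataset from [make_patch_dataset()].
#' @param dir output directory.
#' @export
write_patch_dataset <- function(ds, dir) {
  for (code in unique(ds$labels)) {
    d <- file.path(dir, code)
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    idx <- which(ds$labels == code)
    for (k in seq_along(idx))
      write_image(ds$patches[[idx[k]]], file.path(d, sprintf("%04d.png", k)))
  }
  invisible(dir)
}
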