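# Random sampling of square water patches in the lower two-thirds of the
# corrected frame, scored by the FIS; candidates above the threshold are
# collected until N are found.

#' Candidate extraction configuration
#'
#' Defaults follow the calibrated operating point: collect `N = 11`
#' candidates, keep the `N1 = 5` best, accept a patch when its fuzzy degree
#' exceeds `T = 0.5`, and use a patch side of one twentieth of the image
#' width (rounded to an even number of pixels so the sampled center maps to
#' integer corners).
#'
#' @param N number of candidates to collect.
#' @param N1 number of top-ranked patches kept for classification.
#' @param T acceptance threshold on the fuzzy degree, in (0, 1).
#' @param w patch side in pixels, or `NULL` to derive `round(W / 20)` from
#'   the image at extraction time.
#' @param max_attempts sampling cap before giving up (default `1000 * N`).
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(N = 11L, N1 = 5L, T = 0.5, w = NULL,
                              max_attempts = NULL) {
  stopifnot(N >= 1, N1 >= 1, N1 <= N, T > 0, T < 1,
            is.null(w) || w >= 4)
  structure(list(N = as.integer(N), N1 = as.integer(N1), T = T, w = w,
                 max_attempts = if (is.null(max_attempts)) 1000L * as.integer(N)
                                else as.integer(max_attempts)),
            class = "extraction_config")
}

.patch_side <- function(cfg, W) {
  w <- if (is.null(cfg$w)) round(W / 20) else cfg$w
  w <- max(4L, as.integer(round(w / 2) * 2))  # even, so w/2 is integral
  w
}

#' Mean and standard deviation of a gray patch
#'
#' Population statistics (divisor \eqn{w \times w}) of the pixel
#' intensities: \eqn{\sigma = \sqrt{\overline{f^2} - \mu^2}}. A small
#' \eqn{\sigma} means the patch is flat (textureless), the signature of an
#' undisturbed water surface.
#'
#' @param gray_patch numeric matrix of gray levels in \eqn{[0, 255]}.
#' @return named vector `c(mu, sigma)`.
#' @export
patch_stats <- function(gray_patch) {
  if (length(gray_patch) == 0L) stop("empty patch")
  if (any(gray_patch < 0 | gray_patch > 255))
    stop("gray levels must lie in [0, 255]")
  mu <- mean(gray_patch)
  sigma <- sqrt(max(0, mean(gray_patch^2) - mu^2))
  c(mu = mu, sigma = sigma)
}

#' Minimum distance from a patch to the foam contours
#'
#' Set-to-set Euclidean distance between the patch boundary pixels and the
#' contour pixels of any foam component; 0 when the patch overlaps foam,
#' `L1` when there is no foam at all (the maximal possible distance), and
#' the result is clamped to \eqn{[0, L1]}.
#'
#' @param rect integer vector `c(x1, y1, x2, y2)`, 0-based half-open pixel
#'   bounds of the patch.
#' @param foam a `foam_components` object.
#' @param L1 p1 domain upper bound (see [image_l1()]).
#' @return the scalar distance p1.
#' @export
min_foam_distance <- function(rect, foam, L1) {
  stopifnot(inherits(foam, "foam_components"), length(rect) == 4L)
  if (foam$K == 0L) return(L1)
  x1 <- rect[1]; y1 <- rect[2]; x2 <- rect[3]; y2 <- rect[4]
  # overlap: any foam pixel inside the rect
  allpix <- do.call(rbind, lapply(foam$components, `[[`, "pixels"))
  inside <- allpix[, 1] >= x1 & allpix[, 1] < x2 &
            allpix[, 2] >= y1 & allpix[, 2] < y2
  if (any(inside)) return(0)
  # patch boundary pixel centers
  xs <- x1:(x2 - 1L); ys <- y1:(y2 - 1L)
  bx <- c(xs, xs, rep(x1, length(ys) - 2L), rep(x2 - 1L, length(ys) - 2L))
  by <- c(rep(y1, length(xs)), rep(y2 - 1L, length(xs)),
          ys[-c(1L, length(ys))], ys[-c(1L, length(ys))])
  ct <- do.call(rbind, lapply(foam$components, `[[`, "contour"))
  d2min <- Inf
  for (i in seq_along(bx)) {
    d2 <- (ct[, 1] - bx[i])^2 + (ct[, 2] - by[i])^2
    m <- min(d2)
    if (m < d2min) d2min <- m
  }
  .clamp(sqrt(d2min), 0, L1)
}

#' Extract water-only candidate patches
#'
#' Repeats: sample a patch center uniformly in the lower two-thirds of the
#' frame (with w/2 margins); reject the patch outright if it covers any
#' non-water label; otherwise compute its foam distance p1 and intensity
#' deviation p2 and accept it when the fuzzy degree exceeds the threshold.
#' Stops when `cfg$N` candidates are collected.
#'
#' @param img corrected H x W x 3 image array in \eqn{[0, 255]}.
#' @param mask aligned `class_mask`.
#' @param cfg an [extraction_config()].
#' @param fis a [fis_config()] for this image size (defaults to
#'   `fis_config(image_l1(W, H))`).
#' @param rules a [rule_base()].
#' @param lut optional `fis_lut` fast path; when supplied, degrees come from
#'   the table instead of direct inference.
#' @return list of `cfg$N` candidate patches, each
#'   `list(rect, w, p1, p2, q)` with `rect = c(x1, y1, x2, y2)` 0-based
#'   half-open bounds.
#' @export
extract_candidates <- function(img, mask, cfg = extraction_config(),
                               fis = NULL, rules = rule_base(), lut = NULL) {
  .check_image(img)
  stopifnot(inherits(mask, "class_mask"))
  H <- dim(img)[1]; W <- dim(img)[2]
  if (!identical(dim(mask$labels), c(H, W)))
    stop("image and mask dimensions differ")
  if (is.null(fis)) fis <- fis_config(image_l1(W, H))
  w <- .patch_side(cfg, W)
  half <- w %/% 2L
  ylo <- ceiling(H / 3 + half)   # center bounds, 0-based coords
  yhi <- H - half
  xlo <- half; xhi <- W - half
  if (yhi < ylo || xhi < xlo)
    .aqua_stop("image too small for the configured patch size",
               "extraction_exhausted")
  gray <- round(luma(img))
  foam <- foam_components(mask)
  water <- mask$labels == MASK_CLASSES[["water"]]
  cands <- list()
  attempts <- 0L
  best_q <- -Inf
  while (length(cands) < cfg$N) {
    if (attempts >= cfg$max_attempts)
      .aqua_stop(sprintf(
        "candidate extraction exhausted after %d attempts (best degree %.3f)",
        attempts, if (is.finite(best_q)) best_q else NA_real_),
        "extraction_exhausted")
    attempts <- attempts + 1L
    x <- sample(xlo:xhi, 1L)
    y <- sample(ylo:yhi, 1L)
    x1 <- x - half; y1 <- y - half; x2 <- x1 + w; y2 <- y1 + w
    rows <- (y1 + 1L):y2; cols <- (x1 + 1L):x2
    if (!all(water[rows, cols])) next          # covers a non-water label
    p2 <- patch_stats(gray[rows, cols])[["sigma"]]
    p1 <- min_foam_distance(c(x1, y1, x2, y2), foam, fis$L1)
    q <- if (is.null(lut)) fis_degree(p1, p2, fis, rules)
         else lut_degree(lut, p1, p2)
    if (q > best_q) best_q <- q
    if (q > cfg$T) {
      cands[[length(cands) + 1L]] <-
        list(rect = c(x1, y1, x2, y2), w = w, p1 = p1, p2 = p2, q = q)
    }
  }
  cands
}

#' Rank candidates and keep the best
#'
#' Orders candidates by descending degree `q`; ties broken by larger foam
#' distance `p1`, then by sampling order. Returns the top `N1`.
#'
#' @param cands list of candidate patches from [extract_candidates()].
#' @param N1 number of patches to keep.
#' @return list of `N1` candidates.
#' @export
rank_candidates <- function(cands, N1 = 5L) {
  if (length(cands) < N1)
    stop("need at least N1 = ", N1, " candidates, got ", length(cands))
  qs <- vapply(cands, `[[`, numeric(1), "q")
  p1 <- vapply(cands, `[[`, numeric(1), "p1")
  ord <- order(-qs, -p1, seq_along(cands))
  cands[ord[seq_len(N1)]]
}

# Crop a candidate's pixels from an image.
crop_patch <- function(img, rect) {
  img[(rect[2] + 1L):rect[4], (rect[1] + 1L):rect[3], , drop = FALSE]
}
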