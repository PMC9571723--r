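test_that("all four board markers are detected with their ids", {
  b <- clean_scene()
  mk <- detect_markers(b$image)
  expect_length(mk, 4L)
  expect_setequal(vapply(mk, `[[`, integer(1), "id"), 0:3)
})

test_that("a blank image yields no detections", {
  blank <- array(255, c(220, 220, 3))
  expect_length(detect_markers(blank), 0L)
})

test_that("an occluded marker drops out but the rest still localize", {
  b <- cached("occluded", function()
    render_scene(scene_spec(seed = 7, noise_sd = 0, occlude_markers = 2L)))
  mk <- detect_markers(b$image)
  expect_length(mk, 3L)
  expect_setequal(vapply(mk, `[[`, integer(1), "id"), c(0L, 1L, 3L))
  # three markers give 12 correspondences: homography still estimable
  H <- estimate_roi_homography(mk, checkerboard_layout())
  blocks <- extract_block_colors(b$image, H, checkerboard_layout())
  expect_true(max(abs(blocks - checkerboard_layout()$ref_rgb)) <= 2)
})

test_that("homography estimation recovers known transforms from correspondences", {
  lay <- checkerboard_layout()
  pts <- do.call(rbind, lay$marker_corners)
  # markers already at canonical positions: identity
  mk <- lapply(1:4, function(k)
    list(id = lay$marker_ids[k], corners = lay$marker_corners[[k]]))
  H <- estimate_roi_homography(mk, lay)
  expect_lt(max(abs(H - diag(3))), 1e-6)
  # known projective warp, exact correspondences
  set.seed(21)
  for (i in 1:5) {
    Ht <- diag(3) + matrix(runif(9, -0.05, 0.05), 3, 3)
    Ht[3, 1:2] <- runif(2, -1e-4, 1e-4)
    Ht <- Ht / Ht[3, 3]
    warped <- aquacolor:::apply_homography(solve(Ht), pts)  # image pts
    mk2 <- lapply(1:4, function(k)
      list(id = lay$marker_ids[k], corners = warped[(4 * k - 3):(4 * k), ]))
    Hrec <- estimate_roi_homography(mk2, lay)
    nrm <- function(A) { A <- A / sqrt(sum(A^2)); A * sign(A[9]) }
    expect_lt(sqrt(sum((nrm(Hrec) - nrm(Ht))^2)), 1e-4)
  }
})

test_that("degenerate marker geometry raises a localization error", {
  lay <- checkerboard_layout()
  collinear <- lapply(1:4, function(k)
    list(id = lay$marker_ids[k],
         corners = cbind(seq(4 * k, 4 * k + 3), seq(4 * k, 4 * k + 3))))
  expect_error(estimate_roi_homography(collinear, lay),
               class = "localization_error")
  expect_error(estimate_roi_homography(list(), lay),
               class = "localization_error")
})

test_that("block colors of an undistorted board match the reference values", {
  b <- clean_scene()
  lay <- checkerboard_layout()
  H <- estimate_roi_homography(detect_markers(b$image), lay)
  blocks <- extract_block_colors(b$image, H, lay)
  expect_identical(nrow(blocks), 24L)
  expect_true(max(abs(blocks - lay$ref_rgb)) <= 2)
})

test_that("block colors follow a known color distortion", {
  b <- distorted_scene()
  lay <- checkerboard_layout()
  H <- estimate_roi_homography(detect_markers(b$image), lay)
  blocks <- extract_block_colors(b$image, H, lay)
  want <- lab_to_rgb(rgb_to_lab(lay$ref_rgb) %*% t(mild_distortion()))
  expect_true(max(abs(blocks - want)) <= 3)
})

test_that("block ordering is the fixed row-major bijection with the layout", {
  lay <- checkerboard_layout()
  lay$ref_rgb <- cbind(10 * (1:24), 250 - 10 * (1:24), (37 * (1:24)) %% 251)
  b <- render_scene(scene_spec(seed = 5, noise_sd = 0, n_foam = 0,
                               layout = lay))
  H <- estimate_roi_homography(detect_markers(b$image), lay)
  blocks <- extract_block_colors(b$image, H, lay)
  expect_true(max(abs(blocks - lay$ref_rgb)) <= 2)
})

test_that("block extraction is invariant to mild projective board placements", {
  lay <- checkerboard_layout()
  side <- 190; sc <- side / diff(lay$canvas)
  base <- matrix(c(sc, 0, 12 - sc * lay$canvas[1],
                   0, sc, 8 - sc * lay$canvas[1],
                   0, 0, 1), 3, 3, byrow = TRUE)
  set.seed(9)
  for (i in 1:3) {
    P <- diag(3)
    P[3, 1:2] <- runif(2, -2e-4, 2e-4)    # gentle perspective tilt
    b <- render_scene(scene_spec(seed = 30 + i, noise_sd = 0, n_foam = 0,
                                 board_homography = P %*% base))
    H <- estimate_roi_homography(detect_markers(b$image), lay)
    blocks <- extract_block_colors(b$image, H, lay)
    expect_true(max(abs(blocks - lay$ref_rgb)) <= 2)
  }
})
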