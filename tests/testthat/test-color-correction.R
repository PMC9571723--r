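ref_lab <- function() layout_ref_lab(checkerboard_layout())

test_that("the stacked system has the block-diagonal structure", {
  lab <- ref_lab()
  corr <- block_correspondence(lab, lab)
  sys <- build_lsq_system(corr)
  expect_identical(dim(sys$A), c(72L, 9L))
  expect_length(sys$d, 72L)
  expect_equal(sys$A[1, ], c(lab[1, ], 0, 0, 0, 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(sys$A[2, ], c(0, 0, 0, lab[1, ], 0, 0, 0),
               ignore_attr = TRUE)
  expect_equal(sys$d[1:3], as.numeric(lab[1, ]))
  expect_equal(sys$d[70:72], as.numeric(lab[24, ]))
  expect_error(block_correspondence(lab[1:10, ], lab), "24 x 3")
})

test_that("self-consistent measurements give the identity model", {
  lab <- ref_lab()
  model <- estimate_correction(block_correspondence(lab, lab))
  expect_lt(max(abs(model$M - diag(3))), 1e-8)
  expect_lt(model$residual, 1e-8)
})

test_that("noise-free linear distortions are inverted to machine precision", {
  lab <- ref_lab()
  set.seed(4)
  for (i in 1:10) {
    repeat {
      T_dist <- diag(3) + matrix(runif(9, -0.3, 0.3), 3, 3)
      if (rcond(T_dist) > 1e-3) break
    }
    model <- estimate_correction(
      block_correspondence(lab %*% t(T_dist), lab))
    expect_lt(max(abs(model$M - solve(T_dist))), 1e-6)
  }
})

test_that("estimation is robust to moderate measurement noise", {
  lab <- ref_lab()
  T_dist <- mild_distortion()
  Tinv <- solve(T_dist)
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    noisy <- lab %*% t(T_dist) + matrix(rnorm(72, 0, 0.5), 24, 3)
    model <- estimate_correction(block_correspondence(noisy, lab))
    worst <- max(worst, max(abs(model$M - Tinv)))
  }
  expect_lt(worst, 0.05)
})

test_that("degenerate block measurements raise an estimation error", {
  lab <- ref_lab()
  flat <- matrix(rep(lab[1, ], each = 24), 24, 3)  # all blocks identical
  expect_error(estimate_correction(block_correspondence(flat, lab)),
               class = "estimation_error")
})

test_that("correction on the blocks never increases the stacked residual", {
  lab <- ref_lab()
  set.seed(31)
  for (i in 1:20) {
    noisy <- lab %*% t(diag(3) + matrix(runif(9, -0.2, 0.2), 3, 3)) +
      matrix(rnorm(72, 0, 1), 24, 3)
    model <- estimate_correction(block_correspondence(noisy, lab))
    rms <- function(x) sqrt(mean(rowSums(x^2)))
    expect_lte(rms(noisy %*% t(model$M) - lab), rms(noisy - lab) + 1e-12)
  }
})

test_that("identity model application is the identity within rounding", {
  img <- clean_scene()$image[1:60, 1:80, , drop = FALSE]
  ident <- structure(list(M = diag(3), residual = 0),
                     class = "correction_model")
  out <- apply_correction(img, ident)
  expect_identical(dim(out), dim(img))
  expect_true(max(abs(out - img)) <= 1)
})

test_that("an estimated model restores distorted block colors end to end", {
  b <- distorted_scene()
  lay <- checkerboard_layout()
  res <- correct_image(b$image, lay)
  H <- estimate_roi_homography(detect_markers(res$image), lay)
  blocks <- extract_block_colors(res$image, H, lay)
  expect_true(max(abs(blocks - lay$ref_rgb)) <= 3)
  # corrected chromaticities are closer to the reference in the a-b plane
  ab_dist <- function(rgb) {
    lab <- rgb_to_lab(rgb)
    mean(sqrt(rowSums((lab[, 2:3] - ref_lab()[, 2:3])^2)))
  }
  expect_lt(ab_dist(blocks), ab_dist(res$blocks))
})

test_that("full correction of an identity scene is close to the identity", {
  res <- correct_image(clean_scene()$image)
  expect_lt(max(abs(res$model$M - diag(3))), 0.05)
  expect_lt(res$model$residual, 1.5)
})

test_that("a scene without a checkerboard fails with a localization error", {
  b <- cached("noboard", function()
    render_scene(scene_spec(seed = 13, board = FALSE)))
  expect_error(correct_image(b$image), class = "localization_error")
})

test_that("a correction model survives JSON serialization", {
  lab <- ref_lab()
  model <- estimate_correction(
    block_correspondence(lab %*% t(mild_distortion()), lab))
  path <- withr::local_tempfile(fileext = ".json")
  write_correction_model(model, path)
  back <- read_correction_model(path)
  expect_equal(back$M, model$M, tolerance = 1e-12)
  expect_equal(back$residual, model$residual, tolerance = 1e-12)
})
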