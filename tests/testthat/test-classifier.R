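solid_patch <- function(rgb, w = 16) {
  array(rep(rgb, each = w * w), c(w, w, 3))
}

test_that("patches at palette centroids are classified as that code", {
  pal <- palette_config()
  for (i in c(1, 5, 12, 19)) {
    rgb <- lab_to_rgb(pal$centroids[i, , drop = FALSE], round = FALSE)
    out <- classify_nearest(solid_patch(rgb), pal)
    expect_identical(out$code, pal$codes[i])
    expect_identical(names(which.max(out$probs)), pal$codes[i])
    expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  }
})

test_that("a patch equidistant from two centroids splits their probability", {
  pal <- palette_config()
  mid_rgb <- c(120, 140, 120)
  mid <- rgb_to_lab(mid_rgb)
  delta <- c(0, 8, 0)
  pal$centroids[1, ] <- mid + delta
  pal$centroids[2, ] <- mid - delta
  out <- classify_nearest(solid_patch(mid_rgb), pal)
  expect_lt(abs(out$probs[[1]] - out$probs[[2]]), 1e-9)
})

test_that("patches far from every centroid are unknown", {
  pal <- palette_config()
  far <- solid_patch(c(255, 0, 255))  # saturated magenta: off-palette
  d <- sqrt(rowSums(sweep(pal$centroids, 2,
                          as.numeric(rgb_to_lab(c(255, 0, 255))))^2))
  expect_gt(min(d), max(pal$radius))  # sanity: genuinely out of tolerance
  expect_identical(classify_nearest(far, pal)$code, "unknown")
})

test_that("nearest-centroid is perfect on noise-free centroid patches", {
  pal <- palette_config()
  ds <- make_patch_dataset(pal, n_per_class = 3, noise_sd = 0, seed = 2,
                           gradient_amp = 0)
  got <- vapply(ds$patches, function(p) classify_nearest(p, pal)$code,
                character(1))
  expect_identical(got, ds$labels)
})

test_that("fitted centroids classify held-out noisy patches", {
  pal <- palette_config()
  ds <- make_patch_dataset(pal, n_per_class = 30, noise_sd = 8, seed = 5)
  n <- length(ds$labels)
  set.seed(1)
  hold <- sample.int(n, round(0.2 * n))
  fitted <- fit_palette(ds$patches[-hold], ds$labels[-hold])
  got <- vapply(ds$patches[hold], function(p) classify_nearest(p, fitted)$code,
                character(1))
  expect_gte(mean(got == ds$labels[hold]), 0.96)
})

test_that("the compact trainable network learns the palette", {
  ds <- make_patch_dataset(n_per_class = 25, noise_sd = 8, seed = 9)
  net <- train_color_net(ds$patches, ds$labels, seed = 3)
  expect_gte(net$val_accuracy, 0.9)
  out <- classify_net(net, ds$patches[[1]])
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_identical(out$code, ds$labels[1])
  expect_error(train_color_net(ds$patches[1:2], c("001-001", "999-999")),
               "outside")
})

test_that("confusion matrix rows are normalized", {
  truth <- rep(water_color_codes()$code, each = 3)
  pred <- truth
  pred[1] <- "unknown"
  cm <- confusion_matrix(pred, truth)
  expect_equal(unname(rowSums(cm)), rep(1, 19), tolerance = 1e-6)
})

test_that("representative color voting follows majority, mode, confidence", {
  out <- function(code, conf) structure(
    list(probs = NULL, code = code, confidence = conf),
    class = "classifier_output")
  # strict majority
  expect_identical(representative_color(list(out("001-003", .9), out("001-003", .8),
                                             out("001-003", .7), out("002-001", .95),
                                             out("004-001", .99))), "001-003")
  # unanimity
  expect_identical(representative_color(rep(list(out("005-002", .5)), 5)),
                   "005-002")
  # modal without majority
  expect_identical(representative_color(list(out("001-001", .6), out("001-001", .6),
                                             out("002-002", .7), out("003-003", .7),
                                             out("004-004", .7))), "001-001")
  # tie on frequency: highest confidence wins
  expect_identical(representative_color(list(out("001-001", .6), out("001-001", .7),
                                             out("002-002", .8), out("002-002", .95),
                                             out("003-003", .5))), "002-002")
  expect_error(representative_color(list()), "no classifier outputs")
})

test_that("voting is permutation invariant and majority implies modal", {
  out <- function(code, conf) structure(
    list(probs = NULL, code = code, confidence = conf),
    class = "classifier_output")
  set.seed(23)
  codes_pool <- water_color_codes()$code[1:4]
  for (i in 1:25) {
    os <- lapply(1:5, function(j)
      out(sample(codes_pool, 1), runif(1)))
    base <- representative_color(os)
    for (k in 1:5)
      expect_identical(representative_color(sample(os)), base)
    counts <- table(vapply(os, `[[`, character(1), "code"))
    if (max(counts) > 2.5)  # strict majority present: must pick the mode
      expect_identical(base, names(which.max(counts)))
  }
})
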