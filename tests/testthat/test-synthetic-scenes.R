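test_that("a clean render reproduces the reference board colors exactly", {
  b <- clean_scene()
  lay <- checkerboard_layout()
  # use the generator's own placement homography: board -> image, so the
  # image -> ROI map is its inverse
  H <- solve(b$spec$board_homography)
  blocks <- extract_block_colors(b$image, H, lay)
  expect_true(max(abs(blocks - lay$ref_rgb)) <= 1)
})

test_that("foam blob count and classes match the spec", {
  b <- clean_scene()
  expect_identical(foam_components(b$mask)$K, b$spec$n_foam)
  expect_setequal(unique(as.vector(b$mask$labels)),
                  unname(MASK_CLASSES[c("water", "waterwheel",
                                        "checkerboard", "foam")]))
  # declared water pixels never carry board background color
  wsel <- b$mask$labels == MASK_CLASSES[["water"]]
  expect_false(any(b$image[, , 1][wsel] == 250 &
                   b$image[, , 2][wsel] == 250 &
                   b$image[, , 3][wsel] == 250))
})

test_that("rendering is bit-reproducible under a fixed seed", {
  sp <- scene_spec(seed = 77, noise_sd = 3)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask$labels, b$mask$labels)
  c2 <- render_scene(scene_spec(seed = 78, noise_sd = 3))
  expect_false(identical(a$image, c2$image))
})

test_that("distortion followed by estimated correction restores the blocks", {
  b <- distorted_scene()
  res <- correct_image(b$image)
  lay <- checkerboard_layout()
  H <- estimate_roi_homography(detect_markers(res$image), lay)
  expect_true(max(abs(extract_block_colors(res$image, H, lay) -
                        lay$ref_rgb)) <= 3)
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(water_code = "nope"))
  expect_error(scene_spec(distortion = matrix(0, 3, 3)), "invertible")
  # waterwheel under the board placement collides
  expect_error(render_scene(scene_spec(seed = 1,
                                       waterwheel = c(20, 20, 120, 80))),
               "overlaps")
})

test_that("scene bundles round-trip through the file formats", {
  dir <- withr::local_tempdir()
  b <- clean_scene()
  write_scene_bundle(b, dir, "f1")
  img <- read_image(file.path(dir, "f1.png"))
  expect_equal(img, b$image, ignore_attr = TRUE)
  m <- load_mask(file.path(dir, "f1.mask.png"))
  expect_identical(m$labels, b$mask$labels)
  truth <- jsonlite::read_json(file.path(dir, "f1.truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$water_code, b$spec$water_code)
})

test_that("the patch dataset is balanced, deterministic and separable", {
  ds <- make_patch_dataset(n_per_class = 4, noise_sd = 8, seed = 31)
  expect_length(ds$patches, 19L * 4L)
  expect_true(all(table(ds$labels) == 4L))
  again <- make_patch_dataset(n_per_class = 4, noise_sd = 8, seed = 31)
  expect_identical(ds, again)
  clean <- make_patch_dataset(n_per_class = 2, noise_sd = 0, seed = 1,
                              gradient_amp = 0)
  got <- vapply(clean$patches, function(p) classify_nearest(p)$code,
                character(1))
  expect_identical(got, clean$labels)
})
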