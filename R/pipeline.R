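# End-to-end orchestration: correct -> mask -> extract candidates -> rank
# -> classify -> vote -> report; plus a batch mode over paired files.

#' Pipeline configuration
#'
#' Bundles the per-stage settings. `classifier` is either `"nearest"` (the
#' deterministic nearest-centroid default) or a trained `color_net`;
#' `use_lut` enables the precomputed FIS lookup table fast path.
#'
#' @param layout a [checkerboard_layout()].
#' @param palette a [palette_config()].
#' @param extraction an [extraction_config()].
#' @param rules a [rule_base()].
#' @param alpha1,alpha2 FIS antecedent peak vectors (see [fis_config()]).
#' @param classifier `"nearest"` or a `color_net`.
#' @param use_lut logical; score patches through a lookup table.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(layout = checkerboard_layout(),
                            palette = palette_config(),
                            extraction = extraction_config(),
                            rules = rule_base(),
                            alpha1 = c(0, 25, 50, 75, 100),
                            alpha2 = c(0, 45, 90, 135, 180),
                            classifier = "nearest", use_lut = FALSE) {
  structure(list(layout = layout, palette = palette,
                 extraction = extraction, rules = rules,
                 alpha1 = alpha1, alpha2 = alpha2,
                 classifier = classifier, use_lut = isTRUE(use_lut)),
            class = "pipeline_config")
}

#' Load pipeline settings from a YAML file
#'
#' Recognized top-level keys (all optional; missing keys keep defaults):
#' `extraction` (n_candidates, n_keep, threshold, patch_w, max_attempts),
#' `fis` (alpha1, alpha2), `rules` (5x5 grid of term strings, rows = p2
#' terms), `palette` (path to a palette YAML), `classifier` ("nearest"),
#' `use_lut`, `layout` (marker_ids, roi_size, marker_side, marker_margin,
#' sample_frac). Key names deliberately avoid YAML 1.1 boolean literals
#' (`N`, `T`, ...).
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ex <- y[["extraction"]]
  extraction <- extraction_config(
    N = ex[["n_candidates"]] %||% 11L, N1 = ex[["n_keep"]] %||% 5L,
    T = ex[["threshold"]] %||% 0.5,
    w = ex[["patch_w"]], max_attempts = ex[["max_attempts"]])
  rules <- if (!is.null(y[["rules"]]))
    rule_base(matrix(unlist(y[["rules"]]), 5, 5, byrow = TRUE))
  else rule_base()
  palette <- if (!is.null(y[["palette"]])) read_palette_yaml(y[["palette"]])
             else palette_config()
  lo <- y[["layout"]]
  layout <- checkerboard_layout(
    roi_size = lo[["roi_size"]] %||% 200,
    marker_side = lo[["marker_side"]] %||% 48,
    marker_margin = lo[["marker_margin"]] %||% 12,
    marker_ids = lo[["marker_ids"]] %||% 0:3,
    sample_frac = lo[["sample_frac"]] %||% 0.5)
  pipeline_config(layout = layout, palette = palette,
                  extraction = extraction, rules = rules,
                  alpha1 = y[["fis"]][["alpha1"]] %||% c(0, 25, 50, 75, 100),
                  alpha2 = y[["fis"]][["alpha2"]] %||% c(0, 45, 90, 135, 180),
                  classifier = y[["classifier"]] %||% "nearest",
                  use_lut = y[["use_lut"]] %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.classify_patch <- function(patch, config) {
  if (inherits(config$classifier, "color_net"))
    classify_net(config$classifier, patch)
  else classify_nearest(patch, config$palette)
}

#' Run the full water-color identification pipeline on one frame
#'
#' Executes the four stages in order — color correction against the embedded
#' checkerboard, mask loading, candidate patch extraction on the corrected
#' frame, and classification plus representative-color voting. A failure in
#' any stage yields a structured error report tagged with the stage name
#' instead of a partial color.
#'
#' @param image H x W x 3 array or path to a PNG.
#' @param mask `class_mask` or path to a mask PNG.
#' @param config a [pipeline_config()].
#' @param seed RNG seed for the patch sampling.
#' @param timestamp report timestamp string; pass a fixed value for
#'   bit-reproducible reports.
#' @return object of class `pipeline_report` (JSON-serializable list). On
#'   success it carries `representative` plus per-stage records; on failure
#'   an `error` element `list(stage, message)`.
#' @export
run_pipeline <- function(image, mask, config = pipeline_config(), seed = 1L,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) {
  input_path <- if (is.character(image)) image else NA_character_
  report <- list(input = input_path, seed = as.integer(seed),
                 timestamp = timestamp,
                 config = list(
                   N = config$extraction$N, N1 = config$extraction$N1,
                   T = config$extraction$T,
                   classifier = if (is.character(config$classifier))
                     config$classifier else "color_net",
                   use_lut = config$use_lut))
  fail <- function(stage, e) {
    report$error <- list(stage = stage, message = conditionMessage(e))
    structure(report, class = "pipeline_report")
  }

  # stage 1: color correction
  res <- tryCatch({
    img <- if (is.character(image)) read_image(image) else image
    corr <- correct_image(img, config$layout)
    list(img = corr$image, model = corr$model)
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail("correction", res))
  img <- res$img
  report$correction_residual <- res$model$residual
  report$correction_matrix <- as.numeric(t(res$model$M))

  # stage 2: segmentation mask
  msk <- tryCatch({
    if (is.character(mask)) load_mask(mask, expected_shape = dim(img)[1:2])
    else mask
  }, error = function(e) e)
  if (inherits(msk, "error")) return(fail("segmentation", msk))

  # stage 3: candidate extraction on the corrected frame
  sel <- tryCatch({
    H <- dim(img)[1]; W <- dim(img)[2]
    fis <- fis_config(image_l1(W, H), alpha1 = config$alpha1,
                      alpha2 = config$alpha2)
    lut <- if (config$use_lut) build_lut(fis, config$rules) else NULL
    set.seed(seed)
    cands <- extract_candidates(img, msk, config$extraction, fis,
                                config$rules, lut)
    list(cands = cands,
         top = rank_candidates(cands, config$extraction$N1))
  }, error = function(e) e)
  if (inherits(sel, "error")) return(fail("extraction", sel))
  report$candidates <- lapply(sel$cands, function(cn)
    list(rect = cn$rect, p1 = cn$p1, p2 = cn$p2, q = cn$q))

  # stage 4: classification and vote
  out <- tryCatch({
    outputs <- lapply(sel$top, function(cn)
      .classify_patch(crop_patch(img, cn$rect), config))
    list(outputs = outputs, code = representative_color(outputs))
  }, error = function(e) e)
  if (inherits(out, "error")) return(fail("classification", out))
  report$selected <- mapply(function(cn, o) {
    list(rect = cn$rect, q = cn$q, code = o$code,
         confidence = o$confidence, probs = as.list(o$probs))
  }, sel$top, out$outputs, SIMPLIFY = FALSE)
  report$representative <- out$code
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  if (!is.null(x$error)) {
    cat("pipeline FAILED at stage '", x$error$stage, "': ",
        x$error$message, "\n", sep = "")
  } else {
    cat("representative water color: ", x$representative,
        " (correction residual ", format(x$correction_residual, digits = 3),
        ", ", length(x$candidates), " candidates)\n", sep = "")
  }
  invisible(x)
}

#' Serialize / restore a pipeline report as JSON
#'
#' Numbers are written at full precision so a report round-trips exactly.
#'
#' @param report a `pipeline_report`.
#' @param path JSON file path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
            class = "pipeline_report")
}

#' Run the pipeline over a directory of paired frames
#'
#' Processes every `*.png` in `dir` (excluding `*.mask.png`) with its paired
#' `<stem>.mask.png`. Per-file errors are recorded in the corresponding
#' report and the batch continues. Per-frame seeds are derived as
#' `seed + frame index - 1`.
#'
#' @param dir directory of image/mask pairs.
#' @param config a [pipeline_config()].
#' @param seed base RNG seed.
#' @param csv optional path of the per-frame summary CSV (file, code,
#'   error).
#' @return list with `reports` (named by file) and `summary` (data frame).
#' @export
run_batch <- function(dir, config = pipeline_config(), seed = 1L,
                      csv = NULL) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  files <- files[!grepl("\\.mask\\.png$", files)]
  files <- sort(files)
  reports <- vector("list", length(files))
  names(reports) <- basename(files)
  for (i in seq_along(files)) {
    mask_path <- sub("\\.png$", ".mask.png", files[i])
    reports[[i]] <- if (!file.exists(mask_path)) {
      structure(list(input = files[i],
                     error = list(stage = "segmentation",
                                  message = "missing mask file")),
                class = "pipeline_report")
    } else {
      run_pipeline(files[i], mask_path, config, seed = seed + i - 1L)
    }
  }
  summary <- data.frame(
    file = basename(files),
    code = vapply(reports, function(r) r$representative %||% NA_character_,
                  character(1)),
    error = vapply(reports, function(r)
      if (is.null(r$error)) NA_character_ else r$error$stage, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(csv)) write.csv(summary, csv, row.names = FALSE)
  list(reports = reports, summary = summary)
}
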