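# The 19 standard water-color codes and the default Lab palette.
#
# The coding scheme is the two-part FA-COA water-color code: six major
# colors (green 001, brown 002, red 003, yellow 004, dark 005, blue 006)
# subdivided into 19 categories. The regulation fixes the names but not
# numeric color definitions, so the default centroids below are
# hand-assigned Lab values consistent with the category names; they are
# fully user-overridable (see `palette_config`).

.WATER_CODES <- data.frame(
  index = 1:19,
  major = c(rep("Green", 4), rep("Brown", 3), rep("Red", 4),
            rep("Yellow", 4), rep("Dark", 3), "Blue"),
  name = c("Blue-green", "Dark green", "Green", "Light green",
           "Dark brown", "Brown", "Light brown",
           "Dark red", "Pink", "Light red", "Red",
           "Tawny", "Dark yellow", "Light yellow", "Yellow",
           "Dark gray", "Dark", "Gray", "Blue"),
  code = c("001-001", "001-002", "001-003", "001-004",
           "002-001", "002-002", "002-003",
           "003-001", "003-002", "003-003", "003-004",
           "004-001", "004-002", "004-003", "004-004",
           "005-001", "005-002", "005-003", "006-001"),
  stringsAsFactors = FALSE)

.DEFAULT_PALETTE_RGB <- matrix(c(
   30, 140, 130,   #  001-001 blue-green
   25,  95,  35,   #  001-002 dark green
   60, 150,  60,   #  001-003 green
  150, 215, 140,   #  001-004 light green
   95,  65,  30,   #  002-001 dark brown
  150, 105,  60,   #  002-002 brown
  195, 155, 115,   #  002-003 light brown
  140,  25,  25,   #  003-001 dark red
  250, 180, 190,   #  003-002 pink
  235, 130, 125,   #  003-003 light red
  215,  45,  60,   #  003-004 red
  200, 130,  55,   #  004-001 tawny
  180, 155,  25,   #  004-002 dark yellow
  245, 240, 150,   #  004-003 light yellow
  245, 210,  30,   #  004-004 yellow
   90,  90,  92,   #  005-001 dark gray
   40,  40,  42,   #  005-002 dark
  155, 155, 155,   #  005-003 gray
   60, 100, 180),  #  006-001 blue
  ncol = 3, byrow = TRUE)

#' Water-color code table
#'
#' @return data frame of the 19 categories: `index`, `major`, `name`,
#'   `code` (full "MMM-SSS" string).
#' @export
water_color_codes <- function() .WATER_CODES

#' Palette of nominal class colors
#'
#' One Lab centroid plus tolerance radius per water-color code. The
#' defaults are hand-assigned values consistent with the category names; any
#' site can override them (e.g. from YAML, see [read_palette_yaml()]).
#'
#' @param centroids 19 x 3 matrix of Lab centroids (rows in code order).
#' @param radius tolerance radius (Lab units); a patch farther than this
#'   from every centroid is classified "unknown". Scalar or length 19.
#' @return object of class `palette_config`.
#' @export
palette_config <- function(centroids = rgb_to_lab(.DEFAULT_PALETTE_RGB),
                           radius = 30) {
  centroids <- as.matrix(centroids)
  stopifnot(identical(dim(centroids), c(19L, 3L)))
  radius <- rep_len(radius, 19L)
  d <- as.matrix(dist(centroids))
  diag(d) <- Inf
  if (min(d) <= 5)
    stop("palette centroids too close: min pairwise Lab distance ",
         format(min(d), digits = 3), " <= 5")
  structure(list(codes = .WATER_CODES$code, names = .WATER_CODES$name,
                 centroids = centroids, radius = radius),
            class = "palette_config")
}

#' Read / write a palette as YAML
#'
#' The YAML maps each full code to `name`, `lab` (length-3) and `radius`.
#'
#' @param path YAML file path.
#' @param palette a `palette_config`.
#' @export
write_palette_yaml <- function(palette, path) {
  entries <- lapply(seq_len(19), function(i)
    list(name = palette$names[i],
         lab = as.numeric(palette$centroids[i, ]),
         radius = palette$radius[i]))
  names(entries) <- palette$codes
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_palette_yaml
#' @export
read_palette_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  stopifnot(identical(sort(names(entries)), sort(.WATER_CODES$code)))
  ord <- match(.WATER_CODES$code, names(entries))
  centroids <- t(vapply(entries[ord], function(e) as.numeric(e$lab),
                        numeric(3)))
  radius <- vapply(entries[ord], function(e) as.numeric(e$radius),
                   numeric(1))
  palette_config(centroids = centroids, radius = radius)
}

#' Fit palette centroids from labeled patches
#'
#' Replaces the nominal centroids by the per-class mean patch Lab colors of
#' a training set; the plain "training" step of the nearest-centroid
#' classifier.
#'
#' @param patches list of H x W x 3 patch arrays.
#' @param labels character vector of full codes, parallel to `patches`.
#' @param radius tolerance radius passed through to [palette_config()].
#' @return a fitted `palette_config`.
#' @export
fit_palette <- function(patches, labels, radius = 30) {
  stopifnot(length(patches) == length(labels),
            all(labels %in% .WATER_CODES$code))
  feats <- t(vapply(patches, function(p)
    as.numeric(rgb_to_lab(colMeans(matrix(p, ncol = 3L)))), numeric(3)))
  centroids <- matrix(NA_real_, 19, 3)
  for (i in seq_len(19)) {
    sel <- labels == .WATER_CODES$code[i]
    if (!any(sel))
      stop("no training patches for class ", .WATER_CODES$code[i])
    centroids[i, ] <- colMeans(feats[sel, , drop = FALSE])
  }
  palette_config(centroids = centroids, radius = radius)
}
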