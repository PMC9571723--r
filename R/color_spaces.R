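# RGB -> XYZ transfer matrix (sRGB primaries, D65), applied directly to
# channel values scaled to [0, 1]; no gamma linearization.
.RGB2XYZ <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227), nrow = 3, byrow = TRUE)

.XYZ2RGB <- solve(.RGB2XYZ)

# Reference white used throughout the Lab conversions.
.WHITE <- c(Xn = 0.9515, Yn = 1.0, Zn = 1.0886)

.LAB_EPS <- 0.008856          # cube-root / linear branch threshold on v
.LAB_KAPPA <- 7.787037        # slope of the linear branch
.LAB_FEPS <- 0.008856^(1 / 3) # f(eps): branch threshold on f-values

.as_color_matrix <- function(x, what = "color") {
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop(what, " must have 3 channels, got length ", length(x))
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 3L)
      stop(what, " matrix must have 3 columns, got ", ncol(x))
    storage.mode(x) <- "double"
  }
  if (any(!is.finite(x))) stop("non-finite ", what, " values")
  x
}

#' Convert RGB colors to CIE XYZ tristimulus values
#'
#' Applies the fixed sRGB/D65 3x3 matrix to channel values scaled to
#' \eqn{[0, 1]}. The camera response is taken as already linear: no gamma
#' transfer function is applied.
#'
#' @param rgb numeric vector of length 3 or an n x 3 matrix, channels in
#'   \eqn{[0, 255]}.
#' @return an n x 3 matrix of XYZ tristimulus values (dimensionless).
#' @examples
#' rgb_to_xyz(c(255, 255, 255))
#' @export
rgb_to_xyz <- function(rgb) {
  rgb <- .as_color_matrix(rgb, "RGB")
  if (any(rgb < 0 | rgb > 255))
    stop("RGB channels must lie in [0, 255]")
  out <- (rgb / 255) %*% t(.RGB2XYZ)
  colnames(out) <- c("X", "Y", "Z")
  out
}

.lab_f <- function(v) {
  ifelse(v > .LAB_EPS, v^(1 / 3), .LAB_KAPPA * v + 16 / 116)
}

.lab_f_inv <- function(t) {
  ifelse(t > .LAB_FEPS, t^3, (t - 16 / 116) / .LAB_KAPPA)
}

#' Convert CIE XYZ to CIE Lab
#'
#' Uses the reference white (Xn, Yn, Zn) = (0.9515, 1.0, 1.0886) and the
#' piecewise cube-root compression with linear branch below v = 0.008856.
#' Lightness is \eqn{L = 116 f(Y/Yn) - 16}, so black maps to L = 0 and the
#' reference white to L = 100.
#'
#' @param xyz numeric vector of length 3 or an n x 3 matrix of non-negative
#'   tristimulus values.
#' @return an n x 3 matrix with columns L, a, b.
#' @export
xyz_to_lab <- function(xyz) {
  xyz <- .as_color_matrix(xyz, "XYZ")
  if (any(xyz < 0))
    stop("negative tristimulus values are outside the Lab domain")
  fx <- .lab_f(xyz[, 1] / .WHITE[["Xn"]])
  fy <- .lab_f(xyz[, 2] / .WHITE[["Yn"]])
  fz <- .lab_f(xyz[, 3] / .WHITE[["Zn"]])
  out <- cbind(L = 116 * fy - 16,
               a = 500 * (fx - fy),
               b = 200 * (fy - fz))
  dimnames(out) <- list(NULL, c("L", "a", "b"))
  out
}

#' Convert RGB to CIE Lab
#'
#' Composition of [rgb_to_xyz()] and [xyz_to_lab()]; the working conversion of
#' the whole correction pipeline.
#'
#' @inheritParams rgb_to_xyz
#' @return an n x 3 matrix with columns L, a, b.
#' @export
rgb_to_lab <- function(rgb) {
  xyz_to_lab(rgb_to_xyz(rgb))
}

#' Convert CIE Lab back to XYZ
#'
#' Exact inverse of [xyz_to_lab()]; the branch of the inverse compression is
#' chosen by the f-value threshold \eqn{f(0.008856) \approx 0.2069}.
#' Out-of-gamut Lab values may yield negative tristimulus values; they are
#' passed through and only clamped at the RGB stage.
#'
#' @param lab numeric vector of length 3 or an n x 3 matrix (L, a, b).
#' @return an n x 3 matrix of XYZ values.
#' @export
lab_to_xyz <- function(lab) {
  lab <- .as_color_matrix(lab, "Lab")
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  out <- cbind(X = .WHITE[["Xn"]] * .lab_f_inv(fx),
               Y = .WHITE[["Yn"]] * .lab_f_inv(fy),
               Z = .WHITE[["Zn"]] * .lab_f_inv(fz))
  dimnames(out) <- list(NULL, c("X", "Y", "Z"))
  out
}

#' Convert CIE Lab to 8-bit RGB
#'
#' Inverts the forward path (inverse compression, inverse transfer matrix),
#' scales to \eqn{[0, 255]}, clamps out-of-gamut channels and rounds to
#' integers. Clamping means any finite Lab triple is accepted.
#'
#' @inheritParams lab_to_xyz
#' @param round logical; round to integer channel values (default `TRUE`).
#' @return an n x 3 matrix with columns R, G, B in \eqn{[0, 255]}.
#' @export
lab_to_rgb <- function(lab, round = TRUE) {
  xyz <- lab_to_xyz(lab)
  rgb <- xyz %*% t(.XYZ2RGB) * 255
  rgb[rgb < 0] <- 0
  rgb[rgb > 255] <- 255
  if (round) rgb <- round(rgb)
  colnames(rgb) <- c("R", "G", "B")
  rgb
}
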