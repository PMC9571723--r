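# Mamdani fuzzy inference system scoring how strongly a patch qualifies as a
# water-only candidate: antecedents p1 (minimum distance to foam contours,
# pixels) and p2 (patch intensity standard deviation, gray levels),
# consequent q in [0, 1]. Min conjunction, max aggregation, centroid
# (center-of-gravity) defuzzification on a fixed midpoint grid.

.FIS_TERMS <- c("VS", "S", "M", "L", "VL")

#' Fuzzy inference configuration
#'
#' Five fuzzy sets per antecedent with peaks at `alpha1` / `alpha2`
#' (trapezoidal shoulders at the domain ends, triangles in between). The
#' defaults are the calibrated peak parameters (0, 25, 50, 75, 100) pixels
#' for the foam distance and (0, 45, 90, 135, 180) gray levels for the
#' intensity deviation; `L1`, the p1 domain upper end, is the diagonal of
#' the lower two-thirds of the image and must be supplied per image size.
#' The consequent universe is \eqn{[0, 1]} with five equally spaced sets
#' peaking at 0, 0.25, 0.5, 0.75, 1: interior sets are triangles over
#' adjacent peaks and the end sets are shoulders, mirroring the antecedent
#' shapes.
#'
#' @param L1 upper end of the p1 domain (pixels); diagonal of the lower
#'   two-thirds of the frame, see [image_l1()].
#' @param alpha1,alpha2 strictly increasing length-5 peak vectors with
#'   first element 0.
#' @param n_grid number of midpoint-rule integration points on \eqn{[0, 1]}
#'   used for the centroid (default 1001).
#' @return object of class `fis_config`.
#' @export
fis_config <- function(L1, alpha1 = c(0, 25, 50, 75, 100),
                       alpha2 = c(0, 45, 90, 135, 180), n_grid = 1001L) {
  stopifnot(length(alpha1) == 5L, length(alpha2) == 5L,
            all(diff(alpha1) > 0), all(diff(alpha2) > 0),
            alpha1[1] == 0, alpha2[1] == 0, L1 >= alpha1[5], n_grid >= 11L)
  structure(list(L1 = L1, L2 = 255, alpha1 = alpha1, alpha2 = alpha2,
                 qpeaks = c(0, 0.25, 0.5, 0.75, 1),
                 n_grid = as.integer(n_grid)),
            class = "fis_config")
}

#' Diagonal length of the lower two-thirds of an image
#'
#' @param W,H image width and height in pixels.
#' @return the p1 domain upper bound \eqn{\sqrt{W^2 + (2H/3)^2}}.
#' @export
image_l1 <- function(W, H) sqrt(W^2 + (2 * H / 3)^2)

#' The 25-rule base of the candidate-degree FIS
#'
#' One rule per (p1 term, p2 term) pair. The consequent encodes the
#' selection heuristic: far from foam and flat texture give a high degree.
#' Rows of the default grid (p2 = VS..VL) by columns (p1 = VS..VL):
#' ```
#'        p1: VS  S   M   L   VL
#' p2=VS      M   L   L   VL  VL
#' p2=S       S   M   L   L   VL
#' p2=M       S   S   M   L   L
#' p2=L       VS  S   S   M   L
#' p2=VL      VS  VS  S   S   M
#' ```
#'
#' @param grid optional 5x5 character matrix of consequent terms,
#'   rows indexed by the p2 term and columns by the p1 term.
#' @return object of class `rule_base`: data frame with integer columns
#'   `a1`, `a2`, `b` (term indices 1..5 = VS..VL).
#' @export
rule_base <- function(grid = NULL) {
  if (is.null(grid)) {
    grid <- matrix(c(
      "M",  "L",  "L",  "VL", "VL",
      "S",  "M",  "L",  "L",  "VL",
      "S",  "S",  "M",  "L",  "L",
      "VS", "S",  "S",  "M",  "L",
      "VS", "VS", "S",  "S",  "M"), 5, 5, byrow = TRUE)
  }
  grid <- as.matrix(grid)
  stopifnot(identical(dim(grid), c(5L, 5L)), all(grid %in% .FIS_TERMS))
  df <- expand.grid(a1 = 1:5, a2 = 1:5)
  df$b <- vapply(seq_len(25), function(r)
    match(grid[df$a2[r], df$a1[r]], .FIS_TERMS), integer(1))
  structure(df, class = c("rule_base", "data.frame"))
}

# Membership of x in the 5 sets with peak vector `peaks` on [0, dmax]:
# set 1 is a left shoulder (1 up to peaks[1], falling to 0 at peaks[2]),
# set 5 a right shoulder (rising from peaks[4], 1 from peaks[5] to dmax),
# interior sets are triangles over adjacent peaks. Returns length(x) x 5.
.membership5 <- function(x, peaks) {
  n <- length(x)
  out <- matrix(0, n, 5)
  out[, 1] <- ifelse(x <= peaks[1], 1,
               pmax(0, (peaks[2] - x) / (peaks[2] - peaks[1])))
  for (k in 2:4) {
    up <- (x - peaks[k - 1]) / (peaks[k] - peaks[k - 1])
    dn <- (peaks[k + 1] - x) / (peaks[k + 1] - peaks[k])
    out[, k] <- pmax(0, pmin(up, dn))
  }
  out[, 5] <- ifelse(x >= peaks[5], 1,
               pmax(0, (x - peaks[4]) / (peaks[5] - peaks[4])))
  out
}


# Batch core: q for paired vectors p1, p2 (already clamped to domain).
# Aggregation exploits that rules sharing a consequent term can be collapsed
# to a per-term firing strength before the max-min aggregation.
.fis_core <- function(p1, p2, cfg, rules) {
  n <- length(p1)
  A1 <- .membership5(p1, cfg$alpha1)
  A2 <- .membership5(p2, cfg$alpha2)
  s <- matrix(0, n, 5)                     # per consequent-term strength
  for (r in seq_len(nrow(rules))) {
    w <- pmin(A1[, rules$a1[r]], A2[, rules$a2[r]])
    b <- rules$b[r]
    s[, b] <- pmax(s[, b], w)
  }
  ng <- cfg$n_grid
  qs <- (seq_len(ng) - 0.5) / ng
  Bq <- .membership5(qs, cfg$qpeaks)       # ng x 5
  num <- numeric(n); den <- numeric(n)
  for (j in seq_len(ng)) {
    bp <- pmax(pmax(pmin(s[, 1], Bq[j, 1]), pmin(s[, 2], Bq[j, 2])),
               pmax(pmin(s[, 3], Bq[j, 3]),
                    pmax(pmin(s[, 4], Bq[j, 4]), pmin(s[, 5], Bq[j, 5]))))
    num <- num + qs[j] * bp
    den <- den + bp
  }
  ifelse(den > 0, num / den, 0.5)
}

#' Crisp candidate degree of a (p1, p2) input pair
#'
#' Fuzzifies both antecedents, fires all 25 rules with min conjunction,
#' aggregates the clipped consequent sets by max, and defuzzifies by the
#' centroid of the aggregate (midpoint rule on `n_grid` points).
#' Inputs outside their domains are clamped with a warning. Vectorized over
#' paired inputs.
#'
#' @param p1 minimum distance(s) to foam contours, in \eqn{[0, L1]}.
#' @param p2 patch intensity standard deviation(s), in \eqn{[0, 255]}.
#' @param cfg a [fis_config()].
#' @param rules a [rule_base()].
#' @return degree(s) q in \eqn{[0, 1]}.
#' @export
fis_degree <- function(p1, p2, cfg, rules = rule_base()) {
  stopifnot(inherits(cfg, "fis_config"), length(p1) == length(p2))
  if (any(p1 < 0 | p1 > cfg$L1) || any(p2 < 0 | p2 > cfg$L2)) {
    warning("FIS inputs outside their domains were clamped")
    p1 <- .clamp(p1, 0, cfg$L1)
    p2 <- .clamp(p2, 0, cfg$L2)
  }
  .fis_core(p1, p2, cfg, rules)
}

#' Precompute the FIS as a lookup table
#'
#' Tabulates \eqn{q = \phi(p_1, p_2)} at all integer grid points
#' \eqn{p_1 \in \{0, ..., \lceil L1 \rceil\}}, \eqn{p_2 \in \{0, ..., 255\}},
#' so that repeated inference reduces to a table lookup. Grid points beyond
#' the last membership breakpoint share identical memberships, so the table
#' is computed on the reduced unique set and expanded, which makes it exactly
#' equal to direct inference at every grid point.
#'
#' @param cfg a [fis_config()].
#' @param rules a [rule_base()].
#' @return object of class `fis_lut`: list with `q`
#'   ((ceil(L1)+1) x 256 matrix), `cfg`.
#' @export
build_lut <- function(cfg, rules = rule_base()) {
  stopifnot(inherits(cfg, "fis_config"))
  p1g <- 0:ceiling(cfg$L1)
  p2g <- 0:255
  # collapse the constant plateau beyond the last peak
  k1 <- pmin(p1g, ceiling(cfg$alpha1[5]))
  k2 <- pmin(p2g, ceiling(cfg$alpha2[5]))
  u1 <- unique(k1); u2 <- unique(k2)
  pairs <- expand.grid(a = u1, b = u2)
  qv <- .fis_core(.clamp(pairs$a, 0, cfg$L1), pairs$b, cfg, rules)
  qu <- matrix(qv, length(u1), length(u2))
  q <- qu[match(k1, u1), match(k2, u2)]
  dimnames(q) <- NULL
  structure(list(q = q, cfg = cfg), class = "fis_lut")
}

#' Query a FIS lookup table
#'
#' Non-integer inputs are mapped to the nearest integer grid point; inputs
#' outside the table are clamped.
#'
#' @param lut a `fis_lut` from [build_lut()].
#' @param p1,p2 paired input vectors.
#' @return degree(s) q in \eqn{[0, 1]}.
#' @export
lut_degree <- function(lut, p1, p2) {
  stopifnot(inherits(lut, "fis_lut"), length(p1) == length(p2))
  i <- .clamp(round(p1), 0, nrow(lut$q) - 1L) + 1L
  j <- .clamp(round(p2), 0, 255) + 1L
  lut$q[cbind(i, j)]
}
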