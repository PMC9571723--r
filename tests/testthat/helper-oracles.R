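# Independent oracles used to freeze expected values.

# Brute-force Mamdani centroid: explicit per-set memberships, all 25 rules
# fired individually, fine Riemann grid over [0, 1].
oracle_membership <- function(x, peaks, k) {
  if (k == 1L) {
    if (x <= peaks[1]) 1 else max(0, (peaks[2] - x) / (peaks[2] - peaks[1]))
  } else if (k == 5L) {
    if (x >= peaks[5]) 1 else max(0, (x - peaks[4]) / (peaks[5] - peaks[4]))
  } else {
    max(0, min((x - peaks[k - 1]) / (peaks[k] - peaks[k - 1]),
               (peaks[k + 1] - x) / (peaks[k + 1] - peaks[k])))
  }
}

# Consequent memberships tabulated once on the integration grid (the
# membership formula itself stays the scalar oracle implementation).
oracle_consequent_grid <- function(cfg, grid_n = 1e4) {
  qs <- seq(0, 1, length.out = grid_n)
  Bt <- vapply(1:5, function(k)
    vapply(qs, oracle_membership, numeric(1), peaks = cfg$qpeaks, k = k),
    numeric(grid_n))
  list(qs = qs, Bt = Bt)
}

oracle_fis <- function(p1, p2, cfg, rules = rule_base(), grid = NULL) {
  if (is.null(grid)) grid <- oracle_consequent_grid(cfg)
  B <- rep(0, length(grid$qs))
  for (r in seq_len(nrow(rules))) {
    w <- min(oracle_membership(p1, cfg$alpha1, rules$a1[r]),
             oracle_membership(p2, cfg$alpha2, rules$a2[r]))
    if (w == 0) next
    B <- pmax(B, pmin(w, grid$Bt[, rules$b[r]]))
  }
  sum(grid$qs * B) / sum(B)
}

# Centroid of one consequent set alone (the single-rule case).
oracle_set_centroid <- function(k, cfg, grid_n = 1e4) {
  qs <- seq(0, 1, length.out = grid_n)
  m <- vapply(qs, oracle_membership, numeric(1), peaks = cfg$qpeaks, k = k)
  sum(qs * m) / sum(m)
}

# BFS flood-fill 8-connected labeling (independent of the run-based
# union-find in the package).
oracle_flood_fill <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j0 in seq_len(W)) for (i0 in seq_len(H)) {
    if (!bin[i0, j0] || lab[i0, j0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        i <- p[1] + di; j <- p[2] + dj
        if (i < 1 || i > H || j < 1 || j > W) next
        if (bin[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- nxt
          stack[[length(stack) + 1L]] <- c(i, j)
        }
      }
    }
  }
  lab
}

# Exhaustive patch-boundary to foam-contour distance.
oracle_foam_distance <- function(rect, mask_labels, L1) {
  foam_idx <- which(mask_labels == 4L)
  if (!length(foam_idx)) return(L1)
  H <- nrow(mask_labels)
  fx <- (foam_idx - 1L) %/% H; fy <- (foam_idx - 1L) %% H
  x1 <- rect[1]; y1 <- rect[2]; x2 <- rect[3]; y2 <- rect[4]
  if (any(fx >= x1 & fx < x2 & fy >= y1 & fy < y2)) return(0)
  # contour pixels: foam with a non-foam 4-neighbor or on the border
  is_contour <- vapply(seq_along(fx), function(k) {
    i <- fy[k] + 1L; j <- fx[k] + 1L
    i == 1L || i == H || j == 1L || j == ncol(mask_labels) ||
      mask_labels[i - 1L, j] != 4L || mask_labels[i + 1L, j] != 4L ||
      mask_labels[i, j - 1L] != 4L || mask_labels[i, j + 1L] != 4L
  }, logical(1))
  cx <- fx[is_contour]; cy <- fy[is_contour]
  xs <- x1:(x2 - 1L); ys <- y1:(y2 - 1L)
  b <- unique(rbind(cbind(xs, y1), cbind(xs, y2 - 1L),
                    cbind(x1, ys), cbind(x2 - 1L, ys)))
  best <- Inf
  for (k in seq_len(nrow(b)))
    best <- min(best, min((cx - b[k, 1])^2 + (cy - b[k, 2])^2))
  min(sqrt(best), L1)
}
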