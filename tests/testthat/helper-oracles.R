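# Independent brute-force oracles and small fixture builders.

# connected-component labelling by explicit flood fill (queue-based BFS)
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# shape descriptors via direct moment sums and eigen decomposition
moments_oracle <- function(pixels) {
  n <- nrow(pixels)
  xb <- sum(pixels[, 2]) / n
  yb <- sum(-pixels[, 1]) / n
  sxx <- sxy <- syy <- 0
  for (k in seq_len(n)) {
    dx <- pixels[k, 2] - xb
    dy <- -pixels[k, 1] - yb
    sxx <- sxx + dx * dx; syy <- syy + dy * dy; sxy <- sxy + dx * dy
  }
  C <- matrix(c(sxx, sxy, sxy, syy), 2) / n
  ev <- eigen(C, symmetric = TRUE)
  l1 <- ev$values[1]; l2 <- ev$values[2]
  if (l1 <= .Machine$double.eps)
    return(list(eccentricity = 0, orientation_deg = 0))
  ecc <- sqrt(max(0, 1 - l2 / l1))
  if (abs(l1 - l2) <= .Machine$double.eps * (l1 + l2)) {
    th <- 0
  } else {
    v <- ev$vectors[, 1]
    th <- atan2(v[2], v[1]) * 180 / pi
    if (th <= -90) th <- th + 180
    if (th > 90) th <- th - 180
  }
  list(eccentricity = ecc, orientation_deg = th)
}

# rasterise a filled axis-rotated ellipse from pixel centres (independent
# of the generator's internal rasteriser)
raster_ellipse <- function(row0, col0, a, b, theta_deg, nr, nc) {
  th <- theta_deg * pi / 180
  px <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dx <- c - col0; dy <- -(r - row0)
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    if (u * u + v * v <= 1) px <- rbind(px, c(r, c))
  }
  px
}

# reduced-scale phantom configuration used across the suite
small_phantom <- function(seed, ..., height_px = 240, width_px = 360,
                          n_frames = 4) {
  phantom_config(height_px = height_px, width_px = width_px,
                 n_frames = n_frames, seed = seed, ...)
}

# layer_segmentation built from phantom ground-truth boundaries
oracle_seg <- function(truth, f) {
  b <- truth$boundaries[[f]]
  structure(
    list(ilm_row = b$ilm_row, rpe_inner_row = b$rpe_inner_row,
         rpe_outer_row = b$rpe_outer_row, frame_index = f,
         height_px = truth$config$height_px,
         width_px = truth$config$width_px, n_failed_columns = 0L),
    class = "layer_segmentation")
}
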