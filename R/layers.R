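#' Segment vitreous and RPE boundaries in one B-scan
#'
#' Locates, per image column, the inner limiting membrane (ILM: the
#' dark-to-bright axial transition at the top of the retinal band), the
#' outer RPE boundary (the last sustained bright-to-dark transition) and
#' the inner RPE boundary (the top of the brightest band, the RPE). The
#' detector works on the axial intensity profile of each column after a
#' small centred moving average, classifies rows against the midpoint of
#' the vitreous and retina median intensities (global dark/bright split by
#' Otsu's threshold), and requires `min_band_rows` consecutive rows to
#' call a transition "sustained" so isolated speckle cannot fake a
#' boundary. The ILM is the start of the sustained run that terminates at
#' the outer boundary (speckle dips shorter than `min_band_rows` inside
#' the retina are bridged first), so hyperreflective opacities higher in
#' the vitreous -- which form their own, separate runs -- cannot displace
#' it. The RPE band edges are then refined as change points on
#' ILM-aligned, laterally averaged axial profiles: the inner boundary is
#' the split maximising the upward step contrast between the inner retina
#' and the band, the outer boundary the split maximising the downward
#' step into the dark tissue below. Columns where detection fails are
#' filled by linear interpolation from their neighbours, and all three
#' boundary curves are median-smoothed across columns.
#'
#' Row indices are 1-based; row 1 is the top of the frame (innermost
#' vitreous). `ilm_row` is the first retinal row; `rpe_inner_row` and
#' `rpe_outer_row` delimit the RPE band inclusively, so
#' `ilm_row < rpe_inner_row <= rpe_outer_row` in every column.
#'
#' @param frame numeric matrix, intensities on `[0, 1]`.
#' @param smoothing_window width (columns) of the cross-column running
#'   median applied to each boundary curve; forced odd.
#' @param min_band_rows minimum run length (rows) for a sustained
#'   transition.
#' @param axial_window width (rows) of the centred moving average applied
#'   to each axial profile before thresholding; forced odd.
#' @param min_contrast minimum separation between retina and vitreous
#'   median intensities below which segmentation is refused.
#' @param align_window width (columns) of the ILM-aligned lateral
#'   averaging window used for the inner RPE change point; forced odd.
#'   Wider windows suppress speckle on this low-contrast boundary and are
#'   safe while layer boundaries vary slowly across columns.
#' @param frame_index stored in the result for bookkeeping.
#' @return an object of class `layer_segmentation`: integer vectors
#'   `ilm_row`, `rpe_inner_row`, `rpe_outer_row` (one entry per column),
#'   plus `frame_index`, `height_px`, `width_px`.
#' @export
segment_layers <- function(frame, smoothing_window = 15, min_band_rows = 5,
                           axial_window = 5, min_contrast = 0.05,
                           align_window = 31, frame_index = 1L) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < min_band_rows)
    stop("frame has fewer rows than `min_band_rows`", call. = FALSE)
  m <- as.integer(min_band_rows)

  S <- axial_smooth(frame, axial_window)

  # global dark/bright split
  thr <- EBImage::otsu(EBImage::Image(clamp01(S)))
  vit_med <- median(S[S < thr])
  ret_med <- median(S[S >= thr])
  if (!is.finite(vit_med) || !is.finite(ret_med) ||
      (ret_med - vit_med) < min_contrast)
    stop("segmentation failure: no usable vitreous/retina contrast",
         call. = FALSE)
  midpoint <- (vit_med + ret_med) / 2

  # runs of >= m consecutive above-midpoint rows, per column:
  # roll[r, j] == m  <=>  rows (r-m+1)..r of column j are all above
  B <- (S > midpoint) * 1
  roll <- stats::filter(B, rep(1, m), sides = 1)
  roll <- matrix(as.numeric(roll), nr, nc)

  # pass 1, per column: ILM and a rough outer boundary.
  # The outer boundary is the last row of the last sustained run; the ILM
  # is the start of the sustained run that ends there (the retinal band),
  # with sub-threshold gaps shorter than m rows bridged first so speckle
  # dips inside the retina do not displace it. Bright blobs higher in the
  # vitreous form separate runs and are ignored.
  ilm <- rough_out <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    ends <- which(roll[, j] == m)
    if (length(ends) == 0L) next
    bot <- max(ends)
    runs <- bridged_runs(B[, j] == 1, m)
    band <- runs[runs[, 1] <= bot & runs[, 2] >= bot, , drop = FALSE]
    if (nrow(band) == 0L) next
    ilm[j] <- band[1, 1]
    rough_out[j] <- bot
  }

  n_fail <- sum(is.na(ilm))
  if (n_fail >= nc / 2)
    stop("segmentation failure: boundary not found in >= 50% of columns",
         call. = FALSE)

  # pass 2: inner RPE boundary. The retina/RPE step is low-contrast, so
  # axial profiles are first aligned at their ILM and averaged over a
  # lateral window (layer boundaries vary slowly across columns, so
  # aligned averaging sharpens the step instead of blurring it); the
  # boundary is then the change point maximising the CUSUM-scaled step
  # contrast, whose sqrt(n1 n2 / n) factor equalises the noise variance
  # across candidate split points.
  h <- max(1L, (as.integer(align_window) - 1L) %/% 2L)
  rpe_in <- rep(NA_real_, nc)
  valid <- which(!is.na(ilm))
  rpe_out <- rep(NA_real_, nc)
  if (length(valid)) {
    # outer boundary first: profiles aligned at the rough outer edge,
    # spanning 3m rows of band above it and up to 4m rows of dark tissue
    # below, so the downward step sits inside the window
    back <- 3L * m
    start2 <- pmax(1L, as.integer(rough_out) - back + 1L)
    len2 <- rep(NA_integer_, nc)
    len2[valid] <- pmin(nr - start2[valid] + 1L,
                        as.integer(rough_out[valid]) - start2[valid] +
                          1L + 4L * m)
    W2 <- aligned_mean(frame, start2, len2, valid, h)
    for (j in valid) {
      band_rows <- rough_out[j] - start2[j] + 1L
      tail_rows <- len2[j] - band_rows
      if (tail_rows < m || band_rows < m) { rpe_out[j] <- rough_out[j]; next }
      k_out <- cusum_split(W2[seq_len(len2[j]), j], m, sign = -1)
      rpe_out[j] <- start2[j] + k_out - 2L
    }

    # inner boundary: profiles aligned at the ILM, ending at the refined
    # outer edge (ending at the rough edge instead would leak blurred
    # dark rows into the right segment and bias the split upward)
    Lj <- rep(NA_integer_, nc)
    Lj[valid] <- as.integer(rpe_out[valid] - ilm[valid] + 1L)
    W1 <- aligned_mean(frame, as.integer(ilm), Lj, valid, h)
    for (j in valid) {
      if (Lj[j] < 2L * m) { rpe_in[j] <- ilm[j]; next }
      k_in <- cusum_split(W1[seq_len(Lj[j]), j], m, sign = 1)
      rpe_in[j] <- ilm[j] + k_in - 1L
    }
  }

  k <- as.integer(smoothing_window)
  if (k %% 2L == 0L) k <- k + 1L
  finish <- function(x) {
    x <- fill_na(x)
    if (nc > k) x <- runmed(x, k, endrule = "median")
    as.integer(round(x))
  }
  ilm <- finish(ilm); rpe_in <- finish(rpe_in); rpe_out <- finish(rpe_out)

  # enforce ordering and frame bounds
  ilm <- pmin(pmax(ilm, 1L), nr - 2L)
  rpe_in <- pmin(pmax(rpe_in, ilm + 1L), nr)
  rpe_out <- pmin(pmax(rpe_out, rpe_in), nr)

  structure(
    list(ilm_row = ilm, rpe_inner_row = rpe_in, rpe_outer_row = rpe_out,
         frame_index = as.integer(frame_index),
         height_px = nr, width_px = nc, n_failed_columns = n_fail),
    class = "layer_segmentation"
  )
}

# centred moving average down each column; edge rows keep raw values
axial_smooth <- function(frame, window) {
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(frame)
  S <- stats::filter(frame, rep(1 / w, w), sides = 2)
  S <- matrix(as.numeric(S), nrow(frame), ncol(frame))
  S[is.na(S)] <- frame[is.na(S)]
  S
}

# maximal runs of TRUE with length >= m after bridging FALSE gaps < m,
# as a matrix of (start, end) rows
bridged_runs <- function(b, m) {
  b <- as.logical(b)
  r <- rle(b)
  gap <- !r$values & r$lengths < m
  gap[1] <- gap[length(gap)] <- FALSE   # never bridge the borders
  r$values[gap] <- TRUE
  b2 <- inverse.rle(r)
  r2 <- rle(b2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values & r2$lengths >= m
  cbind(start = starts[keep], end = ends[keep])
}

# per-column profiles frame[start[j] .. start[j]+len[j]-1, j], stacked so
# row i holds offset i, then averaged over a lateral window of half-width h
aligned_mean <- function(frame, start, len, valid, h) {
  K <- max(len[valid])
  A <- matrix(NA_real_, K, ncol(frame))
  for (j in valid)
    A[seq_len(len[j]), j] <- frame[start[j]:(start[j] + len[j] - 1L), j]
  ok <- !is.na(A)
  A[!ok] <- 0
  lateral_runsum(A, h) / lateral_runsum(ok * 1, h)
}

# CUSUM-scaled single change point: the split k maximising the
# variance-equalised mean difference (sign = 1: upward step at k,
# sign = -1: downward); segments shorter than m rows are not considered
cusum_split <- function(w, m, sign = 1) {
  L <- length(w)
  cum <- cumsum(w)
  k <- (m + 1L):(L - m + 1L)
  n1 <- k - 1L; n2 <- L - k + 1L
  obj <- sign * sqrt(n1 * n2 / L) *
    ((cum[L] - cum[k - 1L]) / n2 - cum[k - 1L] / n1)
  k[which.max(obj)]
}

# moving sum across columns with truncated (partial) windows at the edges
lateral_runsum <- function(M, h) {
  nc <- ncol(M)
  cs <- cbind(0, t(apply(M, 1, cumsum)))
  lo <- pmax(0L, seq_len(nc) - h - 1L)
  hi <- pmin(nc, seq_len(nc) + h)
  cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]
}

fill_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' @export
print.layer_segmentation <- function(x, ...) {
  cat(sprintf(
    "<layer_segmentation> frame %d: ILM rows %d-%d, RPE rows %d-%d (%d cols)\n",
    x$frame_index, min(x$ilm_row), max(x$ilm_row),
    min(x$rpe_inner_row), max(x$rpe_outer_row), x$width_px))
  invisible(x)
}

#' Vitreous compartment mask
#'
#' Logical mask of the vitreous: pixels strictly above `ilm_row -
#' margin_rows` in each column. `margin_rows` excludes a safety band at
#' the ILM (opacities adherent to the membrane are ambiguous);
#' `top_margin_rows` optionally excludes an acquisition-artefact band at
#' the top of the frame.
#'
#' @param seg a [segment_layers()] result.
#' @param dim frame dimensions `c(rows, cols)`; defaults to those stored
#'   in `seg`.
#' @param margin_rows rows excluded immediately above the ILM (default 2).
#' @param top_margin_rows rows excluded at the top of the frame
#'   (default 0).
#' @return logical matrix of the requested dimensions.
#' @export
vitreous_mask <- function(seg, dim = NULL, margin_rows = 2,
                          top_margin_rows = 0) {
  stopifnot(inherits(seg, "layer_segmentation"))
  if (is.null(dim)) dim <- c(seg$height_px, seg$width_px)
  if (dim[2] != length(seg$ilm_row))
    stop("segmentation does not match the frame shape", call. = FALSE)
  rows <- seq_len(dim[1])
  outer(rows, seg$ilm_row - margin_rows, `<`) & (rows > top_margin_rows)
}

# RPE band mask (rows rpe_inner..rpe_outer inclusive, per column)
rpe_mask <- function(seg, dim = NULL) {
  if (is.null(dim)) dim <- c(seg$height_px, seg$width_px)
  rows <- seq_len(dim[1])
  outer(rows, seg$rpe_inner_row, `>=`) & outer(rows, seg$rpe_outer_row, `<=`)
}
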