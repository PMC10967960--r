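#' Size-class taxonomy of vitreous opacities
#'
#' Classes, in increasing-size order: `isolated` (< 10 um^2, rounded
#' early-stage cells), `non_activated` (10-50 um^2, resting cells),
#' `activated` (50-250 um^2, reactive cells with enlarged soma) and
#' `complex` (> 250 um^2, cell aggregates). Intervals are half-open and
#' lower-inclusive, so an area of exactly 10 um^2 is `non_activated`.
#'
#' @format character vector of the four class names in size order.
#' @export
SIZE_CLASSES <- c("isolated", "non_activated", "activated", "complex")

#' Classify an opacity by physical area
#'
#' @param area_um2 numeric vector of areas in square micrometres; all
#'   must be positive.
#' @return character vector of size classes (see [SIZE_CLASSES]).
#' @examples
#' classify_size(c(7.63, 10, 150, 251))
#' @export
classify_size <- function(area_um2) {
  if (!is.numeric(area_um2) || any(!is.finite(area_um2)) ||
      any(area_um2 <= 0))
    stop("`area_um2` must be positive and finite", call. = FALSE)
  as.character(cut(area_um2, breaks = c(0, 10, 50, 250, Inf),
                   labels = SIZE_CLASSES, right = FALSE))
}

#' Suppress speckle background in the vitreous
#'
#' Background speckle is darker than hyperreflective opacities, so masked
#' pixels are thresholded at `median + k_sigma * sigma_MAD` of the masked
#' intensities, where `sigma_MAD` is the MAD-derived robust standard
#' deviation. Robust statistics make the threshold insensitive to the
#' opacities themselves and independent of bit depth or illumination. A
#' constant masked region yields an all-false raster (no opacities), not
#' an error.
#'
#' @param frame numeric matrix on `[0, 1]`.
#' @param mask logical matrix, the vitreous compartment
#'   (see [vitreous_mask()]); must contain at least one `TRUE` pixel.
#' @param k_sigma threshold multiplier (default 6).
#' @return logical matrix: `TRUE` where a masked pixel strictly exceeds
#'   the threshold, `FALSE` elsewhere (including outside the mask).
#' @export
suppress_background <- function(frame, mask, k_sigma = 6) {
  stopifnot(is.matrix(frame), is.logical(mask),
            all(dim(frame) == dim(mask)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  vals <- frame[mask]
  thr <- median(vals) + k_sigma * mad(vals)
  out <- matrix(FALSE, nrow(frame), ncol(frame))
  out[mask] <- frame[mask] > thr
  out
}

#' Label connected components in a binary raster
#'
#' Sparse two-pass union-find labelling with selectable 4- or 8-neighbour
#' connectivity (default 8: diagonally touching speckle of a single cell
#' should not split it). Labels are positive integers assigned in
#' column-major scan order of each component's first pixel; background
#' is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)
  lab[idx] <- seq_len(n)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L

  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == "8") offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path halving
      i <- parent[i]
    }
    i
  }
  for (o in offs) {
    ok <- r + o[1] >= 1L & r + o[1] <= nr & cc + o[2] <= nc
    nb <- idx[ok] + o[1] + o[2] * nr
    hit <- which(ok)[mask[nb]]
    nb <- lab[nb[mask[nb]]]
    for (k in seq_along(hit)) {
      a <- find(hit[k]); b <- find(nb[k])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

#' Ellipse-of-inertia shape descriptors of a pixel set
#'
#' Fits the ellipse of inertia from the second central moments of the
#' pixel coordinates (each pixel a unit point mass). Eccentricity is
#' `sqrt(1 - (minor/major)^2)`: values near 0 indicate a rounded or
#' amoeboid soma, values near 1 a linear, elongated or flat morphology.
#' Orientation is the angle of the major axis relative to the image
#' horizontal, in degrees on `(-90, 90]`, positive counter-clockwise
#' (row index increases downwards, so the vertical coordinate is negated
#' before the moment sums). A single pixel, or any isotropic set, has
#' eccentricity 0 and orientation 0 by convention.
#'
#' @param pixels two-column matrix or data frame of `(row, col)`
#'   coordinates; at least one pixel.
#' @return list with `eccentricity` and `orientation_deg`.
#' @examples
#' shape_features(cbind(1, 1:20)) # horizontal line: ecc ~1, orientation 0
#' @export
shape_features <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L) stop("need at least one pixel", call. = FALSE)
  x <- pixels[, 2] - mean(pixels[, 2])
  y <- -(pixels[, 1] - mean(pixels[, 1]))   # y axis points up
  mu20 <- mean(x * x); mu02 <- mean(y * y); mu11 <- mean(x * y)
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  if (l1 <= .Machine$double.eps)
    return(list(eccentricity = 0, orientation_deg = 0))
  ecc <- sqrt(max(0, 1 - l2 / l1))
  if (disc <= .Machine$double.eps * (mu20 + mu02)) {
    theta <- 0                               # isotropic: no major axis
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (theta <= -90) theta <- theta + 180
  }
  list(eccentricity = ecc, orientation_deg = theta)
}

#' Detect hyperreflective opacities in one B-scan
#'
#' Labels connected components of the background-suppressed binary raster
#' (see [suppress_background()]) and extracts one record per component
#' with at least `min_area_px` pixels: pixel and physical area, centroid,
#' mean intensity over the original frame, ellipse-of-inertia eccentricity
#' and orientation, and the size class.
#'
#' @param binary logical matrix from [suppress_background()].
#' @param frame the original intensity frame (same shape).
#' @param pixel_area_um2 pixel area in square micrometres.
#' @param min_area_px minimum component size in pixels (default 1: an
#'   isolated cell can be a single pixel).
#' @param connectivity 4 or 8 (default 8), see [label_components()].
#' @param frame_index stored in the records.
#' @return a tibble with one row per opacity: `frame_index`,
#'   `centroid_row`, `centroid_col`, `area_px`, `area_um2`,
#'   `mean_intensity`, `eccentricity`, `orientation_deg`, `size_class`,
#'   and a `pixels` list-column of `(row, col)` matrices.
#' @export
detect_opacities <- function(binary, frame, pixel_area_um2 = 3.815,
                             min_area_px = 1, connectivity = 8,
                             frame_index = 1L) {
  stopifnot(all(dim(binary) == dim(frame)))
  lab <- label_components(binary, connectivity)
  fg <- which(lab > 0L)
  empty <- tibble::tibble(
    frame_index = integer(0), centroid_row = numeric(0),
    centroid_col = numeric(0), area_px = integer(0), area_um2 = numeric(0),
    mean_intensity = numeric(0), eccentricity = numeric(0),
    orientation_deg = numeric(0), size_class = character(0),
    pixels = list())
  if (length(fg) == 0L) return(empty)
  nr <- nrow(binary)
  comps <- split(fg, lab[fg])
  comps <- comps[lengths(comps) >= min_area_px]
  if (length(comps) == 0L) return(empty)
  rows <- lapply(comps, function(ix) {
    px <- cbind(row = ((ix - 1L) %% nr) + 1L,
                col = ((ix - 1L) %/% nr) + 1L)
    sf <- shape_features(px)
    area <- nrow(px)
    tibble::tibble(
      frame_index = as.integer(frame_index),
      centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
      area_px = area, area_um2 = area * pixel_area_um2,
      mean_intensity = mean(frame[ix]),
      eccentricity = sf$eccentricity,
      orientation_deg = sf$orientation_deg,
      size_class = classify_size(area * pixel_area_um2),
      pixels = list(px))
  })
  do.call(rbind, rows)
}

#' Aggregate opacity records into a per-eye summary
#'
#' Per-eye, per-timepoint aggregates: total opacity area, mean number of
#' opacities per B-scan, mean area over all opacities and per size class,
#' class percentages (summing to 100 when any opacity exists), and
#' per-class mean eccentricity, intensity and orientation. The mean
#' orientation is the signed arithmetic mean, so mixed orientations cancel
#' towards 0 -- the behaviour used to read directed motility.
#'
#' @param records a tibble of opacity records (all frames pooled) or a
#'   list of per-frame tibbles from [detect_opacities()].
#' @param n_frames number of B-scans analysed (denominator of
#'   `mean_n_opacities`).
#' @param vit_rpe optional per-eye VIT/RPE value ([eye_vit_rpe()] result
#'   or scalar).
#' @param eye_meta optional eye metadata list (see [bscan_stack()]).
#' @return an object of class `eye_summary`; `as.data.frame()` flattens
#'   it to one wide row for CSV export.
#' @export
summarise_eye <- function(records, n_frames, vit_rpe = NULL,
                          eye_meta = list()) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(is.data.frame(records), n_frames >= 1)
  if (inherits(vit_rpe, "vit_rpe_result")) vit_rpe <- vit_rpe$eye_mean
  n_total <- nrow(records)

  per_class <- function(stat, col) {
    vapply(SIZE_CLASSES, function(cl) {
      v <- records[[col]][records$size_class == cl]
      if (length(v) == 0L) NA_real_ else stat(v)
    }, numeric(1))
  }
  counts <- vapply(SIZE_CLASSES,
                   function(cl) sum(records$size_class == cl), numeric(1))
  out <- list(
    total_area_um2 = if (n_total) sum(records$area_um2) else 0,
    n_opacities = n_total,
    mean_n_opacities = n_total / n_frames,
    mean_area_um2 = if (n_total) mean(records$area_um2) else 0,
    class_count = counts,
    class_percent = if (n_total) 100 * counts / n_total else counts * 0,
    mean_area_by_class = per_class(mean, "area_um2"),
    mean_eccentricity = per_class(mean, "eccentricity"),
    mean_intensity = per_class(mean, "mean_intensity"),
    mean_orientation_deg = per_class(mean, "orientation_deg"),
    vit_rpe = if (is.null(vit_rpe)) NA_real_ else vit_rpe,
    n_frames = n_frames,
    no_opacities = n_total == 0L,
    eye_meta = eye_meta
  )
  structure(out, class = "eye_summary")
}

#' @export
as.data.frame.eye_summary <- function(x, ...) {
  wide <- function(v, prefix) {
    out <- as.list(v)
    names(out) <- paste0(prefix, "_", SIZE_CLASSES)
    out
  }
  meta <- x$eye_meta[intersect(names(x$eye_meta),
                               c("animal", "cohort", "sex", "eye",
                                 "week", "iop_mmHg"))]
  cols <- c(
    meta,
    list(total_area_um2 = x$total_area_um2,
         n_opacities = x$n_opacities,
         mean_n_opacities = x$mean_n_opacities,
         mean_area_um2 = x$mean_area_um2,
         vit_rpe = x$vit_rpe),
    wide(x$class_percent, "pct"),
    wide(x$mean_area_by_class, "mean_area"),
    wide(x$mean_eccentricity, "mean_ecc"),
    wide(x$mean_intensity, "mean_int"),
    wide(x$mean_orientation_deg, "mean_orient")
  )
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' @export
print.eye_summary <- function(x, ...) {
  cat(sprintf(
    "<eye_summary> %d opacities over %d frame(s); total %.1f um^2, mean %.2f/frame\n",
    x$n_opacities, x$n_frames, x$total_area_um2, x$mean_n_opacities))
  if (x$n_opacities) {
    pc <- sprintf("%s %.1f%%", SIZE_CLASSES, x$class_percent)
    cat("  classes:", paste(pc, collapse = ", "), "\n")
  }
  if (!is.na(x$vit_rpe)) cat(sprintf("  VIT/RPE: %.4f\n", x$vit_rpe))
  invisible(x)
}
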