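#' Construct a B-scan stack
#'
#' The container for one eye at one timepoint: an ordered list of 2-D
#' greyscale rasters (rows = axial depth, top of frame = innermost
#' vitreous; columns = lateral position) plus the pixel scale and eye
#' metadata. Intensities are expected on the normalised `[0, 1]` scale
#' produced by [read_bscan_stack()] and the phantom generator.
#'
#' @param frames list of numeric matrices, all with identical dimensions,
#'   finite and non-negative.
#' @param pixel_area_um2 area of one pixel in square micrometres; the
#'   rodent protocol default is 3.815.
#' @param eye_meta optional named list with any of `animal`, `cohort`
#'   (one of `"MsDx"`, `"MsDxF"`, `"control"`), `sex` (`"M"`/`"F"`),
#'   `eye` (`"RE"`/`"LE"`), `week` (integer), `iop_mmHg`.
#' @return an object of class `bscan_stack` with elements `frames`,
#'   `n_frames`, `height_px`, `width_px`, `pixel_area_um2`, `eye_meta`.
#' @seealso [read_bscan_stack()], [generate_phantom()]
#' @export
bscan_stack <- function(frames, pixel_area_um2 = 3.815, eye_meta = list()) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a 2-D matrix", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  for (f in frames) {
    if (!all(is.finite(f)) || any(f < 0))
      stop("frame intensities must be finite and non-negative",
           call. = FALSE)
  }
  if (!is.numeric(pixel_area_um2) || length(pixel_area_um2) != 1L ||
      !is.finite(pixel_area_um2) || pixel_area_um2 <= 0)
    stop("`pixel_area_um2` must be a single positive number", call. = FALSE)
  cohort <- eye_meta$cohort
  if (!is.null(cohort) && !cohort %in% c("MsDx", "MsDxF", "control"))
    stop("cohort must be one of 'MsDx', 'MsDxF', 'control'", call. = FALSE)
  structure(
    list(
      frames = frames,
      n_frames = length(frames),
      height_px = dims[1, 1],
      width_px = dims[2, 1],
      pixel_area_um2 = pixel_area_um2,
      eye_meta = eye_meta
    ),
    class = "bscan_stack"
  )
}

#' @export
print.bscan_stack <- function(x, ...) {
  cat(sprintf("<bscan_stack> %d frame(s), %d x %d px, %.3f um^2/px\n",
              x$n_frames, x$height_px, x$width_px, x$pixel_area_um2))
  if (length(x$eye_meta)) {
    meta <- vapply(x$eye_meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(meta), meta, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}
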