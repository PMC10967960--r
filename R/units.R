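#' Pixel area from scan geometry
#'
#' OCT B-scans sample a fixed transverse scan length with a fixed number of
#' A-scans (columns); assuming isotropic pixels, the per-pixel area is the
#' square of the lateral pixel pitch. For the rodent posterior-pole protocol
#' (3 mm scan, 1536 columns) this gives 1.953 um laterally and 3.815 um^2
#' per pixel.
#'
#' @param scan_length_mm transverse length of one B-scan in millimetres.
#' @param n_cols number of pixels (A-scans) across the scan.
#' @return pixel area in square micrometres.
#' @examples
#' pixel_area_from_scan(3, 1536) # 3.8147 -> prints as 3.815
#' @export
pixel_area_from_scan <- function(scan_length_mm = 3, n_cols = 1536) {
  stopifnot(scan_length_mm > 0, n_cols >= 1)
  (scan_length_mm * 1000 / n_cols)^2
}

#' Total frame area from raster dimensions and pixel area
#'
#' @param width_px,height_px raster dimensions in pixels.
#' @param pixel_area_um2 per-pixel area in square micrometres.
#' @return frame area in square millimetres.
#' @examples
#' frame_area_mm2(1536, 496, 3.815) # 2.906 mm^2
#' @export
frame_area_mm2 <- function(width_px = 1536, height_px = 496,
                           pixel_area_um2 = 3.815) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_area_um2 > 0)
  width_px * height_px * pixel_area_um2 * 1e-6
}
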