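#' Read an OCT B-scan stack from disk
#'
#' Reads an ordered stack of greyscale B-scans from either a multipage TIFF
#' file or a directory of single-frame PNG/TIFF images (sorted
#' lexicographically, which matches the zero-padded frame names written by
#' [write_bscan_stack()]). Colour frames are reduced to greyscale by the
#' unweighted mean of their channels. Intensities are returned on the
#' normalised `[0, 1]` scale (the tiff and png readers divide by the
#' container's maximum representable value), so downstream thresholds are
#' bit-depth independent.
#'
#' AVI export from the acquisition device is not decoded here: no lossless
#' video decoder is available to R, and lossy codecs would perturb the
#' pixel statistics the analysis rests on. Export frames losslessly
#' (TIFF/PNG) instead; `.avi` paths raise an informative error.
#'
#' @param path a multipage TIFF file or a directory containing PNG/TIFF
#'   frames.
#' @param pixel_area_um2 pixel area in square micrometres (default the
#'   rodent-protocol 3.815; see [pixel_area_from_scan()]).
#' @param eye_meta optional eye metadata list, see [bscan_stack()].
#' @return a [bscan_stack()].
#' @export
read_bscan_stack <- function(path, pixel_area_um2 = 3.815,
                             eye_meta = list()) {
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    stop("AVI decoding is not supported; export the scan as a lossless ",
         "image stack (multipage TIFF or per-frame PNG/TIFF) and point ",
         "read_bscan_stack() at that", call. = FALSE)
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file or directory",
         call. = FALSE)

  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L)
      stop("no PNG/TIFF frames found in '", path, "'", call. = FALSE)
    frames <- lapply(files, read_frame)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L)
      stop("'", path, "' contains no frames", call. = FALSE)
    frames <- lapply(pages, to_grey)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    frames <- list(read_frame(path))
  } else {
    stop("unsupported container '", path,
         "': expected a directory, .tif/.tiff or .png", call. = FALSE)
  }

  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame sizes in '", path, "'", call. = FALSE)
  bscan_stack(frames, pixel_area_um2 = pixel_area_um2, eye_meta = eye_meta)
}

read_frame <- function(file) {
  img <- if (grepl("\\.png$", file, ignore.case = TRUE)) {
    png::readPNG(file)
  } else {
    tiff::readTIFF(file)
  }
  to_grey(img)
}

# unweighted channel mean; drops an alpha channel if present
to_grey <- function(img) {
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch == 4L || nch == 2L) # RGBA / grey+alpha
      img <- img[, , seq_len(nch - 1L), drop = FALSE]
    img <- apply(img, c(1, 2), mean)
  }
  as.matrix(img)
}

#' Write a B-scan stack as lossless images
#'
#' Writes either one multipage 16-bit TIFF or a directory of zero-padded
#' per-frame 16-bit TIFFs. Frames quantised to the 16-bit grid (as the
#' phantom generator emits) round-trip pixel-identically through
#' [read_bscan_stack()].
#'
#' @param stack a [bscan_stack()].
#' @param path output file (`.tif`/`.tiff`) or directory (created if
#'   needed; frames written as `frame_001.tif`, ...).
#' @return `path`, invisibly.
#' @export
write_bscan_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bscan_stack"))
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    ok <- tiff::writeTIFF(lapply(stack$frames, clamp01), path,
                          bits.per.sample = 16L)
    if (!all(ok > 0)) stop("failed to write '", path, "'", call. = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(stack$n_frames)) {
      f <- file.path(path, sprintf("frame_%03d.tif", i))
      tiff::writeTIFF(clamp01(stack$frames[[i]]), f, bits.per.sample = 16L)
    }
  }
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Write / read a per-opacity feature table
#'
#' One row per detected opacity with the columns produced by
#' [detect_opacities()] (frame index, centroid, pixel and physical area,
#' mean intensity, eccentricity, orientation, size class) plus any eye
#' metadata columns present. The `pixels` list-column is dropped; all
#' numeric fields round-trip at full precision.
#'
#' @param records a tibble of opacity records (possibly zero rows).
#' @param path CSV output path.
#' @return `path`, invisibly (`write_feature_table`); a tibble
#'   (`read_feature_table`).
#' @export
write_feature_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  records <- records[, setdiff(names(records), "pixels"), drop = FALSE]
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write per-eye summary rows
#'
#' Serialises one or more [summarise_eye()] results to a CSV with one row
#' per (animal, eye, week).
#'
#' @param summaries a list of `eye_summary` objects or a single one.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_eye_summary <- function(summaries, path) {
  if (inherits(summaries, "eye_summary")) summaries <- list(summaries)
  rows <- do.call(rbind, lapply(summaries, as.data.frame))
  readr::write_csv(tibble::as_tibble(rows), path)
  invisible(path)
}
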