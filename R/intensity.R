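#' VIT/RPE relative intensity of one B-scan
#'
#' Mean pixel intensity over the vitreous compartment divided by the mean
#' over the RPE band. Because it is a ratio of means of the same frame, it
#' is invariant under global intensity rescaling, which makes it
#' comparable across acquisitions. The vitreous region deliberately
#' includes any hyperreflective opacities: the ratio is a turbidity proxy
#' and cells contribute to turbidity.
#'
#' @param frame numeric matrix on `[0, 1]`.
#' @param seg a [segment_layers()] result for this frame.
#' @param margin_rows,top_margin_rows passed to [vitreous_mask()].
#' @return the scalar VIT/RPE ratio.
#' @export
vit_rpe_ratio <- function(frame, seg, margin_rows = 2, top_margin_rows = 0) {
  stopifnot(is.matrix(frame), inherits(seg, "layer_segmentation"))
  vmask <- vitreous_mask(seg, dim(frame), margin_rows, top_margin_rows)
  rmask <- rpe_mask(seg, dim(frame))
  if (!any(vmask) || !any(rmask))
    stop("empty vitreous or RPE region", call. = FALSE)
  rpe_mean <- mean(frame[rmask])
  if (rpe_mean == 0)
    stop("degenerate frame: RPE mean intensity is zero", call. = FALSE)
  mean(frame[vmask]) / rpe_mean
}

#' Per-eye VIT/RPE relative intensity
#'
#' Computes the VIT/RPE ratio of every B-scan in a stack and their
#' unweighted mean, the per-eye value. Frames whose segmentation fails are
#' excluded (not imputed) and reported in `failed_frames`; the eye mean is
#' over the remaining frames.
#'
#' @param stack a [bscan_stack()].
#' @param segs optional list of [segment_layers()] results, one per frame;
#'   segmented on the fly when `NULL`.
#' @param margin_rows,top_margin_rows passed to [vit_rpe_ratio()].
#' @param ... further arguments to [segment_layers()].
#' @return an object of class `vit_rpe_result`: `per_frame_ratio`,
#'   `vit_mean_intensity`, `rpe_mean_intensity` (aligned with frames;
#'   `NA` where segmentation failed), `eye_mean`, `failed_frames`.
#' @export
eye_vit_rpe <- function(stack, segs = NULL, margin_rows = 2,
                        top_margin_rows = 0, ...) {
  stopifnot(inherits(stack, "bscan_stack"))
  n <- stack$n_frames
  if (!is.null(segs) && length(segs) != n)
    stop("need one segmentation per frame", call. = FALSE)
  ratio <- vit <- rpe <- rep(NA_real_, n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    frame <- stack$frames[[i]]
    res <- tryCatch({
      seg <- if (is.null(segs)) {
        segment_layers(frame, frame_index = i, ...)
      } else segs[[i]]
      vmask <- vitreous_mask(seg, dim(frame), margin_rows, top_margin_rows)
      rmask <- rpe_mask(seg, dim(frame))
      c(mean(frame[vmask]), mean(frame[rmask]))
    }, error = function(e) NULL)
    if (is.null(res) || res[2] == 0) { failed <- c(failed, i); next }
    vit[i] <- res[1]; rpe[i] <- res[2]; ratio[i] <- res[1] / res[2]
  }
  ok <- !is.na(ratio)
  if (!any(ok))
    stop("segmentation failed on every frame", call. = FALSE)
  structure(
    list(per_frame_ratio = ratio, vit_mean_intensity = vit,
         rpe_mean_intensity = rpe, eye_mean = mean(ratio[ok]),
         failed_frames = failed),
    class = "vit_rpe_result"
  )
}

#' @export
print.vit_rpe_result <- function(x, ...) {
  cat(sprintf("<vit_rpe_result> eye mean %.4f over %d frame(s)",
              x$eye_mean, sum(!is.na(x$per_frame_ratio))))
  if (length(x$failed_frames))
    cat(sprintf(" (%d failed: %s)", length(x$failed_frames),
                paste(x$failed_frames, collapse = ",")))
  cat("\n")
  invisible(x)
}
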