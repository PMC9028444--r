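#' Median-centre an image
#'
#' Subtracts the scalar median of all pixels (even pixel counts use the mean
#' of the two middle values). For absolute images the median, unlike the
#' mean, leaves an ideal two-valued reconstruction's background at exactly
#' zero, which is why it anchors the modified figures of merit.
#'
#' @param image Numeric matrix.
#' @return The centred image (same dimensions, median 0).
#' @export
median_subtract <- function(image) {
  image - stats::median(image)
}

#' Evaluation mask of a centred reconstruction
#'
#' Below-mode (target less conductive than background): pixels strictly less
#' than half the image minimum. Above-mode: pixels strictly greater than half
#' the maximum. The inequality is strict, so pixels exactly at the threshold
#' are excluded.
#'
#' @param centered Output of [median_subtract()].
#' @param target_sign `"below"` or `"above"`, chosen by the sign of the
#'   target's contrast relative to background.
#' @return Logical matrix; carries attribute `empty = TRUE` when no pixel
#'   qualifies (an all-flat image), with a warning.
#' @export
eval_mask <- function(centered, target_sign = c("below", "above")) {
  target_sign <- match.arg(target_sign)
  m <- if (target_sign == "below") centered < 0.5 * min(centered)
       else centered > 0.5 * max(centered)
  if (!any(m)) {
    warning("evaluation mask is empty (flat image?)")
    attr(m, "empty") <- TRUE
  }
  m
}

#' Amplitude response
#'
#' Sum of the centred pixel values inside the evaluation mask. Its spread
#' across a position series measures how stably the reconstruction renders
#' the same target at different locations.
#'
#' @param centered Centred image.
#' @param mask Logical mask from [eval_mask()].
#' @return Scalar; `NA` (flagged) for an empty mask.
#' @export
amplitude_response <- function(centered, mask) {
  if (!any(mask)) return(structure(NA_real_, reason = "empty mask"))
  sum(centered[mask])
}

#' Position error
#'
#' Euclidean distance, in pixels, between the unweighted centroid of the
#' mask pixels and the ground-truth target position. With
#' `weighted = TRUE` the centroid is weighted by |centred amplitude|.
#'
#' @param mask Logical mask.
#' @param truth `c(tx, ty)` ground-truth position in 0-based pixel
#'   coordinates (see [position_to_pixels()]).
#' @param centered Centred image, only needed when `weighted = TRUE`.
#' @param weighted Use amplitude-weighted centroid.
#' @return Scalar distance in pixels; `NA` (flagged) for an empty mask.
#' @export
position_error <- function(mask, truth, centered = NULL, weighted = FALSE) {
  if (!any(mask)) return(structure(NA_real_, reason = "empty mask"))
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2L] - 1; py <- idx[, 1L] - 1      # 0-based (x = col, y = row)
  if (weighted) {
    stopifnot(!is.null(centered))
    w <- abs(centered[mask])
    cx <- sum(w * px) / sum(w); cy <- sum(w * py) / sum(w)
  } else {
    cx <- mean(px); cy <- mean(py)
  }
  sqrt((cx - truth[1])^2 + (cy - truth[2])^2)
}

#' Ringing
#'
#' Population standard deviation of the centred pixels outside the mask:
#' background oscillation artefacts around the target.
#'
#' @param centered Centred image.
#' @param mask Logical mask.
#' @return Scalar; `NA` (flagged) when the mask covers every pixel.
#' @export
ringing <- function(centered, mask) {
  out <- centered[!mask]
  if (length(out) == 0L) return(structure(NA_real_, reason = "mask covers image"))
  sqrt(mean((out - mean(out))^2))     # population convention
}

#' Figures of merit of one reconstruction
#'
#' @param image Raw reconstructed image (any global offset is absorbed by
#'   the median subtraction).
#' @param truth_px `c(tx, ty)` target position in pixels.
#' @param target_sign `"below"` or `"above"`; see [eval_mask()].
#' @return Object of class `figures_of_merit`: list with `AR`, `PE`, `RNG`.
#' @export
figures_of_merit <- function(image, truth_px, target_sign = "below") {
  centered <- median_subtract(image)
  mask <- suppressWarnings(eval_mask(centered, target_sign))
  structure(list(AR = amplitude_response(centered, mask),
                 PE = position_error(mask, truth_px),
                 RNG = ringing(centered, mask)),
            class = "figures_of_merit")
}

#' @export
print.figures_of_merit <- function(x, ...) {
  cat(sprintf("AR %.4g  PE %.4g  RNG %.4g\n", x$AR, x$PE, x$RNG))
  invisible(x)
}

#' Summarize a position series of figures of merit
#'
#' @param fom_list List of `figures_of_merit`.
#' @return data.frame with one row per metric (AR, PE, RNG in that order):
#'   `mean`, `sd` (sample convention), `n_used`, `n_missing`.
#' @export
summarize_series <- function(fom_list) {
  stopifnot(length(fom_list) >= 2L)
  out <- lapply(c("AR", "PE", "RNG"), function(metric) {
    v <- vapply(fom_list, function(f) as.numeric(f[[metric]]), numeric(1))
    ok <- !is.na(v)
    data.frame(metric = metric, mean = mean(v[ok]), sd = stats::sd(v[ok]),
               n_used = sum(ok), n_missing = sum(!ok))
  })
  do.call(rbind, out)
}
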