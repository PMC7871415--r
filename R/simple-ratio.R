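#' Measure background intensity from a rectangular region
#'
#' Pools the region over all time points and z-slices and returns its mean
#' — the convention for estimating I_b from a non-fluorescent area of the
#' image when no blank acquisition is available.
#'
#' @param stack a \code{TimeLapseStack}.
#' @param roi integer vector \code{c(x, y, w, h)}: 1-based top-left corner
#'   and extent, in X (column) / Y (row) pixel coordinates.
#' @return a \code{\link{BackgroundEstimate}} with source
#'   \code{"measured-roi"}.
#' @export
measureBackgroundROI <- function(stack, roi) {
  stopifnot(is(stack, "TimeLapseStack"))
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(!is.finite(roi)))
    stop("roi must be c(x, y, w, h)")
  d <- dim(stack@frames)
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 1L || h < 1L) stop("empty roi")
  if (x < 1L || y < 1L || x + w - 1L > d[4] || y + h - 1L > d[3])
    stop("roi out of frame bounds (frame is ", d[3], " rows x ",
         d[4], " columns)")
  v <- mean(stack@frames[, , y:(y + h - 1L), x:(x + w - 1L)])
  new("BackgroundEstimate", value = v, source = "measured-roi")
}

.asBackground <- function(background, bitDepth) {
  if (is(background, "BackgroundEstimate")) return(background)
  if (!is.numeric(background) || length(background) != 1L)
    stop("background must be a scalar or a BackgroundEstimate")
  if (background < 0 || background >= 2^bitDepth)
    stop("background ", background, " outside the ", bitDepth,
         "-bit range")
  new("BackgroundEstimate", value = as.numeric(background),
      source = "user")
}

#' Simple-ratio bleach correction
#'
#' Rescales every frame so its background-subtracted mean matches that of
#' the first frame.  With per-frame mean \eqn{\bar I_i} and background
#' \eqn{I_b}, each pixel of frame i becomes
#' \deqn{I_i^c(x,y) = \frac{\bar I_0 - I_b}{\bar I_i - I_b}\,
#'       (I_i(x,y) - I_b).}
#' The ratio at i = 0 is exactly 1.  In consequence the corrected mean of
#' every frame equals \eqn{\bar I_0 - I_b} exactly (float output); this
#' algebraic mean conservation holds whatever value of \eqn{I_b} is
#' supplied, so any drift seen in practice comes from integer rounding and
#' clipping of the exported image, not from the equation.
#'
#' With \code{legacyNoSubtract = TRUE} the ratio multiplies the raw pixels
#' without subtracting \eqn{I_b} from the pixel term, reproducing the
#' historical plugin behaviour (the ratio itself is still computed from
#' background-subtracted means).
#'
#' Negative intermediate values (pixels below \eqn{I_b}) are kept as
#' negative numbers; they are clamped to zero only by the preserve dtype
#' policy on export.
#'
#' @param stack a \code{TimeLapseStack}.
#' @param background scalar I_b or a \code{BackgroundEstimate}; must
#'   satisfy \eqn{\bar I_i - I_b > 0} for every frame.
#' @param legacyNoSubtract logical; multiply raw pixels instead of
#'   background-subtracted pixels.
#' @return a \code{\link{BleachCorrection}}.
#' @export
correctSimpleRatio <- function(stack, background,
                               legacyNoSubtract = FALSE) {
  stopifnot(is(stack, "TimeLapseStack"))
  bg <- .asBackground(background, stack@bitDepth)
  Ib <- bg@value
  m <- meanSeries(stack)
  bad <- which(m <= Ib)
  if (length(bad))
    stop("mean intensity of frame ", bad[1] - 1L, " (", signif(m[bad[1]], 6),
         ") is not above the background ", Ib,
         ": the simple-ratio correction is undefined")
  ratio <- (m[1] - Ib) / (m - Ib)
  d <- dim(stack@frames)
  corrected <- array(0, dim = d)
  for (t in seq_len(d[1])) {
    f <- stack@frames[t, , , , drop = FALSE]
    corrected[t, , , ] <- if (legacyNoSubtract) ratio[t] * f
                          else ratio[t] * (f - Ib)
  }
  post <- .meanSeries(corrected)
  rep <- data.frame(frame_index = seq_len(d[1]) - 1L, pre_mean = m,
                    post_mean = post,
                    ratio_or_lut_id = sprintf("%.10g", ratio),
                    clipped_pixel_count = 0L)
  new("BleachCorrection", corrected = corrected, method = "simple-ratio",
      report = rep, backgroundUsed = Ib,
      warnings = if (legacyNoSubtract) "legacy mode: pixel term not background-subtracted"
                 else character(0),
      sourceBitDepth = stack@bitDepth)
}
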