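#' Histogram and CDF of one time point
#'
#' Pools all z-slices of time point \code{t} into one raw-count histogram
#' over the full dtype range (256 or 65536 bins, never rebinned) and its
#' cumulative form.
#'
#' @param stack a \code{TimeLapseStack} with integer-valued pixels.
#' @param t 0-based frame index.
#' @return a \code{\link{FrameCDF}}.
#' @export
frameCDF <- function(stack, t) {
  stopifnot(is(stack, "TimeLapseStack"))
  T <- dim(stack@frames)[1]
  if (t < 0 || t >= T) stop("frame index ", t, " out of range 0..", T - 1)
  nb <- 2L^stack@bitDepth
  pix <- as.integer(stack@frames[t + 1L, , , ])
  h <- tabulate(pix + 1L, nbins = nb)
  new("FrameCDF", histogram = as.numeric(h), cdf = cumsum(as.numeric(h)),
      nPixels = length(pix), bitDepth = stack@bitDepth)
}

#' Build a histogram-matching lookup table
#'
#' For every representable source value p the table holds
#' \eqn{p' = CDF_{ref}^{-1}(CDF_{src}(p))}, with the discrete inverse
#' taken as the smallest q such that \eqn{CDF_{ref}(q) \ge CDF_{src}(p)}.
#' Monotonicity follows from the CDFs being non-decreasing.  Raw counts
#' are compared directly, so reference and source must hold equally many
#' pixels.
#'
#' @param reference the \code{FrameCDF} of the reference frame.
#' @param source the \code{FrameCDF} of the frame to be matched.
#' @return a \code{\link{MatchingLUT}}.
#' @export
buildMatchingLUT <- function(reference, source) {
  stopifnot(is(reference, "FrameCDF"), is(source, "FrameCDF"))
  if (length(reference@cdf) != length(source@cdf))
    stop("reference and source must share the bit depth / bin count")
  if (reference@nPixels != source@nPixels)
    stop("reference and source must hold the same number of pixels (",
         reference@nPixels, " vs ", source@nPixels, ")")
  # smallest q with cdf_ref[q] >= v  ==  #{q : cdf_ref[q] < v} (0-based q);
  # counts are integers so "< v" is "<= v - 0.5"
  tab <- findInterval(source@cdf - 0.5, reference@cdf)
  new("MatchingLUT", table = as.integer(tab),
      bitDepth = reference@bitDepth)
}

.lutChecksum <- function(lut) {
  v <- as.numeric(lut@table)
  sprintf("lut%.0f", sum(v * (seq_along(v) %% 9973)) %% 2^31)
}

#' Histogram-matching bleach correction
#'
#' Replaces every frame i > 0 pixelwise through the lookup table that
#' matches its pooled histogram to that of frame 0; frame 0 is unchanged.
#' Outputs stay integers in the source dtype by construction, so no
#' rounding or clipping is ever needed, and no background estimate is
#' consumed.  Applying the correction twice equals applying it once.
#'
#' @param stack a \code{TimeLapseStack}.
#' @return a \code{\link{BleachCorrection}}; the report's
#'   ratio_or_lut_id column carries a checksum of each frame's LUT.
#' @export
correctHistogramMatching <- function(stack) {
  stopifnot(is(stack, "TimeLapseStack"))
  d <- dim(stack@frames)
  pre <- meanSeries(stack)
  ref <- frameCDF(stack, 0)
  corrected <- array(0, dim = d)
  corrected[1, , , ] <- stack@frames[1, , , ]
  lutIds <- character(d[1])
  lutIds[1] <- "identity"
  for (t in seq_len(d[1] - 1L)) {
    src <- frameCDF(stack, t)
    lut <- buildMatchingLUT(ref, src)
    pix <- as.integer(stack@frames[t + 1L, , , ])
    corrected[t + 1L, , , ] <- lut@table[pix + 1L]
    lutIds[t + 1L] <- .lutChecksum(lut)
  }
  post <- .meanSeries(corrected)
  rep <- data.frame(frame_index = seq_len(d[1]) - 1L, pre_mean = pre,
                    post_mean = post, ratio_or_lut_id = lutIds,
                    clipped_pixel_count = 0L)
  new("BleachCorrection", corrected = corrected,
      method = "histogram-matching", report = rep,
      backgroundUsed = numeric(0), sourceBitDepth = stack@bitDepth)
}

#' Subtract a constant background with clamping at zero
#'
#' Explicit pre-processing step used when comparing histogram matching
#' with the background-subtracting methods; it is not part of the
#' matching algorithm itself.  Mirrors integer image arithmetic: values
#' below the subtrahend clamp to 0.
#'
#' @param stack a \code{TimeLapseStack}.
#' @param value scalar to subtract.
#' @return a \code{TimeLapseStack}.
#' @export
subtractBackground <- function(stack, value) {
  stopifnot(is(stack, "TimeLapseStack"), is.numeric(value),
            length(value) == 1L)
  f <- stack@frames - value
  f[f < 0] <- 0
  new("TimeLapseStack", frames = round(f), bitDepth = stack@bitDepth,
      axisOrder = stack@axisOrder)
}
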