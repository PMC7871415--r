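#' Pixel data of a stack
#' @param x a \code{TimeLapseStack} or \code{BleachCorrection}.
#' @return the 4D array ordered T, Z, Y, X.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' Bit depth accessor
#' @param x a \code{TimeLapseStack} or \code{BleachCorrection}.
#' @return 8 or 16.
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Number of time points
#' @param x a stack-like object.
#' @return integer T.
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Per-time-point mean intensity series
#'
#' The arithmetic mean over all Z*Y*X pixels of each time point, computed
#' in 64-bit floating point, indexed by frame number i = 0..T-1.  This is
#' the quantity the ratio and exponential-fitting corrections operate on.
#'
#' @param x a \code{TimeLapseStack}, \code{BleachCorrection} or 4D array.
#' @return numeric vector of length T.
#' @export
setGeneric("meanSeries", function(x) standardGeneric("meanSeries"))

#' Per-frame correction report
#' @param x a \code{BleachCorrection}.
#' @return data.frame with columns frame_index, pre_mean, post_mean,
#'   ratio_or_lut_id, clipped_pixel_count.
#' @export
setGeneric("frameReport", function(x) standardGeneric("frameReport"))

#' Fit parameters of a correction
#' @param x a \code{BleachCorrection}.
#' @return list of \code{ExpFit} objects (empty for methods that fit
#'   nothing).
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))

#' @rdname frames
#' @export
setMethod("frames", "TimeLapseStack", function(x) x@frames)
#' @rdname frames
#' @export
setMethod("frames", "BleachCorrection", function(x) x@corrected)

#' @rdname bitDepth
#' @export
setMethod("bitDepth", "TimeLapseStack", function(x) x@bitDepth)
#' @rdname bitDepth
#' @export
setMethod("bitDepth", "BleachCorrection", function(x) x@sourceBitDepth)

#' @rdname nTimePoints
#' @export
setMethod("nTimePoints", "TimeLapseStack", function(x) dim(x@frames)[1])
#' @rdname nTimePoints
#' @export
setMethod("nTimePoints", "BleachCorrection",
          function(x) dim(x@corrected)[1])

.meanSeries <- function(a) {
  d <- dim(a)
  vapply(seq_len(d[1]),
         function(t) mean(as.double(a[t, , , , drop = FALSE])),
         numeric(1))
}

#' @rdname meanSeries
#' @export
setMethod("meanSeries", "TimeLapseStack", function(x) .meanSeries(x@frames))
#' @rdname meanSeries
#' @export
setMethod("meanSeries", "BleachCorrection",
          function(x) .meanSeries(x@corrected))
#' @rdname meanSeries
#' @export
setMethod("meanSeries", "array", function(x) {
  stopifnot(length(dim(x)) == 4L)
  .meanSeries(x)
})

#' @rdname frameReport
#' @export
setMethod("frameReport", "BleachCorrection", function(x) x@report)

#' @rdname fitParams
#' @export
setMethod("fitParams", "BleachCorrection", function(x) x@fitParams)

setMethod("show", "TimeLapseStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "TimeLapseStack: %d time points, %d z-slice(s), %d x %d pixels, %d-bit (%s)\n",
    d[1], d[2], d[3], d[4], object@bitDepth, object@axisOrder))
  m <- meanSeries(object)
  cat(sprintf("  mean intensity: %.2f (frame 0) -> %.2f (frame %d)\n",
              m[1], m[length(m)], length(m) - 1L))
})

setMethod("show", "BleachCorrection", function(object) {
  d <- dim(object@corrected)
  cat(sprintf("BleachCorrection (%s): %d frames of %d x %d x %d\n",
              object@method, d[1], d[2], d[3], d[4]))
  if (length(object@backgroundUsed))
    cat(sprintf("  background used: %g\n", object@backgroundUsed))
  m <- meanSeries(object)
  cat(sprintf("  corrected means: %.3f .. %.3f (sd %.4f)\n",
              min(m), max(m), stats::sd(m)))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf(
    "ExpFit: a = %.6g, b = %.6g, c = %.6g  (rss %.4g, %s%s)\n",
    object@a, object@b, object@c, object@rss,
    if (object@converged) "converged" else "NOT converged",
    if (object@degenerate) ", degenerate" else ""))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "BleachSimConfig", function(object) {
  s <- object@shape
  cat(sprintf(
    "BleachSimConfig: T=%d Z=%d %dx%d, %d blobs (A=%g, sigma=%g), b=%g, background=%g, noise %s sd=%g, seed=%d, %d-bit\n",
    s[1], s[2], s[3], s[4], object@nBlobs, object@blobAmplitude,
    object@blobSigma, object@decayB, object@background,
    object@noiseModel, object@noiseSigma, object@seed, object@dtype))
})
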