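#' @import methods
NULL

#' TimeLapseStack: a single-channel fluorescence time-lapse
#'
#' Container for an ordered sequence of T time points, each a Z x Y x X
#' image (2D series are stored with Z = 1).  Pixel values are kept on the
#' unsigned-integer scale of the source data (8- or 16-bit); the array may
#' hold float values within that range for intermediate products such as
#' noiseless synthetic scenes.
#'
#' @slot frames 4D numeric array ordered T, Z, Y, X.
#' @slot bitDepth integer, 8 or 16; pixel values must lie in
#'   \code{[0, 2^bitDepth - 1]}.
#' @slot axisOrder character tag recording the source axis convention
#'   (e.g. \code{"TZYX"} for an ImageJ hyperstack, \code{"pages"} for a
#'   plain multi-page TIFF grouped by a z-per-t hint).
#' @export
setClass("TimeLapseStack",
  representation(frames = "array", bitDepth = "integer",
                 axisOrder = "character"),
  prototype(bitDepth = 8L, axisOrder = "TZYX"))

setValidity("TimeLapseStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L)
    return("frames must be a 4D array ordered T, Z, Y, X")
  if (d[1] < 2L)
    return("a time-lapse needs T >= 2 (frame 0 is the reference)")
  if (any(d == 0L))
    return("degenerate shape: all of T, Z, Y, X must be positive")
  if (!(object@bitDepth %in% c(8L, 16L)))
    return("bitDepth must be 8 or 16")
  rng <- range(object@frames)
  if (!all(is.finite(rng)))
    return("frames contain non-finite values")
  if (rng[1] < 0 || rng[2] > 2^object@bitDepth - 1)
    return(sprintf("pixel values outside [0, %d]", 2^object@bitDepth - 1L))
  TRUE
})

#' BackgroundEstimate: a scalar background intensity
#'
#' The additive offset I_b measured in non-fluorescent regions, spatially
#' and temporally constant.
#'
#' @slot value scalar intensity in pixel units.
#' @slot source one of \code{"user"}, \code{"measured-roi"}, \code{"fit"}.
#' @export
setClass("BackgroundEstimate",
  representation(value = "numeric", source = "character"),
  prototype(source = "user"))

setValidity("BackgroundEstimate", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    return("value must be a finite scalar")
  if (object@value < 0)
    return("background intensity cannot be negative")
  if (!(object@source %in% c("user", "measured-roi", "fit")))
    return("source must be user, measured-roi or fit")
  TRUE
})

#' ExpFit: parameters of a single-exponential decay fit
#'
#' Least-squares estimates for the model \eqn{a e^{-b i} + c} fitted to a
#' per-time-point mean series indexed by frame number i = 0..T-1.
#'
#' @slot a amplitude (intensity units).
#' @slot b decay rate per frame (negative b is reported, not rejected, and
#'   flagged as "not a decay").
#' @slot c offset (intensity units); the estimated background.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical optimizer status.
#' @slot degenerate logical; TRUE when the series is (numerically)
#'   constant so that a and b are not identifiable.
#' @slot warnings character vector of fit warnings.
#' @export
setClass("ExpFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 rss = "numeric", converged = "logical",
                 degenerate = "logical", warnings = "character"),
  prototype(converged = FALSE, degenerate = FALSE, warnings = character(0)))

setValidity("ExpFit", function(object) {
  for (s in c("a", "b", "c", "rss"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("slot %s must be a finite scalar", s))
  if (object@rss < 0) return("rss must be >= 0")
  TRUE
})

#' FrameCDF: pixel-value histogram and CDF of one time point
#'
#' Raw-count histogram H(p) over the full dtype range p = 0..2^bitDepth-1
#' (all z-slices of the time point pooled) and its cumulative form
#' CDF(p) = sum_{x <= p} H(x).
#'
#' @slot histogram integer counts, one bin per representable pixel value.
#' @slot cdf cumulative counts; non-decreasing, top bin equals nPixels.
#' @slot nPixels total pixel count of the time point.
#' @slot bitDepth 8 or 16.
#' @export
setClass("FrameCDF",
  representation(histogram = "numeric", cdf = "numeric",
                 nPixels = "numeric", bitDepth = "integer"))

setValidity("FrameCDF", function(object) {
  nb <- 2^object@bitDepth
  if (length(object@histogram) != nb || length(object@cdf) != nb)
    return("histogram and cdf must span the full dtype range")
  if (any(diff(object@cdf) < 0)) return("cdf must be non-decreasing")
  if (object@cdf[nb] != object@nPixels)
    return("cdf at the top bin must equal nPixels")
  if (!isTRUE(all.equal(object@cdf, cumsum(object@histogram))))
    return("cdf must be the cumulative sum of the histogram")
  TRUE
})

#' MatchingLUT: histogram-specification lookup table
#'
#' Monotone map from every representable source pixel value p to the
#' matched value p' = CDF_ref^{-1}(CDF_src(p)), with the inverse taken as
#' the smallest q such that CDF_ref(q) >= CDF_src(p).
#'
#' @slot table integer vector of length 2^bitDepth; \code{table[p + 1]} is
#'   the matched value for source value p (0-based values).
#' @slot bitDepth 8 or 16.
#' @export
setClass("MatchingLUT",
  representation(table = "integer", bitDepth = "integer"))

setValidity("MatchingLUT", function(object) {
  nb <- 2^object@bitDepth
  if (length(object@table) != nb)
    return("table must cover the full dtype range")
  if (any(object@table < 0L) || any(object@table > nb - 1L))
    return("table outputs outside the dtype range")
  if (any(diff(object@table) < 0L))
    return("table must be monotone non-decreasing")
  TRUE
})

#' BleachCorrection: result of a bleach-correction run
#'
#' Holds the corrected stack in exact floating point (no rounding or
#' clipping applied; see \code{\link{applyDtypePolicy}} /
#' \code{\link{writeStack}} for integer export), a per-frame report, and
#' method-specific parameters.
#'
#' @slot corrected 4D numeric array, same T, Z, Y, X as the input.
#' @slot method "simple-ratio", "exponential-fit" or "histogram-matching".
#' @slot report data.frame with one row per time point: frame_index,
#'   pre_mean, post_mean, ratio_or_lut_id, clipped_pixel_count.
#' @slot backgroundUsed numeric(1) or numeric(0) when no background is
#'   consumed (histogram matching).
#' @slot fitParams list of \code{ExpFit} (pass1/pass2) or empty.
#' @slot warnings character vector (clipping, non-decay fits, ...).
#' @slot sourceBitDepth bit depth of the input stack.
#' @export
setClass("BleachCorrection",
  representation(corrected = "array", method = "character",
                 report = "data.frame", backgroundUsed = "numeric",
                 fitParams = "list", warnings = "character",
                 sourceBitDepth = "integer"),
  prototype(backgroundUsed = numeric(0), fitParams = list(),
            warnings = character(0)))

setValidity("BleachCorrection", function(object) {
  d <- dim(object@corrected)
  if (length(d) != 4L)
    return("corrected must be a 4D array ordered T, Z, Y, X")
  if (nrow(object@report) != d[1])
    return("per-frame report must have exactly T rows")
  need <- c("frame_index", "pre_mean", "post_mean", "ratio_or_lut_id",
            "clipped_pixel_count")
  if (!all(need %in% names(object@report)))
    return("report is missing required columns")
  if (!(object@method %in%
        c("simple-ratio", "exponential-fit", "histogram-matching")))
    return("unknown method")
  TRUE
})

#' BleachSimConfig: parameters of the synthetic bleached-stack generator
#'
#' The simulator draws Gaussian blobs over a zero signal, scales the
#' signal (never the background offset) by exp(-b i), adds a constant
#' background and additive noise, and discretizes to the requested dtype.
#'
#' @slot shape integer T, Z, Y, X.
#' @slot nBlobs number of Gaussian fluorescent blobs.
#' @slot blobAmplitude peak intensity of each blob.
#' @slot blobSigma Gaussian sigma of each blob, in pixels.
#' @slot decayB bleaching rate b per frame (>= 0).
#' @slot background constant offset c, excluded from the decay.
#' @slot noiseSigma additive Gaussian noise sd (0 disables noise).
#' @slot noiseModel "gaussian" or "poisson".
#' @slot seed RNG seed; identical config + seed gives a bit-identical
#'   stack.
#' @slot dtype 8 or 16.
#' @export
setClass("BleachSimConfig",
  representation(shape = "integer", nBlobs = "integer",
                 blobAmplitude = "numeric", blobSigma = "numeric",
                 decayB = "numeric", background = "numeric",
                 noiseSigma = "numeric", noiseModel = "character",
                 seed = "integer", dtype = "integer"))

setValidity("BleachSimConfig", function(object) {
  if (length(object@shape) != 4L || any(object@shape <= 0L))
    return("shape must be four positive integers T, Z, Y, X")
  if (object@shape[1] < 2L) return("T >= 2 required")
  if (object@decayB < 0) return("decay rate b must be >= 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!(object@noiseModel %in% c("gaussian", "poisson")))
    return("noiseModel must be gaussian or poisson")
  if (!(object@dtype %in% c(8L, 16L))) return("dtype must be 8 or 16")
  if (object@background < 0 || object@background > 2^object@dtype - 1)
    return("background not representable in dtype")
  TRUE
})
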