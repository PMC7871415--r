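#' Configuration for the synthetic bleached-stack generator
#'
#' Defaults are the package's standard fixture: a 30-frame, 4-slice,
#' 64 x 64, 8-bit stack of 20 Gaussian blobs (peak 120, sigma 3 px)
#' bleaching at b = 0.08 per frame over a constant background of 68 with
#' additive Gaussian noise of sd 1, seed 42 — an idealised stand-in for a
#' bleaching yeast movie: signal decays as exp(-b i), the camera offset
#' does not.
#'
#' @param T,Z,Y,X stack shape (time points, z-slices, rows, columns).
#' @param nBlobs number of Gaussian blobs.
#' @param blobAmplitude peak blob intensity.
#' @param blobSigma isotropic blob sigma in pixels.
#' @param decayB bleaching rate per frame (>= 0).
#' @param background constant offset, excluded from the decay.
#' @param noiseSigma additive Gaussian noise sd.
#' @param noiseModel \code{"gaussian"} or \code{"poisson"} (the latter
#'   ignores \code{noiseSigma} and draws each pixel from its expected
#'   value).
#' @param seed RNG seed; identical config + seed gives a bit-identical
#'   stack.
#' @param dtype 8 or 16.
#' @return a \code{\link{BleachSimConfig}}.
#' @export
bleachSimConfig <- function(T = 30L, Z = 4L, Y = 64L, X = 64L,
                            nBlobs = 20L, blobAmplitude = 120,
                            blobSigma = 3, decayB = 0.08,
                            background = 68, noiseSigma = 1,
                            noiseModel = "gaussian", seed = 42L,
                            dtype = 8L) {
  new("BleachSimConfig",
      shape = as.integer(c(T, Z, Y, X)), nBlobs = as.integer(nBlobs),
      blobAmplitude = as.numeric(blobAmplitude),
      blobSigma = as.numeric(blobSigma), decayB = as.numeric(decayB),
      background = as.numeric(background),
      noiseSigma = as.numeric(noiseSigma), noiseModel = noiseModel,
      seed = as.integer(seed), dtype = as.integer(dtype))
}

#' The standard synthetic fixture configuration
#'
#' The named, versioned parameter set every cross-method comparison in
#' this package refers to; see \code{\link{bleachSimConfig}} for the
#' values.
#'
#' @param seed RNG seed (default 42).
#' @return a \code{\link{BleachSimConfig}}.
#' @export
standardFixtureConfig <- function(seed = 42L) bleachSimConfig(seed = seed)

#' Generate the ground-truth scene (no bleach, no noise, no background)
#'
#' Places \code{nBlobs} separable 3D Gaussian blobs at seeded-uniform
#' positions over a zero signal and replicates the static scene across
#' all T frames.  Values are float; the background offset is not yet
#' added.
#'
#' @param config a \code{\link{BleachSimConfig}}.
#' @return a \code{TimeLapseStack} holding float signal values.
#' @export
generateScene <- function(config) {
  stopifnot(is(config, "BleachSimConfig"))
  s <- config@shape
  Z <- s[2]; Y <- s[3]; X <- s[4]
  set.seed(config@seed)
  slice <- array(0, dim = c(Z, Y, X))
  if (config@nBlobs > 0L) {
    cz <- stats::runif(config@nBlobs, 1, Z)
    cy <- stats::runif(config@nBlobs, 1, Y)
    cx <- stats::runif(config@nBlobs, 1, X)
    s2 <- 2 * config@blobSigma^2
    for (k in seq_len(config@nBlobs)) {
      gz <- exp(-(seq_len(Z) - cz[k])^2 / s2)
      gy <- exp(-(seq_len(Y) - cy[k])^2 / s2)
      gx <- exp(-(seq_len(X) - cx[k])^2 / s2)
      slice <- slice + config@blobAmplitude *
        outer(gz, outer(gy, gx))
    }
  }
  hi <- 2^config@dtype - 1
  slice[slice > hi] <- hi  # keep representable even before background
  fr <- array(0, dim = s)
  for (t in seq_len(s[1])) fr[t, , , ] <- slice
  new("TimeLapseStack", frames = fr, bitDepth = config@dtype,
      axisOrder = "TZYX")
}

#' Apply bleaching, background, noise and discretization to a scene
#'
#' Frame i becomes \code{clip(round(scene_i * exp(-b i) + background +
#' noise))} on the dtype range: bleaching scales the signal only, never
#' the background offset, matching the additive-background model in
#' which the offset is fitted and subtracted, not rescaled.  The noise
#' stream is seeded from \code{config@seed} so the operation is
#' deterministic on its own.
#'
#' @param scene ground-truth stack from \code{\link{generateScene}}.
#' @param config the same \code{\link{BleachSimConfig}}.
#' @return an integer-valued \code{TimeLapseStack}.
#' @export
applyBleach <- function(scene, config) {
  stopifnot(is(scene, "TimeLapseStack"), is(config, "BleachSimConfig"))
  s <- config@shape
  if (!identical(dim(scene@frames), as.integer(s)))
    stop("scene shape does not match the config")
  hi <- 2^config@dtype - 1
  set.seed(config@seed + 1L)
  fr <- array(0, dim = s)
  nPix <- prod(s[2:4])
  for (t in seq_len(s[1])) {
    expected <- scene@frames[t, , , ] * exp(-config@decayB * (t - 1)) +
      config@background
    v <- if (config@noiseModel == "poisson") {
      stats::rpois(nPix, lambda = as.vector(expected))
    } else if (config@noiseSigma > 0) {
      expected + stats::rnorm(nPix, sd = config@noiseSigma)
    } else expected
    v <- round(v)
    v[v < 0] <- 0
    v[v > hi] <- hi
    fr[t, , , ] <- v
  }
  new("TimeLapseStack", frames = fr, bitDepth = config@dtype,
      axisOrder = "TZYX")
}

#' Simulate a photobleached stack in one call
#'
#' \code{\link{generateScene}} followed by \code{\link{applyBleach}}.
#'
#' @param config a \code{\link{BleachSimConfig}}.
#' @return an integer-valued \code{TimeLapseStack}.
#' @export
simulateBleachedStack <- function(config = standardFixtureConfig()) {
  applyBleach(generateScene(config), config)
}

#' Write a simulated fixture TIFF plus a parameter sidecar
#'
#' Emits the same ImageJ-hyperstack TIFF dialect \code{\link{readStack}}
#' reads, and \code{<path>.params.txt} with the generating parameters as
#' key=value lines.
#'
#' @param config a \code{\link{BleachSimConfig}}.
#' @param path output TIFF path.
#' @return invisibly, the simulated \code{TimeLapseStack}.
#' @export
writeSimulation <- function(config, path) {
  stk <- simulateBleachedStack(config)
  writeStack(stk, path, dtype = "preserve")
  s <- config@shape
  lines <- c(sprintf("T=%d", s[1]), sprintf("Z=%d", s[2]),
             sprintf("Y=%d", s[3]), sprintf("X=%d", s[4]),
             sprintf("n_blobs=%d", config@nBlobs),
             sprintf("blob_amplitude=%g", config@blobAmplitude),
             sprintf("blob_sigma=%g", config@blobSigma),
             sprintf("decay_b=%g", config@decayB),
             sprintf("background=%g", config@background),
             sprintf("noise_sigma=%g", config@noiseSigma),
             sprintf("noise_model=%s", config@noiseModel),
             sprintf("seed=%d", config@seed),
             sprintf("dtype=%d", config@dtype))
  writeLines(lines, paste0(path, ".params.txt"))
  invisible(stk)
}
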