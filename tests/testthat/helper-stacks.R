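# Builders for small in-memory stacks used across the suite.

# Stack whose time points are spatially constant at the given means.
constStack <- function(means, Z = 1L, Y = 4L, X = 4L, bitDepth = 8L) {
  fr <- array(0, dim = c(length(means), Z, Y, X))
  for (t in seq_along(means)) fr[t, , , ] <- means[t]
  new("TimeLapseStack", frames = fr, bitDepth = as.integer(bitDepth),
      axisOrder = "TZYX")
}

# Stack from a list of per-time-point pixel vectors (filled into Y x X).
pixelStack <- function(pixelList, Y, X, Z = 1L, bitDepth = 8L) {
  fr <- array(0, dim = c(length(pixelList), Z, Y, X))
  for (t in seq_along(pixelList))
    fr[t, 1, , ] <- matrix(pixelList[[t]], nrow = Y, ncol = X)
  new("TimeLapseStack", frames = fr, bitDepth = as.integer(bitDepth),
      axisOrder = "TZYX")
}

# Seeded random integer stack.
randomStack <- function(T = 3L, Z = 2L, Y = 5L, X = 6L, bitDepth = 8L,
                        seed = 1L, lo = 0L, hi = 2^bitDepth - 1L) {
  set.seed(seed)
  fr <- array(as.double(sample(lo:hi, T * Z * Y * X, replace = TRUE)),
              dim = c(T, Z, Y, X))
  new("TimeLapseStack", frames = fr, bitDepth = as.integer(bitDepth),
      axisOrder = "TZYX")
}

# Independent rank-matching oracle for histogram specification: each
# pixel of src gets the reference value at its maximal tie rank (the CDF
# counts all pixels <= p, i.e. the top of the tie block).
rankMatchOracle <- function(refPixels, srcPixels) {
  sort(refPixels)[rank(srcPixels, ties.method = "max")]
}

# Small-fixture simulator config used where the full standard fixture
# would be overkill.
tinyFixtureConfig <- function(seed = 7L)
  bleachSimConfig(T = 8L, Z = 2L, Y = 16L, X = 16L, nBlobs = 4L,
                  seed = seed)
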