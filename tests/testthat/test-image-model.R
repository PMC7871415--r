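test_that("mean series pools all pixels of a time point in float", {
  expect_equal(meanSeries(constStack(c(10, 5))), c(10, 5))
  expect_equal(meanSeries(pixelStack(list(c(0, 1, 2, 3), c(4, 4, 4, 4)),
                                     Y = 2, X = 2)),
               c(1.5, 4))
  # pooled over z: slice means 4 and 6 with equal slice sizes -> 5
  fr <- array(0, dim = c(2, 2, 3, 3))
  fr[1, 1, , ] <- 4; fr[1, 2, , ] <- 6
  fr[2, 1, , ] <- 1; fr[2, 2, , ] <- 3
  stk <- new("TimeLapseStack", frames = fr, bitDepth = 8L,
             axisOrder = "TZYX")
  expect_equal(meanSeries(stk), c(5, 2))
})

test_that("mean series is permutation-invariant and zero on zero", {
  stk <- randomStack(seed = 11)
  m <- meanSeries(stk)
  fr <- frames(stk)
  set.seed(2)
  for (t in seq_len(dim(fr)[1])) {
    v <- as.vector(fr[t, , , ])
    fr[t, , , ] <- array(sample(v), dim = dim(fr)[-1])
  }
  perm <- new("TimeLapseStack", frames = fr, bitDepth = 8L,
              axisOrder = "TZYX")
  expect_equal(meanSeries(perm), m)
  expect_equal(meanSeries(constStack(c(0, 0, 0))), c(0, 0, 0))
})

test_that("stack validity enforces shape, range and T >= 2", {
  expect_error(constStack(5), "T >= 2")
  expect_error(constStack(c(300, 5), bitDepth = 8L), "outside")
  expect_silent(constStack(c(300, 5), bitDepth = 16L))
})

test_that("TIFF round trip preserves pixels bit-exact (8 and 16 bit)", {
  for (bd in c(8L, 16L)) {
    stk <- randomStack(T = 3, Z = 2, Y = 7, X = 5, bitDepth = bd,
                       seed = bd)
    p <- tempfile(fileext = ".tif")
    writeStack(stk, p, dtype = "preserve")
    back <- readStack(p)
    expect_identical(frames(back), frames(stk))
    expect_identical(bitDepth(back), bd)
    expect_identical(back@axisOrder, "TZYX")
  }
})

test_that("plain multi-page TIFFs group by the z-per-t hint", {
  pages <- array(sample(0:255, 16 * 4 * 4, replace = TRUE),
                 dim = c(16, 4, 4))
  p <- tempfile(fileext = ".tif")
  bleachr:::.tiffWrite(p, pages, 8L, 1L, description = NULL)
  s1 <- readStack(p, zPerT = 8)
  expect_equal(dim(frames(s1))[1:2], c(2L, 8L))
  s2 <- readStack(p, zPerT = 1)
  expect_equal(dim(frames(s2))[1:2], c(16L, 1L))
  expect_error(readStack(p, zPerT = 3), "not divisible")
  # pages land in the right T/Z cell, pixel-exact
  expect_equal(s1@frames[2, 3, , ], pages[11, , ])
})

test_that("hyperstack metadata drives auto grouping", {
  stk <- randomStack(T = 4, Z = 3, Y = 6, X = 6, seed = 3)
  p <- tempfile(fileext = ".tif")
  writeStack(stk, p)
  auto <- readStack(p)  # zPerT = "auto" reads slices=3 from the tag
  expect_equal(dim(frames(auto)), dim(frames(stk)))
  expect_identical(frames(auto), frames(stk))
})

test_that("unsupported inputs are rejected with messages", {
  stk <- randomStack(seed = 4)
  p <- tempfile(fileext = ".tif")
  writeStack(stk, p, dtype = "float")
  expect_error(readStack(p), "unsigned integer")
  p2 <- tempfile(fileext = ".tif")
  pages <- array(0, dim = c(2, 4, 4))
  bleachr:::.tiffWrite(p2, pages, 8L, 1L,
                       description = "ImageJ=1.53t\nimages=2\nchannels=2\nframes=1\nslices=1")
  expect_error(readStack(p2), "channel")
  expect_error(readStack(tempfile()), "cannot read")
  p3 <- tempfile(fileext = ".tif")
  bleachr:::.tiffWrite(p3, pages, 8L, 1L, description = NULL)
  expect_error(readStack(p3, zPerT = 2), "T >= 2")
})

test_that("float output is exact; preserve clips and reports", {
  stk <- constStack(c(100, 80), bitDepth = 8L)
  res <- correctSimpleRatio(stk, 0)
  # inflate one frame beyond the 8-bit range
  res@corrected[2, , , ] <- 300.25
  pf <- tempfile(fileext = ".tif")
  writeStack(res, pf, dtype = "float")
  vals <- readFloatStack(pf)
  expect_equal(dim(vals), dim(res@corrected))
  expect_equal(vals, res@corrected, tolerance = 1e-6)
  pp <- tempfile(fileext = ".tif")
  expect_warning(out <- writeStack(res, pp, dtype = "preserve"),
                 "clipped")
  expect_equal(frameReport(out)$clipped_pixel_count, c(0, 16))
  back <- readStack(pp)
  expect_true(all(frames(back)[2, , , ] == 255))
})

test_that("round trip agrees with an independent TIFF reader (tifffile)", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  stk <- randomStack(T = 3, Z = 2, Y = 5, X = 4, bitDepth = 16L,
                     seed = 9)
  p <- tempfile(fileext = ".tif")
  writeStack(stk, p)
  out <- system2(py, c("-c", shQuote(paste0(
    "import tifffile, numpy as np; a = tifffile.imread('", p, "');",
    "print(a.shape); print(int(a.sum())); print(int(a[1,1,2,3]))"))),
    stdout = TRUE)
  expect_equal(out[1], "(3, 2, 5, 4)")  # hyperstack axes honoured
  expect_equal(as.numeric(out[2]), sum(frames(stk)))
  expect_equal(as.numeric(out[3]), frames(stk)[2, 2, 3, 4])
  # and the reverse direction: a tifffile-written stack reads back
  p2 <- tempfile(fileext = ".tif")
  system2(py, c("-c", shQuote(paste0(
    "import tifffile, numpy as np; rng = np.random.default_rng(0);",
    "a = rng.integers(0, 255, size=(6, 8, 9), dtype=np.uint8);",
    "tifffile.imwrite('", p2, "', a); print(int(a.sum()))"))),
    stdout = TRUE) -> out2
  s2 <- readStack(p2, zPerT = 2)
  expect_equal(sum(frames(s2)), as.numeric(out2[1]))
  expect_equal(dim(frames(s2)), c(3L, 2L, 8L, 9L))
})
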