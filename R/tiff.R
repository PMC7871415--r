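# Minimal multi-page TIFF I/O in base R: uncompressed, single-sample
# grayscale, 8/16-bit unsigned or 32-bit float, little- or big-endian on
# read, little-endian on write, one strip per page on write.  Covers the
# plain multi-page and ImageJ-hyperstack dialects this package consumes;
# not a general TIFF library.

.TIFF_TYPESIZE <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)  # BYTE..DOUBLE

.readTagValues <- function(con, type, count, endian, base) {
  size <- .TIFF_TYPESIZE[type]
  nbytes <- size * count
  here <- seek(con, where = NA)
  if (nbytes > 4L) {
    off <- readBin(con, "integer", 1, 4, endian = endian)
    seek(con, where = off)
  }
  vals <- switch(as.character(type),
    "1" = readBin(con, "integer", count, 1, signed = FALSE, endian = endian),
    "2" = readBin(con, "raw", count),
    "3" = readBin(con, "integer", count, 2, signed = FALSE, endian = endian),
    "4" = readBin(con, "integer", count, 4, endian = endian),
    "11" = readBin(con, "double", count, 4, endian = endian),
    "12" = readBin(con, "double", count, 8, endian = endian),
    {seek(con, where = here); NULL})
  seek(con, where = here + 4L)
  vals
}

# Parse a TIFF file into per-page tag lists plus pixel matrices (Y x X).
.tiffRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, charToRaw("II"))) "little"
            else if (identical(magic, charToRaw("MM"))) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  if (readBin(con, "integer", 1, 2, signed = FALSE, endian = endian) != 42L)
    stop("not a TIFF file (bad magic number): ", path)
  ifdOffset <- readBin(con, "integer", 1, 4, endian = endian)
  pages <- list()
  while (ifdOffset != 0L) {
    seek(con, where = ifdOffset)
    nTags <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    tags <- list()
    for (k in seq_len(nTags)) {
      code <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", 1, 4, endian = endian)
      tags[[as.character(code)]] <-
        .readTagValues(con, type, count, endian, ifdOffset)
    }
    ifdOffset <- readBin(con, "integer", 1, 4, endian = endian)
    pages[[length(pages) + 1L]] <- tags
  }
  if (!length(pages)) stop("TIFF contains no images: ", path)

  getTag <- function(tags, code, default = NULL) {
    v <- tags[[as.character(code)]]
    if (is.null(v)) default else v
  }
  description <- {
    d <- getTag(pages[[1]], 270)
    if (is.null(d)) "" else rawToChar(d[d != as.raw(0)])
  }

  imgs <- vector("list", length(pages))
  for (p in seq_along(pages)) {
    tg <- pages[[p]]
    w <- getTag(tg, 256); h <- getTag(tg, 257)
    bits <- getTag(tg, 258, 1L)[1]
    comp <- getTag(tg, 259, 1L)
    spp <- getTag(tg, 277, 1L)
    fmt <- getTag(tg, 339, 1L)[1]
    offs <- getTag(tg, 273); cnts <- getTag(tg, 279)
    if (is.null(w) || is.null(h) || is.null(offs))
      stop("TIFF page ", p, " lacks required tags")
    if (comp != 1L) stop("compressed TIFF not supported (compression=",
                         comp, ")")
    if (spp != 1L)
      stop("multi-channel TIFF not supported; split channels first ",
           "(SamplesPerPixel=", spp, ")")
    if (!(bits %in% c(8L, 16L, 32L)))
      stop("unsupported bits per sample: ", bits)
    if (!(fmt %in% c(1L, 3L)))
      stop("unsupported sample format ", fmt,
           " (only unsigned integer and IEEE float)")
    if (fmt == 3L && bits != 32L)
      stop("float TIFF must be 32-bit")
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8, length(offs))
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      seek(con, where = offs[s])
      n <- cnts[s] / (bits / 8)
      vals <- c(vals, switch(as.character(bits),
        "8"  = readBin(con, "integer", n, 1, signed = FALSE,
                       endian = endian),
        "16" = readBin(con, "integer", n, 2, signed = FALSE,
                       endian = endian),
        "32" = readBin(con, "double", n, 4, endian = endian)))
    }
    if (length(vals) != w * h)
      stop("TIFF page ", p, " has truncated pixel data")
    # TIFF stores rows sequentially (x fastest): transpose into Y x X
    imgs[[p]] <- t(matrix(vals, nrow = w, ncol = h))
  }
  list(pages = imgs, bits = bits, sampleFormat = fmt,
       description = description)
}

.ijDescriptionField <- function(description, field) {
  m <- regmatches(description,
                  regexec(paste0(field, "=([0-9]+)"), description))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

# Write pages (P x Y x X array) as an uncompressed little-endian
# multi-page TIFF, one strip per page.
.tiffWrite <- function(path, pages, bits, sampleFormat = 1L,
                       description = NULL) {
  d <- dim(pages)
  stopifnot(length(d) == 3L)
  P <- d[1]; H <- d[2]; W <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))

  descRaw <- if (!is.null(description)) {
    r <- c(charToRaw(description), as.raw(0))
    if (length(r) %% 2L) r <- c(r, as.raw(0))
    r
  } else raw(0)
  descOffset <- 8L
  dataStart <- descOffset + length(descRaw)
  pageBytes <- W * H * bits / 8
  ifdStart <- dataStart + P * pageBytes
  nTags <- function(p) 10L + (p == 1L && length(descRaw) > 0L)
  ifdSize <- function(p) 2L + 12L * nTags(p) + 4L
  ifdOffsets <- dataStart + P * pageBytes +
    cumsum(c(0L, vapply(seq_len(P), ifdSize, integer(1))))[seq_len(P)]

  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con); w2(42L); w4(ifdOffsets[1])
  if (length(descRaw)) writeBin(descRaw, con)

  for (p in seq_len(P)) {
    v <- as.vector(t(pages[p, , ]))  # row-major, x fastest
    if (sampleFormat == 3L) {
      writeBin(as.double(v), con, size = 4, endian = "little")
    } else if (bits == 8L) {
      writeBin(as.raw(as.integer(round(v))), con)
    } else {
      iv <- as.integer(round(v))
      iv <- ifelse(iv > 32767L, iv - 65536L, iv)  # reinterpret as signed
      writeBin(iv, con, size = 2, endian = "little")
    }
  }

  entry <- function(code, type, count, value) {
    w2(code); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (p in seq_len(P)) {
    w2(nTags(p))
    entry(256L, 4L, 1L, W)
    entry(257L, 4L, 1L, H)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)        # no compression
    entry(262L, 3L, 1L, 1L)        # black is zero
    if (p == 1L && length(descRaw))
      entry(270L, 2L, length(descRaw), descOffset)
    entry(273L, 4L, 1L, dataStart + (p - 1L) * pageBytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, H)
    entry(279L, 4L, 1L, pageBytes)
    entry(339L, 3L, 1L, sampleFormat)
    w4(if (p < P) ifdOffsets[p + 1L] else 0L)
  }
  invisible(path)
}

#' Read a time-lapse stack from a multi-page TIFF
#'
#' Pages are grouped into T time points of Z slices.  For ImageJ
#' hyperstacks the \code{frames}/\code{slices} fields of the
#' ImageDescription tag are honoured; otherwise \code{zPerT} groups the
#' pages (default 1, i.e. a 2D time series).  Pixel values are preserved
#' bit-exact.
#'
#' @param path a readable multi-page TIFF (uncompressed, single channel,
#'   8- or 16-bit unsigned).
#' @param zPerT z-slices per time point, or \code{"auto"} to use the
#'   hyperstack metadata (falling back to 1).
#' @return a \code{\link{TimeLapseStack}}.
#' @export
readStack <- function(path, zPerT = "auto") {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  tf <- .tiffRead(path)
  if (tf$sampleFormat == 3L || tf$bits > 16L)
    stop("only 8- or 16-bit unsigned integer input is supported ",
         "(got ", tf$bits, "-bit, sample format ", tf$sampleFormat, ")")
  nPages <- length(tf$pages)
  nChan <- .ijDescriptionField(tf$description, "channels")
  if (!is.na(nChan) && nChan > 1L)
    stop("multi-channel hyperstack: split channels before correction")
  axisOrder <- "pages"
  if (identical(zPerT, "auto")) {
    z <- .ijDescriptionField(tf$description, "slices")
    if (!is.na(z)) axisOrder <- "TZYX" else z <- 1L
    zPerT <- z
  }
  zPerT <- as.integer(zPerT)
  if (zPerT < 1L) stop("zPerT must be a positive integer")
  if (nPages %% zPerT != 0L)
    stop("page count ", nPages, " not divisible by z-per-t ", zPerT)
  T <- nPages %/% zPerT
  if (T < 2L) stop("a time-lapse needs T >= 2 (got T = ", T, ")")
  H <- nrow(tf$pages[[1]]); W <- ncol(tf$pages[[1]])
  fr <- array(0, dim = c(T, zPerT, H, W))
  for (p in seq_len(nPages)) {
    t <- (p - 1L) %/% zPerT + 1L
    z <- (p - 1L) %% zPerT + 1L
    if (!identical(dim(tf$pages[[p]]), c(H, W)))
      stop("TIFF pages have inconsistent dimensions")
    fr[t, z, , ] <- tf$pages[[p]]
  }
  new("TimeLapseStack", frames = fr, bitDepth = as.integer(tf$bits),
      axisOrder = axisOrder)
}

.ijDescription <- function(T, Z) {
  sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nframes=%d\nhyperstack=true\nmode=grayscale\nunit=pixel\nloop=false",
          T * Z, Z, T)
}

.stackToPages <- function(a) {
  d <- dim(a)
  pg <- array(0, dim = c(d[1] * d[2], d[3], d[4]))
  for (t in seq_len(d[1])) for (z in seq_len(d[2]))
    pg[(t - 1L) * d[2] + z, , ] <- a[t, z, , ]
  pg
}

#' Write a stack or correction result to a multi-page TIFF
#'
#' Under \code{dtype = "preserve"} values are rounded half-to-even and
#' clipped to the source dtype range (clip counts are recorded in the
#' returned report and a warning is raised when any pixel clips); the
#' written file round-trips bit-exact through \code{\link{readStack}}.
#' Under \code{dtype = "float"} a 32-bit float TIFF is written with no
#' clipping.
#'
#' @param x a \code{TimeLapseStack} or \code{BleachCorrection}.
#' @param path output path; parent directory must be writable.
#' @param dtype \code{"preserve"} or \code{"float"}.
#' @return invisibly, the \code{BleachCorrection} with its report's
#'   clipped_pixel_count updated (or the input stack, unchanged).
#' @export
writeStack <- function(x, path, dtype = c("preserve", "float")) {
  dtype <- match.arg(dtype)
  if (!dir.exists(dirname(path)))
    stop("unwritable path (no such directory): ", path)
  if (is(x, "TimeLapseStack")) {
    a <- x@frames; bits <- x@bitDepth
  } else if (is(x, "BleachCorrection")) {
    a <- x@corrected; bits <- x@sourceBitDepth
  } else stop("x must be a TimeLapseStack or BleachCorrection")
  d <- dim(a)
  desc <- .ijDescription(d[1], d[2])
  if (dtype == "float") {
    .tiffWrite(path, .stackToPages(a), 32L, 3L, desc)
    return(invisible(x))
  }
  q <- .quantize(a, bits)
  .tiffWrite(path, .stackToPages(q$values), bits, 1L, desc)
  if (is(x, "BleachCorrection")) {
    x@report$clipped_pixel_count <- q$clippedPerFrame
    if (sum(q$clippedPerFrame) > 0) {
      msg <- sprintf("%d pixel(s) clipped to the %d-bit range on write",
                     sum(q$clippedPerFrame), bits)
      x@warnings <- unique(c(x@warnings, msg))
      warning(msg, call. = FALSE)
    }
  }
  invisible(x)
}

# Round half-to-even then clip to [0, 2^bits - 1]; per-frame clip counts.
.quantize <- function(a, bits) {
  hi <- 2^bits - 1
  r <- round(a)
  clippedPerFrame <- vapply(seq_len(dim(a)[1]), function(t) {
    v <- r[t, , , , drop = FALSE]
    sum(v < 0 | v > hi)
  }, numeric(1))
  r[r < 0] <- 0
  r[r > hi] <- hi
  list(values = r, clippedPerFrame = clippedPerFrame)
}

#' Convert a correction result to an integer stack
#'
#' Applies the preserve dtype policy in memory: round half-to-even, clip
#' to the source dtype range, and record per-frame clip counts in the
#' report.  This is what viewers (and the legacy plugin) see.
#'
#' @param result a \code{BleachCorrection}.
#' @return a list with \code{stack} (a \code{TimeLapseStack}) and
#'   \code{result} (the input with updated clip counts and warnings).
#' @export
applyDtypePolicy <- function(result) {
  stopifnot(is(result, "BleachCorrection"))
  q <- .quantize(result@corrected, result@sourceBitDepth)
  result@report$clipped_pixel_count <- q$clippedPerFrame
  if (sum(q$clippedPerFrame) > 0)
    result@warnings <- unique(c(result@warnings, sprintf(
      "%d pixel(s) clipped to the %d-bit range",
      sum(q$clippedPerFrame), result@sourceBitDepth)))
  list(stack = new("TimeLapseStack", frames = q$values,
                   bitDepth = result@sourceBitDepth, axisOrder = "TZYX"),
       result = result)
}

#' Read back a float TIFF written with dtype = "float"
#'
#' Returns the raw 4D array (T, Z, Y, X) of 32-bit float values; such
#' files are rejected by \code{\link{readStack}}, which is integer-only.
#'
#' @param path a 32-bit float TIFF written by \code{\link{writeStack}}.
#' @return numeric 4D array.
#' @export
readFloatStack <- function(path) {
  tf <- .tiffRead(path)
  z <- .ijDescriptionField(tf$description, "slices")
  if (is.na(z)) z <- 1L
  nPages <- length(tf$pages)
  T <- nPages %/% z
  H <- nrow(tf$pages[[1]]); W <- ncol(tf$pages[[1]])
  fr <- array(0, dim = c(T, z, H, W))
  for (p in seq_len(nPages))
    fr[(p - 1L) %/% z + 1L, (p - 1L) %% z + 1L, , ] <- tf$pages[[p]]
  fr
}
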