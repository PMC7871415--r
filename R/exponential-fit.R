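# Single-exponential decay fit of a mean-intensity series by variable
# projection: for any decay rate b the amplitude a and offset c enter the
# model a*exp(-b*i) + c linearly, so they are solved exactly by linear
# least squares and the profiled residual sum of squares is minimised
# over b alone (deterministic coarse grid + Brent refinement; no random
# restarts).  This recovers exact-model input to machine precision, where
# Gauss-Newton style optimisers abort on zero-residual data.

.profileFit <- function(b, i, y) {
  e <- exp(-b * i)
  X <- cbind(e, 1)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  if (any(is.na(cf))) {  # exp(-b i) collinear with intercept (b ~ 0)
    cf <- c(0, mean(y))
    res <- y - mean(y)
    return(list(a = 0, c = mean(y), rss = sum(res^2), singular = TRUE))
  }
  list(a = unname(cf[1]), c = unname(cf[2]),
       rss = sum(fit$residuals^2), singular = FALSE)
}

#' Fit a single-exponential decay to a mean-intensity series
#'
#' Least-squares estimation of \eqn{\bar I_i \approx a e^{-b i} + c} over
#' frame indices i = 0..T-1.  The fit is deterministic for a given input:
#' b is initialised from the slope of a line fit to
#' \eqn{-\log(\bar I_i - c_0)} with \eqn{c_0} just below the series
#' minimum (fallback 1/T), then refined by a fixed grid and Brent search
#' on the profiled residual sum of squares to parameter tolerance 1e-10
#' within an iteration cap of 1000.  b is unconstrained: a fitted b < 0
#' converges but carries a "not a decay" warning.  A (numerically)
#' constant series yields the degenerate flag with the model reducing to
#' the constant and rss ~ 0.
#'
#' @param means numeric vector of per-time-point means (length >= 4), or
#'   a \code{TimeLapseStack} whose \code{meanSeries} is fitted.
#' @return an \code{\link{ExpFit}}.
#' @export
fitExponential <- function(means) {
  if (is(means, "TimeLapseStack")) means <- meanSeries(means)
  y <- as.numeric(means)
  T <- length(y)
  if (T < 4L)
    stop("need at least 4 time points to fit a, b, c (got ", T, ")")
  if (any(!is.finite(y))) stop("means must be finite")
  i <- seq_len(T) - 1

  scale <- max(abs(y), 1)
  if (stats::sd(y) < 1e-12 * scale) {
    return(new("ExpFit", a = 0, b = 0, c = mean(y), rss = sum((y - mean(y))^2),
               converged = TRUE, degenerate = TRUE,
               warnings = "degenerate: constant mean series; a and b not identifiable"))
  }

  # deterministic initialisation for the decay rate
  c0 <- min(y) - 1e-3 * max(diff(range(y)), 1e-12)
  pos <- y - c0 > 0
  b0 <- if (sum(pos) >= 2L) {
    ly <- -log(y[pos] - c0)
    sl <- stats::cov(i[pos], ly) / stats::var(i[pos])
    if (is.finite(sl) && sl > 0) sl else 1 / T
  } else 1 / T

  # profiled RSS over a fixed bracket around b0 (b unconstrained: the
  # grid extends to growth rates as well)
  bHi <- max(4 * abs(b0), 2)
  grid <- seq(-bHi, bHi, length.out = 401L)
  rssGrid <- vapply(grid, function(b) .profileFit(b, i, y)$rss, numeric(1))
  k <- which.min(rssGrid)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(function(b) .profileFit(b, i, y)$rss,
                         interval = c(lo, hi), tol = 1e-12)
  bHat <- opt$minimum
  fit <- .profileFit(bHat, i, y)

  warnings <- character(0)
  degenerate <- FALSE
  if (fit$singular || abs(fit$a) < 1e-9 * scale || abs(bHat) < 1e-9) {
    degenerate <- TRUE
    warnings <- c(warnings,
                  "degenerate: amplitude or rate indistinguishable from zero")
  }
  if (bHat < -1e-9)
    warnings <- c(warnings, "not a decay: fitted rate b < 0")
  model <- fit$a * exp(-bHat * i) + fit$c
  if (any(!is.finite(model)))
    stop("non-convergence: fitted model is not finite over the series ",
         "(b0 = ", signif(b0, 6), ", last b = ", signif(bHat, 6), ")")
  new("ExpFit", a = fit$a, b = bHat, c = fit$c, rss = fit$rss,
      converged = TRUE, degenerate = degenerate, warnings = warnings)
}

#' Exponential-fitting bleach correction
#'
#' Two-pass pipeline: (1) fit \eqn{a e^{-b i} + c} to the per-time-point
#' mean series to estimate the background offset c; (2) subtract the
#' scalar c from every pixel; (3) refit the subtracted mean series to get
#' \eqn{a', b', c'}; (4) multiply every pixel of frame i by the inverse
#' bleach ratio \eqn{(a' + c') / (a' e^{-b' i} + c')}.  The factor at
#' i = 0 is exactly 1, so frame 0 changes only by the \eqn{-c}
#' subtraction.  Per-frame fluctuations about the fitted decay are
#' preserved, not flattened.
#'
#' @param stack a \code{TimeLapseStack}.
#' @return a \code{\link{BleachCorrection}} whose \code{fitParams} holds
#'   both \code{ExpFit} passes.
#' @export
correctExponential <- function(stack) {
  stopifnot(is(stack, "TimeLapseStack"))
  m <- meanSeries(stack)
  f1 <- tryCatch(fitExponential(m),
                 error = function(e) stop("pass 1 fit failed: ",
                                          conditionMessage(e)))
  f2 <- tryCatch(fitExponential(m - f1@c),
                 error = function(e) stop("pass 2 fit failed: ",
                                          conditionMessage(e)))
  d <- dim(stack@frames)
  i <- seq_len(d[1]) - 1
  if (f2@degenerate) {
    # constant (or amplitude-free) subtracted series: nothing to rescale
    factor <- rep(1, d[1])
  } else {
    factor <- (f2@a + f2@c) / (f2@a * exp(-f2@b * i) + f2@c)
  }
  if (any(!is.finite(factor)) || any(factor <= 0))
    stop("pass 2 fit gives a non-positive or non-finite bleach ratio; ",
         "the exponential model does not describe this series")
  corrected <- array(0, dim = d)
  for (t in seq_len(d[1]))
    corrected[t, , , ] <- factor[t] *
      (stack@frames[t, , , , drop = FALSE] - f1@c)
  post <- .meanSeries(corrected)
  warnings <- unique(c(f1@warnings, f2@warnings))
  rep <- data.frame(frame_index = i, pre_mean = m, post_mean = post,
                    ratio_or_lut_id = sprintf("%.10g", factor),
                    clipped_pixel_count = 0L)
  new("BleachCorrection", corrected = corrected,
      method = "exponential-fit", report = rep,
      backgroundUsed = f1@c, fitParams = list(pass1 = f1, pass2 = f2),
      warnings = warnings, sourceBitDepth = stack@bitDepth)
}

#' Export fit parameters as a CSV report
#'
#' @param result a \code{BleachCorrection} from
#'   \code{\link{correctExponential}}.
#' @param path output CSV path; columns pass, a, b, c, rss, converged.
#' @export
writeFitReport <- function(result, path) {
  stopifnot(is(result, "BleachCorrection"),
            length(result@fitParams) == 2L)
  rows <- do.call(rbind, lapply(names(result@fitParams), function(nm) {
    f <- result@fitParams[[nm]]
    data.frame(pass = nm, a = f@a, b = f@b, c = f@c, rss = f@rss,
               converged = f@converged)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
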