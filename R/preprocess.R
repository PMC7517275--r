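#' Preprocessing configuration
#'
#' @param sg_window Savitzky-Golay window length in grid points (odd,
#'   > `sg_polyorder`). Default 11 points = 5.5 nm on the default grid.
#' @param sg_polyorder Savitzky-Golay polynomial order.
#' @param align_segments Number of contiguous alignment segments.
#' @param align_max_shift Maximum integer lag (grid points) per segment.
#' @param renormalize_after_detrend Restore unit standard deviation after
#'   detrending (detrending perturbs the SD set by normalization).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 11L, sg_polyorder = 3L,
                              align_segments = 1L, align_max_shift = 10L,
                              renormalize_after_detrend = TRUE) {
  sg_window <- as.integer(sg_window); sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  if (align_max_shift < 0L) stop("align_max_shift must be >= 0")
  if (align_segments < 1L) stop("align_segments must be >= 1")
  structure(list(sg_window = sg_window, sg_polyorder = sg_polyorder,
                 align_segments = as.integer(align_segments),
                 align_max_shift = as.integer(align_max_shift),
                 renormalize_after_detrend = isTRUE(renormalize_after_detrend)),
            class = "preprocess_config")
}

as_intensity <- function(x) if (inherits(x, "drs_spectrum")) x$intensity else as.numeric(x)

rewrap <- function(template, intensity) {
  if (inherits(template, "drs_spectrum"))
    drs_spectrum(template$wavelength, intensity, template$meta)
  else intensity
}

#' Reflectance from raw sample, reference and background spectra
#'
#' R(lambda) = (S - B) / (Ref - B), the ratio of background-subtracted sample
#' signal to the background-subtracted signal of a diffusely reflecting
#' reference standard. Wavelengths where |Ref - B| falls below `tolerance`
#' carry no usable reference signal; they are set to `NA` and flagged in the
#' `valid` attribute so downstream stages can exclude them.
#'
#' @param sample,reference,background `drs_spectrum` objects (or numeric
#'   vectors) on the same grid.
#' @param tolerance Minimum usable |Ref - B|.
#' @return Reflectance spectrum (same type as `sample`) with a logical
#'   `valid` attribute on the intensity.
#' @export
compute_reflectance <- function(sample, reference, background,
                                tolerance = 1e-9) {
  if (inherits(sample, "drs_spectrum") && inherits(reference, "drs_spectrum") &&
      !isTRUE(all.equal(sample$wavelength, reference$wavelength)))
    stop("sample and reference grids differ")
  if (inherits(sample, "drs_spectrum") && inherits(background, "drs_spectrum") &&
      !isTRUE(all.equal(sample$wavelength, background$wavelength)))
    stop("sample and background grids differ")
  s <- as_intensity(sample); r <- as_intensity(reference); b <- as_intensity(background)
  if (length(s) != length(r) || length(s) != length(b))
    stop("sample, reference and background lengths differ")
  denom <- r - b
  valid <- abs(denom) >= tolerance
  out <- rep(NA_real_, length(s))
  out[valid] <- (s[valid] - b[valid]) / denom[valid]
  res <- rewrap(sample, out)
  if (inherits(res, "drs_spectrum")) attr(res$intensity, "valid") <- valid
  else attr(res, "valid") <- valid
  res
}

#' Normalize a spectrum to zero mean and unit standard deviation
#'
#' Uses the sample standard deviation (n - 1 denominator). Non-finite points
#' are ignored for the statistics and left as-is.
#'
#' @param x A `drs_spectrum` or numeric vector.
#' @return Normalized spectrum of the same type.
#' @export
normalize_spectrum <- function(x) {
  y <- as_intensity(x)
  ok <- is.finite(y)
  if (sum(ok) < 2L) stop("need at least 2 valid points to normalize")
  s <- stats::sd(y[ok])
  if (s < 1e-12 * max(1, abs(mean(y[ok])))) stop("zero variance spectrum")
  rewrap(x, (y - mean(y[ok])) / s)
}

# least-squares line fit of y on wavelength, returning the residual
line_residual <- function(y, wavelength) {
  ok <- is.finite(y)
  wc <- wavelength - mean(wavelength[ok])
  yc <- y - mean(y[ok])
  slope <- sum(wc[ok] * yc[ok]) / sum(wc[ok]^2)
  yc - slope * wc
}

#' Remove the least-squares straight line from a spectrum
#'
#' Subtracts the intercept-and-slope least-squares fit of intensity on
#' wavelength, suppressing linear instrument/orientation drift. The residual
#' has zero mean and zero least-squares slope.
#'
#' @param x A `drs_spectrum`, or a numeric vector with `wavelength` supplied.
#' @param wavelength Wavelength grid; taken from `x` when it is a spectrum.
#' @return Detrended spectrum of the same type.
#' @export
detrend_spectrum <- function(x, wavelength = NULL) {
  y <- as_intensity(x)
  wl <- if (inherits(x, "drs_spectrum")) x$wavelength else wavelength
  if (is.null(wl)) stop("wavelength grid required to detrend")
  if (sum(is.finite(y)) < 3L) stop("need at least 3 valid points to detrend")
  rewrap(x, line_residual(y, wl))
}

#' Mean absolute deviation from the least-squares line
#'
#' The average absolute difference between a spectrum and its own linear
#' regression fit; 0 for an exact line, and homogeneous of degree 1 in the
#' intensity scale.
#'
#' @inheritParams detrend_spectrum
#' @return Scalar deviation.
#' @export
detrend_deviation <- function(x, wavelength = NULL) {
  y <- as_intensity(x)
  wl <- if (inherits(x, "drs_spectrum")) x$wavelength else wavelength
  if (is.null(wl)) stop("wavelength grid required")
  r <- line_residual(y, wl)
  mean(abs(r[is.finite(r)]))
}

# hat matrix of the local polynomial least-squares fit over one window; row i
# evaluates the fitted polynomial at window position i
sg_hat <- function(window, polyorder) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  A %*% solve(crossprod(A), t(A))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. Interior points use the centered
#' window; the first and last half-windows are evaluated from the polynomial
#' fit of the edge window, so any input that is globally a polynomial of
#' degree <= `polyorder` is reproduced exactly (up to floating point) at all
#' points, and isolated smooth band positions move by less than one grid
#' step.
#'
#' @param x A `drs_spectrum` or numeric vector.
#' @param window Odd window length in grid points.
#' @param polyorder Polynomial order, < `window`.
#' @return Smoothed spectrum of the same type.
#' @export
savitzky_golay <- function(x, window = 11L, polyorder = 3L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder || polyorder < 0L)
    stop("window must be odd and greater than polyorder")
  y <- as_intensity(x)
  if (length(y) < window) stop("spectrum shorter than the filter window")
  rewrap(x, drop(sg_smooth_matrix(matrix(y, 1L), window, polyorder)))
}

# Savitzky-Golay smoothing of every row of a matrix (shared grid)
sg_smooth_matrix <- function(X, window, polyorder) {
  h <- (window - 1L) %/% 2L
  H <- sg_hat(window, polyorder)
  D <- ncol(X)
  tY <- t(X)
  sm <- stats::filter(tY, H[h + 1L, ], sides = 2)
  sm <- matrix(as.numeric(sm), nrow = D)
  sm[seq_len(h), ] <- H[seq_len(h), , drop = FALSE] %*%
    tY[seq_len(window), , drop = FALSE]
  sm[(D - h + 1L):D, ] <- H[(h + 2L):window, , drop = FALSE] %*%
    tY[(D - window + 1L):D, , drop = FALSE]
  t(sm)
}

#' Segment-shift (icoshift-style) alignment against the set mean
#'
#' The grid is split into `align_segments` contiguous segments. For each
#' spectrum and segment the integer lag (|lag| <= `align_max_shift`)
#' maximizing the cross-correlation with the set's mean spectrum is found, and
#' the segment is rebuilt from the spectrum shifted by that lag (values pulled
#' in across grid ends are edge-replicated). Ties prefer the smaller |lag|.
#'
#' @param set A `drs_set`.
#' @param segments Number of segments.
#' @param max_shift Maximum |lag| in grid points; must be smaller than the
#'   shortest segment.
#' @param reference Optional reference spectrum (numeric, grid length);
#'   defaults to the column mean of the set.
#' @return List with `set` (aligned `drs_set`) and `lags` (n x segments
#'   integer matrix of applied corrective lags).
#' @export
align_spectra <- function(set, segments = 1L, max_shift = 10L,
                          reference = NULL) {
  stopifnot(inherits(set, "drs_set"))
  X <- set$intensities
  n <- nrow(X); D <- ncol(X)
  if (n < 1L) stop("empty spectra set")
  segments <- as.integer(segments); max_shift <- as.integer(max_shift)
  bounds <- floor(seq(0L, D, length.out = segments + 1L))
  seg_len <- diff(bounds)
  if (max_shift >= min(seg_len))
    stop("align_max_shift must be smaller than the segment length")
  ref <- if (is.null(reference)) colMeans(X) else as.numeric(reference)
  if (length(ref) != D) stop("reference length does not match the grid")
  lags <- matrix(0L, n, segments)
  aligned <- X
  for (s in seq_len(segments)) {
    cols <- (bounds[s] + 1L):bounds[s + 1L]
    refseg <- ref[cols]
    cand <- seq(-max_shift, max_shift)
    scores <- matrix(NA_real_, n, length(cand))
    for (ci in seq_along(cand)) {
      idx <- pmin(pmax(cols - cand[ci], 1L), D)
      scores[, ci] <- X[, idx, drop = FALSE] %*% refseg
    }
    # best lag per spectrum; ties -> smaller |lag|, then smaller lag
    ord <- order(abs(cand), cand)
    best <- ord[max.col(scores[, ord, drop = FALSE], ties.method = "first")]
    lag <- cand[best]
    lags[, s] <- lag
    for (lg in unique(lag)) {
      if (lg == 0L) next
      rows <- which(lag == lg)
      idx <- pmin(pmax(cols - lg, 1L), D)
      aligned[rows, cols] <- X[rows, idx, drop = FALSE]
    }
  }
  out <- set
  out$intensities <- aligned
  out$steps <- c(set$steps, "align")
  list(set = out, lags = lags)
}

#' Full preprocessing pipeline
#'
#' Applies, per spectrum: normalization (zero mean, unit SD), linear detrend,
#' optional renormalization of the SD to one, Savitzky-Golay smoothing, and
#' segment-shift alignment against the set mean. Applied steps are recorded in
#' the set's `steps` field and the alignment lag table is attached as the
#' `"lags"` attribute.
#'
#' @param set A `drs_set`.
#' @param config A [preprocess_config()].
#' @return The preprocessed `drs_set`.
#' @export
preprocess_pipeline <- function(set, config = preprocess_config()) {
  stopifnot(inherits(set, "drs_set"), inherits(config, "preprocess_config"))
  X <- set$intensities
  wl <- set$wavelength
  n <- nrow(X); D <- ncol(X)
  # normalize rows
  rm1 <- rowMeans(X)
  Xc <- X - rm1
  rsd <- sqrt(rowSums(Xc^2) / (D - 1))
  if (any(rsd < 1e-12)) stop("zero variance spectrum in set")
  Xc <- Xc / rsd
  # detrend rows (slope on centered wavelength)
  wc <- wl - mean(wl)
  denom <- sum(wc^2)
  rm2 <- rowMeans(Xc)
  Xc <- Xc - rm2
  slope <- as.numeric(Xc %*% wc) / denom
  Xc <- Xc - outer(slope, wc)
  steps <- c(set$steps, "normalize", "detrend")
  if (config$renormalize_after_detrend) {
    rsd2 <- sqrt(rowSums(Xc^2) / (D - 1))
    if (any(rsd2 < 1e-12)) stop("zero variance spectrum after detrend")
    Xc <- Xc / rsd2
    steps <- c(steps, "renormalize")
  }
  Xc <- sg_smooth_matrix(Xc, config$sg_window, config$sg_polyorder)
  steps <- c(steps, "savitzky_golay")
  out <- set
  out$intensities <- Xc
  out$steps <- steps
  al <- align_spectra(out, config$align_segments, config$align_max_shift)
  res <- al$set
  attr(res, "lags") <- al$lags
  res
}
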