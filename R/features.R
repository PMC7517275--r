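#' The nine characteristic spectral landmarks
#'
#' Search specifications for the nine landmark points used by the gradient
#' features: hemoglobin minima at 410, 540 and 575 nm, hemoglobin maxima in
#' 450-540 and 545-570 nm, and derivative zero crossings at 436 nm
#' (hemoglobin) and 934, 940-970 and 958 nm (water). Entries given as a single
#' wavelength get a search window of nominal +/- `window_halfwidth`; entries
#' given as a range use the range itself with the midpoint as nominal.
#'
#' @param window_halfwidth Half-width (nm) of the search window around
#'   single-wavelength entries.
#' @return Data frame with columns `index`, `mode` (`minimum`, `maximum`,
#'   `derivative_zero`), `lo`, `hi`, `nominal` (nm) and `compound`.
#' @export
characteristic_point_specs <- function(window_halfwidth = 10) {
  h <- window_halfwidth
  data.frame(
    index = 1:9,
    mode = c("minimum", "maximum", "minimum", "maximum", "minimum",
             "derivative_zero", "derivative_zero", "derivative_zero",
             "derivative_zero"),
    lo = c(410 - h, 450, 540 - h, 545, 575 - h, 940, 436 - h, 934 - h, 958 - h),
    hi = c(410 + h, 540, 540 + h, 570, 575 + h, 970, 436 + h, 934 + h, 958 + h),
    nominal = c(410, 495, 540, 557.5, 575, 955, 436, 934, 958),
    compound = c("hemoglobin", "hemoglobin", "hemoglobin", "hemoglobin",
                 "hemoglobin", "water", "hemoglobin", "water", "water"),
    stringsAsFactors = FALSE)
}

# vectorized landmark detection on an n x D intensity matrix
detect_points_matrix <- function(X, wavelength, specs) {
  n <- nrow(X); D <- ncol(X)
  step <- wavelength[2] - wavelength[1]
  L <- matrix(NA_real_, n, nrow(specs))
  V <- matrix(NA_real_, n, nrow(specs))
  FND <- matrix(FALSE, n, nrow(specs))
  for (s in seq_len(nrow(specs))) {
    lo <- specs$lo[s]; hi <- specs$hi[s]
    j1 <- which(wavelength >= lo)[1]
    j2 <- max(which(wavelength <= hi))
    if (is.na(j1) || j1 < 1L || j2 > D || j2 <= j1)
      stop(sprintf("search window %g-%g nm outside the grid", lo, hi))
    mode <- specs$mode[s]
    if (mode %in% c("minimum", "maximum")) {
      W <- X[, j1:j2, drop = FALSE]
      idx <- if (mode == "minimum") max.col(-W, ties.method = "first")
             else max.col(W, ties.method = "first")
      rng <- apply(W, 1L, function(r) diff(range(r)))
      found <- rng > 1e-12 & idx > 1L & idx < (j2 - j1 + 1L)
      L[, s] <- wavelength[j1 + idx - 1L]
      V[, s] <- W[cbind(seq_len(n), idx)]
      FND[, s] <- found
    } else {
      # central-difference derivative over the window (needs one point margin)
      if (j1 <= 1L || j2 >= D)
        stop(sprintf("derivative window %g-%g nm needs interior grid margin", lo, hi))
      cols <- j1:j2
      Dm <- (X[, cols + 1L, drop = FALSE] - X[, cols - 1L, drop = FALSE]) /
        (2 * step)
      m <- length(cols)
      dl <- Dm[, -m, drop = FALSE]
      dr <- Dm[, -1L, drop = FALSE]
      cross <- (dl == 0 & dr != 0) | (dl * dr < 0)
      # crossing wavelength by linear interpolation of the derivative
      frac <- dl / (dl - dr)
      frac[!cross] <- NA_real_
      lam <- matrix(wavelength[cols[-m]], n, m - 1L, byrow = TRUE) + frac * step
      dist <- abs(lam - specs$nominal[s])
      dist[!cross] <- Inf
      any_cross <- rowSums(cross) > 0L
      pick <- max.col(-dist, ties.method = "first")
      lamstar <- lam[cbind(seq_len(n), pick)]
      fr <- frac[cbind(seq_len(n), pick)]
      vl <- X[cbind(seq_len(n), cols[pick])]
      vr <- X[cbind(seq_len(n), cols[pick] + 1L)]
      vstar <- vl + fr * (vr - vl)
      # fallback: extremum of |derivative| inside the window
      fb <- max.col(abs(Dm), ties.method = "first")
      lam_fb <- wavelength[cols[fb]]
      v_fb <- X[cbind(seq_len(n), cols[fb])]
      L[, s] <- ifelse(any_cross, lamstar, lam_fb)
      V[, s] <- ifelse(any_cross, vstar, v_fb)
      FND[, s] <- any_cross
    }
  }
  colnames(L) <- colnames(V) <- colnames(FND) <- paste0("P", specs$index)
  list(wavelength = L, value = V, found = FND)
}

#' Detect the characteristic points of a spectrum
#'
#' For `minimum`/`maximum` landmarks, the extremum of the (already smoothed)
#' spectrum inside the search window; `found` is FALSE when the window is flat
#' or the extremum sits on the window edge. For `derivative_zero` landmarks,
#' the sign change of the central-difference first derivative closest to the
#' nominal wavelength, with the crossing wavelength (and intensity) linearly
#' interpolated; when no crossing exists the fallback is the window's extremum
#' of |derivative| with `found = FALSE`.
#'
#' @param x A `drs_spectrum`, or a `drs_set` (detects per row).
#' @param specs Landmark table from [characteristic_point_specs()].
#' @return For a spectrum: data frame with `index`, `mode`, `wavelength`,
#'   `value`, `found`. For a set: list of n x 9 matrices `wavelength`,
#'   `value`, `found`.
#' @export
detect_points <- function(x, specs = characteristic_point_specs()) {
  if (inherits(x, "drs_set"))
    return(detect_points_matrix(x$intensities, x$wavelength, specs))
  stopifnot(inherits(x, "drs_spectrum"))
  r <- detect_points_matrix(matrix(x$intensity, 1L), x$wavelength, specs)
  data.frame(index = specs$index, mode = specs$mode,
             wavelength = drop(r$wavelength), value = drop(r$value),
             found = drop(r$found), row.names = NULL)
}

#' Pairwise gradients between characteristic points
#'
#' g[i, j] = (v_j - v_i) / |lambda_j - lambda_i| for i != j and g[i, i] = 0:
#' the slope magnitude of the segment joining points i and j signed by the
#' direction of the intensity change, in (normalized intensity)/nm. The
#' absolute-wavelength-difference denominator makes the matrix antisymmetric
#' (g[j, i] = -g[i, j]) whatever the detected wavelength order. The full
#' ordered 9 x 9 matrix (81 features including the zero diagonal) is
#' flattened row-major with names `grad_i_j`.
#'
#' @param points Data frame as returned by [detect_points()] for one spectrum
#'   (columns `wavelength`, `value`).
#' @param strict Error on coincident wavelengths of two distinct points
#'   (default). With `strict = FALSE` such degenerate pairs yield slope 0,
#'   which is what the set-level feature builder uses.
#' @return List with `matrix` (9 x 9) and `features` (named length-81 vector).
#' @export
gradients <- function(points, strict = TRUE) {
  lam <- points$wavelength; val <- points$value
  p <- length(lam)
  dl <- outer(lam, lam, FUN = function(a, b) b - a)
  dv <- outer(val, val, FUN = function(a, b) b - a)
  off <- row(dl) != col(dl)
  if (strict && any(dl[off] == 0))
    stop("degenerate point pair: identical wavelengths for distinct points")
  G <- matrix(0, p, p)
  ok <- off & dl != 0
  G[ok] <- dv[ok] / abs(dl[ok])
  feat <- as.vector(t(G))
  names(feat) <- paste0("grad_", rep(seq_len(p), each = p), "_",
                        rep(seq_len(p), p))
  list(matrix = G, features = feat)
}

#' Gradient feature matrix for a spectra set
#'
#' Detects the nine characteristic points per spectrum and assembles the 81
#' pairwise gradient features (row-major `grad_i_j` order). Degenerate pairs
#' (two landmarks resolving to the same wavelength on a given spectrum) are
#' assigned slope 0 rather than aborting the run; the detection `found` flags
#' are returned alongside.
#'
#' @param set A preprocessed `drs_set`.
#' @param specs Landmark table from [characteristic_point_specs()].
#' @return List with `features` (n x 81 matrix), `labels`, and `points` (the
#'   [detect_points()] matrices).
#' @export
gradient_features <- function(set, specs = characteristic_point_specs()) {
  pts <- detect_points(set, specs)
  L <- pts$wavelength; V <- pts$value
  p <- ncol(L); n <- nrow(L)
  Fm <- matrix(0, n, p * p)
  colnames(Fm) <- paste0("grad_", rep(seq_len(p), each = p), "_",
                         rep(seq_len(p), p))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    dl <- abs(L[, j] - L[, i])
    g <- ifelse(dl == 0, 0, (V[, j] - V[, i]) / dl)
    Fm[, (i - 1L) * p + j] <- g
  }
  list(features = Fm, labels = set$labels, points = pts)
}

#' One-way ANOVA F ranking of features
#'
#' Per feature, the Snedecor F ratio of between-class to within-class mean
#' squares across the tissue classes: F = [SSB/(K-1)] / [SSW/(N-K)]. Features
#' with zero within-class variance but distinct class means get an infinite
#' sentinel (ranked above all finite values); features with no variance at all
#' get F = 0. Ordering ties break toward the smaller feature index.
#'
#' @param features n x p numeric feature matrix (named columns recommended).
#' @param labels Class label per row (>= 2 classes, each with >= 2 rows).
#' @return An object of class `drs_franking`: list with `F` (named vector) and
#'   `order` (feature indices by descending F).
#' @export
anova_f <- function(features, labels) {
  X <- as.matrix(features)
  g <- factor(labels)
  g <- droplevels(g)
  K <- nlevels(g); N <- nrow(X)
  if (K < 2L) stop("at least 2 classes required")
  nk <- as.integer(table(g))
  if (any(nk < 2L)) stop("every class needs at least 2 observations")
  gm <- colMeans(X)
  sums <- rowsum(X, g)                    # K x p class sums
  means <- sums / nk
  ssb <- colSums(nk * (means - matrix(gm, K, ncol(X), byrow = TRUE))^2)
  sst <- colSums((X - matrix(gm, N, ncol(X), byrow = TRUE))^2)
  ssw <- pmax(sst - ssb, 0)
  tol <- 1e-12 * pmax(sst, 1)
  Fv <- numeric(ncol(X))
  zero_w <- ssw <= tol
  Fv[!zero_w] <- (ssb[!zero_w] / (K - 1)) / (ssw[!zero_w] / (N - K))
  Fv[zero_w & ssb > tol] <- Inf
  Fv[zero_w & ssb <= tol] <- 0
  names(Fv) <- colnames(X)
  structure(list(F = Fv, order = order(-Fv, seq_along(Fv))),
            class = "drs_franking")
}

#' @export
print.drs_franking <- function(x, n = 10L, ...) {
  cat("<drs_franking>", length(x$F), "features; top", n, ":\n")
  top <- x$order[seq_len(min(n, length(x$F)))]
  print(round(x$F[top], 2))
  invisible(x)
}

#' Select the top-k features by F value
#'
#' @param ranking A [anova_f()] result.
#' @param k Number of features to keep (1 <= k <= p).
#' @return Integer vector of the k feature indices with the largest F values,
#'   in descending F order (ties by smaller index).
#' @export
select_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "drs_franking"))
  if (k <= 0) stop("k must be positive")
  if (k > length(ranking$F)) stop("k exceeds the number of features")
  ranking$order[seq_len(k)]
}
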