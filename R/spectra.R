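#' Fixed tissue class order
#'
#' All labels, confusion matrices and metric tables in the package use this
#' class order: fat, skin, nerve, bone, muscle.
#'
#' @return Character vector of the five tissue class names, in order.
#' @export
tissue_classes <- function() c("fat", "skin", "nerve", "bone", "muscle")

#' Wavelength grid
#'
#' The spectrometer grid the pipeline assumes: strictly increasing wavelengths
#' in nm. The default spans 220 to 1100 nm at 0.5 nm resolution (1761 points).
#'
#' @param from,to Range in nm.
#' @param step Grid spacing in nm.
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @export
drs_wavelength_grid <- function(from = 220, to = 1100, step = 0.5) {
  if (step <= 0 || to <= from) stop("invalid wavelength grid specification")
  seq(from, to, by = step)
}

check_grid <- function(wavelength) {
  if (length(wavelength) < 2L) stop("wavelength grid must have at least 2 points")
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelength grid must be finite and strictly increasing")
  invisible(wavelength)
}

#' Single spectrum container
#'
#' @param wavelength Wavelength grid (nm), strictly increasing.
#' @param intensity Intensity vector aligned to the grid.
#' @param meta Named list of metadata (tissue, specimen_id, sample_id,
#'   point_idx, measurement_idx, ...).
#' @return An object of class `drs_spectrum`.
#' @export
drs_spectrum <- function(wavelength, intensity, meta = list()) {
  check_grid(wavelength)
  if (length(intensity) != length(wavelength))
    stop("intensity length does not match wavelength grid length")
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 meta = meta),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("<drs_spectrum> %d points, %.1f-%.1f nm", length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  if (!is.null(x$meta$tissue)) cat(sprintf(", tissue=%s", x$meta$tissue))
  cat("\n")
  invisible(x)
}

#' Spectra set container
#'
#' Holds a matrix of spectra (rows) on a shared wavelength grid (columns),
#' together with tissue labels and a metadata table.
#'
#' @param wavelength Shared wavelength grid (nm).
#' @param intensities n_spectra x n_wavelengths numeric matrix.
#' @param labels Tissue label per row; coerced to a factor with levels
#'   [tissue_classes()].
#' @param meta Data frame with one row per spectrum (at least `spectrum_id`);
#'   generated automatically when omitted.
#' @param steps Character vector recording applied processing steps.
#' @return An object of class `drs_set` with elements `wavelength`,
#'   `intensities`, `labels`, `meta`, `steps`.
#' @export
drs_set <- function(wavelength, intensities, labels, meta = NULL,
                    steps = character()) {
  check_grid(wavelength)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavelength))
    stop("intensity matrix width does not match wavelength grid length")
  if (length(labels) != nrow(intensities))
    stop("one label per spectrum required")
  lab <- factor(as.character(labels), levels = tissue_classes())
  if (anyNA(lab))
    stop("unknown tissue label: ",
         paste(unique(setdiff(as.character(labels), tissue_classes())),
               collapse = ", "))
  if (is.null(meta)) {
    meta <- data.frame(spectrum_id = sprintf("spec%05d", seq_len(nrow(intensities))),
                       tissue = as.character(lab), stringsAsFactors = FALSE)
  }
  if (nrow(meta) != nrow(intensities)) stop("meta must have one row per spectrum")
  if (anyDuplicated(meta$spectrum_id)) stop("duplicated spectrum_id in metadata")
  rownames(intensities) <- meta$spectrum_id
  structure(list(wavelength = as.numeric(wavelength),
                 intensities = intensities,
                 labels = lab, meta = meta, steps = steps),
            class = "drs_set")
}

#' @export
print.drs_set <- function(x, ...) {
  cat(sprintf("<drs_set> %d spectra x %d wavelengths (%.1f-%.1f nm)\n",
              nrow(x$intensities), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  print(table(x$labels))
  if (length(x$steps)) cat("steps:", paste(x$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `drs_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Subset a spectra set by row
#' @param x A `drs_set`.
#' @param i Row index vector.
#' @param ... Unused.
#' @return A `drs_set` with the selected spectra.
#' @export
`[.drs_set` <- function(x, i, ...) {
  drs_set(x$wavelength, x$intensities[i, , drop = FALSE],
          as.character(x$labels[i]), x$meta[i, , drop = FALSE], x$steps)
}

#' Extract one spectrum from a set
#' @param set A `drs_set`.
#' @param i Row index.
#' @return A `drs_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= n_spectra(set))
  drs_spectrum(set$wavelength, set$intensities[i, ],
               as.list(set$meta[i, , drop = FALSE]))
}

# run code with a local RNG state, restoring the caller's stream afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
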