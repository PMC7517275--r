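#' Chromophore absorption bands
#'
#' Gaussian absorption bands used by the synthetic reflectance model. Centers
#' follow the standard tissue-optics landmarks: protein near 280 nm,
#' (oxy/deoxy) hemoglobin Soret and Q bands near 410, 433, 540 and 575 nm,
#' lipid near 930 nm and water near 970 nm.
#'
#' @return Data frame with columns `name`, `center` (nm), `width`
#'   (Gaussian sigma, nm).
#' @export
drs_chromophores <- function() {
  data.frame(
    name   = c("protein_280", "hb_410", "hb_433", "hb_540", "hb_575",
               "lipid_930", "water_970"),
    center = c(280, 410, 433, 540, 575, 930, 970),
    width  = c(16, 16, 7, 10, 9, 12, 14),
    stringsAsFactors = FALSE)
}

#' Tissue optical profile for the synthetic generator
#'
#' A profile defines the noiseless reflectance template of one tissue class
#' (chromophore band weights, scattering level, long-wavelength decay) plus
#' the dispersion of the random effects applied when simulating measurements:
#' log-normal multiplicative gains at specimen / sample / point level, one
#' linear instrument trend and one integer wavelength shift per sample, and
#' additive white noise per measurement.
#'
#' @param name Tissue name, one of [tissue_classes()].
#' @param band_weights Named numeric vector of non-negative absorbance weights;
#'   names must be a subset of `drs_chromophores()$name`.
#' @param scatter_level Overall reflectance scale (dimensionless, > 0).
#' @param decay_center,decay_width Center (nm) and width (nm) of the smooth
#'   sigmoidal reflectance decay at long wavelengths; `decay_width = Inf`
#'   yields a flat background.
#' @param specimen_sd,sample_sd,point_sd SDs (log scale) of the multiplicative
#'   gain per specimen, sample and point.
#' @param noise_sd Additive white-noise SD per wavelength per measurement.
#' @param trend_slope_sd SD of the per-sample linear trend slope (per nm).
#' @param shift_sd SD (grid steps) of the per-sample integer wavelength shift.
#' @return An object of class `tissue_profile`.
#' @export
tissue_profile <- function(name, band_weights, scatter_level = 1,
                           decay_center = 650, decay_width = 60,
                           specimen_sd = 0.12, sample_sd = 0.08,
                           point_sd = 0.04, noise_sd = 0.01,
                           trend_slope_sd = 2e-4, shift_sd = 1.5) {
  name <- match.arg(name, tissue_classes())
  chrom <- drs_chromophores()
  bad <- setdiff(names(band_weights), chrom$name)
  if (length(bad)) stop("unknown chromophore(s): ", paste(bad, collapse = ", "))
  if (any(band_weights < 0)) stop("band weights must be non-negative")
  sds <- c(specimen_sd, sample_sd, point_sd, noise_sd, trend_slope_sd, shift_sd)
  if (any(sds < 0)) stop("all SDs must be non-negative")
  if (decay_width <= 0) stop("decay_width must be positive")
  structure(list(name = name, band_weights = band_weights,
                 scatter_level = scatter_level,
                 decay_center = decay_center, decay_width = decay_width,
                 specimen_sd = specimen_sd, sample_sd = sample_sd,
                 point_sd = point_sd, noise_sd = noise_sd,
                 trend_slope_sd = trend_slope_sd, shift_sd = shift_sd),
            class = "tissue_profile")
}

#' Default tissue profiles
#'
#' One profile per class in the fixed order fat, skin, nerve, bone, muscle.
#' Weights are chosen so that every template exhibits all nine characteristic
#' landmarks (hemoglobin minima/maxima at 410-575 nm, the 436 nm shoulder, the
#' lipid 930 nm and water 970 nm features), every tissue carries a nonzero
#' water-970 and hemoglobin-575 weight, fat carries the largest lipid-930
#' weight, and the classes are separable at the default noise levels.
#'
#' @param noise_scale Multiplier applied to every random-effect SD of every
#'   profile; `noise_scale = 0` gives deterministic noiseless templates.
#' @return Named list of five [tissue_profile()] objects.
#' @export
default_tissue_profiles <- function(noise_scale = 1) {
  w <- function(...) c(...)
  base <- list(
    fat = tissue_profile("fat",
      w(protein_280 = 0.70, hb_410 = 0.60, hb_433 = 0.42, hb_540 = 0.28,
        hb_575 = 0.32, lipid_930 = 0.55, water_970 = 0.30),
      scatter_level = 1.25, decay_center = 680, decay_width = 70),
    skin = tissue_profile("skin",
      w(protein_280 = 1.20, hb_410 = 0.90, hb_433 = 0.63, hb_540 = 0.45,
        hb_575 = 0.52, lipid_930 = 0.20, water_970 = 0.38),
      scatter_level = 1.00, decay_center = 660, decay_width = 60),
    nerve = tissue_profile("nerve",
      w(protein_280 = 1.00, hb_410 = 0.75, hb_433 = 0.53, hb_540 = 0.38,
        hb_575 = 0.42, lipid_930 = 0.33, water_970 = 0.48),
      scatter_level = 1.10, decay_center = 650, decay_width = 60),
    bone = tissue_profile("bone",
      w(protein_280 = 0.90, hb_410 = 1.10, hb_433 = 0.77, hb_540 = 0.56,
        hb_575 = 0.62, lipid_930 = 0.16, water_970 = 0.30),
      scatter_level = 1.20, decay_center = 640, decay_width = 55),
    muscle = tissue_profile("muscle",
      w(protein_280 = 1.10, hb_410 = 1.40, hb_433 = 0.98, hb_540 = 0.72,
        hb_575 = 0.82, lipid_930 = 0.12, water_970 = 0.58),
      scatter_level = 0.85, decay_center = 630, decay_width = 50)
  )
  if (noise_scale != 1) {
    for (nm in names(base)) {
      p <- base[[nm]]
      for (f in c("specimen_sd", "sample_sd", "point_sd", "noise_sd",
                  "trend_slope_sd", "shift_sd"))
        p[[f]] <- p[[f]] * noise_scale
      base[[nm]] <- p
    }
  }
  base
}

#' Experimental design configuration
#'
#' Mirrors the measurement hierarchy of the modeled study: per tissue,
#' specimens x samples-per-specimen x points-per-sample x
#' measurements-per-point. The default design (5 tissues x 10 specimens x 2
#' samples x 16 points x 4 measurements) yields 6400 spectra.
#'
#' @param n_specimens,n_samples,n_points,n_measurements Counts per level
#'   (all >= 1).
#' @param tissues Tissue names included in the design.
#' @param seed Integer master seed for the generator.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_specimens = 10, n_samples = 2, n_points = 16,
                          n_measurements = 4, tissues = tissue_classes(),
                          seed = 1L) {
  counts <- c(n_specimens, n_samples, n_points, n_measurements)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be integers >= 1")
  tissues <- match.arg(tissues, tissue_classes(), several.ok = TRUE)
  structure(list(n_specimens = as.integer(n_specimens),
                 n_samples = as.integer(n_samples),
                 n_points = as.integer(n_points),
                 n_measurements = as.integer(n_measurements),
                 tissues = tissues, seed = as.integer(seed)),
            class = "design_config")
}

#' Total number of spectra implied by a design
#' @param design A [design_config()].
#' @return Integer: n_tissues x n_specimens x n_samples x n_points x
#'   n_measurements.
#' @export
design_size <- function(design) {
  length(design$tissues) * design$n_specimens * design$n_samples *
    design$n_points * design$n_measurements
}

# noiseless reflectance template of a profile on a grid:
# R(lambda) = scatter * B(lambda) * exp(-sum_c w_c * G_c(lambda))
# with Gaussian bands G_c and a sigmoidal decay B starting near decay_center
spectrum_template <- function(profile, wavelength) {
  check_grid(wavelength)
  chrom <- drs_chromophores()
  absorb <- numeric(length(wavelength))
  for (nm in names(profile$band_weights)) {
    i <- match(nm, chrom$name)
    absorb <- absorb + profile$band_weights[[nm]] *
      exp(-(wavelength - chrom$center[i])^2 / (2 * chrom$width[i]^2))
  }
  decay <- 0.2 + 0.8 / (1 + exp((wavelength - profile$decay_center) /
                                  profile$decay_width))
  profile$scatter_level * decay * exp(-absorb)
}

# shift vector content by an integer lag (positive = toward longer
# wavelengths), replicating edge values
shift_vector <- function(x, lag) {
  n <- length(x)
  if (lag == 0L) return(x)
  idx <- pmin(pmax(seq_len(n) - lag, 1L), n)
  x[idx]
}

apply_effects <- function(template, wavelength, effects) {
  mid <- (wavelength[1] + wavelength[length(wavelength)]) / 2
  y <- shift_vector(effects$gain * template, as.integer(effects$shift))
  y <- y + effects$slope * (wavelength - mid)
  if (length(effects$noise) > 1L || any(effects$noise != 0))
    y <- y + effects$noise
  y
}

#' Generate one spectrum from a profile and realized random effects
#'
#' Deterministic given the effects: intensity =
#' shift(gain * template) + slope * (lambda - lambda_mid) + noise, where the
#' template is the profile's noiseless reflectance curve and the integer shift
#' emulates spectrometer wavelength miscalibration (edge values replicated).
#' With `gain = 1`, `slope = 0`, `shift = 0` and zero noise the output is the
#' noiseless template itself.
#'
#' @param profile A [tissue_profile()].
#' @param wavelength Wavelength grid (nm).
#' @param effects List with elements `gain` (multiplicative, default 1),
#'   `slope` (per nm, default 0), `shift` (integer grid steps, default 0),
#'   `noise` (scalar 0 or per-wavelength additive vector).
#' @return A [drs_spectrum()].
#' @export
generate_spectrum <- function(profile, wavelength = drs_wavelength_grid(),
                              effects = list()) {
  defaults <- list(gain = 1, slope = 0, shift = 0L, noise = 0)
  effects <- utils::modifyList(defaults, effects)
  if (!all(vapply(effects[c("gain", "slope", "shift")], is.finite, logical(1))))
    stop("effects must be finite")
  y <- apply_effects(spectrum_template(profile, wavelength), wavelength, effects)
  if (any(!is.finite(y))) stop("generated spectrum contains non-finite values")
  drs_spectrum(wavelength, y, meta = list(tissue = profile$name))
}

#' Generate a seeded synthetic dataset
#'
#' Draws hierarchical random effects in a fixed documented order from a single
#' RNG stream seeded with `seed`: per specimen a log-normal gain; per sample a
#' log-normal gain, a linear trend slope and a rounded-normal integer
#' wavelength shift; per point a log-normal gain; per measurement an additive
#' white-noise vector. Effects drawn at a level are shared by all nested
#' units, so identical seeds give byte-identical datasets and per-sample mean
#' intensities vary more than within-point replicate measurements whenever
#' `sample_sd` dominates `noise_sd`.
#'
#' @param design A [design_config()].
#' @param profiles Named list of [tissue_profile()] covering all design
#'   tissues (default [default_tissue_profiles()]).
#' @param wavelength Wavelength grid (nm).
#' @param seed Master seed; defaults to `design$seed`.
#' @return A [drs_set()] with `design_size(design)` spectra and hierarchical
#'   metadata (tissue, specimen_id, sample_id, point_idx, measurement_idx).
#' @export
generate_dataset <- function(design = design_config(),
                             profiles = default_tissue_profiles(),
                             wavelength = drs_wavelength_grid(),
                             seed = design$seed) {
  check_grid(wavelength)
  missing <- setdiff(design$tissues, names(profiles))
  if (length(missing))
    stop("no profile supplied for tissue: ", paste(missing, collapse = ", "))
  D <- length(wavelength)
  n <- design_size(design)
  X <- matrix(NA_real_, n, D)
  meta <- data.frame(spectrum_id = character(n), tissue = character(n),
                     specimen_id = character(n), sample_id = character(n),
                     point_idx = integer(n), measurement_idx = integer(n),
                     stringsAsFactors = FALSE)
  with_preserved_seed(seed, {
    row <- 0L
    for (tis in design$tissues) {
      p <- profiles[[tis]]
      template <- spectrum_template(p, wavelength)
      for (sp in seq_len(design$n_specimens)) {
        g_spec <- exp(stats::rnorm(1, 0, p$specimen_sd))
        spec_id <- sprintf("%s_sp%02d", tis, sp)
        for (sa in seq_len(design$n_samples)) {
          g_samp <- exp(stats::rnorm(1, 0, p$sample_sd))
          slope <- stats::rnorm(1, 0, p$trend_slope_sd)
          shift <- as.integer(round(stats::rnorm(1, 0, p$shift_sd)))
          samp_id <- sprintf("%s_sa%d", spec_id, sa)
          for (pt in seq_len(design$n_points)) {
            g_point <- exp(stats::rnorm(1, 0, p$point_sd))
            gain <- g_spec * g_samp * g_point
            for (me in seq_len(design$n_measurements)) {
              noise <- if (p$noise_sd > 0) stats::rnorm(D, 0, p$noise_sd) else 0
              row <- row + 1L
              X[row, ] <- apply_effects(template, wavelength,
                                        list(gain = gain, slope = slope,
                                             shift = shift, noise = noise))
              meta$spectrum_id[row] <- sprintf("%s_p%02d_m%d", samp_id, pt, me)
              meta$tissue[row] <- tis
              meta$specimen_id[row] <- spec_id
              meta$sample_id[row] <- samp_id
              meta$point_idx[row] <- pt
              meta$measurement_idx[row] <- me
            }
          }
        }
      }
    }
  })
  if (any(!is.finite(X))) stop("generated dataset contains non-finite values")
  drs_set(wavelength, X, meta$tissue, meta, steps = "simulate")
}
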