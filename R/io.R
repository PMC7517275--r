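#' Write a spectra set as wide CSV plus metadata sidecar
#'
#' The spectra file has a strictly increasing `wavelength_nm` first column and
#' one column per spectrum (named by `spectrum_id`); the sidecar
#' `<name>.meta.csv` holds `spectrum_id`, `tissue`, `specimen_id`,
#' `sample_id`, `point_idx`, `measurement_idx`. Values round-trip to 12+
#' significant digits.
#'
#' @param set A `drs_set`.
#' @param path Output CSV path (the sidecar path is derived from it).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "drs_set"))
  dt <- data.table::data.table(wavelength_nm = set$wavelength)
  M <- t(set$intensities)
  colnames(M) <- set$meta$spectrum_id
  dt <- cbind(dt, data.table::as.data.table(M))
  data.table::fwrite(dt, path)
  meta_cols <- intersect(c("spectrum_id", "tissue", "specimen_id", "sample_id",
                           "point_idx", "measurement_idx"), names(set$meta))
  data.table::fwrite(set$meta[, meta_cols, drop = FALSE], meta_sidecar_path(path))
  invisible(path)
}

meta_sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.csv")

#' Read a spectra set written by [write_spectra()]
#'
#' @param path Spectra CSV path; the sidecar `<name>.meta.csv` must exist.
#' @return A `drs_set`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such spectra file: ", path)
  mp <- meta_sidecar_path(path)
  if (!file.exists(mp)) stop("missing metadata sidecar: ", mp)
  dt <- data.table::fread(path)
  if (names(dt)[1] != "wavelength_nm")
    stop("first column must be wavelength_nm")
  wl <- dt[[1L]]
  if (any(diff(wl) <= 0)) stop("wavelength_nm must be strictly increasing")
  X <- t(as.matrix(dt[, -1L]))
  meta <- as.data.frame(data.table::fread(mp))
  if (anyDuplicated(meta$spectrum_id)) stop("duplicated spectrum_id in sidecar")
  if (!setequal(rownames(X), meta$spectrum_id) ||
      nrow(meta) != nrow(X))
    stop("sidecar spectrum ids do not match the spectra columns")
  X <- X[meta$spectrum_id, , drop = FALSE]
  drs_set(wl, X, meta$tissue, meta)
}

#' Default end-to-end run configuration
#'
#' A nested list mirroring the pipeline stages: design (and seed), tissue
#' profile noise scaling, preprocessing, characteristic-point feature
#' settings (`top_k = 14` gradients), PCA (`n_components = 40`), classifiers,
#' and the split/evaluation protocol (one-fifth training, repeated splits).
#' Serializes losslessly to YAML via [write_run_config()].
#'
#' @param seed Master seed for the whole run.
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    design = list(n_specimens = 10L, n_samples = 2L, n_points = 16L,
                  n_measurements = 4L),
    profiles = list(noise_scale = 1),
    preprocess = list(sg_window = 11L, sg_polyorder = 3L,
                      align_segments = 1L, align_max_shift = 10L,
                      renormalize_after_detrend = TRUE),
    features = list(top_k = 14L, window_halfwidth = 10),
    pca = list(n_components = 40L),
    classifiers = list(lda = list(), qda = list(), knn = list(k = 5L),
                       cart = list(max_depth = 20L, min_leaf = 5L),
                       nb = list()),
    split = list(train_fraction = 0.2, unit = "spectrum", repeats = 20L),
    aggregate_measurements = FALSE
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config` the
#'   configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(utils::modifyList(unclass(default_run_config()), cfg),
            class = "run_config")
}

# average the replicate measurements of each point into one spectrum
aggregate_measurements <- function(set) {
  key <- interaction(set$meta$specimen_id, set$meta$sample_id,
                     set$meta$point_idx, drop = TRUE)
  idx <- split(seq_len(n_spectra(set)), key)
  X <- t(vapply(idx, function(i) colMeans(set$intensities[i, , drop = FALSE]),
                numeric(length(set$wavelength))))
  first <- vapply(idx, `[`, integer(1), 1L)
  meta <- set$meta[first, , drop = FALSE]
  meta$measurement_idx <- NA_integer_
  meta$spectrum_id <- sub("_m[0-9]+$", "", meta$spectrum_id)
  drs_set(set$wavelength, X, meta$tissue, meta,
          c(set$steps, "aggregate_measurements"))
}

#' Run the full two-path classification pipeline
#'
#' Simulates (or loads) spectra, preprocesses them, extracts both feature
#' representations — the characteristics path (9 landmarks, 81 gradients,
#' ANOVA-F ranked, top `top_k` kept) and the PCA path (`n_components`
#' scores) — and runs repeated stratified train/test evaluation of all
#' configured classifiers on both. Fully reproducible per `config$seed`.
#'
#' @param config A [default_run_config()]-style list.
#' @param input Optional path of a spectra CSV to load instead of simulating.
#' @param out_dir Optional directory; when given, feature matrices, accuracy
#'   tables, per-classifier confusion matrices and a YAML run log (config,
#'   seed, stage timings, package version) are written there.
#' @return List with `set` (preprocessed), `gradient` and `pca` result lists
#'   (features, ranking/model, accuracy table), and `log`.
#' @export
run_pipeline <- function(config = default_run_config(), input = NULL,
                         out_dir = NULL) {
  timings <- list()
  tlast <- proc.time()[["elapsed"]]
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - tlast, 3)
    tlast <<- t1
  }

  if (is.null(input)) {
    design <- design_config(config$design$n_specimens, config$design$n_samples,
                            config$design$n_points, config$design$n_measurements,
                            seed = config$seed)
    profiles <- default_tissue_profiles(noise_scale = config$profiles$noise_scale)
    set <- generate_dataset(design, profiles)
  } else {
    set <- read_spectra(input)
  }
  tick("load")
  if (isTRUE(config$aggregate_measurements)) set <- aggregate_measurements(set)

  pp <- do.call(preprocess_config, config$preprocess)
  set <- preprocess_pipeline(set, pp)
  tick("preprocess")

  # characteristics path: landmarks -> 81 gradients -> F-ranking -> top k
  specs <- characteristic_point_specs(config$features$window_halfwidth)
  gf <- gradient_features(set, specs)
  rank <- anova_f(gf$features, gf$labels)
  keep <- select_top_k(rank, config$features$top_k)
  grad_x <- gf$features[, keep, drop = FALSE]
  tick("features")

  # PCA path
  model <- pca_fit(set, config$pca$n_components)
  scores <- pca_transform(model, set)
  tick("pca")

  eval_seed <- (config$seed * 1009L) %% .Machine$integer.max
  grad_acc <- repeated_evaluation(grad_x, set$labels, config$classifiers,
                                  repeats = config$split$repeats,
                                  train_fraction = config$split$train_fraction,
                                  unit = config$split$unit, meta = set$meta,
                                  seed = eval_seed)
  pca_acc <- repeated_evaluation(scores, set$labels, config$classifiers,
                                 repeats = config$split$repeats,
                                 train_fraction = config$split$train_fraction,
                                 unit = config$split$unit, meta = set$meta,
                                 seed = eval_seed + 1L)
  tick("evaluate")

  log <- list(seed = config$seed,
              config_hash = config_hash(config),
              n_spectra = n_spectra(set),
              n_gradient_features = ncol(gf$features),
              n_selected_gradients = ncol(grad_x),
              n_pca_components = config$pca$n_components,
              timings = timings,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("drstissue")))

  res <- list(set = set,
              gradient = list(features = grad_x, ranking = rank,
                              selected = keep, accuracy = grad_acc),
              pca = list(model = model, scores = scores, accuracy = pca_acc),
              log = log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cbind(data.frame(spectrum_id = set$meta$spectrum_id),
                           as.data.frame(grad_x),
                           label = as.character(set$labels)),
                     file.path(out_dir, "gradient_features.csv"),
                     row.names = FALSE)
    utils::write.csv(grad_acc, file.path(out_dir, "gradient_path_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(pca_acc, file.path(out_dir, "pca_path_accuracy.csv"),
                     row.names = FALSE)
    sp <- make_split(set$labels, set$meta, config$split$train_fraction,
                     config$split$unit, seed = eval_seed)
    for (cl in names(config$classifiers)) {
      ev <- evaluate_split(scores, set$labels, sp, cl, config$classifiers[[cl]])
      utils::write.csv(as.data.frame.matrix(unclass(ev$confusion)),
                       file.path(out_dir, sprintf("confusion_pca_%s.csv", cl)))
    }
    yaml::write_yaml(c(log, list(config = unclass(config))),
                     file.path(out_dir, "run_log.yaml"))
  }
  res
}

# deterministic polynomial hash of the configuration's YAML serialization
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
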