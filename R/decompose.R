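#' Fit a principal component model
#'
#' Eigendecomposition of the sample covariance (1/(N-1)) of mean-centered
#' rows, keeping the top `M` eigenpairs. The component sign is fixed
#' deterministically: each component's largest-magnitude entry is positive.
#'
#' @param X N x D numeric matrix (rows = observations), or a `drs_set` /
#'   feature list whose rows are used.
#' @param M Number of components, `1 <= M <= min(N - 1, D)`.
#' @return An object of class `pca_model`: list with `mean` (length D),
#'   `components` (D x M orthonormal columns), `eigenvalues` (length M,
#'   non-increasing), `total_variance`, `N`, `D`, `M`.
#' @export
pca_fit <- function(X, M) {
  if (inherits(X, "drs_set")) X <- X$intensities
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  if (N < 2L) stop("need at least 2 observations")
  if (M < 1L || M > min(N - 1L, D))
    stop("M must satisfy 1 <= M <= min(N - 1, D)")
  mu <- colMeans(X)
  Xc <- X - matrix(mu, N, D, byrow = TRUE)
  S <- crossprod(Xc) / (N - 1)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  U <- eg$vectors[, seq_len(M), drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (m in seq_len(M)) {
    i <- which.max(abs(U[, m]))
    if (U[i, m] < 0) U[, m] <- -U[, m]
  }
  structure(list(mean = mu, components = U,
                 eigenvalues = ev[seq_len(M)],
                 total_variance = sum(ev), N = N, D = D, M = M),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> D=%d, M=%d; explained variance of first %d: %.4f\n",
              x$D, x$M, x$M, sum(x$eigenvalues) / max(x$total_variance, .Machine$double.eps)))
  invisible(x)
}

#' Project data onto the principal components
#'
#' scores = (X - mean) U. On the training data, the per-component score
#' variances equal the model eigenvalues.
#'
#' @param model A [pca_fit()] model.
#' @param X N x D matrix (or `drs_set`) on the model's variable space.
#' @return N x M score matrix.
#' @export
pca_transform <- function(model, X) {
  if (inherits(X, "drs_set")) X <- X$intensities
  X <- as.matrix(X)
  if (ncol(X) != model$D) stop("column count does not match the model dimension")
  (X - matrix(model$mean, nrow(X), model$D, byrow = TRUE)) %*% model$components
}

#' Reconstruct data from component scores
#'
#' x_hat = mean + scores t(U). With `M = D` (complete basis) reconstruction is
#' exact; with fewer components it is the least-squares rank-M approximation.
#'
#' @param model A [pca_fit()] model.
#' @param scores N x M score matrix.
#' @return N x D reconstructed matrix.
#' @export
pca_reconstruct <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$M) stop("score width does not match the model")
  scores %*% t(model$components) +
    matrix(model$mean, nrow(scores), model$D, byrow = TRUE)
}

#' Cumulative explained-variance ratio
#'
#' The fraction of total variance captured by the first `M'` components,
#' sum_{m<=M'} lambda_m / total variance: a reconstruction-similarity measure
#' in [0, 1], non-decreasing in `M'`.
#'
#' @param model A [pca_fit()] model.
#' @param M_prime Number of leading components, `1 <= M' <= M`.
#' @return Scalar in [0, 1].
#' @export
explained_similarity <- function(model, M_prime) {
  if (M_prime <= 0) stop("M' must be positive")
  if (M_prime > model$M) stop("M' exceeds the number of fitted components")
  if (model$total_variance <= 0) return(1)
  min(sum(model$eigenvalues[seq_len(M_prime)]) / model$total_variance, 1)
}

#' Write / read a PCA model as a self-describing text file
#'
#' Plain CSV blocks (header lines starting with `#`): scalars, the mean
#' vector, the eigenvalues and the component matrix.
#'
#' @param model A [pca_fit()] model.
#' @param path File path.
#' @return `write_pca_model` returns `path` invisibly; `read_pca_model`
#'   returns the reconstructed `pca_model`.
#' @export
write_pca_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pca_model N=%d D=%d M=%d total_variance=%.17g",
                     model$N, model$D, model$M, model$total_variance), con)
  writeLines("# mean", con)
  writeLines(paste(sprintf("%.17g", model$mean), collapse = ","), con)
  writeLines("# eigenvalues", con)
  writeLines(paste(sprintf("%.17g", model$eigenvalues), collapse = ","), con)
  writeLines("# components (rows = variables)", con)
  utils::write.table(format(model$components, digits = 17, trim = TRUE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_pca_model
#' @param path File path.
#' @export
read_pca_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# pca_model ", "", lines[1]), " ")[[1]]
  kv <- function(key) as.numeric(sub(paste0(key, "="), "", hdr[grep(paste0("^", key, "="), hdr)]))
  mu <- as.numeric(strsplit(lines[3], ",")[[1]])
  ev <- as.numeric(strsplit(lines[5], ",")[[1]])
  comp <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(l, ",")[[1]])))
  structure(list(mean = mu, components = comp, eigenvalues = ev,
                 total_variance = kv("total_variance"),
                 N = as.integer(kv("N")), D = as.integer(kv("D")),
                 M = as.integer(kv("M"))),
            class = "pca_model")
}
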