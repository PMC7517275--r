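check_xy <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  y <- droplevels(y)
  if (nrow(x) != length(y)) stop("features and labels differ in length")
  if (nlevels(y) < 2L) stop("at least 2 classes required")
  list(x = x, y = y)
}

ridge_amount <- function(S, eps = 1e-6) {
  eps * mean(diag(S)) + 1e-12
}

#' Fit a linear discriminant classifier
#'
#' Gaussian classes with a shared (pooled) covariance give linear
#' discriminants y_k(x) = w_k' x + w_k0 with w_k = S_pooled^{-1} mu_k and
#' w_k0 = -mu_k' S_pooled^{-1} mu_k / 2 + log pi_k; a point is assigned to the
#' class with the largest discriminant. The pooled covariance is the plug-in
#' (maximum-likelihood, 1/N) estimate, which makes the fitted model invariant
#' under duplication of the training rows, and is regularized by a small
#' ridge (1e-6 x mean diagonal) so near-singular feature spaces (e.g. 40
#' component scores from a one-fifth training split) stay invertible.
#'
#' @param x n x d feature matrix.
#' @param y Class labels (>= 2 classes, each with >= 2 rows).
#' @param priors Optional named class priors; default = training proportions.
#' @return An object of class `drs_lda` with `means`, `weights`, `biases`,
#'   `pooled_cov`, `priors`, `classes`.
#' @export
lda_fit <- function(x, y, priors = NULL) {
  d <- check_xy(x, y); x <- d$x; y <- d$y
  cls <- levels(y); K <- length(cls)
  nk <- as.integer(table(y))
  if (any(nk < 2L)) stop("every class needs at least 2 training rows")
  if (is.null(priors)) priors <- nk / sum(nk)
  else {
    priors <- priors[cls]; priors <- priors / sum(priors)
  }
  mu <- rowsum(x, y) / nk
  Sp <- matrix(0, ncol(x), ncol(x))
  for (k in seq_len(K)) {
    xk <- x[y == cls[k], , drop = FALSE]
    xc <- xk - matrix(mu[k, ], nrow(xk), ncol(x), byrow = TRUE)
    Sp <- Sp + crossprod(xc)
  }
  Sp <- Sp / nrow(x)
  Spr <- Sp + diag(ridge_amount(Sp), ncol(x))
  W <- solve(Spr, t(mu))                     # d x K
  b <- -0.5 * colSums(t(mu) * W) + log(priors)
  structure(list(means = mu, weights = W, biases = b, pooled_cov = Sp,
                 priors = priors, classes = cls),
            class = "drs_lda")
}

#' @export
predict.drs_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  sc <- X %*% object$weights + matrix(object$biases, nrow(X),
                                      length(object$classes), byrow = TRUE)
  colnames(sc) <- object$classes
  if (type == "score") return(sc)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

gauss_class_params <- function(x, y) {
  cls <- levels(y)
  lapply(cls, function(k) {
    xk <- x[y == k, , drop = FALSE]
    mu <- colMeans(xk)
    S <- stats::cov(xk) * (nrow(xk) - 1L) / nrow(xk)   # plug-in estimate
    list(mean = mu, cov = S, n = nrow(xk))
  })
}

#' Fit a quadratic discriminant classifier
#'
#' Gaussian classes with their own covariances; the discriminant is
#' log pi_k - log|S_k|/2 - (x - mu_k)' S_k^{-1} (x - mu_k)/2. Covariances are
#' plug-in (1/n_k) estimates with the same small ridge as [lda_fit()].
#'
#' @inheritParams lda_fit
#' @return An object of class `drs_qda`.
#' @export
qda_fit <- function(x, y, priors = NULL) {
  d <- check_xy(x, y); x <- d$x; y <- d$y
  cls <- levels(y)
  nk <- as.integer(table(y))
  if (any(nk < 2L)) stop("every class needs at least 2 training rows")
  if (is.null(priors)) priors <- nk / sum(nk)
  else { priors <- priors[cls]; priors <- priors / sum(priors) }
  params <- gauss_class_params(x, y)
  for (k in seq_along(params)) {
    S <- params[[k]]$cov + diag(ridge_amount(params[[k]]$cov), ncol(x))
    ch <- chol(S)
    params[[k]]$chol <- ch
    params[[k]]$logdet <- 2 * sum(log(diag(ch)))
  }
  structure(list(params = params, priors = priors, classes = cls),
            class = "drs_qda")
}

#' @export
predict.drs_qda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  K <- length(object$classes)
  sc <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, object$classes))
  for (k in seq_len(K)) {
    p <- object$params[[k]]
    Xc <- X - matrix(p$mean, nrow(X), ncol(X), byrow = TRUE)
    z <- backsolve(p$chol, t(Xc), transpose = TRUE)
    maha <- colSums(z^2)
    sc[, k] <- log(object$priors[k]) - 0.5 * p$logdet - 0.5 * maha
  }
  if (type == "score") return(sc)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Assumes feature independence within a class: the log posterior (up to a
#' constant) is log p(C_k) + sum_i log Normal(x_i; mu_ki, sigma2_ki).
#' Per-feature variances are floored at 1e-9.
#'
#' @inheritParams lda_fit
#' @param var_floor Minimum per-feature variance.
#' @return An object of class `drs_nb`.
#' @export
nb_fit <- function(x, y, priors = NULL, var_floor = 1e-9) {
  d <- check_xy(x, y); x <- d$x; y <- d$y
  cls <- levels(y)
  nk <- as.integer(table(y))
  if (any(nk < 2L)) stop("every class needs at least 2 training rows")
  if (is.null(priors)) priors <- nk / sum(nk)
  else { priors <- priors[cls]; priors <- priors / sum(priors) }
  mu <- rowsum(x, y) / nk
  v <- rowsum(x^2, y) / nk - mu^2
  v <- v * nk / pmax(nk - 1L, 1L)           # sample variance
  v <- pmax(v, var_floor)
  structure(list(means = mu, vars = v, priors = priors, classes = cls),
            class = "drs_nb")
}

#' @export
predict.drs_nb <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  K <- length(object$classes)
  sc <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, object$classes))
  for (k in seq_len(K)) {
    mu <- object$means[k, ]; v <- object$vars[k, ]
    Xc <- X - matrix(mu, nrow(X), ncol(X), byrow = TRUE)
    ll <- -0.5 * rowSums(Xc^2 / matrix(v, nrow(X), ncol(X), byrow = TRUE)) -
      0.5 * sum(log(2 * pi * v))
    sc[, k] <- log(object$priors[k]) + ll
  }
  if (type == "score") return(sc)
  factor(object$classes[max.col(sc, ties.method = "first")],
         levels = object$classes)
}

#' Fit (store) a k-nearest-neighbor classifier
#'
#' Prediction takes the majority class among the k Euclidean-nearest training
#' points (the empirical class-membership ratio K_k / K); vote ties break
#' toward the class with the smaller mean neighbor distance, then class
#' order.
#'
#' @inheritParams lda_fit
#' @param k Number of neighbors (1 <= k <= n).
#' @return An object of class `drs_knn`.
#' @export
knn_fit <- function(x, y, k = 5L) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- droplevels(factor(y))
  if (nrow(x) == 0L) stop("empty training set")
  if (k < 1L || k > nrow(x)) stop("k must be between 1 and n_train")
  structure(list(x = x, y = y, k = as.integer(k), classes = levels(y)),
            class = "drs_knn")
}

#' @export
predict.drs_knn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  tr <- object$x
  d2 <- outer(rowSums(X^2), rowSums(tr^2), `+`) - 2 * X %*% t(tr)
  d2 <- pmax(d2, 0)
  k <- object$k
  ycode <- as.integer(object$y)
  K <- length(object$classes)
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[i, ])[seq_len(k)]
    votes <- tabulate(ycode[ord], nbins = K)
    best <- which(votes == max(votes))
    if (length(best) > 1L) {
      md <- vapply(best, function(b) mean(d2[i, ord[ycode[ord] == b]]),
                   numeric(1))
      best <- best[order(md, best)][1L]
    }
    out[i] <- best[1L]
  }
  factor(object$classes[out], levels = object$classes)
}

# ---- CART ------------------------------------------------------------------

gini_from_counts <- function(counts, n) 1 - sum((counts / n)^2)

# vectorized best Gini split over all features for one node
cart_best_split <- function(x, ycode, K, min_leaf) {
  n <- length(ycode)
  best <- NULL
  best_imp <- Inf
  for (j in seq_len(ncol(x))) {
    xo <- x[, j]
    o <- order(xo)
    xs <- xo[o]; ys <- ycode[o]
    cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
    i <- seq_len(n - 1L)
    valid <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(valid)) next
    nl <- i; nr <- n - i
    left <- cum[i, , drop = FALSE]
    right <- matrix(cum[n, ], n - 1L, K, byrow = TRUE) - left
    gl <- 1 - rowSums((left / nl)^2)
    gr <- 1 - rowSums((right / nr)^2)
    imp <- (nl * gl + nr * gr) / n
    imp[!valid] <- Inf
    m <- which.min(imp)
    if (imp[m] < best_imp - 1e-12) {
      best_imp <- imp[m]
      best <- list(feature = j, threshold = (xs[m] + xs[m + 1L]) / 2,
                   impurity = imp[m])
    }
  }
  best
}

cart_build <- function(x, ycode, K, depth, params) {
  n <- length(ycode)
  counts <- tabulate(ycode, nbins = K)
  node_imp <- gini_from_counts(counts, n)
  leaf <- list(leaf = TRUE, counts = counts,
               class = which.max(counts))
  if (node_imp <= 0 || depth >= params$max_depth || n < 2L * params$min_leaf)
    return(leaf)
  sp <- cart_best_split(x, ycode, K, params$min_leaf)
  if (is.null(sp) || sp$impurity >= node_imp - 1e-12) return(leaf)
  go_left <- x[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = cart_build(x[go_left, , drop = FALSE], ycode[go_left], K,
                         depth + 1L, params),
       right = cart_build(x[!go_left, , drop = FALSE], ycode[!go_left], K,
                          depth + 1L, params))
}

#' Fit a classification tree (CART)
#'
#' Greedy binary splitting on axis-aligned thresholds minimizing the Gini
#' impurity, stopping at pure nodes, `max_depth`, or leaves smaller than
#' `min_leaf`; each leaf predicts its majority class. (Impurity-based
#' splitting is the standard CART criterion; a literal "maximize the p-value"
#' rule would select the least-discriminating split, so it is not offered.)
#'
#' @inheritParams lda_fit
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum rows per leaf.
#' @return An object of class `drs_cart`.
#' @export
cart_fit <- function(x, y, max_depth = 20L, min_leaf = 5L) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- droplevels(factor(y))
  if (min_leaf < 1L) stop("min_leaf must be >= 1")
  params <- list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf))
  tree <- cart_build(x, as.integer(y), nlevels(y), 0L, params)
  structure(list(tree = tree, classes = levels(y), params = params),
            class = "drs_cart")
}

cart_walk <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] <= node$threshold) node$left else node$right
  }
  node$class
}

#' @export
predict.drs_cart <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) out[i] <- cart_walk(object$tree, X[i, ])
  factor(object$classes[out], levels = object$classes)
}

# ---- splitting and evaluation ----------------------------------------------

#' Stratified train/test split
#'
#' Random split with `train_fraction` of the data used for training,
#' stratified by class. With `unit = "spectrum"` individual rows are sampled
#' (per-class train counts within 1 of `train_fraction` x class size); with
#' `unit = "sample"` whole physical samples (grouped by `meta$sample_id`) are
#' assigned to one side only, which avoids leaking sample identity between
#' train and test.
#'
#' @param labels Class label per row.
#' @param meta Metadata data frame (needed for `unit = "sample"`).
#' @param train_fraction Fraction in (0, 1); default one fifth.
#' @param unit `"spectrum"` or `"sample"`.
#' @param seed Integer seed; the plan is deterministic per seed.
#' @return An object of class `drs_split`: list with integer `train` and
#'   `test` index vectors (disjoint, covering).
#' @export
make_split <- function(labels, meta = NULL, train_fraction = 0.2,
                       unit = c("spectrum", "sample"), seed = 1L) {
  unit <- match.arg(unit)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  y <- factor(labels)
  y <- droplevels(y)
  train <- integer(0)
  with_preserved_seed(seed, {
    if (unit == "spectrum") {
      for (k in levels(y)) {
        idx <- which(y == k)
        ntr <- max(1L, round(train_fraction * length(idx)))
        train <- c(train, sort(sample(idx, ntr)))
      }
    } else {
      if (is.null(meta) || is.null(meta$sample_id))
        stop("meta with sample_id required for unit = 'sample'")
      for (k in levels(y)) {
        idx <- which(y == k)
        grp <- unique(meta$sample_id[idx])
        ntr <- max(1L, round(train_fraction * length(grp)))
        gtr <- sample(grp, ntr)
        train <- c(train, idx[meta$sample_id[idx] %in% gtr])
      }
    }
  })
  train <- sort(train)
  test <- setdiff(seq_along(y), train)
  if (any(table(y[train]) < 2L))
    stop("a class has fewer than 2 training rows after the split")
  if (nlevels(droplevels(y[test])) < nlevels(y))
    stop("a class is absent from the test set after the split")
  structure(list(train = train, test = as.integer(test),
                 train_fraction = train_fraction, unit = unit,
                 seed = as.integer(seed)),
            class = "drs_split")
}

#' Fit one of the five classifiers by name
#'
#' @param name One of `"lda"`, `"qda"`, `"nb"`, `"knn"`, `"cart"`.
#' @param x,y Training features and labels.
#' @param params Named list of extra arguments for the fit function (e.g.
#'   `list(k = 5)` for kNN).
#' @return The fitted model (has a `predict` method).
#' @export
fit_classifier <- function(name, x, y, params = list()) {
  name <- match.arg(name, c("lda", "qda", "nb", "knn", "cart"))
  fn <- switch(name, lda = lda_fit, qda = qda_fit, nb = nb_fit,
               knn = knn_fit, cart = cart_fit)
  do.call(fn, c(list(x = x, y = y), params))
}

#' Train on a split and evaluate on the held-out part
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param split A [make_split()] plan.
#' @param classifier Classifier name (see [fit_classifier()]).
#' @param params Classifier parameters.
#' @return List with `model`, `confusion` (a [confusion_matrix()]), and
#'   `accuracy`.
#' @export
evaluate_split <- function(x, y, split, classifier = "lda", params = list()) {
  x <- as.matrix(x)
  y <- factor(y)
  model <- fit_classifier(classifier, x[split$train, , drop = FALSE],
                          y[split$train], params)
  pred <- predict(model, x[split$test, , drop = FALSE])
  M <- confusion_matrix(as.character(y[split$test]), as.character(pred),
                        classes = levels(y))
  list(model = model, confusion = M, accuracy = accuracy(M))
}

#' Repeated random-split evaluation
#'
#' Runs `repeats` independent stratified splits and reports, per classifier,
#' the mean and sample standard deviation of the held-out accuracy — the
#' mean +/- SD convention of the reported accuracy tables.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param classifiers Character vector of classifier names, or a named list
#'   `name = params`.
#' @param repeats Number of random splits (>= 2).
#' @param train_fraction,unit,meta Passed to [make_split()].
#' @param seed Master seed; split seeds are drawn deterministically from it.
#' @return Data frame with columns `classifier`, `mean_accuracy`,
#'   `sd_accuracy`; the per-repeat accuracy matrix is in the
#'   `"accuracies"` attribute.
#' @export
repeated_evaluation <- function(x, y, classifiers = c("lda", "qda", "knn",
                                                      "cart", "nb"),
                                repeats = 20L, train_fraction = 0.2,
                                unit = "spectrum", meta = NULL, seed = 1L) {
  if (repeats < 2L) stop("repeats must be >= 2")
  if (!is.list(classifiers))
    classifiers <- stats::setNames(rep(list(list()), length(classifiers)),
                                   classifiers)
  split_seeds <- with_preserved_seed(seed,
                                     sample.int(.Machine$integer.max, repeats))
  acc <- matrix(NA_real_, repeats, length(classifiers),
                dimnames = list(NULL, names(classifiers)))
  for (r in seq_len(repeats)) {
    sp <- make_split(y, meta = meta, train_fraction = train_fraction,
                     unit = unit, seed = split_seeds[r])
    for (cl in names(classifiers)) {
      acc[r, cl] <- evaluate_split(x, y, sp, cl, classifiers[[cl]])$accuracy
    }
  }
  res <- data.frame(classifier = colnames(acc),
                    mean_accuracy = colMeans(acc),
                    sd_accuracy = apply(acc, 2L, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "accuracies") <- acc
  res
}
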