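test_that("LDA places the midpoint boundary between equal-covariance classes", {
  x <- matrix(c(0, 1, 3, 4), ncol = 1)
  y <- c("A", "A", "B", "B")
  m <- lda_fit(x, y)
  expect_equal(as.character(predict(m, matrix(1.9))), "A")
  expect_equal(as.character(predict(m, matrix(2.1))), "B")
  sc <- predict(m, matrix(2.0), type = "score")
  expect_lt(abs(sc[1, "A"] - sc[1, "B"]), 1e-6)
  # duplicated training rows leave the sufficient statistics unchanged
  m2 <- lda_fit(rbind(x, x), c(y, y))
  expect_equal(m2$weights, m$weights, tolerance = 1e-9)
  expect_equal(m2$biases, m$biases, tolerance = 1e-6)
  expect_error(lda_fit(matrix(c(0, 3, 4), ncol = 1), c("A", "B", "B")),
               "2 training rows")
})

test_that("LDA with identity covariance reduces to nearest class mean", {
  set.seed(61)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60 * 2), 60), 2, centers[k, ], `+`)))
  y <- rep(c("A", "B", "C"), each = 60)
  m <- lda_fit(x, y)
  xt <- x + matrix(rnorm(nrow(x) * 2), ncol = 2)
  d <- vapply(1:3, function(k) rowSums(sweep(xt, 2, rowsum(x, y)[k, ] / 60)^2),
              numeric(nrow(xt)))
  nearest <- c("A", "B", "C")[max.col(-d)]
  agree <- mean(nearest == as.character(predict(m, xt)))
  expect_gt(agree, 0.95)
})

test_that("QDA matches LDA under equal covariances and prefers tight classes", {
  set.seed(71)
  b <- make_blobs(n_per = 40, K = 2, sep = 5, sd = 1)
  q <- qda_fit(b$x, b$y); l <- lda_fit(b$x, b$y)
  xt <- b$x + matrix(rnorm(length(b$x), sd = 0.5), ncol = 2)
  expect_gt(mean(predict(q, xt) == predict(l, xt)), 0.95)
  # tight class {-1,0,1} vs wide {-15,0,15}: x = 0.1 goes to the tight one
  x1 <- matrix(c(-1, 0, 1, -15, 0, 15), ncol = 1)
  y1 <- rep(c("tight", "wide"), each = 3)
  qm <- qda_fit(x1, y1)
  expect_equal(as.character(predict(qm, matrix(0.1))), "tight")
  # a point at a class mean with small spread belongs to it
  expect_equal(as.character(predict(qm, matrix(0))), "tight")
})

test_that("discriminant scores match brute-force Gaussian densities", {
  set.seed(81)
  x <- matrix(rnorm(20 * 3), 20)
  y <- factor(rep(c("a", "b", "c", "d"), each = 5))
  xt <- matrix(rnorm(5 * 3), 5)
  cls <- levels(y)
  nk <- as.integer(table(y))
  pri <- nk / sum(nk)
  mus <- lapply(cls, function(k) colMeans(x[y == k, , drop = FALSE]))
  covs <- lapply(cls, function(k) cov(x[y == k, , drop = FALSE]))
  # plug-in pooled covariance + the documented ridge
  Sp <- Reduce(`+`, lapply(seq_along(cls), function(k)
    covs[[k]] * (nk[k] - 1))) / nrow(x)
  Spr <- Sp + diag(1e-6 * mean(diag(Sp)) + 1e-12, 3)
  lm_ <- lda_fit(x, y)
  ql <- qda_fit(x, y)
  nbm <- nb_fit(x, y)
  for (i in seq_len(nrow(xt))) {
    for (k in seq_along(cls)) {
      wk <- solve(Spr, mus[[k]])
      ref_lda <- sum(wk * xt[i, ]) - 0.5 * sum(mus[[k]] * wk) + log(pri[k])
      expect_equal(predict(lm_, xt, type = "score")[i, k], ref_lda,
                   tolerance = 1e-8, ignore_attr = TRUE)
      Sk <- covs[[k]] * (nk[k] - 1) / nk[k]
      Sk <- Sk + diag(1e-6 * mean(diag(Sk)) + 1e-12, 3)
      ref_qda <- log(pri[k]) -
        0.5 * as.numeric(determinant(Sk)$modulus) -
        0.5 * drop(t(xt[i, ] - mus[[k]]) %*% solve(Sk) %*% (xt[i, ] - mus[[k]]))
      expect_equal(predict(ql, xt, type = "score")[i, k], ref_qda,
                   tolerance = 1e-8, ignore_attr = TRUE)
      vks <- pmax(apply(x[y == cls[k], , drop = FALSE], 2, var), 1e-9)
      ref_nb <- log(pri[k]) +
        sum(dnorm(xt[i, ], mus[[k]], sqrt(vks), log = TRUE))
      expect_equal(predict(nbm, xt, type = "score")[i, k], ref_nb,
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("LDA class posteriors order like an established implementation", {
  skip_if_not_installed("MASS")
  b <- make_blobs(n_per = 50, K = 3, sep = 4, sd = 1.2, seed = 91)
  mine <- lda_fit(b$x, b$y)
  ref <- MASS::lda(b$x, b$y)
  xt <- matrix(rnorm(300, sd = 3), ncol = 2)
  expect_gt(mean(predict(mine, xt) ==
                   predict(ref, xt)$class), 0.98)
})

test_that("naive Bayes ignores feature duplication for the argmax", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  y <- c("A", "A", "B", "B")
  m1 <- nb_fit(x, y)
  expect_equal(as.character(predict(m1, matrix(0.4))), "A")
  m2 <- nb_fit(cbind(x, x), y)
  xt <- matrix(seq(-2, 13, by = 0.5), ncol = 1)
  expect_equal(predict(m2, cbind(xt, xt)), predict(m1, xt))
})

test_that("kNN predicts by majority with distance tie-breaks and scale invariance", {
  x <- matrix(c(0, 0.5, 1, 10, 10.5), ncol = 1)
  y <- c("A", "A", "B", "B", "B")
  m1 <- knn_fit(x, y, k = 1)
  expect_equal(as.character(predict(m1, matrix(0.5))), "A")
  m3 <- knn_fit(x, y, k = 3)
  expect_equal(as.character(predict(m3, matrix(0.6))), "A")  # neighbors A,A,B
  # k = 1 memorizes distinct training points
  expect_equal(predict(m1, x), factor(y))
  # multiplying features by a constant preserves distance ranks
  b <- make_blobs(n_per = 25, K = 3, seed = 101)
  xt <- matrix(rnorm(60, sd = 4), ncol = 2)
  ma <- knn_fit(b$x, b$y, k = 5)
  mb <- knn_fit(2 * b$x, b$y, k = 5)
  expect_equal(predict(ma, xt), predict(mb, 2 * xt))
  expect_error(knn_fit(x, y, k = 9), "between 1 and")
})

test_that("kNN agrees with an established implementation on unambiguous data", {
  skip_if_not_installed("class")
  b <- make_blobs(n_per = 40, K = 3, sep = 6, sd = 1, seed = 111)
  xt <- make_blobs(n_per = 15, K = 3, sep = 6, sd = 1, seed = 112)$x
  mine <- predict(knn_fit(b$x, b$y, k = 5), xt)
  ref <- class::knn(b$x, xt, b$y, k = 5)
  expect_gt(mean(as.character(mine) == as.character(ref)), 0.95)
})

test_that("CART isolates separable classes and memorizes with min_leaf 1", {
  x <- matrix(c(0, 0.5, 1, 3, 3.5, 4), ncol = 1)
  y <- c("A", "A", "A", "B", "B", "B")
  m <- cart_fit(x, y, min_leaf = 1)
  expect_false(m$tree$leaf)
  expect_true(m$tree$threshold > 1 && m$tree$threshold < 3)
  expect_equal(predict(m, x), factor(y))
  # pure input -> depth-0 tree
  mp <- cart_fit(x, rep("A", 6) , min_leaf = 1)
  expect_true(mp$tree$leaf)
  expect_equal(as.character(predict(mp, matrix(99))), "A")
  # memorization on distinct separable points, unlimited depth
  b <- make_blobs(n_per = 20, K = 3, sep = 6, seed = 121)
  mm <- cart_fit(b$x, b$y, max_depth = 50, min_leaf = 1)
  expect_equal(predict(mm, b$x), b$y)
})

test_that("CART matches rpart training behavior on simple separable data", {
  skip_if_not_installed("rpart")
  b <- make_blobs(n_per = 30, K = 2, sep = 6, seed = 131)
  df <- data.frame(y = b$y, x1 = b$x[, 1], x2 = b$x[, 2])
  ref <- rpart::rpart(y ~ ., df, method = "class",
                      control = rpart::rpart.control(minsplit = 2,
                                                     minbucket = 1, cp = 0))
  mine <- cart_fit(b$x, b$y, min_leaf = 1)
  expect_equal(as.character(predict(mine, b$x)),
               as.character(predict(ref, df, type = "class")))
})

test_that("all classifiers are invariant to adding a constant feature offset", {
  b <- make_blobs(n_per = 30, K = 3, sep = 5, seed = 141)
  xt <- matrix(rnorm(80, sd = 3), ncol = 2)
  off <- c(100, -50)
  for (cl in c("lda", "qda", "knn", "cart")) {
    m0 <- fit_classifier(cl, b$x, b$y)
    m1 <- fit_classifier(cl, sweep(b$x, 2, off, `+`), b$y)
    expect_equal(predict(m0, xt), predict(m1, sweep(xt, 2, off, `+`)),
                 label = cl)
  }
})

test_that("training accuracy beats chance on separable data for every classifier", {
  b <- make_blobs(n_per = 30, K = 3, sep = 7, seed = 151)
  for (cl in c("lda", "qda", "nb", "knn", "cart")) {
    m <- fit_classifier(cl, b$x, b$y)
    expect_gte(mean(predict(m, b$x) == b$y), 0.9)
  }
})

test_that("make_split stratifies, is deterministic, and can group by sample", {
  y <- rep(tissue_classes(), each = 100)
  sp <- make_split(y, train_fraction = 0.2, seed = 3)
  expect_equal(unname(table(y[sp$train])), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(y))
  sp2 <- make_split(y, train_fraction = 0.2, seed = 3)
  expect_identical(sp$train, sp2$train)
  # grouped split: no sample id on both sides
  meta <- data.frame(sample_id = paste0(y, "_s", rep(rep(1:10, each = 10), 5)))
  spg <- make_split(y, meta, 0.2, unit = "sample", seed = 5)
  expect_length(intersect(meta$sample_id[spg$train], meta$sample_id[spg$test]), 0)
  expect_error(make_split(y, train_fraction = 1.5), "train_fraction")
})

test_that("repeated evaluation reports mean and SD of held-out accuracy", {
  b <- make_blobs(n_per = 60, K = 3, sep = 10, sd = 0.5, seed = 161)
  res <- repeated_evaluation(b$x, b$y, c("lda", "knn"), repeats = 4, seed = 2)
  expect_equal(res$mean_accuracy, c(1, 1), tolerance = 1e-12)
  expect_equal(res$sd_accuracy, c(0, 0), tolerance = 1e-12)
  res2 <- repeated_evaluation(b$x, b$y, c("lda", "knn"), repeats = 4, seed = 2)
  expect_identical(attr(res, "accuracies"), attr(res2, "accuracies"))
  # uninformative features on shuffled balanced labels -> chance level 1/5
  set.seed(7)
  xr <- matrix(rnorm(1000 * 3), 1000)
  yr <- factor(rep(tissue_classes(), each = 200))
  rr <- repeated_evaluation(xr, yr, "lda", repeats = 5, seed = 9)
  expect_lt(abs(rr$mean_accuracy - 0.2), 0.1)
})
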