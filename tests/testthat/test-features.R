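test_that("landmark detection finds planted extrema and interpolated crossings", {
  wl <- drs_wavelength_grid()
  # planted valley at exactly 410 nm
  s <- drs_spectrum(wl, -exp(-(wl - 410)^2 / (2 * 8^2)))
  pts <- detect_points(s)
  p1 <- pts[pts$index == 1, ]
  expect_true(p1$found)
  expect_lt(abs(p1$wavelength - 410), 0.5 + 1e-9)
  # constant spectrum: nothing is found, fallback path everywhere
  flat <- drs_spectrum(wl, rep(1, length(wl)))
  expect_false(any(detect_points(flat)$found))
  # planted local minimum at exactly 575.0 nm
  s5 <- drs_spectrum(wl, -exp(-(wl - 575)^2 / (2 * 9^2)))
  p5 <- detect_points(s5)[5, ]
  expect_true(p5$found)
  expect_equal(p5$wavelength, 575)
  # derivative zero crossing of a smooth band center, interpolated
  s6 <- drs_spectrum(wl, exp(-(wl - 955.25)^2 / (2 * 10^2)))
  p6 <- detect_points(s6)[6, ]
  expect_true(p6$found)
  expect_lt(abs(p6$wavelength - 955.25), 0.5)
})

test_that("set-level and single-spectrum detection agree", {
  set <- small_set(seed = 3)[1:10]
  pp <- preprocess_pipeline(set)
  pts_set <- detect_points(pp)
  for (i in c(1, 5, 10)) {
    pi <- detect_points(get_spectrum(pp, i))
    expect_equal(pi$wavelength, unname(pts_set$wavelength[i, ]))
    expect_equal(pi$value, unname(pts_set$value[i, ]))
    expect_equal(pi$found, unname(pts_set$found[i, ]))
  }
})

test_that("gradients are pairwise slopes with antisymmetry and zero diagonal", {
  pts <- data.frame(wavelength = c(410, 495, 540, 557.5, 575, 970, 436, 934, 958),
                    value = c(-1, 2, -0.5, 1.5, -1, 0.5, 0.2, 0.1, 0.3))
  g <- gradients(pts)
  expect_equal(g$matrix[5, 6], 1.5 / 395)
  expect_equal(g$matrix[6, 5], -g$matrix[5, 6])
  expect_true(all(diag(g$matrix) == 0))
  expect_equal(unname(g$features["grad_5_6"]), g$matrix[5, 6])
  expect_length(g$features, 81L)
  # antisymmetry holds for arbitrary inputs
  set.seed(2)
  pr <- data.frame(wavelength = sort(runif(9, 400, 1000)), value = rnorm(9))
  gr <- gradients(pr)$matrix
  expect_equal(gr, -t(gr))
  # equal values -> zero slope
  pe <- data.frame(wavelength = c(1:9), value = rep(2, 9))
  expect_true(all(gradients(pe)$matrix == 0))
  # coincident wavelengths are an error unless strict = FALSE
  pd <- pts; pd$wavelength[6] <- pd$wavelength[9] <- 950
  expect_error(gradients(pd), "degenerate")
  expect_equal(gradients(pd, strict = FALSE)$matrix[6, 9], 0)
})

test_that("anova_f matches hand computation, an independent oracle, and is order-free", {
  # one feature, groups {1,2,3} vs {4,5,6}: SSB/1 = 13.5, SSW/4 = 1
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- rep(c("a", "b"), each = 3)
  expect_equal(unname(anova_f(x, y)$F), 13.5)
  # identical group means -> F = 0 regardless of spreads
  x0 <- matrix(c(-1, 0, 1, -10, 0, 10), ncol = 1)
  expect_equal(unname(anova_f(x0, y)$F), 0, tolerance = 1e-12)
  # oracle: stats::oneway.test with equal variances on random matrices
  set.seed(8)
  X <- matrix(rnorm(40 * 6), 40)
  g <- factor(sample(letters[1:4], 40, replace = TRUE))
  Fv <- anova_f(X, g)$F
  for (j in seq_len(ncol(X))) {
    ref <- stats::oneway.test(X[, j] ~ g, var.equal = TRUE)$statistic
    expect_equal(unname(Fv[j]), unname(ref), tolerance = 1e-9)
  }
  # jointly permuting rows leaves F unchanged
  perm <- sample(40)
  expect_equal(anova_f(X[perm, ], g[perm])$F, Fv, tolerance = 1e-12)
  # zero within-class variance with distinct means -> infinite sentinel
  xs <- matrix(rep(c(0, 1), each = 3), ncol = 1)
  expect_equal(unname(anova_f(xs, y)$F), Inf)
  expect_error(anova_f(X, rep("a", 40)), "2 classes")
})

test_that("select_top_k orders by descending F with index tie-breaks", {
  r <- structure(list(F = c(5, 1, 9), order = order(-c(5, 1, 9), 1:3)),
                 class = "drs_franking")
  expect_equal(select_top_k(r, 2), c(3L, 1L))
  expect_equal(select_top_k(r, 3), c(3L, 1L, 2L))
  rt <- anova_f(matrix(c(1, 2, 4, 5, 1, 2, 4, 5), ncol = 2),
                rep(c("a", "b"), each = 2))
  expect_equal(select_top_k(rt, 2), c(1L, 2L))  # exact tie -> smaller index
  expect_error(select_top_k(r, 0), "positive")
  expect_error(select_top_k(r, 4), "exceeds")
})

test_that("perturbing one chromophore drives the top-ranked gradient to its landmarks", {
  base_w <- c(protein_280 = 1, hb_410 = 0.8, hb_433 = 0.56, hb_540 = 0.4,
              hb_575 = 0.45, lipid_930 = 0.3, water_970 = 0.35)
  quiet <- function(name, w) tissue_profile(name, w, specimen_sd = 0,
                                            sample_sd = 0, point_sd = 0,
                                            noise_sd = 0.004,
                                            trend_slope_sd = 0, shift_sd = 0)
  pert_w <- base_w
  pert_w[["water_970"]] <- 0.7
  profs <- list(fat = quiet("fat", base_w), skin = quiet("skin", pert_w))
  set <- generate_dataset(design_config(3, 1, 4, 2, tissues = c("fat", "skin")),
                          profs, seed = 13)
  pp <- preprocess_pipeline(set)
  gf <- gradient_features(pp)
  rk <- anova_f(gf$features, gf$labels)
  top <- names(rk$F)[select_top_k(rk, 1)]
  ij <- as.integer(strsplit(sub("grad_", "", top), "_")[[1]])
  expect_true(any(ij %in% c(6L, 8L, 9L)))
})

test_that("landmarks on noiseless templates match a brute-force search within one step", {
  pp <- zero_noise_processed()
  # one spectrum per tissue suffices: templates are identical within tissue
  rows <- match(tissue_classes(), as.character(pp$labels))
  specs <- characteristic_point_specs()
  pts <- detect_points(pp[rows])
  wl <- pp$wavelength
  for (r in seq_along(rows)) {
    y <- pp$intensities[rows[r], ]
    for (s in seq_len(nrow(specs))) {
      win <- which(wl >= specs$lo[s] & wl <= specs$hi[s])
      truth <- if (specs$mode[s] == "minimum") wl[win[which.min(y[win])]]
      else if (specs$mode[s] == "maximum") wl[win[which.max(y[win])]]
      else {
        d <- diff(y) / diff(wl)             # forward differences, independent path
        mids <- (wl[-1] + wl[-length(wl)]) / 2
        inwin <- which(mids >= specs$lo[s] & mids <= specs$hi[s])
        cr <- inwin[which(d[inwin][-1] * d[inwin][-length(inwin)] <= 0)]
        cross_wl <- (mids[cr] + mids[cr + 1]) / 2
        cross_wl[which.min(abs(cross_wl - specs$nominal[s]))]
      }
      expect_true(pts$found[r, s],
                  label = sprintf("%s P%d found", tissue_classes()[r], s))
      expect_lt(abs(pts$wavelength[r, s] - truth), 0.5 + 1e-9)
    }
  }
})
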