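make_cal_data <- function(n = 120, noise_sd = 0, seed = 2, n_comp = 3) {
  set.seed(seed)
  tr <- data.frame(id = paste0("s", 1:n), y = rnorm(n, 50, 3))
  sp <- simulate_spectra(tr, spectra_model(n_components = n_comp,
                                           noise_sd = noise_sd), seed = seed)
  list(X = sp$spectra, y = stats::setNames(tr$y, tr$id))
}

test_that("spectral preprocessing has the expected analytic behavior", {
  x <- matrix(rnorm(300), 3, 100)
  xs <- (x - rowMeans(x)) / apply(x, 1, sd)
  expect_equal(preprocess(xs, "snv"), xs, ignore_attr = TRUE,
               tolerance = 1e-12)

  const <- matrix(5, 2, 50)
  expect_true(all(abs(preprocess(const, "d1")) < 1e-10))

  ramp <- matrix(seq(0, 99) * 0.3, 2, 100, byrow = TRUE)
  d1 <- preprocess(ramp, "d1")
  expect_equal(unname(d1[1, 20:80]), rep(0.3, 61), tolerance = 1e-8)
  expect_true(all(abs(preprocess(ramp, "d2")) < 1e-8))

  # msc undoes per-sample affine scatter exactly
  base <- sin(seq(0, 6, length.out = 100)) + 2
  scat <- rbind(1.3 * base + 0.2, 0.7 * base - 0.1, base)
  m <- preprocess(scat, "msc")
  expect_lt(max(abs(m[1, ] - m[2, ])), 1e-10)

  expect_error(preprocess(matrix(0, 2, 5), "d1", window = 15), "window")
})

test_that("Kennard-Stone picks the max-min configuration on the line", {
  X <- matrix(c(0, 1, 5, 10), 4, 1,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  sel <- kennard_stone(X, 3)
  expect_equal(sel[1:2], c("a", "d"))  # global max-distance pair
  expect_equal(sel[3], "c")            # 5 has max-min distance 4
  expect_setequal(kennard_stone(X, 4), c("a", "b", "c", "d"))
})

test_that("Kennard-Stone equals the brute-force oracle on random instances", {
  set.seed(70)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(paste0("s", 1:n), NULL))
    k <- sample(2:n, 1)
    expect_identical(kennard_stone(X, k), oracle_kennard_stone(X, k))
  }
})

test_that("calibration splits are disjoint, exhaustive when sized so, and seeded", {
  ids <- paste0("s", 1:350)
  sp <- split_calibration(ids, 250, 100, seed = 3)
  expect_length(intersect(sp$estimation, sp$validation), 0)
  expect_setequal(c(sp$estimation, sp$validation), ids)
  sp2 <- split_calibration(ids, 250, 100, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_calibration(paste0("s", 1:200), 150, 50, seed = 4)
  expect_length(sp3$estimation, 150)
  expect_length(sp3$validation, 50)
  expect_error(split_calibration(ids[1:100], 90, 20), "insufficient")
})

test_that("PLS1 reproduces OLS at full rank and fits rank-1 relations exactly", {
  set.seed(80)
  n <- 30; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  m <- fit_pls(X, y, n_comp = p)
  ols <- stats::lm.fit(cbind(1, X), y)
  expect_equal(unname(predict(m, X)), unname(ols$fitted.values),
               tolerance = 1e-8)

  # y exactly linear in rank-1 X: one component suffices
  t1 <- rnorm(n)
  X1 <- tcrossprod(t1, rnorm(p))
  y1 <- 2 * t1 + 1
  m1 <- fit_pls(X1, y1, n_comp = 1)
  expect_lt(max(abs(predict(m1, X1) - y1)), 1e-8)

  # permuting samples leaves the model unchanged
  perm <- sample(n)
  m2 <- fit_pls(X[perm, ], y[perm], n_comp = 3)
  m3 <- fit_pls(X, y, n_comp = 3)
  expect_equal(m2$coef, m3$coef, tolerance = 1e-10)

  expect_error(fit_pls(X, rep(1, n), 2), "zero-variance")
})

test_that("PLS1 agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(81)
  n <- 40; p <- 20
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:20)))
  y <- drop(X[, 1:3] %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.2)
  m <- fit_pls(X, y, n_comp = 4)
  mo <- mixOmics::pls(X, y, ncomp = 4, scale = FALSE, mode = "regression")
  po <- predict(mo, X)$predict[, 1, 4]
  expect_equal(unname(predict(m, X)), unname(po), tolerance = 1e-6)
})

test_that("training RMSE is non-increasing in the number of components", {
  cal <- make_cal_data(n = 60, noise_sd = 0.01, n_comp = 4)
  rmse <- sapply(1:8, function(a) {
    m <- fit_pls(cal$X, cal$y, a)
    sqrt(mean((predict(m, cal$X) - cal$y)^2))
  })
  expect_true(all(diff(rmse) < 1e-10))
})

test_that("cross-validation picks one component for a noiseless rank-1 relation", {
  set.seed(90)
  n <- 50
  t1 <- rnorm(n)
  X <- tcrossprod(t1, rnorm(30))
  y <- 3 * t1 + 2
  expect_equal(as.integer(select_ncomp_cv(X, y, max_comp = 5, seed = 1)), 1L)
  expect_identical(select_ncomp_cv(X, y, max_comp = 5, seed = 7),
                   select_ncomp_cv(X, y, max_comp = 5, seed = 7))

  # pure noise: CV error no better than the trivial mean predictor
  yn <- rnorm(n)
  nc <- select_ncomp_cv(matrix(rnorm(n * 30), n), yn, max_comp = 5, seed = 2)
  cv <- attr(nc, "cv")
  expect_gt(min(cv$rmse), 0.7 * stats::sd(yn))
})

test_that("validation metrics and the acceptance gate follow their definitions", {
  cal <- make_cal_data(n = 100, noise_sd = 0)
  sel <- kennard_stone(cal$X, 80)
  sp <- split_calibration(sel, 60, 20, seed = 5)
  m <- fit_pls(cal$X[sp$estimation, ], cal$y[sp$estimation], 3)
  rep <- validate(m, cal$X[sp$validation, ], cal$y[sp$validation])
  expect_gte(rep$r2p, 0.999)  # noiseless spectra calibrate essentially exactly
  expect_true(rep$accepted)
  expect_gte(rep$rmsep^2, rep$bias^2 - 1e-12)

  # constant shift: bias = c and RMSEP = |c|
  m_shift <- m
  m_shift$intercept <- m$intercept + 1.5
  rep_s <- validate(m_shift, cal$X[sp$validation, ], cal$y[sp$validation])
  expect_equal(rep_s$bias, rep$bias + 1.5, tolerance = 1e-8)
  expect_equal(rep_s$rmsep, sqrt(mean((1.5 + (predict(m, cal$X[sp$validation, ]) -
    cal$y[sp$validation]))^2)), tolerance = 1e-10)

  # gate thresholds mirror the published judgment calls: a calibration at
  # R2p = 0.60 passes, one at 0.36 does not
  set.seed(6)
  yv <- rnorm(50, 20, 2)
  sstot <- sum((yv - mean(yv))^2)
  passthrough <- structure(list(coef = 1, intercept = 0, n_comp = 1,
                                preprocessing = "none", wavelengths = NULL),
                           class = "pls_model")
  mk_xval <- function(target_r2) {
    u <- rnorm(50); u <- u - mean(u)
    matrix(yv + u * sqrt((1 - target_r2) * sstot / sum(u^2)), ncol = 1)
  }
  # a hair above the threshold so floating-point rounding of R2p cannot
  # flip the comparison at exact equality
  rep60 <- validate(passthrough, mk_xval(0.60 + 1e-9), yv)
  expect_equal(rep60$r2p, 0.60, tolerance = 1e-6)
  expect_true(rep60$accepted)
  rep36 <- validate(passthrough, mk_xval(0.36), yv)
  expect_equal(rep36$r2p, 0.36, tolerance = 1e-10)
  expect_false(rep36$accepted)
})

test_that("prediction of unmeasured samples is gated on acceptance", {
  cal <- make_cal_data(n = 100, noise_sd = 0)
  m <- fit_pls(cal$X[1:60, ], cal$y[1:60], 3)
  good <- validate(m, cal$X[61:80, ], cal$y[61:80])
  pred <- predict_unmeasured(m, good, cal$X[81:100, ])
  expect_length(pred, 20)
  expect_named(pred, rownames(cal$X)[81:100])
  # predicting the estimation set reproduces the training fit
  expect_equal(unname(predict_unmeasured(m, good, cal$X[1:60, ])),
               unname(predict(m, cal$X[1:60, ])))

  bad <- good
  bad$accepted <- FALSE
  expect_error(predict_unmeasured(m, bad, cal$X[81:100, ]), "rejected")
  expect_length(predict_unmeasured(m, bad, cal$X[81:100, ], force = TRUE), 20)

  expect_error(predict(m, cal$X[, 1:300]), "grid mismatch")
})

test_that("the end-to-end calibration reproduces the 350/650 partition and degrades with noise", {
  set.seed(95)
  n <- 1000
  tr <- data.frame(id = paste0("t", 1:n), y = rnorm(n, 28, 1.5))
  sp0 <- simulate_spectra(tr, spectra_model(n_components = 3, noise_sd = 0),
                          seed = 7)
  vals <- stats::setNames(tr$y, tr$id)
  vals[351:1000] <- NA  # only 350 "wet-lab measured" samples
  cal <- calibrate_trait(sp0$spectra, vals, n_select = 350, n_est = 250,
                         n_val = 100, menu = c("none", "snv"),
                         max_comp = 6, seed = 3)
  expect_length(cal$selected, 350)
  expect_length(cal$split$estimation, 250)
  expect_length(cal$split$validation, 100)
  expect_gte(cal$report$r2p, 0.999)
  rest <- setdiff(rownames(sp0$spectra), cal$selected)
  expect_length(rest, 650)

  spn <- simulate_spectra(tr, spectra_model(n_components = 3, noise_sd = 0.5),
                          seed = 7)
  caln <- calibrate_trait(spn$spectra, vals, n_select = 350, n_est = 250,
                          n_val = 100, menu = c("none", "snv"),
                          max_comp = 6, seed = 3)
  expect_lt(caln$report$r2p, cal$report$r2p)
})
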