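#' Preprocess NIR spectra
#'
#' Menu of standard transformations: `snv` standardizes each spectrum to
#' zero mean and unit variance; `d1`/`d2` are Savitzky-Golay smoothing
#' derivatives (default window 15 points, polynomial order 2); `msc`
#' regresses each spectrum on the mean spectrum and keeps the residual-plus-
#' mean correction.
#'
#' @param spectra samples x wavelengths matrix.
#' @param method one of `"none"`, `"snv"`, `"d1"`, `"d2"`, `"msc"`.
#' @param window Savitzky-Golay window length (odd; must not exceed the
#'   grid length).
#' @param polyorder Savitzky-Golay polynomial order.
#' @param ref reference spectrum for `msc` (defaults to the mean spectrum of
#'   `spectra`; pass the training reference when transforming new samples).
#' @return transformed matrix with a `preprocessing` attribute (and
#'   `msc_ref` for `msc`).
#' @export
preprocess <- function(spectra, method = c("none", "snv", "d1", "d2", "msc"),
                       window = 15, polyorder = 2, ref = NULL) {
  method <- match.arg(method)
  X <- as.matrix(spectra)
  if (method %in% c("d1", "d2")) {
    if (window > ncol(X)) stop("derivative window exceeds grid length")
    m <- if (method == "d1") 1 else 2
    X <- t(apply(X, 1, function(row)
      signal::sgolayfilt(row, p = polyorder, n = window, m = m)))
    dimnames(X) <- dimnames(spectra)
  } else if (method == "snv") {
    mu <- rowMeans(X)
    s <- apply(X, 1, stats::sd)
    s[s == 0] <- 1
    X <- (X - mu) / s
  } else if (method == "msc") {
    if (is.null(ref)) ref <- colMeans(X)
    X <- t(apply(X, 1, function(row) {
      fit <- stats::lm.fit(cbind(1, ref), row)
      (row - fit$coefficients[1]) / fit$coefficients[2]
    }))
    dimnames(X) <- dimnames(spectra)
    attr(X, "msc_ref") <- ref
  }
  if (any(!is.finite(X))) stop("non-finite values after preprocessing")
  attr(X, "preprocessing") <- method
  X
}

#' Kennard-Stone calibration-subset selection
#'
#' Deterministic max-min selection on Euclidean distances: start from the
#' two most distant samples, then repeatedly add the sample whose minimum
#' distance to the already-selected set is largest. Ties are broken by the
#' lowest row index (first id in the input order).
#'
#' @param spectra samples x variables matrix (rownames used as ids).
#' @param k number of samples to select (2 <= k <= n).
#' @return character vector of selected ids (row indices as character when
#'   unnamed), in selection order.
#' @export
kennard_stone <- function(spectra, k) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  stopifnot(k >= 2, k <= n)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(X), 0)
  # initial pair: maximal distance, lowest indices on ties
  best <- which(D2 == max(D2), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  if (!nrow(best)) best <- matrix(c(1L, 2L), 1)  # all-identical degenerate case
  best <- best[order(best[, 1], best[, 2])[1], ]
  sel <- c(best[[1]], best[[2]])
  mind <- pmin(D2[, sel[1]], D2[, sel[2]])
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)  # which.max returns the first (lowest) index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D2[, nxt])
  }
  ids[sel]
}

#' Split a selected calibration set into estimation and validation sets
#'
#' @param ids candidate sample ids (e.g. from [kennard_stone()]).
#' @param n_est,n_val estimation and validation sizes
#'   (`n_est + n_val <= length(ids)`).
#' @param seed integer seed.
#' @return list `estimation`, `validation` (disjoint id vectors).
#' @export
split_calibration <- function(ids, n_est, n_val, seed = 1L) {
  if (n_est + n_val > length(ids))
    stop("insufficient samples: need ", n_est + n_val, ", have ", length(ids))
  set.seed(seed)
  perm <- sample(ids, n_est + n_val)
  list(estimation = perm[seq_len(n_est)],
       validation = perm[n_est + seq_len(n_val)])
}

#' Fit a single-response PLS regression (PLS1)
#'
#' Orthogonal-scores PLS1 on centered `X` and `y`: at each step the weight
#' vector is the (normalized) covariance of the residual matrix with the
#' response, scores/loadings are extracted and the matrix deflated. With
#' `n_comp = rank(X)` the predictions coincide with ordinary least squares.
#'
#' @param X training spectra (preprocessed), samples x variables.
#' @param y trait values.
#' @param n_comp number of latent components
#'   (1 <= n_comp <= min(n - 1, variables)).
#' @param preprocessing tag recording how X was transformed (stored for
#'   prediction-time replay by the caller).
#' @return object of class `pls_model` with `coef`, `intercept`, `weights`,
#'   `loadings`, `scores_var`, `x_center`, `y_center`.
#' @export
fit_pls <- function(X, y, n_comp, preprocessing = "none") {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n_comp >= 1, n_comp <= min(n - 1, ncol(X)))
  if (stats::sd(y) == 0) stop("zero-variance response")
  xc <- colMeans(X); yc <- mean(y)
  E <- sweep(X, 2, xc); f <- y - yc
  W <- P <- matrix(0, ncol(X), n_comp)
  q <- numeric(n_comp)
  tvar <- numeric(n_comp)
  for (a in seq_len(n_comp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) { n_comp <- a - 1L; break }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - q[a] * t
    W[, a] <- w; P[, a] <- p; tvar[a] <- tt
  }
  if (n_comp < 1) stop("response is orthogonal to the spectra")
  W <- W[, seq_len(n_comp), drop = FALSE]
  P <- P[, seq_len(n_comp), drop = FALSE]
  q <- q[seq_len(n_comp)]
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(coef = drop(beta), intercept = yc - sum(xc * beta),
                 n_comp = n_comp, weights = W, loadings = P, q = q,
                 scores_var = tvar[seq_len(n_comp)], x_center = xc,
                 y_center = yc, preprocessing = preprocessing,
                 wavelengths = colnames(X)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$wavelengths)) {
    if (ncol(X) != length(object$wavelengths) ||
        (!is.null(colnames(X)) && !identical(colnames(X), object$wavelengths)))
      stop("wavelength grid mismatch between model and new spectra")
  }
  drop(X %*% object$coef) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model:", x$n_comp, "components,", length(x$coef),
      "wavelengths, preprocessing =", x$preprocessing, "\n")
  invisible(x)
}

#' Choose the number of PLS components by cross-validation
#'
#' K-fold cross-validated RMSE per component count; the chosen count is the
#' smallest whose CV RMSE is within one standard error of the minimum
#' (one-SE rule toward parsimony).
#'
#' @param X,y training data.
#' @param max_comp largest component count to try.
#' @param folds number of folds (>= 2, default 10).
#' @param seed integer seed for the fold assignment.
#' @return chosen component count; the CV curve is in `attr(, "cv")`.
#' @export
select_ncomp_cv <- function(X, y, max_comp = 15, folds = 10, seed = 1L) {
  stopifnot(folds >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  max_comp <- min(max_comp, floor(n * (folds - 1) / folds) - 1, ncol(X))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  err <- matrix(NA_real_, folds, max_comp)  # per-fold MSE
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- fit_pls(X[tr, , drop = FALSE], y[tr], n_comp = max_comp)
    for (a in seq_len(m$n_comp)) {
      beta <- m$weights[, 1:a, drop = FALSE] %*%
        solve(crossprod(m$loadings[, 1:a, drop = FALSE],
                        m$weights[, 1:a, drop = FALSE]), m$q[1:a])
      pred <- drop(X[!tr, , drop = FALSE] %*% beta) +
        (m$y_center - sum(m$x_center * beta))
      err[f, a] <- mean((pred - y[!tr])^2)
    }
  }
  rmse <- sqrt(colMeans(err, na.rm = TRUE))
  se <- apply(sqrt(err), 2, stats::sd, na.rm = TRUE) / sqrt(folds)
  best <- which.min(rmse)
  pick <- which(rmse <= rmse[best] + se[best])[1]
  structure(as.integer(pick), cv = data.frame(n_comp = seq_along(rmse),
                                              rmse = rmse, se = se))
}

#' Externally validate a PLS calibration
#'
#' `RMSEP = sqrt(mean((pred - obs)^2))`, `bias = mean(pred - obs)`,
#' `R2p = 1 - SS_res / SS_tot` on the validation set. The model is accepted
#' when `R2p >= accept_threshold` (default 0.60).
#'
#' @param model a [fit_pls()] model.
#' @param X_val,y_val validation spectra (same preprocessing as training)
#'   and trait values.
#' @param accept_threshold minimum R2p for acceptance.
#' @return object of class `calibration_report`: `rmsep`, `bias`, `r2p`,
#'   `accepted`, `n_val`, `threshold`.
#' @export
validate <- function(model, X_val, y_val, accept_threshold = 0.60) {
  if (!length(y_val)) stop("empty validation set")
  pred <- stats::predict(model, X_val)
  resid <- pred - y_val
  rmsep <- sqrt(mean(resid^2))
  r2p <- 1 - sum(resid^2) / sum((y_val - mean(y_val))^2)
  structure(list(rmsep = rmsep, bias = mean(resid), r2p = r2p,
                 accepted = r2p >= accept_threshold, n_val = length(y_val),
                 threshold = accept_threshold),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("RMSEP %.4g  bias %.4g  R2p %.3f  -> %s (threshold %.2f)\n",
              x$rmsep, x$bias, x$r2p,
              if (x$accepted) "accepted" else "rejected", x$threshold))
  invisible(x)
}

#' Predict trait values for unmeasured samples from an accepted calibration
#'
#' Refuses to predict from a rejected calibration unless `force = TRUE`.
#'
#' @param model a [fit_pls()] model.
#' @param report the model's [validate()] report.
#' @param spectra new samples' spectra, already carrying the model's
#'   preprocessing.
#' @param force override the acceptance gate.
#' @return named vector of predictions.
#' @export
predict_unmeasured <- function(model, report, spectra, force = FALSE) {
  stopifnot(inherits(report, "calibration_report"))
  if (!report$accepted && !force)
    stop("calibration rejected (R2p = ", signif(report$r2p, 3),
         " < ", report$threshold, "); use force = TRUE to override")
  pred <- stats::predict(model, spectra)
  names(pred) <- rownames(spectra)
  pred
}

#' Calibrate one trait end-to-end over a preprocessing menu
#'
#' Kennard-Stone selects the calibration candidates among samples with
#' measured trait values, a seeded random split forms estimation/validation
#' sets, and for each preprocessing in the menu the component count is
#' chosen by cross-validation and the model validated externally. The
#' preprocessing with the highest validation R2p wins.
#'
#' @param spectra full samples x wavelengths matrix.
#' @param values named trait values (names = sample ids) for the measured
#'   subset.
#' @param n_select Kennard-Stone subset size (e.g. 350 or 200).
#' @param n_est,n_val estimation/validation sizes (e.g. 250/100 or 150/50).
#' @param menu preprocessing methods to try.
#' @param max_comp,folds cross-validation settings.
#' @param accept_threshold see [validate()].
#' @param seed integer seed.
#' @return list `model`, `report`, `method`, `split`, `selected`, `all`
#'   (per-method reports).
#' @export
calibrate_trait <- function(spectra, values, n_select, n_est, n_val,
                            menu = c("none", "snv", "d1", "d2", "msc"),
                            max_comp = 15, folds = 10,
                            accept_threshold = 0.60, seed = 1L) {
  measured <- intersect(rownames(spectra), names(values)[!is.na(values)])
  if (n_select > length(measured))
    stop("n_select exceeds measured samples")
  sel <- kennard_stone(spectra[measured, , drop = FALSE], n_select)
  split <- split_calibration(sel, n_est, n_val, seed = seed)
  best <- NULL
  all <- list()
  for (m in menu) {
    Xe <- preprocess(spectra[split$estimation, , drop = FALSE], m)
    Xv <- preprocess(spectra[split$validation, , drop = FALSE], m,
                     ref = attr(Xe, "msc_ref"))
    nc <- select_ncomp_cv(Xe, values[split$estimation], max_comp = max_comp,
                          folds = folds, seed = seed)
    mod <- fit_pls(Xe, values[split$estimation], n_comp = nc,
                   preprocessing = m)
    rep <- validate(mod, Xv, values[split$validation],
                    accept_threshold = accept_threshold)
    all[[m]] <- rep
    if (is.null(best) || rep$r2p > best$report$r2p)
      best <- list(model = mod, report = rep, method = m)
  }
  c(best, list(split = split, selected = sel, all = all))
}
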