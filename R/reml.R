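#' Specify an individual-tree mixed model
#'
#' Assembles the design for `y = X b + Z_p p + Z_a a + Z_d d + e` with
#' blocks as fixed effects, iid plot effects, and additive (and optionally
#' dominance) individual effects with user-supplied covariance kernels
#' (pedigree A/D or genomic G_A/G_D). Rows with a missing phenotype are
#' dropped and kernels are subset to the phenotyped individuals.
#'
#' @param data data.frame with columns `id`, the trait, and the design
#'   columns named by `block`/`plot`.
#' @param trait name of the response column.
#' @param K_a additive kernel (dimnames must cover the ids).
#' @param K_d optional dominance kernel.
#' @param block,plot design column names; set `plot = NULL` to drop the plot
#'   effect, `block = NULL` for an intercept-only fixed part.
#' @return object of class `mm_spec`: `y`, `X`, a named list `V` of n x n
#'   covariance "design" matrices (one per variance component, residual
#'   excluded), kernels and ids.
#' @export
mixed_model_spec <- function(data, trait, K_a, K_d = NULL,
                             block = "block", plot = "plot") {
  stopifnot(trait %in% names(data), "id" %in% names(data))
  keep <- !is.na(data[[trait]])
  d <- data[keep, , drop = FALSE]
  if (!all(d$id %in% rownames(K_a)))
    stop("kernel/phenotype id mismatch: phenotyped ids missing from K_a")
  y <- d[[trait]]
  X <- if (is.null(block)) matrix(1, nrow(d), 1) else
    stats::model.matrix(~ factor(d[[block]]))
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  Ka <- K_a[d$id, d$id]
  V <- list()
  Z <- list()
  if (!is.null(plot)) {
    fp <- factor(d[[plot]])
    Zp <- stats::model.matrix(~ 0 + fp)
    colnames(Zp) <- levels(fp)
    V$plot <- tcrossprod(Zp)
    Z$plot <- Zp
  }
  V$additive <- Ka
  spec <- list(y = y, X = X, V = V, ids = d$id,
               K = list(additive = Ka))
  if (!is.null(K_d)) {
    if (!all(d$id %in% rownames(K_d)))
      stop("kernel/phenotype id mismatch: phenotyped ids missing from K_d")
    Kd <- K_d[d$id, d$id]
    spec$V$dominance <- Kd
    spec$K$dominance <- Kd
  }
  spec$Z <- Z
  structure(spec, class = "mm_spec")
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates `-0.5 (log|V| + log|X' V^-1 X| + y' P y)` (up to the usual
#' constant) at `theta`, with `V = sum_k theta_k V_k + theta_residual I` and
#' `P` the REML projection matrix. A small diagonal jitter (1e-8 of the mean
#' diagonal) is added at solve time if the Cholesky fails.
#'
#' @param theta named numeric: one entry per component in `spec$V` plus
#'   `residual`.
#' @param spec an [mixed_model_spec()].
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(theta, spec) {
  stopifnot(inherits(spec, "mm_spec"))
  pieces <- reml_pieces(theta, spec)
  pieces$loglik
}

# shared REML computations: loglik, P matrix, Py
reml_pieces <- function(theta, spec, need_P = FALSE) {
  nm <- names(spec$V)
  if (!all(c(nm, "residual") %in% names(theta)))
    stop("theta must name components: ",
         paste(c(nm, "residual"), collapse = ", "))
  n <- length(spec$y)
  Vm <- diag(theta[["residual"]], n)
  for (k in nm) Vm <- Vm + theta[[k]] * spec$V[[k]]
  ch <- tryCatch(chol(Vm), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(Vm))
    ch <- tryCatch(chol(Vm + diag(jit, n)), error = function(e)
      stop("V is singular at theta"))
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% spec$X
  XtViX <- crossprod(spec$X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) stop("X'V^-1X singular"))
  logdetX <- 2 * sum(log(diag(cX)))
  XtViX_inv <- chol2inv(cX)
  Viy <- Vi %*% spec$y
  XtViy <- crossprod(spec$X, Viy)
  Py <- Viy - ViX %*% (XtViX_inv %*% XtViy)
  yPy <- sum(spec$y * Py)
  out <- list(loglik = -0.5 * (logdetV + logdetX + yPy), Py = drop(Py),
              Vi = Vi, XtViX_inv = XtViX_inv, ViX = ViX)
  if (need_P) out$P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
  out
}

#' Fit the univariate additive-dominance model by AI-REML
#'
#' Average-information REML with expectation-maximization fallback steps:
#' an AI update that leaves the parameter space or decreases the restricted
#' likelihood is first step-halved, then replaced by an EM update (which is
#' monotone). Variances are clamped at `1e-10 * var(y)`; convergence when
#' the likelihood change is below `tol_loglik` and the largest relative
#' parameter change below `tol_par`.
#'
#' @param spec an [mixed_model_spec()].
#' @param init optional named starting values.
#' @param max_iter maximum iterations (default 200).
#' @param tol_loglik,tol_par convergence tolerances (1e-8, 1e-6).
#' @param verbose print the iteration trajectory.
#' @return object of class `reml_fit`: `components` (named estimates,
#'   residual included), `se`, `loglik`, `AI` (average-information matrix),
#'   `blup` (list of effect vectors), `boundary` flags, `trajectory`,
#'   `converged`, plus the spec ids.
#' @export
fit_univariate_ad <- function(spec, init = NULL, max_iter = 200,
                              tol_loglik = 1e-8, tol_par = 1e-6,
                              verbose = FALSE) {
  stopifnot(inherits(spec, "mm_spec"))
  nm <- c(names(spec$V), "residual")
  vy <- stats::var(spec$y)
  lb <- 1e-10 * vy
  theta <- if (is.null(init)) {
    stats::setNames(rep(vy / length(nm), length(nm)), nm)
  } else {
    if (!all(nm %in% names(init))) stop("init must name all components")
    pmax(init[nm], lb)
  }
  n <- length(spec$y)
  # EM denominators: number of effect levels per component
  ranks <- c(vapply(names(spec$V), function(k)
    if (k %in% names(spec$Z)) ncol(spec$Z[[k]]) else nrow(spec$V[[k]]),
    1L), residual = n)
  Vfull <- c(spec$V, list(residual = NULL))           # NULL = identity

  pc <- reml_pieces(theta, spec, need_P = TRUE)
  traj <- data.frame(iter = 0, loglik = pc$loglik, step = "init",
                     t(theta))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- pc$P; Py <- pc$Py
    q <- matrix(0, n, length(nm))  # V_k P y
    trPV <- numeric(length(nm))
    for (k in seq_along(nm)) {
      Vk <- Vfull[[k]]
      if (is.null(Vk)) {
        q[, k] <- Py
        trPV[k] <- sum(diag(P))
      } else {
        q[, k] <- Vk %*% Py
        trPV[k] <- sum(P * Vk)  # tr(P V_k), V_k symmetric
      }
    }
    yPVPy <- crossprod(q, Py)                 # y' P V_k P y
    score <- -0.5 * (trPV - drop(yPVPy))
    Pq <- P %*% q
    AI <- 0.5 * crossprod(q, Pq)
    dimnames(AI) <- list(nm, nm)

    free <- !(theta <= lb * 1.0001 & score < 0)  # params pinned at boundary
    step_used <- "AI"
    new_pc <- NULL
    if (it > 1) {  # first iteration: EM warm-up (AI is ill-conditioned far out)
      # Levenberg-style ridge: the AI matrix is near-singular when kernels
      # are collinear; inflate the diagonal until the step is productive
      for (ridge in c(0, 0.01, 0.1, 1, 10)) {
        Af <- AI[free, free, drop = FALSE]
        Af <- Af + diag(ridge * pmax(diag(Af), 1e-12), nrow(Af))
        d_free <- tryCatch(solve(Af, score[free]), error = function(e) NULL)
        if (is.null(d_free)) next
        delta <- rep(0, length(nm))
        delta[free] <- d_free
        fac <- 1
        for (h in 1:4) {
          cand <- pmax(theta + fac * delta, lb)
          cp <- tryCatch(reml_pieces(cand, spec, need_P = TRUE),
                         error = function(e) NULL)
          if (!is.null(cp) && cp$loglik >= pc$loglik - 1e-10) {
            new_pc <- cp; new_theta <- cand
            if (ridge > 0 || h > 1) step_used <- "AI-damped"
            break
          }
          fac <- fac / 2
        }
        if (!is.null(new_pc)) break
      }
    }
    if (is.null(new_pc)) {
      # monotone EM fallback
      em <- theta + theta^2 * (drop(yPVPy) - trPV) / ranks
      new_theta <- pmax(em, lb)
      new_pc <- reml_pieces(new_theta, spec, need_P = TRUE)
      step_used <- "EM"
    }
    dll <- new_pc$loglik - pc$loglik
    rel <- max(abs(new_theta - theta) / pmax(theta, lb))
    theta <- new_theta; pc <- new_pc
    traj <- rbind(traj, data.frame(iter = it, loglik = pc$loglik,
                                   step = step_used, t(theta)))
    if (verbose)
      message(sprintf("it %d [%s] loglik %.8f  %s", it, step_used, pc$loglik,
                      paste(sprintf("%s=%.6g", nm, theta), collapse = " ")))
    if (abs(dll) < tol_loglik && rel < tol_par) { converged <- TRUE; break }
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "AI-REML did not converge in %d iterations (last |dloglik| %.3g)",
      max_iter, abs(dll)))
    err$trajectory <- traj
    stop(err)
  }

  # final AI and SEs at the optimum
  P <- pc$P; Py <- pc$Py
  q <- matrix(0, n, length(nm))
  for (k in seq_along(nm))
    q[, k] <- if (is.null(Vfull[[k]])) Py else Vfull[[k]] %*% Py
  AI <- 0.5 * crossprod(q, P %*% q)
  dimnames(AI) <- list(nm, nm)
  C <- tryCatch(solve(AI), error = function(e) NULL)
  se <- if (is.null(C)) stats::setNames(rep(NA_real_, length(nm)), nm) else
    stats::setNames(sqrt(pmax(diag(C), 0)), nm)
  boundary <- theta <= lb * 1.0001

  blup <- list()
  for (k in names(spec$V)) {
    if (k %in% names(spec$K)) {
      u <- theta[[k]] * spec$K[[k]] %*% Py
      blup[[k]] <- stats::setNames(drop(u), spec$ids)
    } else {
      u <- theta[[k]] * crossprod(spec$Z[[k]], Py)
      blup[[k]] <- stats::setNames(drop(u), colnames(spec$Z[[k]]))
    }
  }
  comp <- theta
  comp[boundary] <- 0
  structure(list(components = comp, se = se, loglik = pc$loglik, AI = AI,
                 AI_inv = C, blup = blup, boundary = boundary,
                 trajectory = traj, converged = converged, ids = spec$ids,
                 n = n, spec_names = nm),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit (n =", x$n, "), restricted log-likelihood",
      format(x$loglik, digits = 10), "\n")
  tab <- data.frame(component = names(x$components),
                    estimate = unname(x$components),
                    se = unname(x$se),
                    boundary = unname(x$boundary))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract BLUP effect tables from a fit
#'
#' @param fit a converged [fit_univariate_ad()] result.
#' @return data.frame `id`, `ebv` (additive BLUP) and, when a dominance
#'   kernel was fitted, `dominance`.
#' @export
blup_effects <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  out <- data.frame(id = fit$ids, ebv = unname(fit$blup$additive),
                    stringsAsFactors = FALSE)
  if (!is.null(fit$blup$dominance))
    out$dominance <- unname(fit$blup$dominance)
  out
}

#' Delta-method standard error of a function of variance components
#'
#' `SE = sqrt(g' C g)` with `C` the inverse average-information matrix and
#' `g` the central-difference gradient of `transform` at the estimates.
#'
#' @param fit a `reml_fit`.
#' @param transform function taking the named component vector to a scalar.
#' @return standard error, or NA when the AI matrix is singular.
#' @export
param_se <- function(fit, transform) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$AI_inv)) return(NA_real_)
  th <- fit$components
  g <- num_grad(transform, th)
  drop(sqrt(max(0, t(g) %*% fit$AI_inv %*% g)))
}

num_grad <- function(f, x, rel_h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- rel_h * max(abs(x[i]), 1e-4)
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- max(x[i] - h, 0)
    g[i] <- (f(xp) - f(xm)) / (xp[i] - xm[i])
  }
  g
}
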