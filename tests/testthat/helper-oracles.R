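# Independent oracles and shared fixtures. Everything here is written as
# directly as possible (scalar loops, closed forms) so it shares no code
# path with the package implementation it checks.

# --- dense REML restricted log-likelihood, straight from the formula -----
oracle_reml_loglik <- function(theta, y, X, Vlist) {
  n <- length(y)
  V <- diag(theta[["residual"]], n)
  for (k in names(Vlist)) V <- V + theta[[k]] * Vlist[[k]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y)))
}

# --- generic bounded optimizer applied to the package's reml_loglik ------
oracle_reml_fit <- function(spec, n_starts = 3) {
  nm <- c(names(spec$V), "residual")
  vy <- stats::var(spec$y)
  lb <- rep(1e-10 * vy, length(nm))
  obj <- function(th) {
    names(th) <- nm
    -reml_loglik(th, spec)
  }
  best <- NULL
  starts <- list(rep(vy / length(nm), length(nm)),
                 rep(vy / (2 * length(nm)), length(nm)),
                 vy * seq_along(nm) / sum(seq_along(nm)))
  for (s in starts[seq_len(n_starts)]) {
    o <- stats::optim(s, obj, method = "L-BFGS-B", lower = lb,
                      control = list(maxit = 2000, factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  stats::setNames(best$par, nm)
}

# --- gene dropping: Monte-Carlo additive relationship ---------------------
oracle_gene_drop_A <- function(ped, n_drops = 50000) {
  ids <- ped$id
  n <- length(ids)
  s <- match(ped$sire, ids)
  d <- match(ped$dam, ids)
  # topological order assumed (founders first), true for our fixtures
  al1 <- matrix(0L, n_drops, n)  # allele labels, one bi-allelic draw per drop
  al2 <- matrix(0L, n_drops, n)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (is.na(s[i])) {
      al1[, i] <- cnt + 1L
      al2[, i] <- cnt + 2L
      cnt <- cnt + 2L
    } else {
      pick1 <- stats::runif(n_drops) < 0.5
      al1[, i] <- ifelse(pick1, al1[, s[i]], al2[, s[i]])
      pick2 <- stats::runif(n_drops) < 0.5
      al2[, i] <- ifelse(pick2, al1[, d[i]], al2[, d[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    ibd <- (al1[, i] == al1[, j]) + (al1[, i] == al2[, j]) +
           (al2[, i] == al1[, j]) + (al2[, i] == al2[, j])
    A[i, j] <- A[j, i] <- mean(ibd) / 2
  }
  A
}

# --- brute-force Kennard-Stone (scalar loops) -----------------------------
oracle_kennard_stone <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  best <- c(1, 2); bestd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bestd) { bestd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids[sel]
}

# --- dense Henderson mixed-model equations --------------------------------
# model: y = X b + sum_k u_k (one record per individual, Z_k = I),
# Var(u_k) = theta_k K_k, Var(e) = theta_residual I
oracle_henderson <- function(y, X, Klist, theta) {
  n <- length(y)
  nm <- names(Klist)
  se2 <- theta[["residual"]]
  W <- do.call(cbind, c(list(X), rep(list(diag(n)), length(nm))))
  C <- crossprod(W) / se2
  off <- ncol(X)
  for (k in nm) {
    idx <- off + seq_len(n)
    C[idx, idx] <- C[idx, idx] + solve(Klist[[k]]) / theta[[k]]
    off <- off + n
  }
  sol <- solve(C, crossprod(W, y) / se2)
  out <- list(beta = sol[1:ncol(X)])
  off <- ncol(X)
  for (k in nm) {
    out[[k]] <- sol[off + seq_len(n)]
    off <- off + n
  }
  out
}

# --- fixtures -------------------------------------------------------------

# two-generation pedigree: unrelated founders, full-sib families
make_two_gen_pedigree <- function(n_sires = 3, n_dams_per = 2, n_off = 3) {
  sires <- paste0("S", seq_len(n_sires))
  dams <- paste0("D", seq_len(n_sires * n_dams_per))
  rows <- list(data.frame(id = c(sires, dams), sire = NA, dam = NA,
                          stringsAsFactors = FALSE))
  cnt <- 0
  for (i in seq_len(n_sires)) for (j in seq_len(n_dams_per)) {
    dm <- dams[(i - 1) * n_dams_per + j]
    for (o in seq_len(n_off)) {
      cnt <- cnt + 1
      rows[[length(rows) + 1]] <- data.frame(
        id = paste0("O", cnt), sire = sires[i], dam = dm,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# small random variance-component instance for REML oracle checks
make_random_instance <- function(n, with_dominance = TRUE, seed = 1) {
  set.seed(seed)
  ped <- make_two_gen_pedigree(3, 2, ceiling(n / 6))
  ped <- ped[c(which(is.na(ped$sire)), which(!is.na(ped$sire))[1:n]), ]
  off <- ped$id[!is.na(ped$sire)]
  A <- build_A(ped)[off, off]
  D <- build_D_from_pedigree(ped)[off, off]
  blocks <- rep_len(1:2, n)
  plots <- paste0(blocks, "_", rep_len(1:4, n))
  theta <- c(plot = 0.3, additive = 0.8,
             if (with_dominance) c(dominance = 0.5), residual = 1)
  Sig <- 0.3 * outer(plots, plots, "==") + 0.8 * A + diag(n)
  if (with_dominance) Sig <- Sig + 0.5 * D
  y <- drop(t(chol(Sig)) %*% rnorm(n)) + blocks * 2
  data <- data.frame(id = off, y = y, block = blocks, plot = plots,
                     stringsAsFactors = FALSE)
  list(data = data, A = A, D = if (with_dominance) D else NULL,
       theta = theta)
}

# memoized mid-size diallel population shared across test files
shared_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_diallel_population(n_loci = 4000, seed = 42)
    cache
  }
})
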