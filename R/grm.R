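#' In-sample allele frequencies of a 0/1/2 genotype matrix
#' @param g genotype matrix (NA allowed).
#' @return per-locus alternative-allele frequency.
#' @export
allele_freq <- function(g) colMeans(g, na.rm = TRUE) / 2

#' Filter co-dominant SNPs on call rate and minor allele frequency
#'
#' @param g individuals x loci 0/1/2 matrix.
#' @param callrate_min minimum fraction of non-missing calls (default 0.90).
#' @param maf_min minimum minor allele frequency (default 0.01; computed on
#'   non-missing calls).
#' @return filtered matrix; `attr(, "filter_report")` counts loci failing
#'   each criterion.
#' @export
filter_codominant <- function(g, callrate_min = 0.90, maf_min = 0.01) {
  stopifnot(callrate_min >= 0, callrate_min <= 1, maf_min >= 0, maf_min <= 1)
  callrate <- 1 - colMeans(is.na(g))
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  keep <- callrate >= callrate_min & maf >= maf_min & !is.na(maf)
  if (!any(keep)) stop("all loci removed by filtering")
  out <- g[, keep, drop = FALSE]
  attr(out, "filter_report") <- c(
    fail_callrate = sum(callrate < callrate_min),
    fail_maf = sum(maf < maf_min | is.na(maf)),
    removed = sum(!keep), kept = sum(keep))
  out
}

#' Filter dominant presence/absence markers
#'
#' The allele frequency behind a dominant marker is estimated from its
#' presence frequency `f` under HWE as `p = 1 - sqrt(1 - f)`; the MAF filter
#' applies to `min(p, 1 - p)`.
#'
#' @param d individuals x markers 0/1 matrix.
#' @param callrate_min minimum call rate (default 0.80).
#' @param maf_min minimum estimated MAF (default 0.02).
#' @return filtered matrix with a `filter_report` attribute.
#' @export
filter_dominant <- function(d, callrate_min = 0.80, maf_min = 0.02) {
  stopifnot(callrate_min >= 0, callrate_min <= 1, maf_min >= 0, maf_min <= 1)
  callrate <- 1 - colMeans(is.na(d))
  f <- colMeans(d, na.rm = TRUE)
  p <- 1 - sqrt(pmax(0, 1 - f))
  maf <- pmin(p, 1 - p)
  keep <- callrate >= callrate_min & maf >= maf_min & !is.na(maf)
  if (!any(keep)) stop("all markers removed by filtering")
  out <- d[, keep, drop = FALSE]
  attr(out, "filter_report") <- c(
    fail_callrate = sum(callrate < callrate_min),
    fail_maf = sum(maf < maf_min | is.na(maf)),
    removed = sum(!keep), kept = sum(keep))
  out
}

#' Additive genomic relationship matrix from co-dominant SNPs (VanRaden)
#'
#' `G = W W' / (2 sum p_i (1 - p_i))` with `W = M - 2p` and in-sample
#' frequencies `p`. Missing genotypes are imputed by the locus mean `2p`
#' before centering, which preserves the grand-mean-zero identity.
#'
#' @param g 0/1/2 matrix.
#' @return relationship matrix, construction tag `"GA-snp"`.
#' @export
build_GA_snp <- function(g) {
  p <- allele_freq(g)
  W <- center_impute(g, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all loci monomorphic")
  G <- tcrossprod(W) / denom
  relmat(G, "GA-snp", ncol(g))
}

#' Additive genomic relationship matrix from dominant markers
#'
#' `G = S S' / sum p_i (1 - p_i)` with `S = Z - p`, `p` the in-sample
#' frequency of marker presence. (Note the denominator carries no factor 2,
#' unlike the SNP construction; the difference rescales variance components
#' but not matrix correlations.)
#'
#' @param d 0/1 matrix.
#' @return relationship matrix, construction tag `"GA-dominant"`.
#' @export
build_GA_dominant <- function(d) {
  p <- colMeans(d, na.rm = TRUE)
  S <- center_impute(d, p)
  denom <- sum(p * (1 - p))
  if (denom <= 0) stop("zero denominator: all markers monomorphic")
  G <- tcrossprod(S) / denom
  relmat(G, "GA-dominant", ncol(d))
}

#' Dominance genomic relationship matrix, Vitezica parameterization
#'
#' Genotypes \{0, 1, 2\} are coded \{-2p^2, 2pq, -2q^2\} per locus
#' (q = 1 - p) and `G_D = H H' / sum (2 p_i q_i)^2`. The coding has zero
#' expectation at HWE and is orthogonal to the additive contrast.
#'
#' @param g 0/1/2 matrix.
#' @return relationship matrix, construction tag `"GD-Vitezica"`.
#' @export
build_GD_vitezica <- function(g) {
  p <- allele_freq(g)
  H <- hetero_code_na(g, p)
  denom <- sum((2 * p * (1 - p))^2)
  if (denom <= 0) stop("zero denominator: no heterozygosity")
  G <- tcrossprod(H) / denom
  relmat(G, "GD-Vitezica", ncol(g))
}

#' Dominance genomic relationship matrix, Su parameterization
#'
#' Heterozygosity indicators `x` in \{0, 1, 0\} are centered on `2pq`,
#' `H = x - 2pq`, and `G_D = H H' / sum 2 p_i q_i (1 - 2 p_i q_i)`.
#'
#' @param g 0/1/2 matrix.
#' @return relationship matrix, construction tag `"GD-Su"`.
#' @export
build_GD_su <- function(g) {
  p <- allele_freq(g)
  pq2 <- 2 * p * (1 - p)
  x <- (g == 1L) * 1
  H <- center_impute(x, pq2)
  denom <- sum(pq2 * (1 - pq2))
  if (denom <= 0) stop("zero denominator: degenerate heterozygosity")
  G <- tcrossprod(H) / denom
  relmat(G, "GD-Su", ncol(g))
}

# center columns on `ctr`, missing entries to 0 (i.e. imputed at the mean)
center_impute <- function(m, ctr) {
  W <- sweep(m, 2, ctr)
  W[is.na(W)] <- 0
  W
}

# Vitezica coding with missing entries imputed at the locus mean code
hetero_code_na <- function(g, p) {
  q <- 1 - p
  h <- sweep((g == 1L), 2, 2 * p * q, `*`) +
       sweep((g == 0L), 2, -2 * p^2, `*`) +
       sweep((g == 2L), 2, -2 * q^2, `*`)
  if (anyNA(g)) {
    mu <- colMeans(h, na.rm = TRUE)
    idx <- which(is.na(h), arr.ind = TRUE)
    h[idx] <- mu[idx[, 2]]
  }
  h
}

relmat <- function(G, construction, m) {
  G <- (G + t(G)) / 2
  attr(G, "construction") <- construction
  attr(G, "m_markers") <- m
  G
}

#' Product-moment correlation between two relationship matrices
#'
#' Pearson correlation over the strictly-upper-triangle (off-diagonal)
#' entries; both matrices must cover the same individuals in the same order.
#'
#' @param G1,G2 same-dimension symmetric matrices.
#' @return correlation in `[-1, 1]`.
#' @export
matrix_correlation <- function(G1, G2) {
  stopifnot(all(dim(G1) == dim(G2)))
  if (!is.null(rownames(G1)) && !is.null(rownames(G2)) &&
      !identical(rownames(G1), rownames(G2)))
    stop("matrices cover different individuals or orders")
  ut <- upper.tri(G1)
  x <- G1[ut]; y <- G2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant matrix")
  stats::cor(x, y)
}

#' Marker-subsampling stability of genomic relationship matrices
#'
#' Rebuilds the GRM from uniform random marker subsets of increasing size
#' and records the off-diagonal correlation with the full-marker reference,
#' plus per-relatedness-class mean relationships when classes are supplied.
#'
#' @param markers genotype (0/1/2) or dominant (0/1) matrix.
#' @param sizes subset sizes (each <= number of markers).
#' @param n_reps replicates per size (default 10).
#' @param reference full-marker GRM (built from `markers` if NULL).
#' @param classes optional [classify_pairs()] result for class means.
#' @param type `"snp"` (build via [build_GA_snp()]) or `"dominant"`.
#' @param seed integer seed.
#' @return data.frame (size, rep, correlation, and class-mean columns).
#' @export
subsample_stability <- function(markers, sizes, n_reps = 10, reference = NULL,
                                classes = NULL, type = c("snp", "dominant"),
                                seed = 1L) {
  type <- match.arg(type)
  build <- if (type == "snp") build_GA_snp else build_GA_dominant
  if (any(sizes > ncol(markers))) stop("subset size exceeds available markers")
  if (is.null(reference)) reference <- build(markers)
  set.seed(seed)
  rows <- list()
  for (s in sizes) for (r in seq_len(n_reps)) {
    sub <- sort(sample.int(ncol(markers), s))
    Gs <- build(markers[, sub, drop = FALSE])
    row <- data.frame(size = s, rep = r,
                      correlation = matrix_correlation(Gs, reference))
    if (!is.null(classes)) {
      cm <- class_means(Gs, classes)
      row <- cbind(row, as.data.frame(as.list(cm)))
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

class_means <- function(G, classes) {
  stopifnot(inherits(classes, "pair_classes"))
  v <- G[cbind(match(classes$ids, rownames(G))[classes$i],
               match(classes$ids, rownames(G))[classes$j])]
  tapply(v, classes$class, mean)
}

#' Per-relatedness-class summary of pairwise relationships
#'
#' @param G relationship matrix covering `classes$ids`.
#' @param classes a [classify_pairs()] result.
#' @param breaks histogram bin breaks; default width 0.05 over
#'   `[-0.4, 1.6]`, extended in 0.05 steps if values fall outside.
#' @return list with `stats` (class, n, mean, se) and `histogram`
#'   (data.frame of bin mid, class, count); bin counts sum to the number of
#'   pairs. Empty classes are absent from the output rather than errors.
#' @export
relatedness_summary <- function(G, classes,
                                breaks = seq(-0.4, 1.6, by = 0.05)) {
  stopifnot(inherits(classes, "pair_classes"))
  ids <- match(classes$ids, rownames(G))
  if (anyNA(ids)) stop("G does not cover the classified individuals")
  v <- G[cbind(ids[classes$i], ids[classes$j])]
  while (min(v) < min(breaks)) breaks <- c(min(breaks) - 0.05, breaks)
  while (max(v) > max(breaks)) breaks <- c(breaks, max(breaks) + 0.05)
  keep <- table(classes$class) > 0
  stats <- do.call(rbind, lapply(names(keep)[keep], function(cl) {
    x <- v[classes$class == cl]
    data.frame(class = cl, n = length(x), mean = mean(x),
               se = stats::sd(x) / sqrt(length(x)))
  }))
  hist_df <- do.call(rbind, lapply(names(keep)[keep], function(cl) {
    x <- v[classes$class == cl]
    cnt <- table(cut(x, breaks, include.lowest = TRUE))
    data.frame(class = cl, bin_mid = breaks[-length(breaks)] + 0.025,
               count = as.integer(cnt))
  }))
  list(stats = stats, histogram = hist_df, n_pairs = length(v))
}
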