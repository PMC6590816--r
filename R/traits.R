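#' Derive stem volume and mean annual increment from DBH and height
#'
#' Volume treats the stem as a cylinder on the breast-height section scaled
#' by a taper factor: `vol = (pi/4) (dbh/100)^2 height taper`. Mean annual
#' increment scales single-tree volume to stand level:
#' `mai = vol * stems_per_ha / years`.
#'
#' @param dbh diameter at breast height, cm.
#' @param height total height, m.
#' @param taper taper factor (default 0.45).
#' @param stems_per_ha planting density (default 1200 trees/ha).
#' @param years stand age (default 5).
#' @return data.frame `dbh`, `height`, `vol` (m^3), `mai`
#'   (m^3 ha^-1 year^-1).
#' @examples
#' derive_growth_traits(16.6, 24.2)  # vol ~ 0.236 m^3
#' @export
derive_growth_traits <- function(dbh, height, taper = 0.45,
                                 stems_per_ha = 1200, years = 5) {
  if (any(dbh < 0, na.rm = TRUE) || any(height < 0, na.rm = TRUE))
    stop("dbh and height must be non-negative")
  vol <- (pi / 4) * (dbh / 100)^2 * height * taper
  data.frame(dbh = dbh, height = height, vol = vol,
             mai = vol * stems_per_ha / years)
}

#' Heritabilities and dominance ratio from a variance-component fit
#'
#' `hN2 = s2_a / (s2_plot + s2_a + s2_d + s2_e)` (the plot variance is part
#' of the denominator), `hB2` adds `s2_d` to the numerator, and the
#' dominance ratio is `s2_d / s2_a`. Standard errors come from the delta
#' method on the inverse average-information matrix.
#'
#' @param fit a converged [fit_univariate_ad()] result.
#' @return list of class `heritability_report`: `hN2`, `hN2_se`, `hB2`,
#'   `hB2_se`, `dominance_ratio` (NA when the additive variance sits at its
#'   boundary), `components`.
#' @export
heritabilities <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  th <- fit$components
  need <- c("additive", "residual")
  if (!all(need %in% names(th))) stop("fit lacks additive/residual components")
  tot <- sum(th[names(th) %in% c("plot", "additive", "dominance", "residual")])
  if (tot <= 0) stop("zero total variance")
  s2a <- th[["additive"]]
  s2d <- if ("dominance" %in% names(th)) th[["dominance"]] else 0
  hN2 <- s2a / tot
  hB2 <- (s2a + s2d) / tot
  f_h <- function(x) {
    dtot <- sum(x[names(x) %in% c("plot", "additive", "dominance", "residual")])
    x[["additive"]] / dtot
  }
  f_b <- function(x) {
    dtot <- sum(x[names(x) %in% c("plot", "additive", "dominance", "residual")])
    dd <- if ("dominance" %in% names(x)) x[["dominance"]] else 0
    (x[["additive"]] + dd) / dtot
  }
  ratio <- if (fit$boundary[["additive"]]) NA_real_ else s2d / s2a
  structure(list(hN2 = hN2, hN2_se = param_se(fit, f_h),
                 hB2 = hB2, hB2_se = param_se(fit, f_b),
                 dominance_ratio = ratio, components = th),
            class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, ...) {
  cat(sprintf("hN2 = %.3f +/- %.3f   hB2 = %.3f +/- %.3f   s2_d/s2_a = %s\n",
              x$hN2, x$hN2_se, x$hB2, x$hB2_se,
              if (is.na(x$dominance_ratio)) "-" else
                sprintf("%.2f", x$dominance_ratio)))
  invisible(x)
}

#' Dominance-to-additive ratio implied by a heritability pair
#'
#' Algebraic identity `(hB2 - hN2) / hN2 = s2_d / s2_a`, which holds because
#' both heritabilities share one denominator. Useful for checking the
#' internal consistency of published heritability tables.
#'
#' @param hN2,hB2 narrow- and broad-sense heritabilities (`hN2 > 0`).
#' @return implied dominance ratio.
#' @export
implied_dominance_ratio <- function(hN2, hB2) {
  if (any(hN2 <= 0)) stop("hN2 must be positive")
  (hB2 - hN2) / hN2
}

#' Genetic correlation from a bivariate fit
#'
#' `r = sigma_a_ij / sqrt(sigma2_a_i * sigma2_a_j)`, clamped to `[-1, 1]`,
#' with a delta-method SE from the observed-information covariance of the
#' components.
#'
#' @param fit a [fit_bivariate_additive()] result.
#' @param boundary_frac variances below this fraction of the corresponding
#'   residual variance are treated as boundary (correlation undefined).
#' @return list `r`, `se` (NA when unavailable).
#' @export
genetic_correlation <- function(fit, boundary_frac = 1e-6) {
  stopifnot(inherits(fit, "bivar_fit"))
  th <- fit$components
  a1 <- th[["sigma2_a_i"]]; a2 <- th[["sigma2_a_j"]]
  if (a1 <= boundary_frac * th[["sigma2_e_i"]] ||
      a2 <= boundary_frac * th[["sigma2_e_j"]])
    return(list(r = NA_real_, se = NA_real_))
  r <- max(-1, min(1, th[["sigma_a_ij"]] / sqrt(a1 * a2)))
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    g <- c(-0.5 * th[["sigma_a_ij"]] / (a1^1.5 * sqrt(a2)),
           -0.5 * th[["sigma_a_ij"]] / (a2^1.5 * sqrt(a1)),
           1 / sqrt(a1 * a2), 0, 0, 0)
    g <- g[seq_len(ncol(fit$vcov))]
    v <- drop(t(g) %*% fit$vcov %*% g)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  list(r = r, se = se)
}

#' Descriptive summary of trait distributions
#'
#' One row per trait: n, mean, median, SD, coefficient of variation
#' (CV = SD/mean), minimum and maximum.
#'
#' @param data data.frame of phenotypes.
#' @param traits trait column names.
#' @return data.frame summary.
#' @export
trait_summary <- function(data, traits) {
  do.call(rbind, lapply(traits, function(tr) {
    x <- data[[tr]]
    x <- x[!is.na(x)]
    data.frame(trait = tr, n = length(x), mean = mean(x),
               median = stats::median(x), sd = stats::sd(x),
               cv = stats::sd(x) / mean(x), min = min(x), max = max(x))
  }))
}

#' Trait-correlation tables across breeding-value sources
#'
#' For each source (phenotypes and each table of estimated breeding values)
#' computes the trait x trait Pearson correlation matrix with two-sided
#' p-values from `t = r sqrt((n-2)/(1-r^2))`, tiered `NS` (p >= 0.05), `*`
#' (0.01 <= p < 0.05), `**` (p < 0.01); Benjamini-Hochberg adjusted
#' p-values are carried alongside. Between sources, Spearman rank
#' correlations of each trait's values compare breeding-value rankings.
#'
#' @param ebv_sources named list of data.frames (`id` + trait columns).
#' @param phenotypes data.frame (`id` + trait columns), included as source
#'   `"phenotype"`.
#' @param traits trait columns shared by all sources.
#' @return list: `pearson` (long data.frame source/trait pair/r/p/tier/
#'   p_adj), `spearman` (trait/source pair/rho).
#' @export
correlation_tables <- function(ebv_sources, phenotypes, traits) {
  sources <- c(list(phenotype = phenotypes), ebv_sources)
  pearson <- list()
  for (src in names(sources)) {
    d <- sources[[src]]
    cols <- intersect(traits, names(d))
    for (i in seq_along(cols)) for (j in seq_len(i - 1)) {
      ct <- cor_with_p(d[[cols[i]]], d[[cols[j]]])
      pearson[[length(pearson) + 1]] <-
        data.frame(source = src, trait_i = cols[i], trait_j = cols[j],
                   r = ct$r, p = ct$p, n = ct$n)
    }
  }
  pearson <- do.call(rbind, pearson)
  pearson$p_adj <- stats::p.adjust(pearson$p, method = "BH")
  pearson$tier <- cut(pearson$p, c(-Inf, 0.01, 0.05, Inf),
                      labels = c("**", "*", "NS"))
  spearman <- list()
  nm <- names(sources)
  for (tr in traits) for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
    di <- sources[[nm[i]]]; dj <- sources[[nm[j]]]
    if (!(tr %in% names(di)) || !(tr %in% names(dj))) next
    shared <- intersect(di$id, dj$id)
    if (length(shared) < 3) next
    rho <- stats::cor(di[[tr]][match(shared, di$id)],
                      dj[[tr]][match(shared, dj$id)], method = "spearman")
    spearman[[length(spearman) + 1]] <-
      data.frame(trait = tr, source_i = nm[i], source_j = nm[j], rho = rho)
  }
  list(pearson = pearson,
       spearman = if (length(spearman)) do.call(rbind, spearman) else NULL)
}

cor_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}
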