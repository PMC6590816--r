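#' Simulate founder genotypes at Hardy-Weinberg proportions
#'
#' Draws unrelated parent genotypes at `n_loci` unlinked biallelic loci.
#' Each locus gets an alternative-allele frequency from `maf_law` and the
#' two alleles of each individual are sampled independently (HWE).
#'
#' @param n_parents number of founder individuals (>= 2).
#' @param n_loci number of loci (>= 1).
#' @param maf_law per-locus frequency law: a single value in (0, 0.5], a
#'   length-2 range to sample uniformly from, or a function `f(m)` returning
#'   `m` frequencies in (0, 0.5].
#' @param seed integer seed.
#' @return integer matrix (`n_parents` x `n_loci`) of 0/1/2 alternative-allele
#'   counts, with the sampled frequencies in `attr(, "maf")`.
#' @examples
#' g <- simulate_parent_genotypes(4, 10, maf_law = 0.5, seed = 1)
#' @export
simulate_parent_genotypes <- function(n_parents, n_loci, maf_law = c(0.05, 0.5),
                                      seed = 1L) {
  stopifnot(n_parents >= 2, n_loci >= 1)
  set.seed(seed)
  p <- sample_maf(maf_law, n_loci)
  bad <- which(p <= 0 | p > 0.5)
  if (length(bad))
    stop("degenerate maf_law: frequency outside (0, 0.5] at locus ", bad[1])
  g <- matrix(stats::rbinom(n_parents * n_loci, 2L, rep(p, each = n_parents)),
              n_parents, n_loci)
  dimnames(g) <- list(paste0("P", seq_len(n_parents)),
                      paste0("L", seq_len(n_loci)))
  attr(g, "maf") <- p
  g
}

sample_maf <- function(maf_law, m) {
  if (is.function(maf_law)) return(maf_law(m))
  if (length(maf_law) == 1) return(rep(maf_law, m))
  if (length(maf_law) == 2) return(stats::runif(m, maf_law[1], maf_law[2]))
  stop("maf_law must be a value, a range, or a function")
}

#' Build an incomplete half-diallel pedigree
#'
#' Crosses `n_parents` founders in `n_families` distinct unordered pairs
#' (no selfs, no reciprocal duplicates) and attaches full-sib offspring to
#' each family. The default sizes mirror a hardwood progeny trial: 46
#' parents, 45 full-sib families, about 22 offspring per family, optionally
#' trimmed to a fixed total.
#'
#' @param n_parents number of founders.
#' @param n_families number of full-sib families; at most
#'   `choose(n_parents, 2)`.
#' @param offspring_per_family a single count or a length-2 inclusive range
#'   sampled uniformly per family.
#' @param n_total optional total number of offspring to keep (trimmed from
#'   the end, round-robin over families so no family is emptied).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `sire`, `dam` (NA for founders) and
#'   `family` (NA for founders, "FxxXFyy" label otherwise).
#' @export
make_diallel <- function(n_parents = 46, n_families = 45,
                         offspring_per_family = c(20, 25),
                         n_total = NULL, seed = 1L) {
  stopifnot(n_parents >= 2, n_families >= 1,
            all(offspring_per_family >= 1))
  max_fam <- choose(n_parents, 2)
  if (n_families > max_fam)
    stop("n_families (", n_families, ") exceeds available unordered pairs (",
         max_fam, ")")
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n_parents, n_parents)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), n_families), , drop = FALSE]
  sizes <- if (length(offspring_per_family) == 1) {
    rep(offspring_per_family, n_families)
  } else {
    sample(seq(offspring_per_family[1], offspring_per_family[2]),
           n_families, replace = TRUE)
  }
  parents <- paste0("P", seq_len(n_parents))
  sire <- rep(parents[pick[, 1]], sizes)
  dam <- rep(parents[pick[, 2]], sizes)
  fam <- paste0(rep(parents[pick[, 1]], sizes), "x",
                rep(parents[pick[, 2]], sizes))
  if (!is.null(n_total)) {
    if (n_total > length(sire)) stop("n_total exceeds generated offspring")
    # drop evenly across families so every family keeps most of its trees
    ord <- order(stats::ave(seq_along(fam), fam, FUN = seq_along),
                 seq_along(fam))
    keep <- sort(ord[seq_len(n_total)])
    sire <- sire[keep]; dam <- dam[keep]; fam <- fam[keep]
  }
  off <- paste0("O", seq_along(sire))
  rbind(
    data.frame(id = parents, sire = NA_character_, dam = NA_character_,
               family = NA_character_, stringsAsFactors = FALSE),
    data.frame(id = off, sire = sire, dam = dam, family = fam,
               stringsAsFactors = FALSE)
  )
}

#' Assign trees to randomized complete blocks with small plots
#'
#' Offspring of each family are dealt round-robin across blocks and, within
#' each block, grouped into plots of at most `trees_per_plot` trees of the
#' same family (plots nested within blocks).
#'
#' @param pedigree pedigree as returned by [make_diallel()].
#' @param n_blocks number of complete blocks.
#' @param trees_per_plot plot size (trees of one family per plot).
#' @param seed integer seed (randomizes family-to-plot order within block).
#' @return data.frame `id`, `family`, `block`, `plot` for all non-founders.
#' @export
make_trial_design <- function(pedigree, n_blocks = 5, trees_per_plot = 5,
                              seed = 1L) {
  off <- pedigree[!is.na(pedigree$sire), ]
  if (!nrow(off)) stop("pedigree has no offspring rows")
  set.seed(seed)
  block <- integer(nrow(off))
  plot <- character(nrow(off))
  for (f in unique(off$family)) {
    idx <- which(off$family == f)
    idx <- idx[sample.int(length(idx))]
    b <- rep_len(seq_len(n_blocks), length(idx))
    block[idx] <- b
    for (bb in unique(b)) {
      in_b <- idx[b == bb]
      grp <- ceiling(seq_along(in_b) / trees_per_plot)
      plot[in_b] <- paste0("B", bb, "_", f, "_", grp)
    }
  }
  data.frame(id = off$id, family = off$family, block = block, plot = plot,
             stringsAsFactors = FALSE)
}

#' Drop Mendelian offspring genotypes from parent genotypes
#'
#' Each offspring receives, at every locus independently, one allele sampled
#' uniformly from each parent's pair (loci unlinked).
#'
#' @param parents genotype matrix of founders (rows named by parent id).
#' @param pedigree pedigree data.frame (`id`, `sire`, `dam`); founder rows
#'   (NA parents) are ignored.
#' @param seed integer seed.
#' @return integer matrix of offspring genotypes, rows named by offspring id.
#' @export
mendelian_offspring <- function(parents, pedigree, seed = 1L) {
  off <- pedigree[!is.na(pedigree$sire), ]
  miss <- setdiff(unique(c(off$sire, off$dam)), rownames(parents))
  if (length(miss)) {
    bad <- off$id[off$sire %in% miss | off$dam %in% miss][1]
    stop("missing parent genotype (", miss[1], ") for offspring ", bad)
  }
  set.seed(seed)
  n <- nrow(off); m <- ncol(parents)
  gam <- function(g) {
    # one gamete per entry: homozygotes transmit deterministically,
    # heterozygotes a fair coin
    (g == 2L) + (g == 1L) * matrix(stats::rbinom(length(g), 1L, 0.5),
                                   nrow(g), ncol(g))
  }
  g <- gam(parents[off$sire, , drop = FALSE]) +
       gam(parents[off$dam, , drop = FALSE])
  storage.mode(g) <- "integer"
  dimnames(g) <- list(off$id, colnames(parents))
  g
}

#' Trait architecture for phenotype simulation
#'
#' @param n_qtl number of causal loci (sampled from the genotyped loci).
#' @param sigma2_a,sigma2_d,sigma2_plot,sigma2_e additive, dominance, plot
#'   and residual variances (trait units squared, all >= 0).
#' @param block_means fixed block effects; recycled over blocks.
#' @param genetic_corr optional additive correlation with a second trait in
#'   `[-1, 1]`; when set, [simulate_traits()] returns two traits.
#' @return list of class `trait_architecture`.
#' @export
trait_architecture <- function(n_qtl = 1000, sigma2_a = 0.23,
                               sigma2_d = 0.207, sigma2_plot = 0.05,
                               sigma2_e = 0.513, block_means = 10,
                               genetic_corr = NULL) {
  stopifnot(sigma2_a >= 0, sigma2_d >= 0, sigma2_plot >= 0, sigma2_e >= 0,
            n_qtl >= 1)
  if (!is.null(genetic_corr)) stopifnot(abs(genetic_corr) <= 1)
  structure(list(n_qtl = n_qtl, sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                 sigma2_plot = sigma2_plot, sigma2_e = sigma2_e,
                 block_means = block_means, genetic_corr = genetic_corr),
            class = "trait_architecture")
}

#' Simulate phenotypes under the additive-dominance individual-tree model
#'
#' Phenotype = block fixed effect + plot effect + additive genetic value +
#' dominance deviation + residual. Additive values are sums of per-QTL
#' allele-count effects; dominance deviations use the orthogonal
#' heterozygosity coding \{-2p^2, 2pq, -2q^2\}. Both are rescaled
#' empirically so their in-sample variances hit the targets exactly, which
#' makes parameter-recovery experiments sharp.
#'
#' @param genotypes individuals x loci 0/1/2 matrix (the individuals that
#'   appear in `design`).
#' @param arch a [trait_architecture()].
#' @param design trial design from [make_trial_design()].
#' @param seed integer seed.
#' @return data.frame with id/family/block/plot, phenotype column(s) `y`
#'   (and `y2`), true breeding values `tbv` and dominance deviations `dom`
#'   (and `tbv2`/`dom2`), plus `plot_eff` and `resid` for bookkeeping.
#' @export
simulate_traits <- function(genotypes, arch, design, seed = 1L) {
  stopifnot(inherits(arch, "trait_architecture"))
  if (arch$n_qtl > ncol(genotypes)) stop("n_qtl exceeds number of loci")
  if (!all(design$id %in% rownames(genotypes)))
    stop("design covers individuals without genotypes")
  tot <- arch$sigma2_a + arch$sigma2_d + arch$sigma2_plot + arch$sigma2_e
  set.seed(seed)
  g <- genotypes[design$id, , drop = FALSE]
  n <- nrow(g)
  qtl <- sort(sample.int(ncol(g), arch$n_qtl))
  gq <- g[, qtl, drop = FALSE]
  p <- colMeans(gq) / 2

  two_traits <- !is.null(arch$genetic_corr)
  n_tr <- if (two_traits) 2L else 1L
  # additive QTL effects; correlated across traits when requested
  alpha <- matrix(stats::rnorm(arch$n_qtl * n_tr), arch$n_qtl, n_tr)
  if (two_traits) {
    r <- arch$genetic_corr
    alpha[, 2] <- r * alpha[, 1] + sqrt(1 - r^2) * alpha[, 2]
  }
  W <- sweep(gq, 2, 2 * p)                      # centered allele counts
  q <- 1 - p
  H <- hetero_code(gq, p)                       # {-2p^2, 2pq, -2q^2}
  delta <- matrix(stats::rnorm(arch$n_qtl * n_tr), arch$n_qtl, n_tr)

  out <- data.frame(id = design$id, family = design$family,
                    block = design$block, plot = design$plot,
                    stringsAsFactors = FALSE)
  bm <- rep_len(arch$block_means, max(design$block))
  plots <- unique(design$plot)
  pe <- stats::rnorm(length(plots), 0, sqrt(arch$sigma2_plot))
  names(pe) <- plots
  out$plot_eff <- pe[design$plot]

  for (t in seq_len(n_tr)) {
    a <- drop(W %*% alpha[, t])
    a <- rescale_var(a, arch$sigma2_a)
    d <- drop(H %*% delta[, t])
    d <- rescale_var(d, arch$sigma2_d)
    e <- stats::rnorm(n, 0, sqrt(arch$sigma2_e))
    y <- bm[design$block] + out$plot_eff + a + d + e
    suf <- if (t == 1) "" else "2"
    out[[paste0("y", suf)]] <- y
    out[[paste0("tbv", suf)]] <- a
    out[[paste0("dom", suf)]] <- d
    out[[paste0("resid", suf)]] <- e
  }
  attr(out, "qtl") <- colnames(gq)
  out
}

# orthogonal dominance coding per locus: 0 -> -2p^2, 1 -> 2pq, 2 -> -2q^2
hetero_code <- function(g, p) {
  q <- 1 - p
  h <- sweep((g == 1L), 2, 2 * p * q, `*`) +
       sweep((g == 0L), 2, -2 * p^2, `*`) +
       sweep((g == 2L), 2, -2 * q^2, `*`)
  dimnames(h) <- dimnames(g)
  h
}

rescale_var <- function(x, target) {
  if (target == 0) return(x * 0)
  s <- stats::sd(x)
  if (s == 0) stop("component has zero realized variance but a nonzero target")
  (x - mean(x)) / s * sqrt(target)
}

#' Derive dominant presence/absence markers from co-dominant genotypes
#'
#' A dominant marker scores 1 when the individual carries at least one copy
#' of the alternative allele (genotype >= 1), emulating presence/absence
#' calls from reduced-representation sequencing.
#'
#' @param genotypes 0/1/2 matrix.
#' @param dropout per-entry missingness probability in `[0, 1)`.
#' @param seed integer seed for dropout.
#' @return 0/1 matrix (NA where dropped).
#' @export
derive_dominant_markers <- function(genotypes, dropout = 0, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1)
  z <- (genotypes >= 1L) * 1L
  if (dropout > 0) {
    set.seed(seed)
    z[stats::runif(length(z)) < dropout] <- NA_integer_
  }
  dimnames(z) <- list(rownames(genotypes),
                      paste0("D", seq_len(ncol(genotypes))))
  z
}

#' Default near-infrared wavelength grid
#'
#' 700 wavelengths starting at 1,100 nm with a 2 nm step (every second
#' wavelength of a 1 nm instrument grid up to 2,500 nm).
#' @return numeric vector of length 700.
#' @export
nir_grid <- function() seq(1100, by = 2, length.out = 700)

#' Spectra simulation model
#'
#' @param wavelength_grid strictly increasing grid; default [nir_grid()].
#' @param n_components number of latent spectral components (>= 1).
#' @param loading_smoothness width (in nm) of the Gaussian bands composing
#'   loadings and baseline; larger is smoother.
#' @param noise_sd iid noise standard deviation (absorbance units).
#' @param trait_linkage coefficients tying the first components'
#'   concentrations to (standardized) trait values; recycled over traits.
#' @return list of class `spectra_model`.
#' @export
spectra_model <- function(wavelength_grid = nir_grid(), n_components = 4,
                          loading_smoothness = 80, noise_sd = 0.002,
                          trait_linkage = 1) {
  stopifnot(all(diff(wavelength_grid) > 0), noise_sd >= 0, n_components >= 1)
  structure(list(wavelength_grid = wavelength_grid,
                 n_components = n_components,
                 loading_smoothness = loading_smoothness,
                 noise_sd = noise_sd, trait_linkage = trait_linkage),
            class = "spectra_model")
}

#' Simulate NIR spectra linearly informative about traits
#'
#' Each spectrum is a fixed smooth baseline plus `n_components` smooth
#' Gaussian-band loadings weighted by per-sample concentrations, plus iid
#' noise. The first `length(trait_cols)` component concentrations are the
#' standardized trait values (times `trait_linkage`), the rest are
#' independent standard normals, so traits are recoverable by linear
#' calibration.
#'
#' @param traits data.frame holding `id` and the trait columns.
#' @param model a [spectra_model()].
#' @param trait_cols names of trait columns to encode (default `"y"`).
#' @param seed integer seed.
#' @return list with `spectra` (samples x wavelengths matrix, columns named
#'   by nm), `grid`, and the generating `loadings`/`baseline`.
#' @export
simulate_spectra <- function(traits, model = spectra_model(),
                             trait_cols = "y", seed = 1L) {
  stopifnot(inherits(model, "spectra_model"))
  if (identical(length(model$wavelength_grid), 0L))
    stop("empty wavelength grid")
  tv <- as.matrix(traits[, trait_cols, drop = FALSE])
  if (any(!is.finite(tv))) stop("trait values must be finite")
  if (model$n_components < length(trait_cols))
    stop("need at least one component per encoded trait")
  set.seed(seed)
  wl <- model$wavelength_grid
  nw <- length(wl); n <- nrow(tv); k <- model$n_components
  bump <- function() {
    ctr <- stats::runif(3, min(wl), max(wl))
    amp <- stats::runif(3, 0.2, 1)
    rowSums(sapply(seq_len(3), function(j)
      amp[j] * exp(-((wl - ctr[j]) / model$loading_smoothness)^2)))
  }
  baseline <- 0.5 + bump()
  L <- t(sapply(seq_len(k), function(j) bump()))     # k x nw loadings
  conc <- matrix(stats::rnorm(n * k), n, k)
  link <- rep_len(model$trait_linkage, ncol(tv))
  for (j in seq_len(ncol(tv)))
    conc[, j] <- link[j] * scale(tv[, j])[, 1]
  spectra <- matrix(baseline, n, nw, byrow = TRUE) + conc %*% L
  if (model$noise_sd > 0)
    spectra <- spectra + matrix(stats::rnorm(n * nw, 0, model$noise_sd), n, nw)
  dimnames(spectra) <- list(traits$id, paste0("nm", wl))
  list(spectra = spectra, grid = wl, loadings = L, baseline = baseline)
}

#' Simulate a complete half-diallel trial population
#'
#' One-stop generator mirroring the default study conditions: 46 unrelated
#' parents, 45 full-sib families from an incomplete half-diallel, 22
#' offspring per family trimmed to 970 trees, randomized complete blocks
#' with 5-tree plots, unlinked biallelic SNPs, derived dominant markers,
#' one or two phenotypes, and optional NIR spectra.
#'
#' @param n_parents,n_families,offspring_per_family,n_total diallel layout.
#' @param n_loci number of SNP loci.
#' @param n_blocks,trees_per_plot trial layout.
#' @param arch a [trait_architecture()].
#' @param maf_law founder allele-frequency law (see
#'   [simulate_parent_genotypes()]).
#' @param spectra logical; also simulate NIR spectra for the trait `y`.
#' @param dropout missingness rate for the dominant markers.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return list with `pedigree`, `design`, `parents`, `genotypes` (offspring),
#'   `dominant`, `phenotypes`, and optionally `spectra`.
#' @export
simulate_diallel_population <- function(n_parents = 46, n_families = 45,
                                        offspring_per_family = 22,
                                        n_total = 970, n_loci = 30000,
                                        n_blocks = 5, trees_per_plot = 5,
                                        arch = trait_architecture(),
                                        maf_law = c(0.05, 0.5),
                                        spectra = FALSE, dropout = 0,
                                        seed = 1L) {
  seeds <- derive_seeds(seed, 6)
  ped <- make_diallel(n_parents, n_families, offspring_per_family,
                      n_total = n_total, seed = seeds[1])
  design <- make_trial_design(ped, n_blocks, trees_per_plot, seed = seeds[2])
  par_g <- simulate_parent_genotypes(n_parents, n_loci, maf_law,
                                     seed = seeds[3])
  g <- mendelian_offspring(par_g, ped, seed = seeds[4])
  pheno <- simulate_traits(g, arch, design, seed = seeds[5])
  dom <- derive_dominant_markers(g, dropout = dropout, seed = seeds[6])
  out <- list(pedigree = ped, design = design, parents = par_g,
              genotypes = g, dominant = dom, phenotypes = pheno)
  if (spectra)
    out$spectra <- simulate_spectra(pheno, seed = seeds[6])
  out
}

# spawn reproducible sub-seeds below 2^31 from one master seed
derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max, k)
}
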