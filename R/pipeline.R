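#' Run the full analysis pipeline from a configuration
#'
#' Configuration-driven end-to-end runner: simulate a half-diallel
#' population (or read genotype/pedigree/phenotype files), apply the marker
#' filters, build pedigree (A, D) and genomic (GA-snp, GA-dominant,
#' GD-Vitezica, GD-Su) kernels, fit the univariate additive-dominance model
#' per trait and kernel set, re-parameterize to heritabilities, assemble
#' trait-summary and correlation tables, summarize relatedness classes, run
#' the marker-subsampling stability analysis, and (optionally) calibrate
#' NIR spectra and fit bivariate models for requested trait pairs. Failure
#' of one trait x kernel fit is logged and does not abort the rest.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   `simulate` (arguments to [simulate_diallel_population()]) or `files`
#'   (paths `genotypes`, `pedigree`, `phenotypes`, optionally `spectra`);
#'   `traits` (phenotype columns, default `"y"`); `filters`
#'   (`snp_callrate`, `snp_maf`, `dart_callrate`, `dart_maf`); `kernels`
#'   (subset of `"pedigree"`, `"snp"`, `"dart"`, default all);
#'   `dominance` (logical, fit dominance components, default TRUE);
#'   `subsampling` (`sizes`, `reps`); `bivariate` (list of trait pairs);
#'   `nirs` (`trait`, `n_select`, `n_est`, `n_val`); `seed`; `out_dir`
#'   (optional; write CSV/TSV reports there).
#' @return list of class `pipeline_result` with the fitted objects and
#'   report tables; `$log` holds the timestamped event log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  seed <- config$seed %||% 1L
  log <- character()
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
    log <<- c(log, line)
    message(line)
  }
  cfg_hash <- config_hash(config)
  prov <- function(stage) c(stage = stage, seed = as.character(seed),
                            config = cfg_hash)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, name, writer) {
    if (is.null(out_dir)) return(invisible())
    writer(obj, file.path(out_dir, name), provenance = prov(name))
  }

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    logit("simulate: generating half-diallel population (seed ", seed, ")")
    sim <- do.call(simulate_diallel_population,
                   c(config$simulate, list(seed = seed)))
    ped <- sim$pedigree; pheno <- sim$phenotypes
    geno <- sim$genotypes; dart <- sim$dominant
    spectra <- sim$spectra$spectra
  } else {
    logit("read: loading input files")
    geno <- read_genotypes(config$files$genotypes)
    ped <- read_pedigree(config$files$pedigree)
    pheno <- read_phenotypes(config$files$phenotypes)
    dart <- if (!is.null(config$files$dominant))
      read_genotypes(config$files$dominant) else NULL
    spectra <- if (!is.null(config$files$spectra))
      read_spectra(config$files$spectra) else NULL
  }
  traits <- config$traits %||% "y"
  filt <- config$filters %||% list()

  # ---- filters ----
  geno <- filter_codominant(geno, filt$snp_callrate %||% 0.90,
                            filt$snp_maf %||% 0.01)
  logit("filter: SNPs kept ", ncol(geno), " (",
        paste(names(attr(geno, "filter_report")),
              attr(geno, "filter_report"), sep = "=", collapse = " "), ")")
  if (!is.null(dart)) {
    dart <- filter_dominant(dart, filt$dart_callrate %||% 0.80,
                            filt$dart_maf %||% 0.02)
    logit("filter: dominant markers kept ", ncol(dart))
  }

  # ---- kernels ----
  use <- config$kernels %||% c("pedigree", "snp", "dart")
  dominance <- config$dominance %||% TRUE
  kernels <- list()
  if ("pedigree" %in% use) {
    A <- build_A(ped)
    kernels$A <- list(K_a = A, K_d = if (dominance)
      build_D_from_pedigree(ped, A) else NULL)
  }
  if ("snp" %in% use) {
    GA <- build_GA_snp(geno)
    if (dominance) {
      kernels$GDVitezica <- list(K_a = GA, K_d = build_GD_vitezica(geno))
      kernels$GDSu <- list(K_a = GA, K_d = build_GD_su(geno))
    } else {
      kernels$GAsnp <- list(K_a = GA, K_d = NULL)
    }
  }
  if ("dart" %in% use && !is.null(dart)) {
    # dominant markers only support the additive construction
    kernels$GAdart <- list(K_a = build_GA_dominant(dart), K_d = NULL)
  }
  logit("kernels: ", paste(names(kernels), collapse = ", "))
  if (!is.null(out_dir))
    for (nm in names(kernels))
      emit(kernels[[nm]]$K_a, paste0("kernel_", nm, ".tsv"), write_relmat)

  # ---- NIRS (optional) ----
  nirs <- NULL
  if (!is.null(config$nirs) && !is.null(spectra)) {
    nc <- config$nirs
    vals <- stats::setNames(pheno[[nc$trait %||% traits[1]]], pheno$id)
    nirs <- calibrate_trait(spectra, vals,
                            n_select = nc$n_select %||% 350,
                            n_est = nc$n_est %||% 250,
                            n_val = nc$n_val %||% 100, seed = seed)
    logit("nirs: best preprocessing '", nirs$method, "', R2p ",
          round(nirs$report$r2p, 3),
          if (nirs$report$accepted) " (accepted)" else " (rejected)")
    rest <- setdiff(rownames(spectra), nirs$selected)
    if (nirs$report$accepted && length(rest)) {
      Xr <- preprocess(spectra[rest, , drop = FALSE], nirs$method,
                       ref = attr(preprocess(
                         spectra[nirs$split$estimation, , drop = FALSE],
                         nirs$method), "msc_ref"))
      nirs$predictions <- predict_unmeasured(nirs$model, nirs$report, Xr)
    }
  }

  # ---- univariate fits ----
  fits <- list(); h2 <- list(); ebv_sources <- list()
  for (tr in traits) for (nm in names(kernels)) {
    key <- paste(tr, nm, sep = ".")
    res <- tryCatch({
      spec <- mixed_model_spec(pheno, tr, kernels[[nm]]$K_a,
                               kernels[[nm]]$K_d)
      fit_univariate_ad(spec)
    }, error = function(e) {
      logit("fit ", key, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    fits[[key]] <- res
    h <- heritabilities(res)
    h2[[length(h2) + 1]] <- data.frame(
      trait = tr, kernel = nm, hN2 = h$hN2, hN2_se = h$hN2_se,
      hB2 = h$hB2, hB2_se = h$hB2_se,
      dominance_ratio = h$dominance_ratio)
    logit("fit ", key, ": hN2 ", round(h$hN2, 3), ", hB2 ", round(h$hB2, 3))
    eb <- blup_effects(res)
    src <- ebv_sources[[nm]] %||% data.frame(id = eb$id)
    src[[tr]] <- eb$ebv[match(src$id, eb$id)]
    ebv_sources[[nm]] <- src
  }
  h2_table <- if (length(h2)) do.call(rbind, h2) else NULL

  # ---- reports ----
  summary_table <- trait_summary(pheno, traits)
  corr <- tryCatch(
    correlation_tables(ebv_sources, pheno[, c("id", traits)], traits),
    error = function(e) NULL)
  classes <- classify_pairs(ped)
  relsum <- list()
  for (nm in names(kernels)) {
    K <- kernels[[nm]]$K_a
    if (all(classes$ids %in% rownames(K)))
      relsum[[nm]] <- relatedness_summary(K, classes)
  }

  stability <- NULL
  if (!is.null(config$subsampling)) {
    ss <- config$subsampling
    stability <- subsample_stability(
      geno, sizes = ss$sizes, n_reps = ss$reps %||% 10,
      classes = classes, seed = seed)
    logit("stability: ", nrow(stability), " subsample GRMs")
  }

  bivar <- list()
  for (pair in config$bivariate %||% list()) {
    key <- paste(pair, collapse = ".")
    bivar[[key]] <- tryCatch(
      fit_bivariate_additive(pheno, pair, kernels[[1]]$K_a),
      error = function(e) {
        logit("bivariate ", key, " FAILED: ", conditionMessage(e)); NULL
      })
  }

  emit(summary_table, "trait_summary.csv", write_phenotypes)
  if (!is.null(h2_table)) emit(h2_table, "heritabilities.csv",
                               write_phenotypes)
  if (!is.null(stability)) emit(stability, "subsampling.csv",
                                write_phenotypes)
  if (!is.null(corr) && !is.null(corr$pearson))
    emit(corr$pearson, "correlations.csv", write_phenotypes)
  if (!is.null(out_dir)) {
    write_manifest(c(list(config_hash = cfg_hash, seed = seed),
                     strip_classes(config[setdiff(names(config), "out_dir")])),
                   file.path(out_dir, "manifest.json"))
    writeLines(log, file.path(out_dir, "pipeline.log"))
  }
  structure(list(h2_table = h2_table, trait_summary = summary_table,
                 correlations = corr, relatedness = relsum,
                 stability = stability, fits = fits, bivariate = bivar,
                 nirs = nirs, ebv = ebv_sources, classes = classes,
                 kernels = lapply(kernels, function(k) k$K_a),
                 log = log, config_hash = cfg_hash),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("diallelqg pipeline result (config", x$config_hash, ")\n")
  if (!is.null(x$h2_table)) {
    cat("\nheritabilities:\n")
    print(x$h2_table, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

validate_config <- function(config) {
  problems <- character()
  if (!is.list(config)) return("config must be a list")
  if (is.null(config$simulate) && is.null(config$files))
    problems <- c(problems, "need either a 'simulate' block or 'files' paths")
  if (!is.null(config$files)) {
    for (f in unlist(config$files))
      if (!file.exists(f)) problems <- c(problems, paste("missing file:", f))
  }
  if (!is.null(config$subsampling) && is.null(config$subsampling$sizes))
    problems <- c(problems, "subsampling block needs 'sizes'")
  for (pair in config$bivariate %||% list())
    if (length(pair) != 2)
      problems <- c(problems, "bivariate entries must be trait pairs")
  problems
}

# drop S3 classes (and NULL leaves) so configs serialize as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[!vapply(x, is.null, TRUE)] <- lapply(x[!vapply(x, is.null, TRUE)],
                                           strip_classes)
  }
  x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
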