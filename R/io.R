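#' Write / read the package's delimited data formats
#'
#' Genotype and relationship matrices travel as TSV with a header row of
#' locus (or individual) ids and row ids in the first column; pedigrees,
#' phenotypes and spectra as CSV. `NA` marks missing genotypes and `0` or an
#' empty field an unknown parent. Every writer can stamp a one-line
#' provenance header (`# diallelqg stage=... seed=... config=...`), which
#' the readers skip.
#'
#' @param m matrix to write.
#' @param path file path.
#' @param provenance optional named character vector stamped as a comment.
#' @name diallelqg-io
NULL

prov_line <- function(provenance) {
  if (is.null(provenance)) return(NULL)
  paste0("# diallelqg ", paste(names(provenance), provenance,
                               sep = "=", collapse = " "))
}

write_with_header <- function(writer, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  pl <- prov_line(provenance)
  if (!is.null(pl)) writeLines(pl, con)
  writer(con)
}

#' @rdname diallelqg-io
#' @export
write_genotypes <- function(m, path, provenance = NULL) {
  write_with_header(function(con) {
    utils::write.table(
      data.frame(id = rownames(m), m, check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  }, path, provenance)
  invisible(path)
}

#' @rdname diallelqg-io
#' @export
read_genotypes <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname diallelqg-io
#' @param pedigree pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path, provenance = NULL) {
  ped <- pedigree
  for (col in c("sire", "dam")) ped[[col]][is.na(ped[[col]])] <- "0"
  write_with_header(function(con) {
    utils::write.csv(ped, con, row.names = FALSE, quote = FALSE)
  }, path, provenance)
  invisible(path)
}

#' @rdname diallelqg-io
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character")
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("", "0")] <- NA
  ped
}

#' @rdname diallelqg-io
#' @param data data.frame (phenotypes).
#' @export
write_phenotypes <- function(data, path, provenance = NULL) {
  write_with_header(function(con) {
    utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  }, path, provenance)
  invisible(path)
}

#' @rdname diallelqg-io
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' @rdname diallelqg-io
#' @param G relationship matrix.
#' @export
write_relmat <- function(G, path, provenance = NULL) {
  pv <- c(construction = attr(G, "construction") %||% "unknown", provenance)
  write_with_header(function(con) {
    utils::write.table(
      data.frame(id = rownames(G), G, check.names = FALSE),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path, pv)
  invisible(path)
}

#' @rdname diallelqg-io
#' @export
read_relmat <- function(path) {
  first <- readLines(path, n = 1)
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (startsWith(first, "# diallelqg")) {
    tag <- sub(".*construction=([^ ]+).*", "\\1", first)
    if (tag != first) attr(m, "construction") <- tag
  }
  m
}

#' @rdname diallelqg-io
#' @param spectra samples x wavelengths matrix with `nm`-prefixed column
#'   names.
#' @export
write_spectra <- function(spectra, path, provenance = NULL) {
  write_with_header(function(con) {
    utils::write.csv(data.frame(id = rownames(spectra), spectra,
                                check.names = FALSE),
                     con, row.names = FALSE, quote = FALSE)
  }, path, provenance)
  invisible(path)
}

#' @rdname diallelqg-io
#' @export
read_spectra <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Read biallelic VCF genotypes as 0/1/2 alternative-allele counts
#'
#' Thin ingestion path for SNP data arriving as VCF: biallelic sites are
#' converted to counts of the ALT allele; anything unparsable is NA.
#'
#' @param path VCF file (plain text or gzipped).
#' @return individuals x sites integer matrix.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  samples <- hdr[-(1:9)]
  keep <- vapply(body, function(f) !grepl(",", f[5]), TRUE)  # biallelic only
  body <- body[keep]
  gt <- vapply(body, function(f) {
    calls <- sub(":.*", "", f[-(1:9)])
    a <- as.integer(substr(calls, 1, 1)) + as.integer(substr(calls, 3, 3))
    a
  }, integer(length(samples)))
  gt <- matrix(gt, nrow = length(samples))
  rownames(gt) <- samples
  colnames(gt) <- vapply(body, function(f)
    if (f[3] %in% c(".", "")) paste0(f[1], "_", f[2]) else f[3], "")
  gt
}

#' Write a JSON manifest of simulation/analysis parameters
#'
#' @param params named list (seeds included).
#' @param path output path.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
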