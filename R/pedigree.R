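#' Pedigree numerator relationship matrix (A)
#'
#' Tabular recursion over a topologically sorted pedigree:
#' `a_ii = 1 + 0.5 a_{sire,dam}` and
#' `a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})`; founders are mutually
#' unrelated and non-inbred. Individuals with a single known parent take
#' `a_ij = 0.5 a_{j,known}`.
#'
#' @param pedigree data.frame `id`, `sire`, `dam` (NA/""/0 = unknown).
#'   Input order is free; a cyclic pedigree is an error.
#' @return symmetric matrix with `id` dimnames, construction tag
#'   `"pedigree-A"`.
#' @export
build_A <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  ord <- topo_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      rel <- numeric(i - 1)
      if (!is.na(si)) rel <- rel + 0.5 * A[j, si]
      if (!is.na(di)) rel <- rel + 0.5 * A[j, di]
      A[j, i] <- A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(si) && !is.na(di)) 0.5 * A[si, di] else 0
  }
  # return in the caller's order
  back <- match(normalize_pedigree(pedigree)$id, ped$id)
  A <- A[back, back, drop = FALSE]
  attr(A, "construction") <- "pedigree-A"
  A
}

#' Pedigree dominance relationship matrix (D)
#'
#' For non-founders i, j with parents (f_i, m_i) and (f_j, m_j):
#' `d_ij = 0.25 (a_{f_i f_j} a_{m_i m_j} + a_{f_i m_j} a_{m_i f_j})`,
#' with `d_ii = 1` (non-inbred convention). Founders get identity rows
#' (no parental records, so no dominance relationship is defined).
#'
#' @param pedigree pedigree data.frame.
#' @param A matrix from [build_A()] on the same pedigree (built if missing).
#' @return symmetric matrix, construction tag `"pedigree-D"`.
#' @export
build_D_from_pedigree <- function(pedigree, A = NULL) {
  ped <- normalize_pedigree(pedigree)
  if (is.null(A)) A <- build_A(pedigree)
  if (!all(ped$id %in% rownames(A))) stop("A does not cover the pedigree ids")
  nf <- !is.na(ped$sire) & !is.na(ped$dam)
  if (any(xor(is.na(ped$sire), is.na(ped$dam))))
    stop("missing parent records: dominance needs both parents known: ",
         ped$id[xor(is.na(ped$sire), is.na(ped$dam))][1])
  n <- nrow(ped)
  D <- diag(n)
  dimnames(D) <- list(ped$id, ped$id)
  if (any(nf)) {
    f <- ped$sire[nf]; m <- ped$dam[nf]
    Dnf <- 0.25 * (A[f, f, drop = FALSE] * A[m, m, drop = FALSE] +
                   A[f, m, drop = FALSE] * A[m, f, drop = FALSE])
    diag(Dnf) <- 1
    D[nf, nf] <- Dnf
  }
  attr(D, "construction") <- "pedigree-D"
  D
}

#' Classify non-founder pairs into relatedness classes
#'
#' Labels every unordered pair of non-founders as `full-sib` (both parents
#' shared), `half-sib` (exactly one shared) or `unrelated`.
#'
#' @param pedigree pedigree data.frame.
#' @return list of class `pair_classes` with `ids`, upper-triangle indices
#'   `i`, `j`, and a factor `class`; counts sum to `choose(n, 2)`.
#' @export
classify_pairs <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  off <- ped[!is.na(ped$sire) & !is.na(ped$dam), ]
  n <- nrow(off)
  if (n < 2) stop("need at least two non-founders")
  same_sire <- outer(off$sire, off$sire, `==`)
  same_dam <- outer(off$dam, off$dam, `==`)
  # unordered parent pairs can also match crosswise (sire of one = dam of other)
  cross1 <- outer(off$sire, off$dam, `==`)
  cross2 <- outer(off$dam, off$sire, `==`)
  shared <- same_sire + same_dam
  shared_cross <- cross1 + cross2
  nshared <- pmax(shared, shared_cross)
  ut <- upper.tri(nshared)
  idx <- which(ut, arr.ind = TRUE)
  lab <- cut(nshared[ut], breaks = c(-0.5, 0.5, 1.5, 2.5),
             labels = c("unrelated", "half-sib", "full-sib"))
  structure(list(ids = off$id, i = idx[, 1], j = idx[, 2], class = lab),
            class = "pair_classes")
}

#' @export
print.pair_classes <- function(x, ...) {
  cat("pair classes over", length(x$ids), "individuals:",
      length(x$class), "pairs\n")
  print(table(x$class))
  invisible(x)
}

normalize_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs id, sire, dam columns")
  for (col in need) ped[[col]] <- as.character(ped[[col]])
  for (col in c("sire", "dam"))
    ped[[col]][ped[[col]] %in% c("", "0", "NA") | is.na(ped[[col]])] <- NA
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  unknown <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  if (length(unknown))
    stop("parents absent from pedigree: ", paste(unknown, collapse = ", "))
  ped[need]
}

topo_order <- function(ped) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$id)
  d <- match(ped$dam, ped$id)
  state <- integer(n)  # 0 unseen, 1 in progress, 2 done
  ord <- integer(0)
  visit <- function(i, path) {
    if (state[i] == 1L)
      stop("cyclic pedigree through ",
           paste(ped$id[c(path, i)], collapse = " -> "))
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(s[i], d[i])) if (!is.na(p)) visit(p, c(path, i))
    state[i] <<- 2L
    ord <<- c(ord, i)
  }
  for (i in seq_len(n)) visit(i, integer(0))
  ord
}
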