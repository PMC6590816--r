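test_that("SNP and dominant marker filters apply the thresholds", {
  set.seed(10)
  g <- matrix(sample(0:2, 200, replace = TRUE), 20, 10,
              dimnames = list(paste0("i", 1:20), paste0("L", 1:10)))
  g[, 3] <- 0L                         # monomorphic -> MAF 0
  g[1:3, 5] <- NA                      # 15% missing
  g[, 8] <- c(1L, rep(0L, 19))         # MAF 0.025 -> survives 0.01
  gf <- filter_codominant(g, callrate_min = 0.90, maf_min = 0.01)
  expect_false("L3" %in% colnames(gf))
  expect_false("L5" %in% colnames(gf))
  expect_true("L8" %in% colnames(gf))
  rep <- attr(gf, "filter_report")
  expect_equal(unname(rep["kept"]), ncol(gf))

  # hand-constructed 10-locus fixture with exactly 3 failures
  g2 <- matrix(1L, 20, 10, dimnames = list(NULL, paste0("M", 1:10)))
  g2[, 1:7] <- matrix(sample(0:2, 140, replace = TRUE), 20, 7)
  g2[, 7] <- rep(c(0L, 1L), 10)        # safe polymorphic locus
  g2[, 8] <- 0L                        # MAF 0
  g2[1:5, 9] <- NA                     # 25% missing
  g2[, 10] <- 2L                       # MAF 0
  gf2 <- filter_codominant(g2, 0.90, 0.05)
  expect_equal(ncol(gf2), 7)

  d <- matrix(sample(0:1, 200, replace = TRUE), 20, 10,
              dimnames = list(NULL, paste0("D", 1:10)))
  d[, 1] <- 1L                         # present in all -> estimated MAF 0
  d[1:5, 2] <- NA                      # 25% missing at callrate 0.80
  df <- filter_dominant(d, callrate_min = 0.80, maf_min = 0.02)
  expect_false(any(c("D1", "D2") %in% colnames(df)))

  # presence frequency 0.19 -> p = 1 - sqrt(0.81) = 0.1, retained
  d2 <- matrix(0L, 100, 2, dimnames = list(NULL, c("A", "B")))
  d2[1:19, 1] <- 1L
  d2[1:50, 2] <- 1L
  df2 <- filter_dominant(d2, maf_min = 0.02)
  expect_true("A" %in% colnames(df2))
  expect_error(filter_dominant(matrix(1L, 5, 2)), "removed")
})

test_that("additive GRM constructions match their closed-form toy values", {
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "L1"))
  G <- build_GA_snp(g)  # in-sample p = 0.5
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  het <- matrix(1L, 1, 1, dimnames = list("a", "L1"))
  expect_equal(unname(diag(build_GA_snp(het))), 0)

  d <- matrix(c(1L, 0L), 2, 1, dimnames = list(c("a", "b"), "D1"))
  Gd <- build_GA_dominant(d)
  expect_equal(unname(Gd), matrix(c(1, -1, -1, 1), 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical score vectors give identical rows
  d2 <- matrix(c(1L, 1L, 0L, 1L, 1L, 0L), 3, 2)
  rownames(d2) <- c("a", "b", "c")
  G2 <- build_GA_dominant(d2)
  expect_equal(G2["a", ], G2["b", ])
  expect_equal(G2["a", "a"], G2["b", "b"])
})

test_that("both additive GRMs have exactly zero grand mean with in-sample frequencies", {
  pop <- shared_pop()
  g <- pop$genotypes[1:80, 1:500]
  expect_lt(abs(mean(build_GA_snp(g))), 1e-12)
  d <- derive_dominant_markers(g)
  expect_lt(abs(mean(build_GA_dominant(d))), 1e-12)
})

test_that("dominance GRM parameterizations match their defining formulas", {
  het <- matrix(1L, 1, 1, dimnames = list("a", "L1"))
  expect_equal(unname(diag(build_GD_vitezica(het))), 1)  # (2pq)^2/(2pq)^2
  expect_equal(unname(diag(build_GD_su(het))), 1)        # (1-2pq)^2/(2pq(1-2pq)) at p=.5 -> (0.5)^2/0.25

  # single homozygote at p = 0.5 cannot arise in-sample; use a 2-individual
  # case with p = 0.5 where individual a is homozygous: su code -2pq = -0.5
  g <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "L1"))
  Gs <- build_GD_su(g)
  expect_equal(unname(diag(Gs)), c(1, 1))  # (-0.5)^2 / (0.5*0.5)

  # Vitezica code has zero expectation at any HWE locus (enumeration)
  for (p in c(0.1, 0.3, 0.5, 0.7)) {
    q <- 1 - p
    probs <- c(q^2, 2 * p * q, p^2)
    codes <- c(-2 * p^2, 2 * p * q, -2 * q^2)
    expect_equal(sum(probs * codes), 0, tolerance = 1e-12)
    # additive-by-dominance orthogonality at one HWE locus
    add <- c(0, 1, 2) - 2 * p
    expect_equal(sum(probs * codes * add), 0, tolerance = 1e-12)
  }

  # HWE simulation: mean diagonal near 1
  gg <- simulate_parent_genotypes(5000, 300, maf_law = c(0.1, 0.5), seed = 8)
  expect_lt(abs(mean(diag(build_GD_vitezica(gg))) - 1), 0.05)
})

test_that("each GRM builder matches an entry-by-entry brute-force oracle", {
  set.seed(20)
  g <- matrix(sample(0:2, 500, replace = TRUE), 10, 50,
              dimnames = list(paste0("i", 1:10), paste0("L", 1:50)))
  p <- colMeans(g) / 2
  n <- nrow(g); m <- ncol(g)

  bf <- function(code_fun, denom) {
    G <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      s <- 0
      for (l in 1:m) s <- s + code_fun(g[i, l], p[l]) * code_fun(g[j, l], p[l])
      G[i, j] <- s / denom
    }
    G
  }
  add_code <- function(x, pl) x - 2 * pl
  vit_code <- function(x, pl) {
    ql <- 1 - pl
    if (x == 0) -2 * pl^2 else if (x == 1) 2 * pl * ql else -2 * ql^2
  }
  su_code <- function(x, pl) (x == 1) - 2 * pl * (1 - pl)

  expect_lt(max(abs(build_GA_snp(g) -
                      bf(add_code, 2 * sum(p * (1 - p))))), 1e-10)
  expect_lt(max(abs(build_GD_vitezica(g) -
                      bf(vit_code, sum((2 * p * (1 - p))^2)))), 1e-10)
  pq <- 2 * p * (1 - p)
  expect_lt(max(abs(build_GD_su(g) -
                      bf(su_code, sum(pq * (1 - pq))))), 1e-10)

  d <- (g >= 1) * 1L
  f <- colMeans(d)
  dom_code <- function(x, fl) x - fl
  Gd_bf <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (l in 1:m) s <- s + (d[i, l] - f[l]) * (d[j, l] - f[l])
    Gd_bf[i, j] <- s / sum(f * (1 - f))
  }
  expect_lt(max(abs(build_GA_dominant(d) - Gd_bf)), 1e-10)
})

test_that("matrix correlation is the off-diagonal Pearson coefficient", {
  set.seed(30)
  G <- crossprod(matrix(rnorm(16), 4))
  expect_equal(matrix_correlation(G, G), 1)
  expect_equal(matrix_correlation(G, 2 * G + 3), 1)
  H <- crossprod(matrix(rnorm(16), 4))
  ut <- upper.tri(G)
  expect_equal(matrix_correlation(G, H), stats::cor(G[ut], H[ut]))
  expect_error(matrix_correlation(G, matrix(1, 4, 4)), "constant")
})

test_that("relatedness summaries recover exact pedigree class means", {
  pop <- shared_pop()
  cl <- classify_pairs(pop$pedigree)
  A <- build_A(pop$pedigree)
  rs <- relatedness_summary(A, cl)
  st <- rs$stats
  expect_equal(st$mean[st$class == "unrelated"], 0)
  expect_equal(st$mean[st$class == "half-sib"], 0.25)
  expect_equal(st$mean[st$class == "full-sib"], 0.5)
  expect_equal(sum(rs$histogram$count), choose(970, 2))
  expect_equal(rs$n_pairs, 469965)
})

test_that("GRM class means approach pedigree expectations and subsampling stabilizes", {
  pop <- shared_pop()
  cl <- classify_pairs(pop$pedigree)
  GA <- build_GA_snp(pop$genotypes)
  st <- relatedness_summary(GA, cl)$stats
  expect_lt(abs(st$mean[st$class == "full-sib"] - 0.5), 0.05)
  expect_lt(abs(st$mean[st$class == "half-sib"] - 0.25), 0.05)
  expect_lt(abs(st$mean[st$class == "unrelated"]), 0.05)

  tab <- subsample_stability(pop$genotypes, sizes = c(250, 1000, 3000),
                             n_reps = 3, reference = GA, classes = cl,
                             seed = 6)
  m <- tapply(tab$correlation, tab$size, mean)
  expect_true(all(diff(m) > 0))
  full <- subsample_stability(pop$genotypes, sizes = ncol(pop$genotypes),
                              n_reps = 1, reference = GA, seed = 1)
  expect_equal(full$correlation, 1)

  # two disjoint-seed 1000-marker subsets agree strongly with each other
  set.seed(41)
  s1 <- sample(ncol(pop$genotypes), 1000)
  s2 <- sample(ncol(pop$genotypes), 1000)
  r <- matrix_correlation(build_GA_snp(pop$genotypes[, s1]),
                          build_GA_snp(pop$genotypes[, s2]))
  expect_gt(r, 0.9)
})
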