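## small descriptor config so tests stay fast
desc_small <- function(seqs) compute_descriptors(seqs, paac_lambda = 8L,
                                                 nlag = 8L)

test_that("composition descriptors follow their closed forms", {
  X <- desc_small(c(a = paste(rep("A", 30), collapse = "")))
  expect_equal(unname(X[1, "AAC:A"]), 1)
  expect_equal(sum(X[1, grep("^AAC:", colnames(X))]), 1)
  expect_equal(unname(X[1, "GAAC:aliphatic"]), 1)
  ## AAC / GAAC rows sum to 1 for arbitrary sequences
  set.seed(47)
  X2 <- desc_small(setNames(vapply(1:5, function(i) random_protein(40),
                                   character(1)), paste0("s", 1:5)))
  expect_equal(unname(rowSums(X2[, grep("^AAC:", colnames(X2))])),
               rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(rowSums(X2[, grep("^GAAC:", colnames(X2))])),
               rep(1, 5), tolerance = 1e-9)
})

test_that("CTD transition counting matches direct evaluation", {
  ## "ARA" under the hydrophobicity partition: A in g2, R in g1 ->
  ## two g1<->g2 transitions over len-1 = 2 -> 1.0
  s <- paste0("ARA", paste(rep("A", 27), collapse = ""))
  X <- desc_small(c(x = s))
  chars <- strsplit(s, "")[[1]]
  g <- ifelse(chars == "R", 1L, 2L)
  trans12 <- sum((g[-length(g)] == 1 & g[-1] == 2) |
                   (g[-length(g)] == 2 & g[-1] == 1)) / (length(g) - 1)
  expect_equal(unname(X[1, "CTDT:hydrophobicity.g12"]), trans12)
  expect_equal(unname(X[1, "CTDC:hydrophobicity.g1"]), mean(g == 1))
})

test_that("Moran autocorrelation matches a hand evaluation of the formula", {
  set.seed(49)
  s <- random_protein(40)
  X <- compute_descriptors(c(x = s), paac_lambda = 5L, nlag = 5L,
                           autocorr_props = "CIDH920105")
  props <- ferriscan:::aaindex_properties("CIDH920105")[[1]]
  p <- (props - mean(props)) / sqrt(mean((props - mean(props))^2))
  xv <- p[strsplit(s, "")[[1]]]
  L <- length(xv); d <- 3L
  i <- seq_len(L - d)
  moran <- (sum((xv[i] - mean(xv)) * (xv[i + d] - mean(xv))) / (L - d)) /
    (sum((xv - mean(xv))^2) / L)
  expect_equal(unname(X[1, "Moran:CIDH920105.lag3"]), moran,
               tolerance = 1e-12)
  geary <- (sum((xv[i] - xv[i + d])^2) / (2 * (L - d))) /
    (sum((xv - mean(xv))^2) / (L - 1))
  expect_equal(unname(X[1, "Geary:CIDH920105.lag3"]), geary,
               tolerance = 1e-12)
})

test_that("descriptors are invariant to record order and reject bad input", {
  set.seed(53)
  seqs <- setNames(vapply(1:4, function(i) random_protein(50),
                          character(1)), paste0("s", 1:4))
  X1 <- desc_small(seqs)
  X2 <- desc_small(rev(seqs))
  expect_equal(X1[rownames(X2), ], X2[, ], ignore_attr = TRUE)
  expect_error(desc_small(c(bad = "MKXV")), "standard residues")
  expect_error(desc_small(c(short = "MKV")), "too short")
})

test_that("Laplacian score matches an independent implementation and finds the informative feature", {
  set.seed(59)
  ## two well-separated clusters along feature 1; features 2-4 noise
  f1 <- c(rnorm(10, -5, 0.3), rnorm(10, 5, 0.3))
  X <- cbind(f1, matrix(rnorm(60), 20, 3))
  colnames(X) <- paste0("f", 1:4)
  sel <- select_features(X, "laplacian_score")
  expect_equal(sel$ranking[1], 1L)
  ## closed-form oracle on standardized data
  Xs <- scale(X)
  expect_equal(sel$score, brute_laplacian_score(Xs), tolerance = 1e-8)
  ## and on random matrices up to 20 x 10
  for (k in 1:5) {
    Xr <- matrix(rnorm(15 * 8), 15, 8)
    s1 <- select_features(Xr, "laplacian_score")$score
    expect_equal(s1, brute_laplacian_score(scale(Xr)), tolerance = 1e-8)
  }
})

test_that("duplicated columns receive equal scores in all five algorithms", {
  set.seed(61)
  X <- matrix(rnorm(12 * 5), 12, 5)
  X <- cbind(X, X[, 2])  # column 6 duplicates column 2
  for (alg in c("laplacian_score", "SPEC", "MCFS", "NDFS", "UDFS")) {
    s <- select_features(X, alg, seed = 5L)$score
    ## MCFS solves its sparse regression iteratively; duplicates agree
    ## to numerical (not exact) precision there
    tol <- if (alg == "MCFS") 1e-3 else 1e-6
    expect_equal(s[2], s[6], tolerance = tol, info = alg)
  }
})

test_that("constant features get the worst rank and are flagged", {
  set.seed(67)
  X <- cbind(matrix(rnorm(10 * 4), 10, 4), rep(3, 10))
  for (alg in c("laplacian_score", "SPEC", "MCFS", "NDFS", "UDFS")) {
    sel <- select_features(X, alg, seed = 2L)
    expect_true(sel$constant[5], info = alg)
    expect_equal(sel$ranking[5], 5L, info = alg)
  }
})

test_that("selectors are permutation-equivariant and seed-deterministic", {
  set.seed(71)
  X <- matrix(rnorm(14 * 6), 14, 6)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  for (alg in c("laplacian_score", "SPEC", "MCFS", "NDFS", "UDFS")) {
    s1 <- select_features(X, alg, seed = 4L)$score
    s2 <- select_features(X[, perm], alg, seed = 4L)$score
    tol <- if (alg == "MCFS") 1e-3 else 1e-6
    expect_equal(s2, s1[perm], tolerance = tol, info = alg)
  }
  for (alg in c("MCFS", "NDFS", "UDFS")) {
    r1 <- select_features(X, alg, seed = 9L)
    r2 <- select_features(X, alg, seed = 9L)
    expect_identical(r1$score, r2$score, info = alg)
    expect_identical(r1$ranking, r2$ranking, info = alg)
  }
})

test_that("top-k union follows set arithmetic", {
  r1 <- 1:10; r2 <- 1:10
  expect_equal(union_top_k(list(r1, r2), k = 5), 1:5)
  expect_length(union_top_k(list(1:10, 11:20, 21:30), k = 5), 15)
  set.seed(73)
  ranks <- lapply(1:5, function(i) sample(600))
  u <- union_top_k(ranks, k = 100)
  expect_equal(sort(u), sort(Reduce(union, lapply(ranks, head, 100))))
  expect_lte(length(u), 500)
  expect_error(union_top_k(list(1:5, 1:6), k = 2), "same column set")
  expect_error(union_top_k(list(1:5), k = 6), "exceeds")
})

test_that("PCA matches an eigendecomposition oracle and reconstructs the input", {
  ## collinear points: PC1 explains everything
  X <- cbind(1:10, 2 * (1:10))
  p <- pca_project(X, 2)
  expect_equal(p$explained[1], 1)
  set.seed(79)
  X <- matrix(rnorm(50), 10, 5)
  p <- pca_project(X, 5)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eg <- eigen(cov(Xc))
  for (k in 1:5) {
    expect_equal(abs(drop(crossprod(p$loadings[, k], eg$vectors[, k]))),
                 1, tolerance = 1e-8)
  }
  expect_equal(p$explained, eg$values / sum(eg$values),
               tolerance = 1e-10)
  ## full reconstruction of the centered matrix
  expect_equal(p$scores %*% t(p$loadings), Xc, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_error(pca_project(matrix(1, 5, 3), 2), "zero variance")
})

test_that("selected features separate SP from SP-less classes better than random subsets", {
  ## qualitative end-to-end analogue of the published projection: on a
  ## synthetic family the between/within variance ratio of PC1-2 scores
  ## for the selected subset beats an equal-size random subset
  fam <- generate_family(n_per_class = c(conservative = 8L,
                                         atypical = 0L, SP = 8L),
                         seed = 83L)
  X <- desc_small(fam$records)
  lab <- rep(c("noSP", "SP"), each = 8)
  ratio <- function(sc) {
    mu <- colMeans(sc)
    between <- 0; within <- 0
    for (g in unique(lab)) {
      sg <- sc[lab == g, , drop = FALSE]
      between <- between + nrow(sg) * sum((colMeans(sg) - mu)^2)
      within <- within + sum(sweep(sg, 2, colMeans(sg))^2)
    }
    between / within
  }
  sels <- lapply(c("laplacian_score", "SPEC", "MCFS", "NDFS", "UDFS"),
                 function(a) select_features(X, a, seed = 17L))
  u <- union_top_k(sels, k = 40L)
  sel_ratio <- ratio(pca_project(X[, u, drop = FALSE], 2)$scores)
  set.seed(17)
  rand_ratios <- vapply(1:20, function(i) {
    cols <- sample(ncol(X), length(u))
    ratio(pca_project(X[, cols, drop = FALSE], 2)$scores)
  }, numeric(1))
  expect_gt(sel_ratio, median(rand_ratios))
})
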