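## Protein descriptor computation, five unsupervised feature-selection
## algorithms, top-k union, and PCA projection.

## ---- descriptor property tables ------------------------------------------

## CTD: seven physicochemical attributes, each splitting the 20 residues
## into three groups (standard PROFEAT partitions).
CTD_GROUPS <- list(
  hydrophobicity = c(g1 = "RKEDQN", g2 = "GASTPHY", g3 = "CLVIMFW"),
  vdw_volume     = c(g1 = "GASTPDC", g2 = "NVEQIL", g3 = "MHKFRYW"),
  polarity       = c(g1 = "LIFWCMVY", g2 = "PATGS", g3 = "HQRKNED"),
  polarizability = c(g1 = "GASDT", g2 = "CPNVEQIL", g3 = "KMHFRYW"),
  charge         = c(g1 = "KR", g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  secondary_structure = c(g1 = "EALMQKRH", g2 = "VIYCWFT", g3 = "GNPSD"),
  solvent_accessibility = c(g1 = "ALFCGIVW", g2 = "RKQEND", g3 = "MSPTHY"))

GAAC_GROUPS <- c(aliphatic = "GAVLMI", aromatic = "FYW", positive = "KRH",
                 negative = "DE", uncharged = "STCPNQ")

## Pseudo amino acid composition property tables (Chou's standard set):
## hydrophobicity, hydrophilicity, side-chain mass.
PAAC_HYDROPHOBICITY <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90,
  C = 0.29, Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06,
  K = -1.50, M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
  Y = 0.26, V = 1.08)
PAAC_HYDROPHILICITY <- c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0,
  Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
  M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3,
  V = -1.5)
PAAC_SIDECHAIN_MASS <- c(A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72,
  E = 73, G = 1, H = 82, I = 57, L = 57, K = 73, M = 75, F = 91, P = 42,
  S = 31, T = 45, W = 130, Y = 107, V = 43)

## AAindex accessions used by default for the autocorrelation descriptors;
## numeric values are pulled from the AAindex copy shipped with seqinr.
AUTOCORR_DEFAULT_PROPS <- c("CIDH920105", "BHAR880101", "CHAM820101",
                            "CHAM820102", "CHOC760101", "BIGC670101",
                            "CHAM810101", "DAYM780201")

aaindex_properties <- function(accessions = AUTOCORR_DEFAULT_PROPS) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- env$aaindex
  acc <- vapply(aaindex, function(e) e$H, character(1))
  out <- lapply(accessions, function(a) {
    k <- match(a, acc)
    if (is.na(k)) stop("AAindex accession not found: ", a)
    v <- aaindex[[k]]$I
    one <- seqinr::a(names(v))  # three-letter -> one-letter codes
    setNames(as.numeric(v), one)[PROTEIN_ALPHABET]
  })
  names(out) <- accessions
  out
}

## ---- individual descriptors ----------------------------------------------

aac_descriptor <- function(chars) {
  f <- table(factor(chars, levels = PROTEIN_ALPHABET)) / length(chars)
  setNames(as.numeric(f), paste0("AAC:", PROTEIN_ALPHABET))
}

gaac_descriptor <- function(chars) {
  f <- vapply(GAAC_GROUPS, function(g)
    mean(chars %in% strsplit(g, "")[[1]]), numeric(1))
  setNames(f, paste0("GAAC:", names(GAAC_GROUPS)))
}

paac_descriptor <- function(chars, lambda = 30L, w = 0.05) {
  L <- length(chars)
  props <- list(PAAC_HYDROPHOBICITY, PAAC_HYDROPHILICITY,
                PAAC_SIDECHAIN_MASS)
  ## each property standardized over the 20 residues (population sd)
  norm <- lapply(props, function(p) {
    p <- p[PROTEIN_ALPHABET]
    (p - mean(p)) / sqrt(mean((p - mean(p))^2))
  })
  theta <- vapply(seq_len(lambda), function(k) {
    i <- seq_len(L - k)
    mean(vapply(norm, function(p)
      mean((p[chars[i + k]] - p[chars[i]])^2), numeric(1)))
  }, numeric(1))
  f <- as.numeric(table(factor(chars, levels = PROTEIN_ALPHABET))) / L
  denom <- sum(f) + w * sum(theta)
  c(setNames(f / denom, paste0("PAAC:", PROTEIN_ALPHABET)),
    setNames(w * theta / denom, paste0("PAAC:lambda", seq_len(lambda))))
}

ctd_descriptor <- function(chars) {
  L <- length(chars)
  out <- numeric(0)
  for (prop in names(CTD_GROUPS)) {
    gs <- lapply(CTD_GROUPS[[prop]], function(g) strsplit(g, "")[[1]])
    gidx <- integer(L)
    for (k in 1:3) gidx[chars %in% gs[[k]]] <- k
    ## composition
    comp <- vapply(1:3, function(k) mean(gidx == k), numeric(1))
    names(comp) <- paste0("CTDC:", prop, ".g", 1:3)
    ## transition (both directions pooled)
    pairs <- cbind(gidx[-L], gidx[-1])
    tr <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p)
      sum((pairs[, 1] == p[1] & pairs[, 2] == p[2]) |
          (pairs[, 1] == p[2] & pairs[, 2] == p[1])) / (L - 1),
      numeric(1))
    names(tr) <- paste0("CTDT:", prop, ".g", c("12", "13", "23"))
    ## distribution: relative positions of the 1st/25%/50%/75%/100%
    ## occurrence of each group (0 when the group is absent)
    dis <- numeric(0)
    for (k in 1:3) {
      pos <- which(gidx == k)
      n <- length(pos)
      v <- if (n == 0L) rep(0, 5) else {
        cuts <- pmax(1L, c(1L, floor(0.25 * n), floor(0.5 * n),
                           floor(0.75 * n), n))
        100 * pos[cuts] / L
      }
      names(v) <- paste0("CTDD:", prop, ".g", k, ".",
                         c("first", "p25", "p50", "p75", "p100"))
      dis <- c(dis, v)
    }
    out <- c(out, comp, tr, dis)
  }
  out
}

autocorr_descriptor <- function(chars, props, nlag = 30L) {
  L <- length(chars)
  out <- numeric(0)
  for (pn in names(props)) {
    p <- props[[pn]]
    p <- (p - mean(p)) / sqrt(mean((p - mean(p))^2))
    x <- p[chars]
    xbar <- mean(x)
    devsq <- sum((x - xbar)^2)
    for (d in seq_len(nlag)) {
      i <- seq_len(L - d)
      moran <- if (devsq > 0)
        (sum((x[i] - xbar) * (x[i + d] - xbar)) / (L - d)) /
        (devsq / L) else 0
      geary <- if (devsq > 0)
        (sum((x[i] - x[i + d])^2) / (2 * (L - d))) /
        (devsq / (L - 1)) else 0
      nmbroto <- sum(x[i] * x[i + d]) / (L - d)
      out <- c(out, setNames(c(moran, geary, nmbroto),
                             paste0(c("Moran:", "Geary:", "NMBroto:"),
                                    pn, ".lag", d)))
    }
  }
  out
}

#' Compute protein sequence descriptors
#'
#' Computes, per sequence: amino acid composition (AAC, 20), grouped
#' composition (GAAC, 5), pseudo amino acid composition (PAAC, 20 +
#' lambda), composition/transition/distribution over seven property
#' partitions (CTD, 147), and Moran, Geary and normalized Moreau-Broto
#' autocorrelations over a configurable AAindex property set with lags
#' `1..nlag`.
#'
#' @param records List of [ferritin_record()]s, or a character vector of
#'   protein sequences (named by id).
#' @param paac_lambda,paac_w PAAC rank parameter and weight (defaults 30,
#'   0.05).
#' @param nlag Maximum autocorrelation lag (default 30).
#' @param autocorr_props AAindex accessions for the autocorrelation
#'   property set (default: eight standard indices).
#' @return A numeric matrix (class `feature_matrix`): rows = sequences,
#'   columns = `descriptor:parameter` names; attribute `provenance` maps
#'   each column to its descriptor family.
#' @export
compute_descriptors <- function(records, paac_lambda = 30L, paac_w = 0.05,
                                nlag = 30L,
                                autocorr_props = AUTOCORR_DEFAULT_PROPS) {
  seqs <- if (is.character(records)) records
  else setNames(vapply(records, function(r) r$protein, character(1)),
                vapply(records, function(r) r$id, character(1)))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  props <- aaindex_properties(autocorr_props)
  rows <- lapply(seq_along(seqs), function(i) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    if (any(!chars %in% PROTEIN_ALPHABET))
      stop("sequence '", names(seqs)[i],
           "': descriptors require the 20 standard residues")
    L <- length(chars)
    if (L <= max(paac_lambda, nlag))
      stop("sequence '", names(seqs)[i], "' is too short (", L,
           " aa) for PAAC lambda/autocorrelation nlag = ",
           max(paac_lambda, nlag))
    c(aac_descriptor(chars), gaac_descriptor(chars),
      paac_descriptor(chars, paac_lambda, paac_w), ctd_descriptor(chars),
      autocorr_descriptor(chars, props, nlag))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- names(seqs)
  prov <- sub(":.*$", "", colnames(X))
  structure(X, provenance = prov, class = c("feature_matrix", "matrix",
                                            "array"))
}

## ---- unsupervised feature selection --------------------------------------

## kNN heat-kernel affinity graph; bandwidth = mean squared kNN distance.
knn_heat_graph <- function(X, k_neighbors = 5L) {
  n <- nrow(X)
  k <- min(k_neighbors, n - 1L)
  Dm <- as.matrix(dist(X))
  W <- matrix(0, n, n)
  knn_d2 <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(Dm[i, ])[-1][seq_len(k)]
    W[i, ord] <- 1
    knn_d2 <- c(knn_d2, Dm[i, ord]^2)
  }
  t <- mean(knn_d2)
  if (t <= 0) t <- 1
  A <- exp(-Dm^2 / t)
  W <- pmax(W, t(W)) * A   # symmetrized kNN mask, heat-kernel weights
  diag(W) <- 0
  W
}

laplacian_score_raw <- function(X, k_neighbors = 5L) {
  W <- knn_heat_graph(X, k_neighbors)
  d <- rowSums(W)
  n <- nrow(X)
  vapply(seq_len(ncol(X)), function(j) {
    f <- X[, j]
    ftil <- f - sum(f * d) / sum(d)
    den <- sum(d * ftil^2)
    if (den < 1e-12) return(Inf)  # constant feature: worst score
    num <- sum(ftil * (d * ftil - W %*% ftil))
    num / den
  }, numeric(1))
}

spec_score_raw <- function(X, k_neighbors = 5L) {
  W <- knn_heat_graph(X, k_neighbors)
  d <- rowSums(W)
  dh <- sqrt(pmax(d, 1e-12))
  n <- nrow(X)
  Lnorm <- diag(n) - t(W / dh) / dh  # I - D^-1/2 W D^-1/2
  xi1 <- dh / sqrt(sum(dh^2))        # trivial eigenvector
  vapply(seq_len(ncol(X)), function(j) {
    fh <- dh * X[, j]
    nf <- sqrt(sum(fh^2))
    if (nf < 1e-12) return(Inf)
    fh <- fh / nf
    num <- drop(crossprod(fh, Lnorm %*% fh))
    den <- 1 - drop(crossprod(fh, xi1))^2
    if (den < 1e-12) return(Inf)
    num / den
  }, numeric(1))
}

spectral_embedding <- function(W, n_clusters) {
  d <- rowSums(W)
  dh <- sqrt(pmax(d, 1e-12))
  S <- t(W / dh) / dh
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  keep <- seq_len(min(n_clusters + 1L, ncol(eg$vectors)))[-1]
  Y <- eg$vectors[, keep, drop = FALSE] / dh
  ## fix the eigenvector sign deterministically
  for (j in seq_len(ncol(Y))) {
    s <- sign(Y[which.max(abs(Y[, j])), j])
    if (s < 0) Y[, j] <- -Y[, j]
  }
  Y
}

mcfs_score_raw <- function(X, k_neighbors = 5L, n_clusters = 2L,
                           enet_alpha = 0.9) {
  W <- knn_heat_graph(X, k_neighbors)
  Y <- spectral_embedding(W, n_clusters)
  scores <- matrix(0, ncol(X), ncol(Y))
  for (k in seq_len(ncol(Y))) {
    ## very tight threshold: the flat direction spanned by (near-)
    ## duplicate columns converges slowly in coordinate descent
    fit <- suppressWarnings(
      glmnet::glmnet(X, Y[, k], alpha = enet_alpha,
                     standardize = FALSE, thresh = 1e-16))
    co <- as.matrix(fit$beta)
    scores[, k] <- abs(co[, ncol(co)])  # densest end of the path
  }
  apply(scores, 1, max)
}

ndfs_score_raw <- function(X, k_neighbors = 5L, n_clusters = 2L,
                           alpha = 1, beta = 1, gamma = 1e8,
                           max_iter = 100L, tol = 1e-6, seed = 1L) {
  n <- nrow(X); d <- ncol(X)
  W <- knn_heat_graph(X, k_neighbors)
  L <- diag(rowSums(W)) - W
  ## nonnegative cluster-indicator init from seeded kmeans on the data
  set.seed(seed)
  cl <- kmeans(X, centers = min(n_clusters, n - 1L), nstart = 5)$cluster
  Fm <- matrix(0, n, max(cl))
  Fm[cbind(seq_len(n), cl)] <- 1
  Fm <- Fm + 0.2
  Dw <- diag(d)
  XtX <- crossprod(X)
  obj_prev <- Inf
  converged <- FALSE
  Wm <- NULL
  for (it in seq_len(max_iter)) {
    Tm <- solve(XtX + beta * Dw + 1e-6 * diag(d))
    Wm <- Tm %*% crossprod(X, Fm)
    wn <- pmax(sqrt(rowSums(Wm^2)), 1e-8)
    Dw <- diag(1 / (2 * wn), d)
    M <- L + alpha * (diag(n) - X %*% Tm %*% t(X))
    denom <- M %*% Fm + gamma * Fm %*% crossprod(Fm)
    Fm <- Fm * (gamma * Fm) / pmax(denom, 1e-10)
    obj <- sum(diag(crossprod(Fm, M %*% Fm))) + beta * sum(wn)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) <= tol * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(score = sqrt(rowSums(Wm^2)), converged = converged)
}

udfs_score_raw <- function(X, k_neighbors = 5L, n_clusters = 2L,
                           gamma = 0.1, reg = 1e-6, max_iter = 100L,
                           tol = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  k <- min(k_neighbors, n - 1L)
  Dm <- as.matrix(dist(X))
  H <- diag(k + 1L) - matrix(1 / (k + 1L), k + 1L, k + 1L)
  Mn <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- c(i, order(Dm[i, ])[-1][seq_len(k)])
    Xi <- X[idx, , drop = FALSE]
    Bi <- solve(H %*% Xi %*% t(Xi) %*% H + reg * diag(k + 1L))
    Mn[idx, idx] <- Mn[idx, idx] + H %*% Bi %*% H
  }
  M <- crossprod(X, Mn %*% X)
  M <- (M + t(M)) / 2
  Dw <- diag(d)
  c_use <- min(n_clusters, d)
  obj_prev <- Inf
  converged <- FALSE
  Wm <- NULL
  for (it in seq_len(max_iter)) {
    P <- M + gamma * Dw
    eg <- eigen((P + t(P)) / 2, symmetric = TRUE)
    Wm <- eg$vectors[, d - seq_len(c_use) + 1L, drop = FALSE]
    wn <- pmax(sqrt(rowSums(Wm^2)), 1e-8)
    Dw <- diag(1 / (2 * wn), d)
    obj <- sum(diag(crossprod(Wm, M %*% Wm))) + gamma * sum(wn)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) <= tol * max(1, abs(obj_prev))) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  list(score = sqrt(rowSums(Wm^2)), converged = converged)
}

#' Score features with an unsupervised selection algorithm
#'
#' Five algorithms: Laplacian score (smaller is better), SPEC spectral
#' ranking on the normalized Laplacian (smaller is better), MCFS via
#' spectral embedding plus an L1-regularized regression path (larger is
#' better), and the iterative l2,1-regularized NDFS and UDFS objectives
#' (larger row-norm is better).  Features are standardized internally;
#' constant features receive the worst possible score and are flagged.
#' The ranking is a stable sort in the algorithm's preference direction
#' with ties broken by column index.
#'
#' @param X Feature matrix (rows = sequences), e.g. from
#'   [compute_descriptors()].
#' @param algorithm One of `"laplacian_score"`, `"SPEC"`, `"MCFS"`,
#'   `"NDFS"`, `"UDFS"`.
#' @param k_neighbors Neighborhood size of the affinity graph (default 5).
#' @param n_clusters Embedding dimension for MCFS/NDFS/UDFS (default 2).
#' @param max_iter,tol Iteration budget and relative objective tolerance
#'   for NDFS/UDFS (defaults 100, 1e-6).
#' @param seed Seed for stochastic initializations (NDFS k-means).
#' @return Object of class `selection_result`: list with `algorithm`,
#'   `score`, `ranking` (a permutation of column indices, best first),
#'   `direction`, `constant` (flag per feature) and `converged`.
#' @export
select_features <- function(X, algorithm = c("laplacian_score", "SPEC",
                                             "MCFS", "NDFS", "UDFS"),
                            k_neighbors = 5L, n_clusters = 2L,
                            max_iter = 100L, tol = 1e-6, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(nrow(X) >= 3)
  constant <- apply(X, 2, function(v) max(v) - min(v) < 1e-12)
  Xs <- scale(X)
  Xs[, constant] <- 0
  converged <- TRUE
  res <- switch(algorithm,
    laplacian_score = list(score = laplacian_score_raw(Xs, k_neighbors)),
    SPEC = list(score = spec_score_raw(Xs, k_neighbors)),
    MCFS = list(score = mcfs_score_raw(Xs, k_neighbors, n_clusters)),
    NDFS = ndfs_score_raw(Xs, k_neighbors, n_clusters,
                          max_iter = max_iter, tol = tol, seed = seed),
    UDFS = udfs_score_raw(Xs, k_neighbors, n_clusters,
                          max_iter = max_iter, tol = tol))
  score <- res$score
  if (!is.null(res$converged)) converged <- res$converged
  direction <- if (algorithm %in% c("laplacian_score", "SPEC"))
    "smaller" else "larger"
  worst <- if (direction == "smaller") Inf else -Inf
  score[constant] <- worst
  key <- if (direction == "smaller") score else -score
  ranking <- order(key, seq_along(score))
  structure(list(algorithm = algorithm, score = score, ranking = ranking,
                 direction = direction, constant = constant,
                 converged = converged),
            class = "selection_result")
}

#' Union of per-algorithm top-k features
#'
#' @param rankings List of rankings (each a `selection_result` or an
#'   integer permutation of the same column set), in a fixed algorithm
#'   order.
#' @param k Number of leading features to take from each ranking
#'   (default 100).
#' @return Integer vector of column indices: the set union of the five
#'   top-k lists, ordered by first appearance across algorithms.
#' @export
union_top_k <- function(rankings, k = 100L) {
  ranks <- lapply(rankings, function(r)
    if (inherits(r, "selection_result")) r$ranking else as.integer(r))
  lens <- unique(vapply(ranks, length, integer(1)))
  if (length(lens) != 1L)
    stop("all rankings must cover the same column set")
  if (k > lens) stop("k exceeds the number of columns")
  unique(unlist(lapply(ranks, head, k)))
}

#' PCA projection of a feature subset
#'
#' Column-centered (not scaled) principal component analysis via
#' [stats::prcomp()].
#'
#' @param X Numeric matrix (rows = sequences).
#' @param n_components Number of components (at most
#'   `min(nrow - 1, ncol)`).
#' @return List with `scores` (rows x components), `loadings`
#'   (orthonormal columns) and `explained` (variance fractions,
#'   non-increasing).
#' @export
pca_project <- function(X, n_components = 2L) {
  stopifnot(nrow(X) > 1, n_components >= 1,
            n_components <= min(nrow(X) - 1L, ncol(X)))
  if (sum(apply(X, 2, stats::var)) < 1e-300)
    stop("pca_project: input has zero variance")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  list(scores = p$x[, keep, drop = FALSE],
       loadings = p$rotation[, keep, drop = FALSE],
       explained = (p$sdev^2 / sum(p$sdev^2))[keep])
}
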