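## Independent reference implementations used as oracles.  These are
## deliberately written top-down / by direct enumeration, separate from the
## package's own code paths.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n,
                                       replace = TRUE), collapse = "")

## -- alignment score oracle: memoized recursion over all gapped alignments
## of the two suffixes, affine gaps (open + (L-1)*ext), end gaps free.
## prev: "M" match column, "X" gap-in-ref run, "Y" gap-in-query run;
## leading runs ("X0"/"Y0", adjacent to the start) are free, trailing
## remainders are free.
oracle_align_score <- function(q, r, mat, open = 10, ext = 0.5) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  memo <- new.env(parent = emptyenv())
  rec2 <- function(i, j, prev) {
    if (i > n || j > m) return(0)  # trailing gap run is free
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    diag_val <- mat[qc[i], rc[j]] + rec2(i + 1, j + 1, "M")
    x_free <- prev %in% c("X0", "S0")   # leading gap run: free
    y_free <- prev %in% c("Y0", "S0")
    gapq <- if (prev == "X") -ext else if (x_free) 0 else -open
    x_val <- gapq + rec2(i + 1, j, if (x_free) "X0" else "X")
    gapr <- if (prev == "Y") -ext else if (y_free) 0 else -open
    y_val <- gapr + rec2(i, j + 1, if (y_free) "Y0" else "Y")
    best <- max(diag_val, x_val, y_val)
    memo[[key]] <- best
    best
  }
  rec2(1, 1, "S0")  # start: first gap run on either side is free
}

## -- IUPAC brute-force matcher (regex-free, explicit per-position sets)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A","G"), Y = c("C","T"), S = c("C","G"),
                   W = c("A","T"), K = c("G","T"), M = c("A","C"),
                   B = c("C","G","T"), D = c("A","G","T"),
                   H = c("A","C","T"), V = c("A","C","G"),
                   N = c("A","C","G","T"))
IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

iupac_revcomp <- function(pattern) {
  paste(rev(unname(IUPAC_COMP[strsplit(pattern, "")[[1]]])),
        collapse = "")
}

brute_iupac_scan <- function(sequence, pattern, max_mismatches = 0L,
                             both_strands = TRUE) {
  scan1 <- function(pat, strand) {
    pc <- strsplit(pat, "")[[1]]
    sc <- strsplit(sequence, "")[[1]]
    w <- length(pc); n <- length(sc)
    if (w > n) return(NULL)
    rows <- list()
    for (s in seq_len(n - w + 1L)) {
      mm <- 0L
      for (k in seq_len(w))
        if (!(sc[s + k - 1L] %in% IUPAC_SETS[[pc[k]]])) mm <- mm + 1L
      if (mm <= max_mismatches)
        rows[[length(rows) + 1L]] <- data.frame(start = s,
                                                end = s + w - 1L,
                                                strand = strand,
                                                mismatches = mm)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  out <- scan1(pattern, "+")
  if (both_strands) out <- rbind(out, scan1(iupac_revcomp(pattern), "-"))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## -- CpG island brute force (naive per-window loop + coverage runs)
brute_cpg <- function(sequence, window = 100L, min_len = 200L,
                      min_gc = 50, min_oe = 0.6) {
  sc <- strsplit(sequence, "")[[1]]
  n <- length(sc)
  if (n < window) return(data.frame(start = integer(0),
                                    end = integer(0)))
  covered <- logical(n)
  for (s in seq_len(n - window + 1L)) {
    win <- sc[s:(s + window - 1L)]
    nC <- sum(win == "C"); nG <- sum(win == "G")
    nCG <- sum(win[-window] == "C" & win[-1] == "G")
    gc <- 100 * (nC + nG) / window
    oe <- if (nC > 0 && nG > 0) nCG * window / (nC * nG) else 0
    if (gc >= min_gc && oe >= min_oe)
      covered[s:(s + window - 1L)] <- TRUE
  }
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

## -- exact PWM p-value by enumeration of all 20^w windows
brute_pwm_pvalue <- function(lods_int, background, score_int) {
  w <- ncol(lods_int)
  grid <- expand.grid(rep(list(seq_len(20)), w))
  tot <- 0
  for (rowi in seq_len(nrow(grid))) {
    idx <- as.integer(grid[rowi, ])
    sc <- sum(lods_int[cbind(idx, seq_len(w))])
    if (sc >= score_int) tot <- tot + prod(background[idx])
  }
  tot
}

## -- Laplacian score closed form, independent graph construction
brute_laplacian_score <- function(X, k = 5L) {
  n <- nrow(X)
  k <- min(k, n - 1L)
  D2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D2[i, j] <- sum((X[i, ] - X[j, ])^2)
  nb <- matrix(FALSE, n, n)
  d2s <- numeric(0)
  for (i in seq_len(n)) {
    ord <- order(sqrt(D2[i, ]))[-1][seq_len(k)]
    nb[i, ord] <- TRUE
    d2s <- c(d2s, D2[i, ord])
  }
  t <- mean(d2s); if (t <= 0) t <- 1
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && (nb[i, j] || nb[j, i])) W[i, j] <- exp(-D2[i, j] / t)
  dd <- rowSums(W)
  ones <- rep(1, n)
  L <- diag(dd) - W
  vapply(seq_len(ncol(X)), function(col) {
    f <- X[, col]
    ft <- f - as.numeric((f %*% dd) / (ones %*% dd)) * ones
    den <- as.numeric(t(ft) %*% diag(dd) %*% ft)
    if (den < 1e-12) return(Inf)
    as.numeric(t(ft) %*% L %*% ft) / den
  }, numeric(1))
}

## -- IRE hit structural re-validation (independent pairing checker)
check_ire_hit <- function(utr, hit) {
  x <- strsplit(chartr("Uu", "Tt", toupper(utr)), "")[[1]]
  pairs_ok <- function(a, b) paste0(a, b) %in% c("AT","TA","GC","CG",
                                                 "GT","TG")
  l <- hit$loop_start
  loop <- paste(x[l:(l + 5)], collapse = "")
  if (!grepl("^CAGTG[ACT]$", loop)) return(FALSE)
  up5 <- x[(l - 5):(l - 1)]; up3 <- x[(l + 6):(l + 10)]
  if (!all(mapply(pairs_ok, up5, rev(up3)))) return(FALSE)
  if (hit$bulge_type == "C") {
    if (x[l - 6] != "C") return(FALSE)
    lo5 <- l - 7L; lo3 <- l + 11L
  } else {
    if (paste(x[(l - 8):(l - 6)], collapse = "") != "TGC") return(FALSE)
    if (x[l + 11] != "C") return(FALSE)
    lo5 <- l - 9L; lo3 <- l + 12L
  }
  len <- hit$lower_stem_len
  if (len < 3) return(FALSE)
  for (k in 0:(len - 1))
    if (!pairs_ok(x[lo5 - k], x[lo3 + k])) return(FALSE)
  hit$start == lo5 - len + 1L && hit$end == lo3 + len - 1L
}
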