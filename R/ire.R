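## Combinatorial prediction of iron-responsive element (IRE) stem-loops in
## 5' UTRs: apical loop CAGUGH, a 5-bp upper stem of Watson-Crick or G.U
## pairs, a C-bulge (or UGC/C mismatch bulge) on the 5' arm immediately
## below the upper stem, and a lower stem of >= 3 pairs.  Pattern plus
## pairing constraints only -- no thermodynamic folding -- following the
## architecture used by SIREs-style predictors; the quality grades are an
## approximation of that scheme.

ire_pairs <- function(a, b) {
  ## allowed: Watson-Crick and G.U wobble (DNA alphabet, T == U)
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

ire_is_wc <- function(a, b) paste0(a, b) %in% c("AT", "TA", "GC", "CG")

#' Find iron-responsive elements in a 5' UTR
#'
#' Scans for the canonical IRE architecture around every apical-loop match
#' `CAGUGH` (`H` = A, C or U).  Reported quality is `high` for a C-bulge
#' with an all-Watson-Crick upper stem, `medium` for one G.U pair in the
#' upper stem or a UGC/C mismatch bulge, and `low` otherwise; `low` hits
#' are only reported when `allow_variants` is set.  Overlapping hits are
#' all reported.
#'
#' @param utr RNA or DNA string (T and U are equivalent); at least 25 nt.
#' @param allow_variants Report `low` quality variants as well.
#' @param min_lower_stem Minimum lower-stem pairing (default 3 bp).
#' @param best_only Keep only the best hit (highest quality, then
#'   5'-most).
#' @return data.frame of hits: `start`, `end` (1-based, spanning the full
#'   hairpin), `loop_start`, `loop_seq` (RNA letters), `loop_pairing`
#'   (whether loop C1.G5 can pair), `bulge_type` (`"C"` or `"UGC"`),
#'   `upper_gu` (G.U pairs in the upper stem), `lower_stem_len`,
#'   `quality`.
#' @export
find_ire <- function(utr, allow_variants = FALSE, min_lower_stem = 3L,
                     best_only = FALSE) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      loop_start = integer(0), loop_seq = character(0),
                      loop_pairing = logical(0), bulge_type = character(0),
                      upper_gu = integer(0), lower_stem_len = integer(0),
                      quality = character(0), stringsAsFactors = FALSE)
  seq <- normalize_dna(utr)
  n <- nchar(seq)
  if (n < 25) {
    warning("UTR shorter than 25 nt; no IRE search performed")
    return(empty)
  }
  x <- strsplit(seq, "")[[1]]
  loop_starts <- which(vapply(seq_len(n - 5L), function(l)
    x[l] == "C" && x[l + 1] == "A" && x[l + 2] == "G" && x[l + 3] == "T" &&
      x[l + 4] == "G" && x[l + 5] %in% c("A", "C", "T"), logical(1)))
  out <- empty
  for (l in loop_starts) {
    for (bulge in c("C", "UGC")) {
      b5 <- if (bulge == "C") 1L else 3L   # extra nt on the 5' arm
      b3 <- if (bulge == "C") 0L else 1L   # extra nt on the 3' arm
      up5_start <- l - 5L
      lo5_end <- up5_start - b5 - 1L       # innermost lower-stem 5' base
      up3_start <- l + 6L
      lo3_start <- up3_start + 5L + b3     # innermost lower-stem 3' base
      if (up5_start - b5 < 1L || lo3_start + min_lower_stem - 1L > n ||
          lo5_end - min_lower_stem + 1L < 1L) next
      ## bulge content
      if (bulge == "C") {
        if (x[up5_start - 1L] != "C") next
      } else {
        if (paste(x[(up5_start - 3L):(up5_start - 1L)],
                  collapse = "") != "TGC") next
        if (x[up3_start + 5L] != "C") next
      }
      ## upper stem: 5 pairs, arm positions pair inside-out
      up5 <- x[up5_start:(up5_start + 4L)]
      up3 <- x[up3_start:(up3_start + 4L)]
      prs <- mapply(ire_pairs, up5, rev(up3))
      if (!all(prs)) next
      gu <- sum(!mapply(ire_is_wc, up5, rev(up3)))
      ## lower stem: consecutive pairs outward from the innermost pair
      len <- 0L
      while (lo5_end - len >= 1L && lo3_start + len <= n &&
             ire_pairs(x[lo5_end - len], x[lo3_start + len]))
        len <- len + 1L
      if (len < min_lower_stem) next
      quality <- if (bulge == "C" && gu == 0L) "high"
      else if ((bulge == "C" && gu == 1L) || (bulge == "UGC" && gu == 0L))
        "medium"
      else "low"
      if (quality == "low" && !allow_variants) next
      loop_seq <- chartr("T", "U", paste(x[l:(l + 5L)], collapse = ""))
      out <- rbind(out, data.frame(
        start = lo5_end - len + 1L, end = lo3_start + len - 1L,
        loop_start = l, loop_seq = loop_seq,
        loop_pairing = ire_pairs(x[l], x[l + 4L]),
        bulge_type = bulge, upper_gu = gu, lower_stem_len = len,
        quality = quality, stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$start, out$loop_start), , drop = FALSE]
  rownames(out) <- NULL
  if (best_only && nrow(out) > 1L) {
    rank <- match(out$quality, c("high", "medium", "low"))
    out <- out[order(rank, out$start), , drop = FALSE][1, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
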