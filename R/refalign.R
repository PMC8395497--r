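## Global pairwise alignment against the human ferritin heavy chain (HuHF)
## and mapping of query residues to conventional HuHF numbering.

#' Packaged human ferritin heavy-chain reference
#'
#' Returns the amino acid sequence of the human ferritin heavy chain
#' (UniProt P02794), the reference against which identity, similarity and
#' functional-domain replacements are computed.
#'
#' @return A single character string (183 residues, starting with the
#'   initial methionine).
#' @export
huhf_reference <- function() {
  rec <- read_fasta(fs_extdata("huhf.fasta"), alphabet = "protein")
  rec$sequence[[1]]
}

#' Read a substitution matrix in NCBI/EMBOSS text format
#'
#' Parses the whitespace-separated matrix layout used by NCBI BLAST and the
#' EMBOSS data files (comment lines starting with `#`, a header row of
#' residue letters, one labelled row per residue).
#'
#' @param path Path to a matrix file. Default: the packaged EBLOSUM62 copy.
#' @return A numeric matrix with residue letters as row and column names.
#' @export
read_substitution_matrix <- function(path = fs_extdata("EBLOSUM62")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  if (!isTRUE(all.equal(rownames(vals), colnames(vals))))
    stop("substitution matrix must have identical row and column labels")
  vals
}

## Encode residues as 1-based indices into the matrix alphabet.  Residues
## absent from the matrix fall back to the 'X' row when present, otherwise
## they score the matrix minimum (handled by adding a synthetic row).
encode_for_matrix <- function(seq, matrix) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, rownames(matrix))
  if (anyNA(idx)) {
    xi <- match("X", rownames(matrix))
    if (!is.na(xi)) idx[is.na(idx)] <- xi
    else stop("residue(s) absent from substitution matrix: ",
              paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Global pairwise alignment with Needle-style scoring
#'
#' Needleman-Wunsch alignment under affine gap penalties with unpenalized
#' end gaps, as in the EMBOSS Needle tool with its default end-gap setting.
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`.  Identity is
#' the percentage of identical columns over the full alignment length
#' (gap columns included); similarity the percentage of columns whose
#' residue pair has a positive substitution score.  Among co-optimal
#' alignments the traceback deterministically prefers a match column over a
#' gap in the reference over a gap in the query, so identity of reported
#' co-optima may differ from other implementations by a column or two.
#'
#' @param query,reference Protein sequences (plain character strings).
#' @param matrix Substitution matrix as returned by
#'   [read_substitution_matrix()]; default BLOSUM62.
#' @param gap_open,gap_extend Gap penalties (positive numbers); defaults
#'   10 and 0.5 follow Needle.
#' @return An object of class `pairwise_alignment`: a list with
#'   `aligned_query`, `aligned_ref` (gapped strings of equal length),
#'   `score`, `identity_pct`, `similarity_pct` and `gaps` (gap columns).
#' @export
global_align <- function(query, reference,
                         matrix = read_substitution_matrix(),
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  if (!nzchar(query) || !nzchar(reference))
    stop("global_align requires non-empty sequences")
  q <- encode_for_matrix(query, matrix)
  r <- encode_for_matrix(reference, matrix)
  res <- .needle_align(q, r, matrix, gap_open, gap_extend)
  alpha <- rownames(matrix)
  decode <- function(v) paste(c("-", alpha)[v + 1L], collapse = "")
  aq <- decode(res$q)
  ar <- decode(res$r)
  qc <- strsplit(aq, "")[[1]]
  rc <- strsplit(ar, "")[[1]]
  len <- length(qc)
  both <- qc != "-" & rc != "-"
  ident <- sum(both & qc == rc)
  pair_scores <- matrix[cbind(match(qc[both], alpha),
                              match(rc[both], alpha))]
  simil <- sum(pair_scores > 0)
  structure(list(
    aligned_query = aq,
    aligned_ref = ar,
    score = res$score,
    identity_pct = 100 * ident / len,
    similarity_pct = 100 * simil / len,
    gaps = sum(!both)
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "Global alignment: length %d, score %.1f, identity %.1f%%, similarity %.1f%%, gaps %d\n",
    nchar(x$aligned_query), x$score, x$identity_pct, x$similarity_pct,
    x$gaps))
  invisible(x)
}

#' Map query residues to conventional HuHF numbering
#'
#' Conventional HuHF numbering starts after the reference's initial
#' methionine: the residue following M is number 1.  Every aligned query
#' residue receives the number of its reference column; query residues
#' opposite a reference gap are unaligned (`NA`).
#'
#' @param alignment A `pairwise_alignment` whose `aligned_ref` is the
#'   reference the numbering should follow.
#' @return Object of class `reference_numbering`: integer vector of length
#'   `nchar(query)` with the HuHF number of each query residue, `NA` where
#'   unaligned. Attribute `ref_offset` records how reference positions were
#'   shifted (1 when the reference starts with M, 0 otherwise).
#' @export
map_to_reference_numbering <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  qc <- strsplit(alignment$aligned_query, "")[[1]]
  rc <- strsplit(alignment$aligned_ref, "")[[1]]
  ref_seq <- gsub("-", "", alignment$aligned_ref, fixed = TRUE)
  offset <- if (startsWith(ref_seq, "M")) 1L else {
    warning("reference does not start with methionine; ",
            "numbering starts at its first residue")
    0L
  }
  rpos <- cumsum(rc != "-")       # 1-based position within reference
  qidx <- which(qc != "-")
  num <- ifelse(rc[qidx] != "-", rpos[qidx] - offset, NA_integer_)
  num[!is.na(num) & num < 1L] <- NA_integer_  # query vs the initial M itself
  structure(as.integer(num), class = "reference_numbering",
            ref_offset = offset)
}
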