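## Domain records, FASTA/TSV reading and GFF3 writing shared by all stages.

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                      "Q","R","S","T","V","W","Y")
DNA_ALPHABET <- c("A","C","G","T")
IUPAC_DNA <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A","G"), Y = c("C","T"), S = c("C","G"),
                  W = c("A","T"), K = c("G","T"), M = c("A","C"),
                  B = c("C","G","T"), D = c("A","G","T"),
                  H = c("A","C","T"), V = c("A","C","G"),
                  N = c("A","C","G","T"))

#' Construct a ferritin record
#'
#' One protein sequence with its optional companions: a 5' UTR, a promoter
#' region with a declared transcription start site, a signal-peptide flag
#' (an upstream annotation, e.g. from SignalP; never predicted here) and a
#' free-text taxonomy group label.
#'
#' @param id Record identifier.
#' @param protein Amino acid sequence (uppercase; `X` allowed).
#' @param description Free-text description.
#' @param sp_flag One of `"present"`, `"absent"`, `"unknown"`.
#' @param group Group label such as `"Insecta"`, `"Porifera"`, `"other"`.
#' @param utr5 Optional 5' UTR sequence (DNA or RNA; U is normalized to T).
#' @param promoter Optional promoter/genomic DNA string.
#' @param tss_index 1-based index of the first transcribed base within
#'   `promoter`; required when `promoter` is given.
#' @return An object of class `ferritin_record`.
#' @export
ferritin_record <- function(id, protein, description = "",
                            sp_flag = c("unknown", "present", "absent"),
                            group = "other", utr5 = NULL, promoter = NULL,
                            tss_index = NULL) {
  sp_flag <- match.arg(sp_flag)
  protein <- toupper(protein)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(protein), length(protein) == 1L, nzchar(protein))
  bad <- setdiff(unique(strsplit(protein, "")[[1]]),
                 c(PROTEIN_ALPHABET, "X"))
  if (length(bad))
    stop("record '", id, "': illegal protein character(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(utr5)) utr5 <- normalize_dna(utr5, id)
  if (!is.null(promoter)) {
    promoter <- normalize_dna(promoter, id)
    if (is.null(tss_index) || tss_index < 1 || tss_index > nchar(promoter))
      stop("record '", id, "': tss_index must lie within the promoter")
    tss_index <- as.integer(tss_index)
  }
  structure(list(id = id, description = description, protein = protein,
                 sp_flag = sp_flag, group = group, utr5 = utr5,
                 promoter = promoter, tss_index = tss_index),
            class = "ferritin_record")
}

normalize_dna <- function(seq, id = "?") {
  seq <- chartr("u", "t", tolower(seq))
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_DNA))
  if (length(bad))
    stop("record '", id, "': illegal DNA character '", chars[bad[1]],
         "' at position ", bad[1])
  seq
}

#' @export
print.ferritin_record <- function(x, ...) {
  cat(sprintf("<ferritin_record> %s [%s, SP %s]: %d aa%s%s\n", x$id,
              x$group, x$sp_flag, nchar(x$protein),
              if (!is.null(x$utr5)) sprintf(", 5'UTR %d nt", nchar(x$utr5))
              else "",
              if (!is.null(x$promoter))
                sprintf(", promoter %d bp (TSS @ %d)", nchar(x$promoter),
                        x$tss_index) else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] and validates records against the
#' declared alphabet.  Sequences are uppercased, line wrapping removed,
#' a trailing `*` (stop) stripped in protein mode, and `U` normalized to
#' `T` in RNA mode.
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"`, `"dna"` or `"rna"`.
#' @return A data.frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (alphabet == "protein") seqs <- sub("\\*$", "", seqs)
  if (alphabet == "rna") seqs <- chartr("U", "T", seqs)
  ok <- switch(alphabet,
               protein = c(PROTEIN_ALPHABET, "X"),
               dna = names(IUPAC_DNA),
               rna = names(IUPAC_DNA))
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[[k]])) stop("record '", ids[[k]], "': empty sequence")
    chars <- strsplit(seqs[[k]], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad))
      stop("record '", ids[[k]], "': illegal ", alphabet, " character '",
           chars[bad[1]], "' at position ", bad[1])
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read the signal-peptide / group sidecar TSV
#'
#' Columns `id`, `sp_flag`, `group`.  Records absent from the sidecar get
#' `sp_flag = "unknown"` and `group = "other"`.
#'
#' @param path TSV path.
#' @param ids Optional character vector of record ids to complete.
#' @return data.frame with columns `id`, `sp_flag`, `group`.
#' @export
read_sidecar <- function(path, ids = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sp_flag", "group")
  if (!all(need %in% names(tab)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$sp_flag), c("present", "absent", "unknown"))
  if (length(bad)) stop("invalid sp_flag value(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(ids)) {
    miss <- setdiff(ids, tab$id)
    if (length(miss))
      tab <- rbind(tab[need],
                   data.frame(id = miss, sp_flag = "unknown",
                              group = "other"))
    tab <- tab[match(ids, tab$id), need]
    rownames(tab) <- NULL
  }
  tab
}

#' Convert absolute to TSS-relative coordinates
#'
#' Signed no-zero convention: the first transcribed base is +1 and the base
#' immediately upstream is -1 (so, for absolute position `a` and TSS at
#' `t`, the value is `a - t + 1` when `a >= t` and `a - t` otherwise).
#'
#' @param abs_pos Absolute 1-based position(s).
#' @param tss_index Absolute 1-based position of the TSS.
#' @return Signed integer(s), never 0.
#' @export
tss_relative <- function(abs_pos, tss_index) {
  stopifnot(tss_index >= 1)
  as.integer(ifelse(abs_pos >= tss_index, abs_pos - tss_index + 1L,
                    abs_pos - tss_index))
}

#' Convert TSS-relative back to absolute coordinates
#'
#' Inverse of [tss_relative()].
#' @param rel_pos Signed TSS-relative position(s) (never 0).
#' @param tss_index Absolute 1-based position of the TSS.
#' @return Absolute 1-based positions.
#' @export
tss_absolute <- function(rel_pos, tss_index) {
  stopifnot(all(rel_pos != 0))
  as.integer(ifelse(rel_pos > 0, rel_pos + tss_index - 1L,
                    rel_pos + tss_index))
}

#' Write located features as GFF3
#'
#' Features carry 1-based inclusive absolute coordinates and a strand; the
#' TSS-relative start is stored in the `tss_start` attribute when a
#' `tss_index` is supplied.  Output is valid GFF3 that round-trips through
#' [rtracklayer::import()].
#'
#' @param hits data.frame with columns `start`, `end`, `type` and
#'   optionally `strand`, `name`, `score`; extra columns become GFF3
#'   attributes.
#' @param seq_id Name of the annotated sequence.
#' @param path Output file.
#' @param seq_length Length of the sequence, for bounds checking.
#' @param tss_index Optional TSS position used for the relative attribute.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(hits, seq_id, path, seq_length = NULL,
                       tss_index = NULL) {
  if (is.null(hits) || nrow(hits) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  stopifnot(all(c("start", "end", "type") %in% names(hits)))
  if (any(hits$end < hits$start)) stop("feature end < start")
  if (any(hits$start < 1)) stop("feature start < 1")
  if (!is.null(seq_length) && any(hits$end > seq_length))
    stop("feature outside sequence bounds")
  strand <- if ("strand" %in% names(hits)) hits$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = strand)
  GenomicRanges::mcols(gr)$type <- hits$type
  if ("score" %in% names(hits)) GenomicRanges::mcols(gr)$score <- hits$score
  extras <- setdiff(names(hits), c("start", "end", "type", "strand",
                                   "score"))
  for (col in extras) GenomicRanges::mcols(gr)[[col]] <- hits[[col]]
  if (!is.null(tss_index))
    GenomicRanges::mcols(gr)$tss_start <-
      as.character(tss_relative(hits$start, tss_index))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
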