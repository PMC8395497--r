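## Promoter annotation: IUPAC motif scanning on both strands, HRE + HAS
## compound calls with the 7-15 bp spacing rule, CpG island detection.

#' Read a motif catalog
#'
#' YAML list of motifs, each with `name`, an IUPAC degenerate `pattern`,
#' `max_mismatches` and `strands` (`both` or `forward`).  The shipped
#' default covers MRE, HRE, HAS, TATA, Inr, DPE, GC box, NFkB, NRF1 and
#' CsMBE consensus strings taken from the literature.
#'
#' @param path YAML path; default the packaged catalog.
#' @return List of motif definitions.
#' @export
read_motif_catalog <- function(path = fs_extdata("motif_catalog.yaml")) {
  raw <- yaml::read_yaml(path)$motifs
  lapply(raw, function(m) motif_definition(m$name, m$pattern,
                                           m$max_mismatches %||% 0L,
                                           m$strands %||% "both"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define an IUPAC motif
#'
#' @param name Motif name.
#' @param pattern IUPAC degenerate DNA string (15-letter code).
#' @param max_mismatches Allowed mismatches per window (>= 0).
#' @param strands `"both"` or `"forward"`.
#' @return A `motif_definition` list.
#' @export
motif_definition <- function(name, pattern, max_mismatches = 0L,
                             strands = c("both", "forward")) {
  strands <- match.arg(strands)
  pattern <- toupper(pattern)
  bad <- setdiff(unique(strsplit(pattern, "")[[1]]), names(IUPAC_DNA))
  if (length(bad))
    stop("motif '", name, "': non-IUPAC character(s): ",
         paste(bad, collapse = ", "))
  stopifnot(max_mismatches >= 0)
  structure(list(name = name, pattern = pattern,
                 max_mismatches = as.integer(max_mismatches),
                 strands = strands),
            class = "motif_definition")
}

#' Fuzzy IUPAC motif scan
#'
#' Reports every window matching the degenerate pattern with at most
#' `max_mismatches` mismatching positions, via
#' [Biostrings::matchPattern()] with pattern ambiguities enabled.  The
#' reverse strand is scanned by matching the reverse-complement pattern;
#' its hits are reported in forward-axis coordinates with `strand = "-"`.
#'
#' @param sequence DNA string.
#' @param motif A [motif_definition()].
#' @param tss_index Optional TSS position; adds TSS-relative starts.
#' @return data.frame of hits: `motif`, `start`, `end`, `strand`,
#'   `matched`, `mismatches` (plus `tss_start` when `tss_index` given),
#'   sorted by `start` then strand.
#' @export
fuzzy_scan <- function(sequence, motif, tss_index = NULL) {
  sequence <- normalize_dna(sequence)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(motif$pattern)
  scan_one <- function(p, strand) {
    if (length(p) > length(subj))
      return(NULL)
    m <- Biostrings::matchPattern(p, subj,
                                  max.mismatch = motif$max_mismatches,
                                  with.indels = FALSE, fixed = "subject")
    if (length(m) == 0L) return(NULL)
    starts <- BiocGenerics::start(m)
    ends <- BiocGenerics::end(m)
    ## drop matches overhanging the sequence ends
    keep <- starts >= 1L & ends <= length(subj)
    if (!any(keep)) return(NULL)
    starts <- starts[keep]; ends <- ends[keep]
    mm <- Biostrings::neditStartingAt(p, subj, starting.at = starts,
                                      with.indels = FALSE,
                                      fixed = "subject")
    data.frame(motif = motif$name, start = starts, end = ends,
               strand = strand,
               matched = substring(sequence, starts, ends),
               mismatches = as.integer(mm),
               stringsAsFactors = FALSE)
  }
  out <- scan_one(pat, "+")
  if (motif$strands == "both") {
    rc <- Biostrings::reverseComplement(pat)
    rev_hits <- scan_one(rc, "-")
    out <- rbind(out, rev_hits)
  }
  if (is.null(out))
    out <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  ## palindromic patterns produce the same window on both strands; keep both
  rownames(out) <- NULL
  if (!is.null(tss_index)) out$tss_start <- tss_relative(out$start,
                                                         tss_index)
  out
}

#' Pair HRE hits with downstream HAS hits
#'
#' A hypoxia response element is called robust when a hypoxia ancillary
#' sequence lies 7-15 bp downstream on the same strand.  The gap counts
#' the bases strictly between the HRE 3' end and the HAS 5' start in the
#' motif's own 5'->3' sense; on the minus strand downstream means
#' decreasing forward-axis coordinates.
#'
#' @param hre_hits,has_hits Hit data.frames from [fuzzy_scan()] over the
#'   same sequence.
#' @param min_gap,max_gap Inclusive spacing bounds (defaults 7, 15).
#' @return data.frame of composite hits with the HRE and HAS coordinates,
#'   strand and `gap`.
#' @export
pair_hre_has <- function(hre_hits, has_hits, min_gap = 7L, max_gap = 15L) {
  empty <- data.frame(hre_start = integer(0), hre_end = integer(0),
                      has_start = integer(0), has_end = integer(0),
                      strand = character(0), gap = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hre_hits) || is.null(has_hits) ||
      nrow(hre_hits) == 0L || nrow(has_hits) == 0L) return(empty)
  out <- empty
  for (i in seq_len(nrow(hre_hits))) {
    h <- hre_hits[i, ]
    same <- has_hits[has_hits$strand == h$strand, , drop = FALSE]
    if (nrow(same) == 0L) next
    gap <- if (h$strand == "+") same$start - h$end - 1L
    else h$start - same$end - 1L
    keep <- which(gap >= min_gap & gap <= max_gap)
    if (length(keep))
      out <- rbind(out, data.frame(
        hre_start = h$start, hre_end = h$end,
        has_start = same$start[keep], has_end = same$end[keep],
        strand = h$strand, gap = as.integer(gap[keep]),
        stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Detect CpG islands (Gardiner-Garden & Frommer criteria)
#'
#' Slides a window of `window` bp with step `shift`; a window qualifies
#' when its GC percentage is at least `min_gc` and its observed/expected
#' CpG ratio, `count(CG) * window / (count(C) * count(G))`, is at least
#' `min_oe` (ratio 0 when C or G is absent).  Overlapping or adjacent
#' qualifying windows are merged; merged regions shorter than `min_len`
#' are discarded; GC% and Obs/Exp are recomputed over each island.
#' Truncated trailing windows are not evaluated.
#'
#' @param sequence DNA string.
#' @param window,shift Window size and step in bp (defaults 100, 1).
#' @param min_len Minimum island length (default 200 bp).
#' @param min_gc Minimum GC percentage (default 50).
#' @param min_oe Minimum Obs/Exp CpG ratio (default 0.6).
#' @return data.frame of islands: `start`, `end`, `length`, `gc_pct`,
#'   `obs_exp`.
#' @export
detect_cpg_islands <- function(sequence, window = 100L, shift = 1L,
                               min_len = 200L, min_gc = 50, min_oe = 0.6) {
  sequence <- normalize_dna(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_pct = numeric(0),
                      obs_exp = numeric(0))
  n <- nchar(sequence)
  if (n < window) {
    warning("sequence shorter than the window; no islands evaluated")
    return(empty)
  }
  chars <- strsplit(sequence, "")[[1]]
  isC <- as.integer(chars == "C")
  isG <- as.integer(chars == "G")
  isCG <- as.integer(chars[-n] == "C" & chars[-1] == "G")
  cumC <- c(0L, cumsum(isC)); cumG <- c(0L, cumsum(isG))
  cumCG <- c(0L, cumsum(isCG))
  starts <- seq.int(1L, n - window + 1L, by = shift)
  nC <- cumC[starts + window] - cumC[starts]
  nG <- cumG[starts + window] - cumG[starts]
  ## CG dinucleotides fully inside the window: starts s .. s + w - 2
  nCG <- cumCG[pmin(starts + window - 2L, n - 1L) + 1L] - cumCG[starts]
  gc <- 100 * (nC + nG) / window
  oe <- ifelse(nC > 0 & nG > 0, nCG * window / (nC * nG), 0)
  ok <- which(gc >= min_gc & oe >= min_oe)
  if (length(ok) == 0L) return(empty)
  spans <- IRanges::reduce(IRanges::IRanges(start = starts[ok],
                                            width = window))
  spans <- spans[IRanges::width(spans) >= min_len]
  if (length(spans) == 0L) return(empty)
  st <- IRanges::start(spans); en <- IRanges::end(spans)
  iC <- cumC[en + 1L] - cumC[st]
  iG <- cumG[en + 1L] - cumG[st]
  iCG <- cumCG[pmin(en - 1L, n - 1L) + 1L] - cumCG[st]
  len <- en - st + 1L
  data.frame(start = st, end = en, length = len,
             gc_pct = 100 * (iC + iG) / len,
             obs_exp = ifelse(iC > 0 & iG > 0, iCG * len / (iC * iG), 0))
}

#' Annotate a promoter with motifs, HRE/HAS pairs and CpG islands
#'
#' Runs [fuzzy_scan()] for every catalog motif, [pair_hre_has()] on the
#' HRE and HAS hit sets, and [detect_cpg_islands()], reporting all
#' coordinates both absolute and TSS-relative.
#'
#' @param record A [ferritin_record()] with `promoter` and `tss_index`.
#' @param catalog Motif catalog (list of [motif_definition()]); default
#'   the packaged one.
#' @param cpg_params Named list overriding [detect_cpg_islands()]
#'   defaults.
#' @return Object of class `promoter_report`: list with `id`, `motifs`,
#'   `composites`, `cpg_islands`, `tss_index`.
#' @export
scan_promoter <- function(record, catalog = read_motif_catalog(),
                          cpg_params = list()) {
  if (is.null(record$promoter) || is.null(record$tss_index)) {
    warning("record '", record$id, "' has no promoter; skipped")
    return(NULL)
  }
  hits <- do.call(rbind, lapply(catalog, function(m)
    fuzzy_scan(record$promoter, m, tss_index = record$tss_index)))
  if (is.null(hits))
    hits <- fuzzy_scan(paste(rep("A", 1), collapse = ""),
                       motif_definition("none", "C"))[0, ]
  comp <- pair_hre_has(hits[hits$motif == "HRE", , drop = FALSE],
                       hits[hits$motif == "HAS", , drop = FALSE])
  if (nrow(comp))
    comp$tss_start <- tss_relative(comp$hre_start, record$tss_index)
  cpg <- do.call(detect_cpg_islands,
                 c(list(sequence = record$promoter), cpg_params))
  if (nrow(cpg)) cpg$tss_start <- tss_relative(cpg$start,
                                               record$tss_index)
  structure(list(id = record$id, motifs = hits, composites = comp,
                 cpg_islands = cpg, tss_index = record$tss_index),
            class = "promoter_report")
}

#' @export
print.promoter_report <- function(x, ...) {
  cat(sprintf(
    "<promoter_report> %s: %d motif hit(s), %d HRE+HAS pair(s), %d CpG island(s)\n",
    x$id, nrow(x$motifs), nrow(x$composites), nrow(x$cpg_islands)))
  invisible(x)
}

#' Write a promoter report as GFF3
#'
#' One feature per motif hit, composite HRE+HAS hit and CpG island, with
#' TSS-relative starts as attributes.
#'
#' @param report A `promoter_report`.
#' @param path Output file.
#' @param seq_length Optional sequence length for bounds checking.
#' @return `path`, invisibly.
#' @export
promoter_report_gff3 <- function(report, path, seq_length = NULL) {
  feats <- list()
  if (nrow(report$motifs))
    feats$motifs <- data.frame(start = report$motifs$start,
                               end = report$motifs$end,
                               type = "TF_binding_site",
                               strand = report$motifs$strand,
                               name = report$motifs$motif,
                               stringsAsFactors = FALSE)
  if (nrow(report$composites))
    feats$comp <- data.frame(
      start = pmin(report$composites$hre_start,
                   report$composites$has_start),
      end = pmax(report$composites$hre_end, report$composites$has_end),
      type = "regulatory_region", strand = report$composites$strand,
      name = "HRE_HAS", stringsAsFactors = FALSE)
  if (nrow(report$cpg_islands))
    feats$cpg <- data.frame(start = report$cpg_islands$start,
                            end = report$cpg_islands$end,
                            type = "CpG_island", strand = "*",
                            name = "CpG_island", stringsAsFactors = FALSE)
  hits <- if (length(feats)) do.call(rbind, feats) else NULL
  write_gff3(hits, report$id, path, seq_length = seq_length,
             tss_index = report$tss_index)
}
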