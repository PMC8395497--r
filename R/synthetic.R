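## Ground-truth generators: ferritin families with controlled divergence
## and planted domain replacements, promoters with planted motifs and CpG
## islands, 5' UTRs with planted IRE hairpins.  Every generator takes an
## explicit seed and restores the caller's RNG state on exit.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic ferritin family with known class labels
#'
#' Conservative members mutate only non-domain sites of the reference, at
#' the per-site `background_divergence` rate (substitutions uniform over
#' the 19 alternatives).  Atypical members additionally receive
#' `atypical_domain_mutations` replacements drawn without replacement from
#' the configured domain positions.  SP members are conservative backbones
#' with a synthetic signal peptide prepended (positively charged
#' n-region, hydrophobic core, AxA cleavage motif) and
#' `sp_flag = "present"`; the peptide only exercises the annotation
#' pathway, it is not meant to fool a predictor.
#'
#' @param reference Reference protein (default: packaged HuHF).
#' @param n_per_class Named counts for `conservative`, `atypical`, `SP`.
#' @param background_divergence Per-site substitution probability in
#'   `[0, 0.5]`.
#' @param atypical_domain_mutations Domain replacements planted per
#'   atypical member (> 5 so the class rule holds with margin).
#' @param sp_peptide_length Signal peptide length in residues (>= 10).
#' @param domains Domain definitions ([read_domain_definitions()]).
#' @param group Group label assigned to all records.
#' @param seed Random seed.
#' @return List with `records` (list of [ferritin_record()]) and `truth`
#'   (per-record intended label and planted replacements, plus the
#'   generator parameters).
#' @export
generate_family <- function(reference = huhf_reference(),
                            n_per_class = c(conservative = 10L,
                                            atypical = 10L, SP = 10L),
                            background_divergence = 0.1,
                            atypical_domain_mutations = 7L,
                            sp_peptide_length = 20L,
                            domains = read_domain_definitions(),
                            group = "synthetic", seed = 1L) {
  stopifnot(background_divergence >= 0, background_divergence <= 0.5,
            sp_peptide_length >= 10)
  dom_tab <- do.call(rbind, domains)
  n_dom <- nrow(dom_tab)
  if (atypical_domain_mutations > n_dom)
    stop("requested domain mutations (", atypical_domain_mutations,
         ") exceed available domain positions (", n_dom, ")")
  ref <- strsplit(reference, "")[[1]]
  offset <- if (ref[1] == "M") 1L else 0L
  dom_idx <- dom_tab$position + offset       # string index in reference
  if (any(dom_idx > length(ref)))
    stop("reference shorter than the configured domain positions")
  free_idx <- setdiff(seq_along(ref), dom_idx)

  mutate_background <- function(chars) {
    hit <- free_idx[stats::runif(length(free_idx)) <
                      background_divergence]
    for (i in hit)
      chars[i] <- sample(setdiff(PROTEIN_ALPHABET, chars[i]), 1)
    chars
  }
  make_sp <- function() {
    core_len <- sp_peptide_length - 6L
    paste(c("M", sample(c("K", "R"), 2, replace = TRUE),
            sample(c("L", "V", "A", "I", "F"), core_len, replace = TRUE),
            "A", sample(PROTEIN_ALPHABET, 1), "A"), collapse = "")
  }

  with_seed(seed, {
    records <- list()
    truth <- list()
    counter <- 0L
    for (cls in c("conservative", "atypical", "SP")) {
      n <- n_per_class[[cls]]
      if (is.null(n) || n == 0L) next
      for (r in seq_len(n)) {
        counter <- counter + 1L
        id <- sprintf("syn%03d_%s", counter, cls)
        chars <- mutate_background(ref)
        planted <- character(0)
        if (cls == "atypical") {
          rows <- sample(n_dom, atypical_domain_mutations)
          for (k in rows) {
            pos <- dom_tab$position[k]
            new <- sample(setdiff(PROTEIN_ALPHABET,
                                  dom_tab$consensus[k]), 1)
            chars[pos + offset] <- new
            planted <- c(planted,
                         paste0(dom_tab$consensus[k], pos, new))
          }
        }
        protein <- paste(chars, collapse = "")
        sp_flag <- "absent"
        if (cls == "SP") {
          protein <- paste0(make_sp(), protein)
          sp_flag <- "present"
        }
        records[[id]] <- ferritin_record(id, protein, group = group,
                                         sp_flag = sp_flag)
        truth[[id]] <- list(label = if (cls == "SP") "SP_ferritin"
                            else cls,
                            planted_replacements = planted)
      }
    }
    list(records = unname(records),
         truth = list(records = truth,
                      params = list(
                        background_divergence = background_divergence,
                        atypical_domain_mutations =
                          atypical_domain_mutations,
                        sp_peptide_length = sp_peptide_length,
                        n_per_class = as.list(n_per_class),
                        seed = seed)))
  })
}

sample_dna <- function(n, gc = 0.4) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a promoter with planted regulatory features
#'
#' I.i.d. background at the requested GC fraction, with concrete motif
#' instances spliced in at TSS-relative positions and, optionally, a
#' GC-rich span with elevated CpG content (a synthetic CpG island,
#' regenerated until it satisfies GC >= 55% and Obs/Exp >= 0.7).
#'
#' @param length Promoter length in bp.
#' @param planted List of `list(name=, instance=, tss_rel=)`: a concrete
#'   sequence planted so its first base sits at the TSS-relative
#'   position.
#' @param cpg_island Optional `c(position, length)`: absolute start and
#'   length of a planted island.
#' @param tss_offset Absolute 1-based position of the TSS in the string.
#' @param gc_background Background GC fraction.
#' @param id Record id.
#' @param seed Random seed.
#' @return List with `record` (a [ferritin_record()] carrying the
#'   promoter; the protein slot holds a placeholder residue) and `truth`
#'   (planted features with absolute and TSS-relative coordinates).
#' @export
generate_promoter <- function(length = 2000L, planted = list(),
                              cpg_island = NULL, tss_offset = 1500L,
                              gc_background = 0.4, id = "syn_promoter",
                              seed = 1L) {
  stopifnot(tss_offset >= 1, tss_offset <= length)
  with_seed(seed, {
    chars <- sample_dna(length, gc_background)
    spans <- list()
    claim <- function(start, end, what) {
      if (start < 1 || end > length)
        stop("planted feature '", what, "' out of bounds [", start, ", ",
             end, "]")
      for (s in spans)
        if (start <= s$end && end >= s$start)
          stop("planted features overlap: '", what, "' [", start, ", ",
               end, "] vs '", s$what, "' [", s$start, ", ", s$end, "]")
      spans[[length(spans) + 1L]] <<- list(start = start, end = end,
                                           what = what)
    }
    truth_feats <- list()
    for (p in planted) {
      inst <- normalize_dna(p$instance)
      start <- tss_absolute(p$tss_rel, tss_offset)
      end <- start + nchar(inst) - 1L
      claim(start, end, p$name)
      chars[start:end] <- strsplit(inst, "")[[1]]
      truth_feats[[length(truth_feats) + 1L]] <-
        list(name = p$name, start = start, end = end,
             tss_rel = p$tss_rel, instance = inst)
    }
    island_truth <- NULL
    if (!is.null(cpg_island)) {
      st <- as.integer(cpg_island[[1]])
      len <- as.integer(cpg_island[[2]])
      en <- st + len - 1L
      claim(st, en, "cpg_island")
      for (try in 1:50) {
        isl <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.15, 0.35, 0.35, 0.15))
        s <- paste(isl, collapse = "")
        gc <- 100 * mean(isl %in% c("C", "G"))
        nC <- sum(isl == "C"); nG <- sum(isl == "G")
        nCG <- sum(isl[-len] == "C" & isl[-1] == "G")
        oe <- if (nC > 0 && nG > 0) nCG * len / (nC * nG) else 0
        if (gc >= 55 && oe >= 0.7) break
      }
      chars[st:en] <- isl
      island_truth <- list(start = st, end = en, length = len,
                           gc_pct = gc, obs_exp = oe)
    }
    record <- ferritin_record(id, "M", promoter = paste(chars,
                                                        collapse = ""),
                              tss_index = tss_offset)
    list(record = record,
         truth = list(motifs = truth_feats, cpg_island = island_truth,
                      tss_index = tss_offset,
                      params = list(length = length,
                                    gc_background = gc_background,
                                    seed = seed)))
  })
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chars <- function(chars) rev(unname(DNA_COMPLEMENT[chars]))

#' Generate a 5' UTR with one planted IRE
#'
#' Random background with a structurally valid IRE spliced at the given
#' offset: 5-bp lower and upper stems built as exact reverse complements,
#' a `CAGUGH` apical loop, and either a C-bulge or a UGC/C mismatch bulge.
#' The two background bases flanking the element are forced to `A` so the
#' lower stem cannot extend by chance and the planted coordinates are
#' exact.
#'
#' @param length UTR length in nt.
#' @param ire_position 1-based offset of the element's first base
#'   (`ire_position + 30 <= length`).
#' @param bulge_type `"C"` or `"UGC"`.
#' @param id Record id.
#' @param seed Random seed.
#' @return List with `record` (a [ferritin_record()] carrying `utr5`;
#'   placeholder protein) and `truth` (element coordinates and
#'   structure).
#' @export
generate_utr_with_ire <- function(length = 150L, ire_position = 12L,
                                  bulge_type = c("C", "UGC"),
                                  id = "syn_utr", seed = 1L) {
  bulge_type <- match.arg(bulge_type)
  if (ire_position < 1L || ire_position + 30L > length)
    stop("ire_position + 30 must be <= length")
  with_seed(seed, {
    lower5 <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    upper5 <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    loop <- c("C", "A", "G", "T", "G", sample(c("A", "C", "T"), 1))
    b5 <- if (bulge_type == "C") "C" else c("T", "G", "C")
    b3 <- if (bulge_type == "C") character(0) else "C"
    element <- c(lower5, b5, upper5, loop, revcomp_chars(upper5), b3,
                 revcomp_chars(lower5))
    chars <- sample_dna(length, gc = 0.5)
    st <- ire_position
    en <- st + length(element) - 1L
    chars[st:en] <- element
    if (st > 1L) chars[st - 1L] <- "A"
    if (en < length) chars[en + 1L] <- "A"
    record <- ferritin_record(id, "M",
                              utr5 = paste(chars, collapse = ""))
    loop_start <- st + 5L + length(b5) + 5L  # lower arm + bulge + upper arm
    list(record = record,
         truth = list(start = st, end = en, loop_start = loop_start,
                      bulge_type = bulge_type,
                      element = chartr("T", "U",
                                       paste(element, collapse = "")),
                      params = list(length = length,
                                    ire_position = ire_position,
                                    seed = seed)))
  })
}
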