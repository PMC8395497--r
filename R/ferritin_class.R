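## Functional-domain replacement counting, physicochemical properties,
## xRGG secretion-motif scanning and the three-way ferritin classification.

#' Read functional-domain definitions
#'
#' Loads the residue sets of the three HuHF functional domains (iron ion
#' channel, ferroxidase di-iron center, ferrihydrite nucleation site) from
#' a YAML file mapping consensus residues to HuHF numbers.  The shipped
#' default uses literature-standard residue sets, configured so the three
#' lists are disjoint.
#'
#' @param path YAML file; default the packaged catalog.
#' @return Named list of data.frames with columns `position` (HuHF number)
#'   and `consensus` (expected residue).
#' @export
read_domain_definitions <- function(path = fs_extdata("domains.yaml")) {
  raw <- yaml::read_yaml(path)
  doms <- lapply(raw, function(d) {
    df <- do.call(rbind, lapply(names(d), function(res) {
      data.frame(position = as.integer(d[[res]]), consensus = res)
    }))
    df[order(df$position), , drop = FALSE]
  })
  all_pos <- unlist(lapply(doms, `[[`, "position"))
  if (anyDuplicated(all_pos))
    stop("domain positions must be unique across domains")
  bad <- setdiff(unique(unlist(lapply(doms, `[[`, "consensus"))),
                 PROTEIN_ALPHABET)
  if (length(bad)) stop("invalid consensus residue(s): ",
                        paste(bad, collapse = ", "))
  doms
}

#' Count amino acid replacements in the functional domains
#'
#' A domain position counts as replaced when the query residue mapped to
#' that HuHF number differs from the consensus residue, or when the query
#' has no residue aligned there (deletions are counted so that truncated
#' sequences remain classifiable; such positions are flagged).
#'
#' @param query Query protein sequence (ungapped).
#' @param numbering [map_to_reference_numbering()] result for `query`
#'   aligned against the reference the domain positions refer to.
#' @param domains Domain definitions from [read_domain_definitions()].
#' @return Object of class `replacement_report`: list with `per_domain`
#'   (data.frames with `position`, `consensus`, `observed`, `label`,
#'   `unaligned`), `counts` per domain and `total`.
#' @export
count_domain_replacements <- function(query, numbering,
                                      domains = read_domain_definitions()) {
  stopifnot(inherits(numbering, "reference_numbering"))
  qc <- strsplit(query, "")[[1]]
  if (length(qc) != length(numbering))
    stop("numbering length does not match query length")
  per <- lapply(domains, function(dom) {
    obs <- character(nrow(dom))
    unal <- logical(nrow(dom))
    for (k in seq_len(nrow(dom))) {
      hit <- which(!is.na(numbering) & numbering == dom$position[k])
      if (length(hit) == 0L) {
        obs[k] <- "-"; unal[k] <- TRUE
      } else obs[k] <- qc[hit[1]]
    }
    repl <- unal | obs != dom$consensus
    data.frame(position = dom$position, consensus = dom$consensus,
               observed = obs,
               label = paste0(dom$consensus, dom$position,
                              ifelse(unal, "del", obs)),
               unaligned = unal, replaced = repl)
  })
  counts <- vapply(per, function(d) sum(d$replaced), integer(1))
  structure(list(per_domain = per, counts = counts,
                 total = sum(counts)),
            class = "replacement_report")
}

#' @export
print.replacement_report <- function(x, ...) {
  cat("Replacements in functional domains (HuHF numbering):\n")
  for (nm in names(x$per_domain)) {
    d <- x$per_domain[[nm]]
    lab <- d$label[d$replaced]
    cat(sprintf("  %-20s %d%s\n", nm, x$counts[[nm]],
                if (length(lab)) paste0(" (", paste(lab, collapse = ", "),
                                        ")") else ""))
  }
  cat("  total:", x$total, "\n")
  invisible(x)
}

## ExPASy average isotopic residue masses (Da) and the mass of one water.
AA_MONO_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water, as on the ExPASy server.
#'
#' @param protein Amino acid sequence; `X` is not allowed.
#' @return Mass in Da.
#' @export
molecular_weight <- function(protein) {
  chars <- strsplit(toupper(protein), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  if (any(!chars %in% names(AA_MONO_AVG)))
    stop("molecular_weight: sequence contains residues without a defined ",
         "mass: ", paste(unique(setdiff(chars, names(AA_MONO_AVG))),
                         collapse = ", "))
  sum(AA_MONO_AVG[chars]) + WATER_MASS
}

## Bjellqvist pK set as used by ExPASy: side chains plus residue-specific
## N-terminal pKs and C-terminal corrections for terminal D/E.
PK_SIDE <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00, R = 12.00,
             Y = 10.00)
PK_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.70, G = 7.50)
PK_NTERM_DEFAULT <- 7.50
PK_CTERM <- 3.55
PK_CTERM_SPECIAL <- c(D = 4.55, E = 4.75)

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the Bjellqvist pK set (C, D, E, H, K, R,
#' Y side chains plus the termini).  Strictly decreasing in pH.
#'
#' @param protein Amino acid sequence.
#' @param pH pH value(s).
#' @return Net charge(s).
#' @export
protein_charge <- function(protein, pH) {
  chars <- strsplit(toupper(protein), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  pos_pks <- c(PK_NTERM[chars[1]],
               rep(PK_SIDE["H"], sum(chars == "H")),
               rep(PK_SIDE["K"], sum(chars == "K")),
               rep(PK_SIDE["R"], sum(chars == "R")))
  pos_pks[is.na(pos_pks)] <- PK_NTERM_DEFAULT
  last <- chars[length(chars)]
  cterm_pk <- if (last %in% names(PK_CTERM_SPECIAL))
    PK_CTERM_SPECIAL[[last]] else PK_CTERM
  neg_pks <- c(cterm_pk,
               rep(PK_SIDE["D"], sum(chars == "D")),
               rep(PK_SIDE["E"], sum(chars == "E")),
               rep(PK_SIDE["C"], sum(chars == "C")),
               rep(PK_SIDE["Y"], sum(chars == "Y")))
  vapply(pH, function(p)
    sum(1 / (1 + 10^(p - pos_pks))) - sum(1 / (1 + 10^(neg_pks - p))),
    numeric(1))
}

#' Isoelectric point
#'
#' pH at which [protein_charge()] is zero, found by bisection on
#' `[0, 14]` to `|charge| < 1e-4` or a pH interval below 1e-3.
#'
#' @param protein Amino acid sequence.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(protein) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- protein_charge(protein, mid)
    if (abs(ch) < 1e-4 || (hi - lo) < 1e-3) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
}

#' Classify a ferritin as SP, conservative or atypical
#'
#' Sequences carrying a signal peptide are the SP class.  Among SP-less
#' sequences, a ferritin is atypical when it has less than
#' `identity_cut` percent identity with HuHF **or** more than
#' `replacement_cut` replacements across the three functional domains
#' (both inequalities strict); otherwise it is conservative.
#'
#' @param identity_with_ref Identity percentage with HuHF, in `[0, 100]`.
#' @param replacement_total Total domain replacements (non-negative).
#' @param sp_flag `"present"`, `"absent"` or `"unknown"`; unknown is
#'   treated as absent with a warning recorded in the result.
#' @param identity_cut,replacement_cut Class thresholds (defaults 49, 5).
#' @return Object of class `classification_result`: list with `label`
#'   (`"SP_ferritin"`, `"conservative"` or `"atypical"`), the inputs, the
#'   thresholds used and `warnings`.
#' @export
classify_ferritin <- function(identity_with_ref, replacement_total,
                              sp_flag = c("absent", "present", "unknown"),
                              identity_cut = 49, replacement_cut = 5) {
  sp_flag <- match.arg(sp_flag)
  stopifnot(identity_with_ref >= 0, identity_with_ref <= 100,
            replacement_total >= 0)
  warnings <- character(0)
  if (sp_flag == "unknown") {
    warnings <- "sp_flag unknown: treated as absent"
    sp_used <- "absent"
  } else sp_used <- sp_flag
  label <- if (sp_used == "present") "SP_ferritin"
  else if (identity_with_ref < identity_cut ||
           replacement_total > replacement_cut) "atypical"
  else "conservative"
  structure(list(label = label, identity_with_ref = identity_with_ref,
                 replacement_total = replacement_total, sp_flag = sp_flag,
                 identity_cut = identity_cut,
                 replacement_cut = replacement_cut, warnings = warnings),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s> identity %.1f%%, %d replacement(s), SP %s\n", x$label,
              x$identity_with_ref, x$replacement_total, x$sp_flag))
  invisible(x)
}

#' Build a position weight matrix from an aligned residue block
#'
#' Column j frequency of residue a is
#' `(count + pseudocount) / (rows + 20 * pseudocount)`.
#'
#' @param aligned_block Character vector of equal-length, gap-free
#'   residue strings (at least two).
#' @param pseudocount Non-negative pseudocount weight.
#' @return 20 x width matrix of probabilities; columns sum to 1.
#' @export
build_pwm <- function(aligned_block, pseudocount = 0.1) {
  stopifnot(length(aligned_block) >= 2, pseudocount >= 0)
  widths <- nchar(aligned_block)
  if (length(unique(widths)) != 1L)
    stop("aligned block rows must have equal length")
  rows <- do.call(rbind, strsplit(toupper(aligned_block), ""))
  if (any(!rows %in% PROTEIN_ALPHABET))
    stop("aligned block must contain standard residues only (no gaps)")
  w <- ncol(rows)
  pwm <- matrix(0, nrow = 20, ncol = w,
                dimnames = list(PROTEIN_ALPHABET, NULL))
  for (j in seq_len(w)) {
    cnt <- table(factor(rows[, j], levels = PROTEIN_ALPHABET))
    pwm[, j] <- (as.numeric(cnt) + pseudocount) /
      (nrow(rows) + 20 * pseudocount)
  }
  pwm
}

## Exact tail probability of the log-odds score under the background,
## by dynamic programming over scores discretized to `unit` bits
## (the FIMO approach).
pwm_pvalue_table <- function(lods_int, background) {
  ## lods_int: integer score matrix (20 x w); returns function(score_int)
  w <- ncol(lods_int)
  offset <- sum(apply(lods_int, 2, min))
  span <- sum(apply(lods_int, 2, max)) - offset
  dist <- c(1, rep(0, span))  # P(sum - offset = k), k = 0..span
  done <- 0
  for (j in seq_len(w)) {
    newdist <- rep(0, span + 1)
    mn <- min(lods_int[, j])
    for (a in seq_len(nrow(lods_int))) {
      shift <- lods_int[a, j] - mn
      nz <- which(dist > 0)
      newdist[nz + shift] <- newdist[nz + shift] +
        dist[nz] * background[a]
    }
    dist <- newdist
  }
  tail_p <- rev(cumsum(rev(dist)))
  function(score_int) {
    k <- score_int - offset
    if (k <= 0) return(1)
    if (k > span) return(0)
    tail_p[k + 1]
  }
}

#' Scan a protein for the xRGG secretion motif
#'
#' Slides a PWM over the sequence, scoring each window by the base-2
#' log-odds against a background residue distribution.  The best window is
#' reported with an exact p-value: the tail probability of its score under
#' the background, computed by dynamic programming over scores discretized
#' to 1/1000 bit.
#'
#' @param protein Amino acid sequence.
#' @param pwm PWM from [build_pwm()] (rows = 20 residues).
#' @param background Residue background frequencies (default uniform).
#' @return Object of class `motif_scan`: list with `start`, `end`,
#'   `score` (bits), `p_value`, `matched` (window string), or `NULL`
#'   fields and `no_hit = TRUE` when the protein is shorter than the PWM.
#' @export
scan_xrgg <- function(protein, pwm,
                      background = setNames(rep(1 / 20, 20),
                                            PROTEIN_ALPHABET)) {
  chars <- strsplit(toupper(protein), "")[[1]]
  w <- ncol(pwm)
  if (length(chars) < w)
    return(structure(list(no_hit = TRUE, start = NA_integer_,
                          end = NA_integer_, score = NA_real_,
                          p_value = NA_real_, matched = NA_character_),
                     class = "motif_scan"))
  background <- background[PROTEIN_ALPHABET]
  background <- background / sum(background)
  pwm <- pwm[PROTEIN_ALPHABET, , drop = FALSE]
  lods <- log2(pwm / as.numeric(background))
  unit <- 1 / 1000
  lods_int <- round(lods / unit)
  storage.mode(lods_int) <- "integer"
  idx <- match(chars, PROTEIN_ALPHABET)
  if (anyNA(idx)) stop("scan_xrgg: sequence contains X or non-standard ",
                       "residues")
  nwin <- length(chars) - w + 1L
  scores <- vapply(seq_len(nwin), function(s)
    sum(lods_int[cbind(idx[s:(s + w - 1L)], seq_len(w))]), integer(1))
  best <- which.max(scores)
  pfun <- pwm_pvalue_table(lods_int, as.numeric(background))
  structure(list(no_hit = FALSE, start = best, end = best + w - 1L,
                 score = scores[best] * unit,
                 p_value = pfun(scores[best]),
                 matched = paste(chars[best:(best + w - 1L)],
                                 collapse = "")),
            class = "motif_scan")
}

#' Benjamini-Hochberg q-values for a batch of motif scans
#'
#' @param scans List of `motif_scan` results for one sequence set.
#' @return The list with a `q_value` added to each scan (NA for no-hits).
#' @export
xrgg_qvalues <- function(scans) {
  p <- vapply(scans, function(s) s$p_value, numeric(1))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  for (k in seq_along(scans)) scans[[k]]$q_value <- q[k]
  scans
}
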