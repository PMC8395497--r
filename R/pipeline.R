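## Orchestration: batch classification, the full analysis pipeline and
## per-group summaries.

## 15-residue secretion-motif window in HuHF numbering: "QRGGRIFLQDIKKPD"
## starting at the xRGG motif (x = Q75).
XRGG_WINDOW_START <- 75L
XRGG_WINDOW_LEN <- 15L

extract_numbered_window <- function(protein, numbering,
                                    start = XRGG_WINDOW_START,
                                    len = XRGG_WINDOW_LEN) {
  chars <- strsplit(protein, "")[[1]]
  want <- start:(start + len - 1L)
  idx <- match(want, numbering)
  if (anyNA(idx)) return(NULL)
  paste(chars[idx], collapse = "")
}

#' Classify a batch of ferritin records
#'
#' For every record: global alignment against the reference, HuHF
#' numbering, functional-domain replacement counting, molecular weight,
#' isoelectric point, class label, and xRGG motif scanning.  The xRGG PWM
#' is built from the BC-region window (HuHF 75-89) of the conservative,
#' SP-less records of the batch (or a supplied PWM); q-values are
#' Benjamini-Hochberg across the batch.
#'
#' @param records List of [ferritin_record()]s.
#' @param reference Reference protein sequence (default packaged HuHF).
#' @param matrix Substitution matrix (default packaged BLOSUM62).
#' @param domains Domain definitions.
#' @param identity_cut,replacement_cut Classification thresholds.
#' @param pwm Optional pre-built xRGG PWM; by default built from the
#'   batch itself (NULL when fewer than two usable windows exist).
#' @return data.frame with one row per record: `id`, `group`, `sp_flag`,
#'   `identity_pct`, `similarity_pct`, `replacements_total`,
#'   `replacements_list`, `mw_da`, `pi`, `xrgg_qvalue`, `label`.
#'   Attribute `details` keeps the per-record alignment, numbering and
#'   replacement report.
#' @export
classify_records <- function(records,
                             reference = huhf_reference(),
                             matrix = read_substitution_matrix(),
                             domains = read_domain_definitions(),
                             identity_cut = 49, replacement_cut = 5,
                             pwm = NULL) {
  stopifnot(length(records) > 0)
  details <- lapply(records, function(rec) {
    aln <- global_align(rec$protein, reference, matrix = matrix)
    num <- map_to_reference_numbering(aln)
    rep <- count_domain_replacements(rec$protein, num, domains)
    cls <- classify_ferritin(aln$identity_pct, rep$total, rec$sp_flag,
                             identity_cut, replacement_cut)
    list(record = rec, alignment = aln, numbering = num,
         replacements = rep, classification = cls)
  })
  if (is.null(pwm)) {
    block <- Filter(Negate(is.null), lapply(details, function(d) {
      if (d$classification$label != "conservative") return(NULL)
      extract_numbered_window(d$record$protein, d$numbering)
    }))
    pwm <- if (length(block) >= 2) build_pwm(unlist(block)) else NULL
  }
  scans <- lapply(details, function(d)
    if (is.null(pwm))
      structure(list(no_hit = TRUE, p_value = NA_real_),
                class = "motif_scan")
    else scan_xrgg(d$record$protein, pwm))
  scans <- xrgg_qvalues(scans)
  out <- data.frame(
    id = vapply(details, function(d) d$record$id, character(1)),
    group = vapply(details, function(d) d$record$group, character(1)),
    sp_flag = vapply(details, function(d) d$record$sp_flag,
                     character(1)),
    identity_pct = vapply(details, function(d)
      d$alignment$identity_pct, numeric(1)),
    similarity_pct = vapply(details, function(d)
      d$alignment$similarity_pct, numeric(1)),
    replacements_total = vapply(details, function(d)
      d$replacements$total, integer(1)),
    replacements_list = vapply(details, function(d)
      paste(unlist(lapply(d$replacements$per_domain, function(p)
        p$label[p$replaced])), collapse = ","), character(1)),
    mw_da = vapply(details, function(d)
      tryCatch(molecular_weight(d$record$protein),
               error = function(e) NA_real_), numeric(1)),
    pi = vapply(details, function(d)
      isoelectric_point(d$record$protein), numeric(1)),
    xrgg_qvalue = vapply(scans, function(s)
      s$q_value %||% NA_real_, numeric(1)),
    label = vapply(details, function(d) d$classification$label,
                   character(1)),
    stringsAsFactors = FALSE)
  attr(out, "details") <- details
  attr(out, "pwm") <- pwm
  out
}

#' Summarize classification and IRE presence per group
#'
#' @param classifications data.frame with columns `group` and `label`
#'   (e.g. from [classify_records()]).
#' @param ire_presence Optional logical vector (per record) flagging an
#'   IRE in the record's 5' UTR.
#' @return data.frame with one row per group: exact class fractions
#'   (`sp`, `conservative`, `atypical`, in percent), display-rounded
#'   integer percentages (round-half-up, `*_pct` columns), `n`, and
#'   `ire_pct` when `ire_presence` is given.
#' @export
summarize_groups <- function(classifications, ire_presence = NULL) {
  stopifnot(is.data.frame(classifications),
            all(c("group", "label") %in% names(classifications)))
  if (nrow(classifications) == 0L) stop("no records to summarize")
  round_half_up <- function(x) floor(x + 0.5)
  groups <- unique(classifications$group)
  rows <- lapply(groups, function(g) {
    sel <- classifications$group == g
    lab <- classifications$label[sel]
    n <- sum(sel)
    frac <- c(sp = mean(lab == "SP_ferritin"),
              conservative = mean(lab == "conservative"),
              atypical = mean(lab == "atypical")) * 100
    row <- data.frame(group = g, n = n,
                      sp = frac[["sp"]],
                      conservative = frac[["conservative"]],
                      atypical = frac[["atypical"]],
                      sp_pct = round_half_up(frac[["sp"]]),
                      conservative_pct =
                        round_half_up(frac[["conservative"]]),
                      atypical_pct = round_half_up(frac[["atypical"]]),
                      stringsAsFactors = FALSE)
    if (!is.null(ire_presence)) {
      ire <- ire_presence[sel]
      row$ire <- 100 * mean(ire, na.rm = TRUE)
      row$ire_pct <- round_half_up(row$ire)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$proteins),
            !is.null(config$out_dir))
  defaults <- list(identity_cut = 49, replacement_cut = 5, top_k = 100L,
                   seed = 1L, paac_lambda = 30L, nlag = 30L,
                   paac_w = 0.05, run_features = TRUE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (f in c("proteins", "sidecar", "promoters", "utrs", "reference",
              "motif_catalog", "domains"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config file does not exist: ", config[[f]])
  if (config$identity_cut <= 0 || config$replacement_cut <= 0)
    stop("thresholds must be positive")
  config
}

#' Run the full ferritin analysis pipeline
#'
#' Reads protein FASTA (plus optional SP/group sidecar TSV, promoter and
#' 5' UTR FASTA files), classifies every protein, annotates promoters
#' (motifs, HRE/HAS pairs, CpG islands) and UTRs (IREs), computes the
#' descriptor matrix, runs the five feature selectors, unites their top-k
#' sets and projects them by PCA.  Stages whose optional inputs are
#' missing are skipped per record with a warning in the log.  Output is a
#' pure function of (inputs, config, seed).
#'
#' @param config A named list or YAML path with at least `proteins`
#'   (FASTA) and `out_dir`; optional `sidecar`, `promoters` (FASTA whose
#'   headers carry `tss=<n>` tokens), `utrs` (FASTA), `reference`,
#'   `domains`, `motif_catalog`, thresholds `identity_cut` /
#'   `replacement_cut`, `top_k`, descriptor parameters and `seed`.
#' @return Invisibly, a list with the classification table, promoter
#'   reports, IRE table, selection outcome and the summary written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(level, ...) {
    msg <- paste0("[", level, "] ", ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    if (level == "WARN") message(msg)
  }
  cat("", file = log_path)

  prot <- read_fasta(config$proteins, "protein")
  side <- if (!is.null(config$sidecar))
    read_sidecar(config$sidecar, prot$id)
  else data.frame(id = prot$id, sp_flag = "unknown", group = "other")
  promoters <- NULL
  if (!is.null(config$promoters)) {
    pr <- read_fasta(config$promoters, "dna")
    tss <- suppressWarnings(as.integer(sub(".*tss=(\\d+).*", "\\1",
                                           pr$description)))
    if (anyNA(tss))
      stop("promoter FASTA headers must carry 'tss=<n>' tokens")
    promoters <- data.frame(id = pr$id, sequence = pr$sequence,
                            tss_index = tss, stringsAsFactors = FALSE)
  }
  utrs <- if (!is.null(config$utrs)) read_fasta(config$utrs, "rna")

  records <- lapply(seq_len(nrow(prot)), function(i) {
    id <- prot$id[i]
    pi_ <- if (!is.null(promoters)) match(id, promoters$id) else NA
    ui <- if (!is.null(utrs)) match(id, utrs$id) else NA
    ferritin_record(
      id, prot$sequence[i], description = prot$description[i],
      sp_flag = side$sp_flag[i], group = side$group[i],
      utr5 = if (!is.na(ui)) utrs$sequence[ui] else NULL,
      promoter = if (!is.na(pi_)) promoters$sequence[pi_] else NULL,
      tss_index = if (!is.na(pi_)) promoters$tss_index[pi_] else NULL)
  })
  logf("INFO", "read ", length(records), " protein record(s)")

  reference <- if (!is.null(config$reference))
    read_fasta(config$reference, "protein")$sequence[1]
  else huhf_reference()
  domains <- if (!is.null(config$domains))
    read_domain_definitions(config$domains) else read_domain_definitions()
  catalog <- if (!is.null(config$motif_catalog))
    read_motif_catalog(config$motif_catalog) else read_motif_catalog()

  class_df <- classify_records(records, reference = reference,
                               domains = domains,
                               identity_cut = config$identity_cut,
                               replacement_cut = config$replacement_cut)
  write.table(class_df, file.path(config$out_dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  promoter_reports <- list()
  for (rec in records) {
    if (is.null(rec$promoter)) {
      logf("WARN", "record '", rec$id, "': no promoter; regscan skipped")
      next
    }
    rep <- scan_promoter(rec, catalog = catalog)
    promoter_reports[[rec$id]] <- rep
    promoter_report_gff3(rep, file.path(config$out_dir,
                                        paste0(rec$id,
                                               "_promoter.gff3")),
                         seq_length = nchar(rec$promoter))
  }

  ire_rows <- list()
  ire_presence <- rep(NA, length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.null(rec$utr5)) {
      logf("WARN", "record '", rec$id, "': no 5'UTR; IRE scan skipped")
      next
    }
    hits <- find_ire(rec$utr5)
    ire_presence[i] <- nrow(hits) > 0
    if (nrow(hits)) ire_rows[[rec$id]] <- cbind(id = rec$id, hits)
  }
  ire_tab <- if (length(ire_rows)) do.call(rbind, ire_rows)
  else data.frame(id = character(0))
  write.table(ire_tab, file.path(config$out_dir, "ire.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  selection <- NULL
  if (isTRUE(config$run_features) && length(records) >= 3) {
    X <- compute_descriptors(records, paac_lambda = config$paac_lambda,
                             paac_w = config$paac_w, nlag = config$nlag)
    algos <- c("laplacian_score", "SPEC", "MCFS", "NDFS", "UDFS")
    sels <- lapply(algos, function(a)
      select_features(X, a, seed = config$seed))
    names(sels) <- algos
    k <- min(config$top_k, ncol(X))
    union <- union_top_k(sels, k)
    pca <- pca_project(X[, union, drop = FALSE],
                       n_components = min(2L, length(union),
                                          nrow(X) - 1L))
    selection <- list(
      n_features = ncol(X), k = k, union_size = length(union),
      union = colnames(X)[union],
      top_k = lapply(sels, function(s)
        colnames(X)[head(s$ranking, k)]),
      converged = lapply(sels, function(s) s$converged),
      pca_explained = pca$explained,
      pca_scores = apply(pca$scores, 2, identity, simplify = FALSE))
    jsonlite::write_json(selection,
                         file.path(config$out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("ferriscan")),
    parameters = config[setdiff(names(config), "out_dir")],
    n_records = length(records),
    class_counts = as.list(table(class_df$label)),
    n_promoters_scanned = length(promoter_reports),
    n_utrs_scanned = sum(!is.na(ire_presence)),
    n_with_ire = sum(ire_presence %in% TRUE),
    groups = summarize_groups(class_df, ire_presence))
  jsonlite::write_json(summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("INFO", "pipeline complete: ", length(records), " record(s)")
  invisible(list(classification = class_df,
                 promoters = promoter_reports, ire = ire_tab,
                 selection = selection, summary = summary))
}
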