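test_that("fuzzy scan finds planted IUPAC motifs on both strands", {
  m <- motif_definition("MRE", "TGCRCNC")
  seqd <- paste0("AAAA", "TGCACTC", strrep("A", 20))
  hits <- fuzzy_scan(seqd, m)
  expect_equal(hits$start, 5L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$strand, "+")
  ## same instance on the reverse strand
  rc <- paste0(strrep("T", 20), "GAGTGCA", "TTTT")
  hits2 <- fuzzy_scan(rc, m)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$start, 21L)
  ## no match at all
  expect_equal(nrow(fuzzy_scan(strrep("A", 50),
                               motif_definition("g4", "GGGG"))), 0L)
  ## pattern longer than sequence
  expect_equal(nrow(fuzzy_scan("ACG", m)), 0L)
})

test_that("fuzzy scan equals a brute-force IUPAC matcher on random cases", {
  set.seed(29)
  iupac <- names(ferriscan:::IUPAC_DNA)
  for (k in 1:500) {
    n <- sample(10:50, 1)
    w <- sample(3:10, 1)
    seqd <- random_dna(n)
    pat <- paste(sample(iupac, w, replace = TRUE,
                        prob = c(rep(4, 4), rep(1, 11))), collapse = "")
    mm <- sample(0:2, 1)
    got <- fuzzy_scan(seqd, motif_definition("m", pat, mm))
    want <- brute_iupac_scan(seqd, pat, mm)
    expect_equal(got[, c("start", "end", "strand", "mismatches")],
                 want, info = paste(seqd, pat, mm))
  }
})

test_that("reverse-complementing the sequence mirrors the hit set", {
  set.seed(31)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in 1:40) {
    n <- sample(20:60, 1)
    seqd <- random_dna(n)
    rcseq <- paste(rev(unname(comp[strsplit(seqd, "")[[1]]])),
                   collapse = "")
    m <- motif_definition("m", paste(sample(names(ferriscan:::IUPAC_DNA),
                                            5, replace = TRUE),
                                     collapse = ""),
                          max_mismatches = 1)
    h1 <- fuzzy_scan(seqd, m)
    h2 <- fuzzy_scan(rcseq, m)
    ## a + hit at [s, e] maps to a - hit at [n-e+1, n-s+1] and vice versa
    mirror <- data.frame(start = n - h2$end + 1L, end = n - h2$start + 1L,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         mismatches = h2$mismatches)
    mirror <- mirror[order(mirror$start, mirror$strand), ]
    rownames(mirror) <- NULL
    expect_equal(h1[, c("start", "end", "strand", "mismatches")], mirror)
  }
})

test_that("HRE and HAS pair only at 7-15 bp same-strand spacing", {
  hre <- data.frame(motif = "HRE", start = 96L, end = 100L, strand = "+",
                    matched = "ACGTG", mismatches = 0L)
  has <- function(s, strand = "+")
    data.frame(motif = "HAS", start = s, end = s + 4L, strand = strand,
               matched = "CAGAG", mismatches = 0L)
  expect_equal(pair_hre_has(hre, has(111))$gap, 10L)   # 10 bases between
  expect_equal(nrow(pair_hre_has(hre, has(107))), 0L)  # gap 6, too close
  expect_equal(pair_hre_has(hre, has(108))$gap, 7L)    # boundary
  expect_equal(pair_hre_has(hre, has(116))$gap, 15L)   # boundary
  expect_equal(nrow(pair_hre_has(hre, has(117))), 0L)  # gap 16
  expect_equal(nrow(pair_hre_has(hre, has(111, "-"))), 0L)  # strand
  expect_equal(nrow(pair_hre_has(hre, has(111)[0, ])), 0L)  # no HAS
  ## minus strand: downstream is decreasing coordinates
  hre_m <- transform(hre, strand = "-")
  has_m <- data.frame(motif = "HAS", start = 80L, end = 84L,
                      strand = "-", matched = "CTGTG", mismatches = 0L)
  expect_equal(pair_hre_has(hre_m, has_m)$gap, 96L - 84L - 1L)
})

test_that("CpG island detection matches the brute-force window oracle", {
  set.seed(37)
  for (k in 1:100) {
    gc <- runif(1, 0.35, 0.65)
    seqd <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                         prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                  (1 - gc) / 2)), collapse = "")
    got <- detect_cpg_islands(seqd)
    want <- brute_cpg(seqd)
    expect_equal(got[, c("start", "end")], want, info = k)
  }
})

test_that("CpG islands satisfy thresholds; degenerate inputs are handled", {
  isl <- detect_cpg_islands(strrep("CG", 150))
  expect_equal(nrow(isl), 1L)
  expect_gte(isl$length, 200L)
  expect_gte(isl$gc_pct, 50)
  expect_gte(isl$obs_exp, 0.6)
  expect_equal(nrow(detect_cpg_islands(strrep("AT", 1000))), 0L)
  expect_warning(res <- detect_cpg_islands(strrep("CG", 20)), "window")
  expect_equal(nrow(res), 0L)
})

test_that("promoter scanning recovers planted features at TSS-relative positions", {
  pr <- generate_promoter(
    length = 2000L,
    planted = list(list(name = "MRE", instance = "TGCACTC",
                        tss_rel = -133L),
                   list(name = "TATA", instance = "TATAAAAG",
                        tss_rel = -30L),
                   list(name = "HRE", instance = "ACGTG",
                        tss_rel = -300L),
                   list(name = "HAS", instance = "CAGAG",
                        tss_rel = -284L)),
    cpg_island = c(200L, 220L), tss_offset = 1500L, seed = 11L)
  rep <- scan_promoter(pr$record)
  mre <- rep$motifs[rep$motifs$motif == "MRE" & rep$motifs$strand == "+", ]
  expect_true(-133L %in% mre$tss_start)
  tata <- rep$motifs[rep$motifs$motif == "TATA", ]
  expect_true(-30L %in% tata$tss_start)
  expect_true(any(rep$composites$tss_start == -300L))
  ## every composite member appears in the motif hit list
  for (i in seq_len(nrow(rep$composites))) {
    expect_true(any(rep$motifs$motif == "HRE" &
                      rep$motifs$start == rep$composites$hre_start[i]))
    expect_true(any(rep$motifs$motif == "HAS" &
                      rep$motifs$start == rep$composites$has_start[i]))
  }
  ## planted island recovered with >= 90% overlap of the planted span
  isl <- rep$cpg_islands
  expect_gte(nrow(isl), 1L)
  overlap <- max(pmin(isl$end, 419L) - pmax(isl$start, 200L) + 1L)
  expect_gte(overlap / 220L, 0.9)
  ## empty catalog: only the CpG section remains
  rep2 <- scan_promoter(pr$record, catalog = list())
  expect_equal(nrow(rep2$motifs), 0L)
  expect_gte(nrow(rep2$cpg_islands), 1L)
  ## missing promoter skipped with a warning
  rec <- ferritin_record("x", "MKV")
  expect_warning(expect_null(scan_promoter(rec)), "no promoter")
})

test_that("promoter reports export as parseable GFF3", {
  pr <- generate_promoter(length = 1500L,
                          planted = list(list(name = "MRE",
                                              instance = "TGCACTC",
                                              tss_rel = -133L)),
                          tss_offset = 1000L, seed = 13L)
  rep <- scan_promoter(pr$record)
  f <- withr::local_tempfile(fileext = ".gff3")
  promoter_report_gff3(rep, f, seq_length = 1500L)
  gr <- rtracklayer::import(f)
  expect_gte(length(gr), nrow(rep$motifs))
  ## TSS-relative attribute matches the conversion rule
  expect_equal(gr$tss_start,
               as.character(tss_relative(BiocGenerics::start(gr),
                                         1000L)))
})
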