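domains <- read_domain_definitions()
ref <- huhf_reference()

test_that("the reference itself has zero domain replacements", {
  num <- map_to_reference_numbering(global_align(ref, ref))
  rep <- count_domain_replacements(ref, num, domains)
  expect_equal(rep$total, 0L)
  expect_equal(unname(rep$counts), rep(0L, 3))
})

test_that("planted domain mutations are counted and localized exactly", {
  ## mutate E27 -> Q and E134 -> A (string index = HuHF number + 1)
  chars <- strsplit(ref, "")[[1]]
  chars[28] <- "Q"; chars[135] <- "A"
  query <- paste(chars, collapse = "")
  num <- map_to_reference_numbering(global_align(query, ref))
  rep <- count_domain_replacements(query, num, domains)
  expect_equal(rep$total, 2L)
  expect_true("E27Q" %in% rep$per_domain$ferroxidase_center$label[
    rep$per_domain$ferroxidase_center$replaced])
  expect_true("E134A" %in% rep$per_domain$iron_ion_channel$label[
    rep$per_domain$iron_ion_channel$replaced])
  ## totals conserved under domain re-ordering
  rep2 <- count_domain_replacements(query, num, rev(domains))
  expect_equal(rep2$total, rep$total)
  expect_equal(sum(rep2$counts), sum(rep$counts))
})

test_that("unaligned domain positions count as flagged replacements", {
  query <- substr(ref, 1, 100)  # truncation removes D131/E134/Q141/E134...
  num <- map_to_reference_numbering(global_align(query, ref))
  rep <- count_domain_replacements(query, num, domains)
  chan <- rep$per_domain$iron_ion_channel
  expect_true(all(chan$unaligned))
  expect_true(all(chan$replaced))
})

test_that("molecular weight matches residue-mass arithmetic", {
  expect_equal(molecular_weight("G"), 75.0672, tolerance = 1e-6)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("MKXV"), "without a defined mass")
  ## additivity: MW(s1 + s2) = MW(s1) + MW(s2) - water
  set.seed(9)
  for (k in 1:25) {
    s1 <- random_protein(sample(1:30, 1))
    s2 <- random_protein(sample(1:30, 1))
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.01524,
                 tolerance = 1e-9)
  }
})

test_that("isoelectric point agrees with a dense grid scan of the charge curve", {
  grid_pi <- function(p) {
    ph <- seq(0, 14, by = 1e-4)
    ph[which.min(abs(protein_charge(p, ph)))]
  }
  expect_equal(isoelectric_point("AAAA"), grid_pi("AAAA"),
               tolerance = 2e-3)
  set.seed(13)
  for (k in 1:8) {
    p <- random_protein(sample(5:50, 1))
    expect_equal(isoelectric_point(p), grid_pi(p), tolerance = 2e-3)
  }
})

test_that("the charge curve is strictly decreasing and lysines raise the pI", {
  set.seed(14)
  ph <- seq(0.5, 13.5, by = 0.25)
  for (k in 1:50) {
    p <- random_protein(sample(5:40, 1))
    ch <- protein_charge(p, ph)
    expect_true(all(diff(ch) < 0))
    expect_gt(isoelectric_point(paste0(p, "K")) + 1e-6,
              isoelectric_point(p))
  }
})

test_that("classification applies strict inequalities at the class boundary", {
  expect_equal(classify_ferritin(37.7, 8, "absent")$label, "atypical")
  ## exactly at the thresholds: conservative (rule is strictly less /
  ## strictly more)
  expect_equal(classify_ferritin(49.0, 5, "absent")$label,
               "conservative")
  expect_equal(classify_ferritin(48.999, 5, "absent")$label, "atypical")
  expect_equal(classify_ferritin(49.0, 6, "absent")$label, "atypical")
  ## the SP class precedes the identity split
  expect_equal(classify_ferritin(90, 0, "present")$label, "SP_ferritin")
  expect_equal(classify_ferritin(10, 9, "present")$label, "SP_ferritin")
  res <- classify_ferritin(60, 0, "unknown")
  expect_equal(res$label, "conservative")
  expect_match(res$warnings, "unknown")
})

test_that("PWM construction follows the pseudocount formula", {
  pwm <- build_pwm(c("RGG", "RGG"), pseudocount = 0)
  expect_equal(unname(pwm["R", 1]), 1)
  expect_equal(unname(pwm["G", 2]), 1)
  expect_equal(unname(colSums(pwm)), rep(1, 3))
  ## mixed column splits mass
  pwm2 <- build_pwm(c("ARG", "KRG"), pseudocount = 0)
  expect_equal(unname(pwm2["A", 1]), 0.5)
  expect_equal(unname(pwm2["K", 1]), 0.5)
  ## pseudocount 0.1, single-residue column over 2 rows -> 2.1 / 4.0
  pwm3 <- build_pwm(c("W", "W"), pseudocount = 0.1)
  expect_equal(unname(pwm3["W", 1]), 2.1 / 4.0)
  expect_error(build_pwm(c("AA", "A")), "equal length")
})

test_that("xRGG scanning finds planted motifs and a uniform PWM is null", {
  set.seed(17)
  consensus <- "QRGGRIFLQDIKKPD"
  pwm <- build_pwm(c(consensus, consensus), pseudocount = 0.05)
  hits <- 0
  for (k in 1:100) {
    bg <- random_protein(60)
    offset <- sample(1:45, 1)
    seqp <- paste0(substr(bg, 1, offset - 1), consensus,
                   substr(bg, offset + 15, 60))
    h <- scan_xrgg(seqp, pwm)
    if (h$start == offset) hits <- hits + 1
  }
  expect_equal(hits, 100)
  ## uniform PWM equal to the background: p-value 1 for any window
  upwm <- matrix(1 / 20, nrow = 20, ncol = 4,
                 dimnames = list(ferriscan:::PROTEIN_ALPHABET, NULL))
  h <- scan_xrgg(random_protein(30), upwm)
  expect_equal(h$p_value, 1, tolerance = 1e-9)
  expect_equal(h$score, 0, tolerance = 1e-6)
  ## too-short protein: flagged, no hit
  expect_true(scan_xrgg("MK", pwm)$no_hit)
})

test_that("exact PWM p-values match enumeration over all 20^3 windows", {
  set.seed(19)
  block <- vapply(1:6, function(i) random_protein(3), character(1))
  pwm <- build_pwm(block, pseudocount = 0.2)
  bg <- setNames(rep(1 / 20, 20), ferriscan:::PROTEIN_ALPHABET)
  lods_int <- round(log2(pwm / as.numeric(bg)) / 0.001)
  storage.mode(lods_int) <- "integer"
  for (p in c("MKV", "RGG", "WWW", "AQL")) {
    h <- scan_xrgg(p, pwm)
    idx <- match(strsplit(p, "")[[1]], ferriscan:::PROTEIN_ALPHABET)
    sc <- sum(lods_int[cbind(idx, 1:3)])
    expect_equal(h$p_value,
                 brute_pwm_pvalue(lods_int, as.numeric(bg), sc),
                 tolerance = 1e-9, info = p)
  }
})

test_that("q-values are BH-adjusted across a batch", {
  set.seed(23)
  pwm <- build_pwm(c("QRGGR", "QRGGR", "QRGGK"), pseudocount = 0.1)
  scans <- lapply(1:8, function(i) scan_xrgg(random_protein(40), pwm))
  scans <- xrgg_qvalues(scans)
  p <- vapply(scans, `[[`, numeric(1), "p_value")
  q <- vapply(scans, `[[`, numeric(1), "q_value")
  expect_equal(q, p.adjust(p, "BH"))
})
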