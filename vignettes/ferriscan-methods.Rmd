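---
title: "ferriscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferriscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how each stage of the package works, which
parameters matter, and where the design was genuinely open and a choice
had to be made.

## Reference alignment and HuHF numbering

Queries are aligned to the human ferritin heavy chain (HuHF, UniProt
P02794, 183 aa, shipped in `inst/extdata/huhf.fasta`) by Needleman–Wunsch
with affine gap penalties and *free end gaps*, matching the EMBOSS Needle
defaults: BLOSUM62 in half-bit units, gap open 10, gap extend 0.5 (a gap
of length $L$ costs $\mathrm{open} + (L-1)\,\mathrm{extend}$). Identity is
the fraction of identical columns over the **full** alignment length,
including gap columns; similarity counts columns whose residue pair has a
positive substitution score. Both conventions follow Needle, so
percentages are comparable to values produced with that tool, with one
caveat: among co-optimal alignments the traceback deterministically
prefers a match column over a gap in the reference over a gap in the
query, and different co-optima can differ by a column or two of identity.

Free end gaps are implemented the standard way (zero initialization plus a
free remainder after the best last-row/last-column cell). A consequence
worth knowing: an alignment cannot leave *both* terminal residues
unaligned on both sides simultaneously, so neither the score nor the
identity is strictly monotone under appending the same residue to both
sequences — the optimum may restructure. The test suite therefore asserts
the exact-extension property on identical pairs and dominance over the
explicit gapless alignment, plus full score agreement with an independent
enumeration oracle on random pairs up to length 8.

HuHF numbering starts after the initial methionine: the residue following
M is number 1. `map_to_reference_numbering()` assigns each aligned query
residue the number of its reference column; insertions relative to the
reference are unaligned (`NA`). If a user-supplied reference does not
start with M the numbering starts at its first residue and a warning is
raised.

## Functional domains and classification

The three domains are configured in `inst/extdata/domains.yaml` as
residue–number pairs in HuHF numbering: ferroxidase di-iron center
{E27, Y34, E61, E62, H65, E107, Q141}, iron ion channel {D131, E134},
ferrihydrite nucleation site {E64, E67}. These are literature-standard
HuHF sets. E61 is sometimes attributed to both the ferroxidase center and
the nucleation site; because the replacement report requires every
position to belong to exactly one domain (so totals are a clean sum), E61
is assigned to the ferroxidase set and the nucleation default is the
disjoint {E64, E67}. Users studying L-chain-like nucleation explicitly
can override the YAML.

A domain position counts as replaced when the aligned query residue
differs from the consensus *or* the position is unaligned (deletion).
Counting deletions keeps truncated sequences classifiable; such positions
are flagged separately in the report.

Classification applies, in order: records annotated with a signal peptide
are `SP_ferritin` (the annotation comes from an upstream tool such as
SignalP — the package never predicts signal peptides); among SP-less
records, `atypical` means identity < 49 % **or** replacements > 5, both
strict, so a record at exactly 49 %/5 is `conservative`. An `unknown` SP
flag is treated as absent and a warning is recorded in the result.

## Physicochemical properties

Molecular weight sums ExPASy average residue masses plus one water
(18.01524 Da); `X` is rejected. The isoelectric point solves
$Q(\mathrm{pH}) = 0$ for the Henderson–Hasselbalch net charge with the
Bjellqvist pK set (side chains C 9.0, D 4.05, E 4.45, H 5.98, K 10.0,
R 12.0, Y 10.0; residue-specific N-terminal pKs; C-terminal 3.55 with
terminal D/E adjustments) by bisection on [0, 14], stopping at
$|Q| < 10^{-4}$ or a pH interval below $10^{-3}$. $Q$ is strictly
decreasing in pH, so the root is unique; the tests verify the bisection
against a dense $10^{-4}$-step grid scan of the same charge curve.

## xRGG secretion-motif scanning

The 15-residue window starting at the xRGG motif lies at HuHF numbers
75–89 (in HuHF itself: `QRGGRIFLQDIKKPD`). In batch classification the
PWM is built from that window of the batch's conservative SP-less
records (pseudocount formula
$(\mathrm{count} + c)/(\mathrm{rows} + 20c)$); this choice — building the
motif model from the best-conserved members of the input — is the
package's answer to the open question of where the motif model should
come from, and a pre-built PWM can be supplied instead. Scanning scores
each window by base-2 log-odds against a background (uniform by
default). The p-value is exact: scores are discretized to 1/1000 bit and
the tail probability of the window score under the background is computed
by dynamic programming (the FIMO approach); the tests verify it against
enumeration of all $20^3$ windows for width-3 PWMs. q-values are
Benjamini–Hochberg across one sequence batch.

## Promoter annotation

`fuzzy_scan()` matches IUPAC consensus strings with up to
`max_mismatches` mismatching positions via `Biostrings::matchPattern`
(ambiguities in the pattern only); matches that would overhang the
sequence ends are discarded. The reverse strand is scanned with the
reverse-complement pattern and reported in forward coordinates. The
default catalog (`inst/extdata/motif_catalog.yaml`) carries
literature-consensus strings for MRE (TGCRCNC), HRE (RCGTG), HAS (CASAG),
TATA, Inr, DPE, GC box, NFkB, NRF1 and CsMBE, each with 0 allowed
mismatches; it is a YAML file meant to be edited, since regulatory
catalogs are inherently curation-dependent.

HRE+HAS composite calls pair same-strand hits whose gap — bases strictly
between the HRE 3' end and HAS 5' start, measured in the motif's own
5'→3' direction (decreasing coordinates on the minus strand) — lies in
[7, 15] bp.

CpG islands follow Gardiner-Garden & Frommer: 100-bp windows at 1-bp
shift, GC ≥ 50 %, Obs/Exp CpG $= N_{CG} \cdot w /(N_C N_G) \ge 0.6$
(ratio 0 when C or G is absent), counting only CG dinucleotides fully
inside the window; qualifying windows are merged
(overlapping-or-adjacent), merged spans shorter than 200 bp are dropped,
and the island statistics are recomputed over the merged span. Trailing
windows shorter than 100 bp are not evaluated. A brute-force
reimplementation in the test helpers checks this on random 1-kb
sequences.

TSS-relative coordinates use the signed, no-zero convention: +1 is the
first transcribed base, −1 the base immediately upstream.

## IRE prediction

`find_ire()` is a pure combinatorial matcher — no thermodynamic folding.
Anchored at every apical-loop match `CAGUGH`, it requires a 5-bp upper
stem of Watson-Crick or G·U pairs, then either a single unpaired C
(C-bulge) or a UGC/C asymmetric bulge immediately below the upper stem on
the 5' arm, then a lower stem of ≥ 3 consecutive pairs (extended
maximally and reported). Quality grades approximate the SIREs scheme:
`high` = C-bulge with an all-Watson-Crick upper stem, `medium` = one G·U
pair or the UGC/C bulge, `low` = anything else that still satisfies the
architecture (reported only with `allow_variants`). The grades are an
approximation — the exact grading rules of SIREs live in its own
publication — and are labelled as such. Loop position 6 is left unpaired;
the loop C1·G5 pairing is recorded but not required. Every reported hit is
re-validated in the tests by an independent pairing checker.

## Descriptors

`compute_descriptors()` produces, per sequence: AAC (20), grouped AAC
over aliphatic/aromatic/positive/negative/uncharged groups (5), pseudo
amino acid composition with $\lambda = 30$, $w = 0.05$ (Chou's standard
hydrophobicity/hydrophilicity/side-chain-mass property triple, each
standardized over the 20 residues), CTD over the seven standard property
partitions (147: composition 21, transition 21, distribution 105 — the
distribution cut points are the 1st, ⌊25 %⌋, ⌊50 %⌋, ⌊75 %⌋ and last
occurrence of each group, as position/length × 100, zero for absent
groups), and Moran, Geary and normalized Moreau-Broto autocorrelations
with lags 1–30 over eight AAindex properties (CIDH920105, BHAR880101,
CHAM820101, CHAM820102, CHOC760101, BIGC670101, CHAM810101, DAYM780201;
values taken from the AAindex copy shipped with `seqinr`, standardized per
property). This yields 942 features at the defaults. Descriptor totals
are configuration-dependent — published feature counts from other
parameterizations are not reproducible without the exact settings, so the
package treats the total as a config property rather than a target.
Sequences must be longer than max(λ, nlag) and contain standard residues
only; violations raise errors naming the sequence.

## Unsupervised feature selection

All five selectors operate on internally standardized features and share
the affinity graph: kNN (k = 5) symmetrized, heat-kernel weights with
bandwidth = mean squared kNN distance.

* **Laplacian score** (smaller better): $\tilde f^T L \tilde f / \tilde
  f^T D \tilde f$ with the degree-weighted centering of He et al.
* **SPEC** (smaller better): $\hat f^T \mathcal{L} \hat f / (1 - (\hat
  f^T \xi_1)^2)$ on the normalized Laplacian, trivial eigenvector
  removed.
* **MCFS** (larger better): spectral embedding into `n_clusters`
  dimensions, then per dimension an L1-regularized regression path;
  score = max |coefficient| at the densest end of the path. The
  regression uses glmnet's elastic net with α = 0.9 and threshold
  1e−16 rather than pure-lasso LARS: the small ridge component makes the
  solution unique and (near-)symmetric for duplicated columns, at the
  cost of exact sparsity of the path. Duplicate columns agree to
  numerical precision (~1e−4), not exactly.
* **NDFS** (larger better): nonnegative spectral clustering indicators
  (seeded k-means init) with the multiplicative F-update and the
  $\ell_{2,1}$-regularized regression W-update; score = row norms of W.
* **UDFS** (larger better): the local discriminative M matrix, then
  alternating eigendecomposition / reweighting of the
  $\ell_{2,1}$-regularized trace objective.

NDFS and UDFS run at most 100 iterations with a relative objective
tolerance of 1e−6; non-convergence within the budget returns the result
with `converged = FALSE`. All stochastic initializations take an explicit
seed; fixed seed means bit-identical rankings. Constant features are
assigned the worst score, flagged, and ranked last; ranking ties break by
column index.

`union_top_k()` unites the per-algorithm top-k (k = 100 by default) in a
fixed algorithm order; `pca_project()` wraps `stats::prcomp` with
centering and no scaling.

## The synthetic generator

The generator defines the validation conditions for the whole package:

* **Families**: 10 conservative + 10 atypical + 10 SP members by default.
  Conservative members mutate non-domain sites at a per-site rate of 0.1
  (substitutions uniform over the 19 alternatives — the simplest null, no
  substitution-matrix bias), keeping identity near 90 %, far above the
  49 % cut. Atypical members additionally receive 7 domain replacements
  drawn without replacement from the 11 configured domain positions —
  above the 5-replacement cut with margin. SP members get a synthetic
  signal peptide (M + two K/R, a hydrophobic core, an AxA cleavage
  motif; 20 residues by default) and `sp_flag = "present"`. The peptide
  exercises the annotation pathway only; it is not designed to fool a
  predictor.
* **Promoters**: i.i.d. background at a set GC fraction (0.4 default)
  with concrete motif instances spliced at TSS-relative positions and an
  optional CpG-island span resampled until GC ≥ 55 % and Obs/Exp ≥ 0.7.
* **UTRs**: a structurally forced IRE (arms built as exact reverse
  complements) spliced at a given offset, with the two flanking
  background bases set to `A` so the lower stem cannot extend by chance
  and planted coordinates are exact.

What this emulates: controlled divergence, planted domain lesions, and
planted regulatory architecture with known coordinates. What it does not
emulate: phylogenetic correlation between sequences, codon-level
evolution, indel processes inside the family, compositional biases of
real promoters, or motif degeneracy beyond the planted instances. Tests
passing on this generator demonstrate that each stage recovers known
truth under its stated conditions; they do not certify performance on
real, messier collections.

## Problem sizes and numerical notes

The test suite and acceptance script run at desk scale: 200+ random pairs
(length ≤ 8) for the alignment oracle, 100 random 1-kb sequences for the
CpG oracle (25 in the acceptance script), 500 random sequence/pattern
pairs for the IUPAC oracle, 100 planted and 100 null UTRs for IRE recall
and false positives, 30-record families for classification and the full
942-feature selection stack. These sizes were chosen so the whole
validation runs in a couple of minutes on one CPU while keeping binomial
noise on the recall estimates negligible.

Degenerate inputs are contracts, not surprises: empty sequences, `X` in
mass/pI/descriptor computations, sequences shorter than a window/motif,
zero-variance PCA input and constant features all raise errors or flagged
results as documented on each function.

## Known limitations

* Identity of co-optimal alignments can differ slightly between
  implementations (traceback tie-breaking); comparisons against printed
  integer percentages should allow ±1 identical column.
* The IRE quality grades are approximations of the SIREs scheme.
* The xRGG PWM depends on the batch composition when not supplied
  explicitly; q-values are only comparable within one batch.
* The promoter catalog ships consensus strings, not PWMs; highly
  degenerate elements are better served by user-supplied entries with
  mismatch allowances.
* Group-level proportion summaries reproduce published survey statistics
  only when the corresponding curated sequence collections are supplied
  by the user; the package validates the summary arithmetic on synthetic
  data.
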