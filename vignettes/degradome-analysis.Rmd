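---
title: "Degradome (PARE) analysis with degradomeKit: models, parameters and design"
author: "degradomeKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradome (PARE) analysis with degradomeKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomeKit)
```

# The measurement and the model

Parallel analysis of RNA ends (PARE) sequences short 5' signatures of
uncapped, polyadenylated mRNA fragments. Each tag marks the exact 5'
terminus of a decay intermediate, so a library of tags observes the
degradome: the products of decapping-initiated 5'→3' decay and of
endonucleolytic cuts, most prominently miRNA-guided slicing. Two kinds of
information live in these data:

* **abundance** — how many tags a gene's transcript accumulates measures
  its uncapped (degrading) mRNA level, the *degradation layer* (D),
  complementary to RNA-seq's *transcription layer* (R);
* **position** — a sharp pile-up of tag 5' ends at one nucleotide marks a
  discrete cleavage event: a miRNA slice site on an mRNA, or a DCL cut on
  a miRNA precursor hairpin.

degradomeKit implements the full desk-scale analysis on both axes, plus a
planted-truth simulator so every stage can be validated end to end without
any external data.

# Quantification

Tags are matched to the transcriptome on the sense strand, end-to-end,
with at most one substitution (`mapTags()`). The one-mismatch search is
exact: a 20-nt tag with a single mismatch must match one of its halves
perfectly, so two `Biostrings::PDict` scans with complementary trusted
bands enumerate precisely the loci with ≤ 1 substitution (the pigeonhole
principle); no heuristic seeding is involved, and an oracle test checks
equivalence against a brute-force scan of every position.

A tag matching $k$ loci contributes mass $1/k$ at each locus
(`buildProfiles()`), so total profile mass equals matched tag copies
exactly — an invariant the tests assert to machine precision. Equal
splitting (rather than weighted) is the convention adopted because the
multi-mapper rule in this analysis family states division among
positions without weights.

Per-gene degradation abundance is reads per million:
$\mathrm{RPM}_g = 10^6 \cdot m_g / M$ with $m_g$ the gene's profile mass
and $M$ the library's mapped total; transcription abundance is
$\mathrm{FPKM}_g = c_g / \left(\frac{L_g}{10^3}\cdot\frac{N}{10^6}\right)$.
With a transcriptome mapping universe, "genome-mapped total" and "matched
total" coincide on synthetic data; the denominator is an explicit,
auditable argument (`totalMapped`). Replicates are averaged after a QC
step reporting the squared Pearson correlation of $\log_2(\mathrm{RPM}+1)$
(`mergeReplicates()`); with more than two replicates the mean of pairwise
$r^2$ values is reported.

# Two-library differential testing

The differential test (`twoLibraryTest()`) is the pooled two-proportion
z-test under the random-sampling model — the same null family as the
classic two-library count tests for digital expression data:

$$\hat p = \frac{c_1+c_2}{n_1+n_2},\qquad
z = \frac{c_1/n_1 - c_2/n_2}
        {\sqrt{\hat p(1-\hat p)(1/n_1 + 1/n_2)}},\qquad
p = 2\Phi(-|z|).$$

It is implemented, not wrapped, and its accept/reject decisions at
$\alpha = 10^{-3}$ are checked against the exact conditional binomial test
(given $k = c_1+c_2$, $c_1 \sim \mathrm{Bin}(k,\, n_1/(n_1+n_2))$) with
≥ 99% agreement required for informative genes. Adjustment is
Benjamini–Hochberg step-up false-discovery-rate control, the standard
choice for genome-wide count testing.

Status calls use the printed thresholds: *up* when
$\log_2 \mathrm{FC} \ge 1$ and $p_{adj} < 10^{-3}$; *down* for the
mirrored rule; *unchanged* when $|\log_2 \mathrm{FC}| < 1$ and
$p_{adj} > 10^{-3}$. Those two rules do not tile the threshold grid: a
gene with a large fold change but non-significant p (or the converse)
falls in neither. Such genes get an explicit **ambiguous** status, are
excluded from decay classification, and are reported separately — an
honest bookkeeping category rather than a silent coercion. Fold changes
use a pseudo-abundance, $\log_2\frac{v_t+\varepsilon}{v_c+\varepsilon}$
with $\varepsilon = 0.5$ in the value's own unit, so genes undetected in
one condition still yield finite, rankable ratios; the pseudo-count is
declared and configurable. Replicate counts are summed per condition for
testing (the test wants raw sampling counts); RPM is averaged across
replicates for reporting.

# Decay classes and types

Joint (D, R) statuses map onto a 3×3 grid lettered A–I row-major (rows:
D up/unchanged/down; columns: R down/unchanged/up):

|        | R down | R unch. | R up |
|--------|--------|---------|------|
| D up   | A (III) | B (II) | C (I) |
| D unch.| D (IV)  | E (–)  | F (IV) |
| D down | G (I)   | H (II) | I (III) |

The letter layout is this package's documented convention: the
row-major assignment that satisfies the class system's defining
constraints (E central; C,G concordant = type I; B,H degradation-only =
type II; A,I discordant = type III; D,F transcription-only = type IV),
and the tests enumerate the grid to prove all five. Genes
detected in only one layer are excluded from classification;
`summarizeTypes()` renders the type-by-direction count table, and
`uncappedTotalRatio()` computes the per-gene RPM/FPKM ratio with a
two-sided Mann–Whitney comparison between gene sets (FPKM-zero genes
excluded and counted).

# Sequence features

`computeFeatures()` reports per-transcript mRNA/UTR lengths, regional GC,
the annotated intron count, and the minimal folding free energy index

$$\mathrm{MFEI} = \frac{\mathrm{MFE}}{\mathrm{length}}\times
  \frac{100}{\mathrm{GC\%}},$$

i.e. MFE per nucleotide per GC percentage point (so
$\mathrm{MFEI}(-40, 100, 0.5) = -0.8$). Missing UTRs yield `NA`
features, never zeros.

Folding is injectable. The default backend is a deliberately simple
base-pair-maximisation dynamic program (−1 per canonical pair including
G:U wobble, hairpin loops ≥ 3 nt) — an approximate, thermodynamics-free
score whose identity is recorded in the output and which is verified
exactly against exhaustive enumeration of all nested pairings for
sequences ≤ 12 nt. ViennaRNA's `RNAfold` can be selected
(`engine = "vienna"`) when the binary is on the PATH; published MFE
values require a real thermodynamic engine, so nothing in the test suite
depends on one. The fallback is cubic in sequence length; sequences
beyond `maxFoldLength` (default 3000 nt) return `NA` rather than stall,
and the pipeline computes MFEI only on request (`computeMfei = TRUE`).

Group comparisons (`compareFeature()`) use the two-sided Wilcoxon
rank-sum (Mann–Whitney U) test — the appropriate nonparametric choice
for skewed quantities such as lengths and folding indices. Random
control sets are size-matched to the mean of the type-group sizes and
drawn without replacement under a caller-visible seed, so a feature
shift in a decay-type group is always judged against both a same-sized
random draw and the full gene universe.

# miRNA target identification

`scoreAlignment()` scores a gapless miRNA–site duplex with the
established plant-target convention: miRNA base $i$ pairs site base
$L-i+1$; penalties 0 (Watson–Crick), 0.5 (G:U), 1 (other), doubled for
miRNA positions 2–13; candidate sites score ≤ 4 by default. Gapless-only
is a documented limitation — bulged sites exist but are rare among
validated plant targets. `scanCandidates()` is exhaustive over every
window of every transcript (vectorised per miRNA as a sum of shifted
penalty lookups), so no planted site can be missed by a search
heuristic.

The slice position is the transcript nucleotide paired with miRNA base
10 — the first nucleotide of the 3' cleavage fragment, hence exactly
where a PARE tag 5' end maps. `validateWithDegradome()` accepts a
candidate when the control-library profile carries ≥ `minReads` (default
2) mass at the slice position (± `offsetTolerance`, default 0); a
single-read signal is admitted only as category 4. Categories follow the
degradome-tool convention, computed on fractional post-splitting mass
over positions with signal: 0 unique maximum, 1 tied maximum, 2 above
the median, 3 at/below the median, 4 at most one read. Hit tables are
stably sorted by (miRNA, transcript, slice position) so identical inputs
give byte-identical outputs.

# Hairpin processing modes

A DCL cut leaves a polyadenylated 3' fragment whose first nucleotide is
the position after the cut; that is the position a PARE tag reports. For
the 3'-arm duplex strand $[b_1, b_2]$, the loop-proximal signal position
is therefore $b_1$ and the loop-distal one $b_2+1$ (`locateCutSites()`);
mirror positions on the 5' arm are computed but feed only the
arm-simultaneity check, since mode evidence in these data is 3'-arm
signal. `classifyMode()` compares mass within ±1 nt of the two sites
(DCL ends are heterogeneous by about a nucleotide; the window is
configurable): below `minTotal` (5) → `no_signal`; less than half the
total at the two sites → `dispersed`; otherwise `loop_last` when distal
dominates proximal two-fold (first cut loop-distal), `loop_first` for
the converse, `ambiguous` between. Because only 3' fragments carry a
poly(A) tail and are cloned, simultaneous first cuts on both arms
predict scarce 5'-arm signal; `armSimultaneity()` reports the 5'-arm
mass fraction with a 10% verdict threshold. `detectMidDuplex()` flags
signal strictly inside the miRNA/miRNA* intervals (≥ 2 nt from the
ends, ≥ 3 reads), the signature of small-RNA-guided self-regulation of
the precursor. Two-duplex precursors are represented as two hairpin
records sharing one sequence, classified independently.

# The synthetic-data generator

`simulateExperiment()` plants known truth at conditions that emulate a
scaled-down two-condition, two-replicate PARE + RNA-seq study:

* **Transcriptome** — 500 genes of 600–2500 nt with 5'UTR/CDS/3'UTR
  structure (CDS divisible by 3, `ATG`…stop), GC 0.5, Poisson(3) intron
  counts recorded in the annotation.
* **Targets** — 50 perfect-complement sites written into CDSs of 20
  random 20–22-nt miRNAs; slice position recorded as site start +
  (L − 10).
* **PARE tags** — exactly 20-nt 5' signatures (real libraries sequence
  longer reads containing the tag; adapter handling is out of scope),
  10^5 per library, multinomial across genes over log-normal baseline
  abundances (sdlog 0.8) shared by all libraries so replicates differ
  only by sampling noise — which is what makes the observed replicate
  $r^2 \approx 0.97$ an emergent property rather than an input. A
  planted target transcript puts 80% of its tags exactly at the slice
  site; the remainder follows a 5'→3' decay background (5' ends
  increasingly frequent toward the 3' end, as expected of exonucleolysis
  survivors; a uniform background is available for null experiments).
* **Condition effects** — responsive genes carry |log2FC| = 2: types I
  and II on the degradation layer, types I and IV on the transcription
  layer, directions 50/50; default fractions 6% / 2% / 6% of genes.
* **RNA-seq** — negative binomial, mean ∝ abundance × length,
  dispersion 0.01, 5×10^5 expected fragments per library.
* **Hairpins** — single stem-loops with ≥ 8-nt loops and classic 2-nt
  3'-overhang duplex geometry (≤ 2 mispairs in the star strand).
  Loop-last hairpins put 80% of their tags at the loop-distal 3'-arm
  cut, loop-first at the loop-proximal cut; 2% leaks to the 5' arm and
  the rest spreads over the 3' side of the hairpin (only 3' fragments
  are cloned); dispersed hairpins spread uniformly. 40% of hairpins
  receive tags (40 each) by default.

Every output is a pure function of the configuration (each generator
derives a private seed from `cfg$seed` and restores the caller's RNG
state). What the generator does **not** emulate: sequencing errors,
adapters and quality scores, genomic (spliced) coordinates, repeat/ncRNA
contamination, polymorphism, and biological covariance structure beyond
the planted effects. Passing tests therefore demonstrate that the
algorithms recover what they are defined to recover under the stated
noise model — not that real libraries are this clean.

# Numerical choices and degenerate inputs

* `c1 = c2 = 0` (and the saturated degenerate case) → p = 1 by
  definition; zero library totals are errors.
* Mapping supports 0 or 1 mismatches (the pigeonhole construction is
  specific to 1); non-ACGT tags are skipped and counted, unmatched tags
  counted separately.
* Multi-mapper mass uses exact rationals of the form copies/k summed in
  double precision; conservation is asserted exactly in tests.
* `categorize()` takes the median over positions with positive mass;
  "one raw read" boundaries are interpreted on fractional mass
  (≤ 1 → category 4, and a category-4 hit needs mass ≥ 1).
* Ties: tied profile maxima give category 1; tied distal/proximal mass
  gives an ambiguous mode call; increasing the dominance threshold can
  only demote calls (tested as a monotonicity property).
* Empty UTRs give `NA` features; GC = 0 makes MFEI undefined (error in
  `mfei()`, `NA` in `computeFeatures()`).

# Problem sizes

Defaults throughout target desk-scale validation: 500 genes × 10^5 tags
per library for recovery experiments, 2×10^5 genes for null calibration
of the differential test, 100 hairpins for mode recovery, and ≤ 12-nt
sequences for exhaustive folding enumeration. These sizes make every
planted effect comfortably detectable while each stage completes in
seconds to tens of seconds.

# Known limitations

* Gapless target alignment only; no bulges, no translational-repression
  targets (invisible to degradome data by nature).
* The fallback folding score is not a free energy; MFEI values from it
  are comparable within a run, not against published thermodynamic
  values.
* The differential test inherits the random-sampling model's
  anti-conservatism under biological overdispersion — with deeply
  sequenced, noisy replicates, weakly changed genes drift into the
  ambiguous bin rather than "unchanged". A dispersion-aware NB test is
  deliberately out of scope.
* Mapping is transcriptome-space; spliced/genomic alignment and
  repeat/ncRNA pre-filtering are out of scope.

# A worked run

```{r pipeline, eval = FALSE}
sim <- simulateExperiment(simConfig(seed = 1))
res <- runPipeline(sim$transcripts, sim$pareLibraries, sim$rnaseqCounts,
                   sim$mirnas, sim$hairpins, sim$hairpinTags)
res$replicateR2          # log2(RPM + 1) replicate concordance
res$typeSummary          # decay-type counts by direction
head(res$targets)        # validated cleavage sites with categories
table(res$hairpinCalls$mode)
```

The same quantities, recomputed from scratch against planted truth, are
what `scripts/acceptance.R` reports (see the README).
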