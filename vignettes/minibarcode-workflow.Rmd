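---
title: "COI mini-barcoding from guano: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COI mini-barcoding from guano: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batbarcode)
```

## The problem

Bat guano is an abundant, non-invasive DNA source, but fecal DNA is
degraded: the standard 658 bp COI-5P animal barcode rarely amplifies from
it. A mini-barcode — a short (~200 bp) sub-region cut out by degenerate
primers — amplifies reliably from feces, retains most of COI's
species-level signal in bats, and is short enough for paired-end Illumina
amplicon sequencing of pooled samples. `batbarcode` implements the whole
pathway: designing and evaluating such primers, building a curated
reference library trimmed to the amplicon, classifying amplicon sequences
with calibrated confidence, and processing pooled-sample reads into
per-species detection profiles.

This vignette records the models, the tunable parameters, and the design
decisions taken where the underlying methods left genuine choices open.

## Degenerate primers and site scoring

Primers are IUPAC strings stored 5'→3' in their own sense
(`degenerate_primer()`); reverse primers are matched against the plus
strand as their reverse complement, with all coordinates reported 0-based
on the plus strand. Matching is **gapless**: mammalian COI has no length
variation across this amplicon, so insertions/deletions are treated as
non-hits rather than modeled.

A site's weighted mismatch score is

```
score = w_non3 * mm_non3  +  w_3 * (mm_3 - terminal)  +  w_terminal * terminal
```

where `mm_3` counts mismatches in the primer's final `three_prime_window`
bases (default 5) and `terminal` indicates a 3'-terminal mismatch. The
defaults — 0.4 / 1.0 / 3.0 with hit threshold 1.0 — emulate the standard
"default parameters, allowing some mismatch" behavior of microbial primer
analysis tools: a perfect match scores exactly 0, up to two non-3'
mismatches still count as a hit, a single 3' mismatch is borderline, and a
3'-terminal mismatch alone disqualifies a site (polymerase extension is
most sensitive there). All weights are configurable via
`scoring_params()`; none of the package's conclusions hinge on their exact
values because the synthetic worlds plant exact footprints.

`insilico_pcr()` pairs the best below-threshold forward and reverse sites
with the forward footprint strictly upstream, and reports the **product**
(first base of the forward footprint through the last base of the reverse
footprint, inclusive) and the **insert** (product minus both footprints).
With the selected 26 nt forward and 22 nt reverse primers, a 154 nt insert
gives the assay's canonical 202 bp product. This inclusive convention is
the one used in the bundled primer table's amplicon lengths.

## De novo primer design

The design step reproduces conserved-region seeding without requiring a
multiple sequence alignment:

1. find exact 5-mers present in ≥ 60% of targets (`seed_fraction`);
2. anchor every target on its first occurrence of the most widely shared
   seed, discarding targets whose anchor sits more than ±10 nt
   (`band`) from the median anchor — an MSA-free stand-in for positional
   homology;
3. for every primer-length window containing the seed, build per-position
   base frequency profiles and emit the IUPAC code covering all bases with
   frequency ≥ 5% (`base_freq_min`);
4. keep candidates with degeneracy ≤ 512 (`degeneracy_cap`) and score each
   against the target and exclusion sets with the site-scoring machinery.

Candidates are ranked by target coverage (descending), exclusion coverage
(ascending) and degeneracy (ascending). On synthetic worlds with a planted
invariant site, the planted footprint is recovered with coverage 1.0
(tested). Thermodynamic modelling (melting temperature, hairpins, dimers)
is deliberately out of scope; annealing temperatures in the bundled primer
table are metadata only.

One bundled primer (SFF_210f) has degeneracy 576; `primer_pair()` therefore
constructs bundled primers under a raised cap of 1024 while user-designed
candidates default to 512.

## Reference library construction

`curate()` applies filters in a fixed order — marker label, length,
ambiguous characters, lineage depth — and logs the first failing filter per
rejected record, so provenance is reproducible and order-independent. Two
presets mirror the two passes a barcoding study makes over public data:
`"design"` (500–700 nt, ambiguity drop: primer-design input) and
`"reference"` (≥ 500 nt, COI-5P label, genus-or-deeper lineage:
classification library).

`greedy_cluster()` visits records in deterministic order (length
descending, then id ascending); a record joins the first centroid with
identity ≥ t, else founds a new centroid. Identity is matching columns over
alignment columns; equal-length sequences compare position-wise, unequal
lengths fall back to a Needleman–Wunsch global alignment (Biostrings) with
gap penalties high enough that length-matched COI inputs align gaplessly.
The published tools do not document their exact identity definition or
tie-breaking; these are our stand-ins, chosen for determinism, and the
brute-force membership property (every member ≥ t to its centroid; every
founder below t to all earlier centroids) is asserted in the tests.

Trimming to the mini-barcode is **primer-anchored** (via `insilico_pcr()`)
rather than MSA-column-based: exact for records containing the footprints,
and records lacking them are excluded and logged rather than imputed.
Trimming with `keep_primers = TRUE` is idempotent.

## The classifier

`train_bayes()` implements the word-presence naive-Bayes model familiar
from 16S classification, at word size k = 8: the prior for word *w* is
P(w) = (n(w)+0.5)/(N+1) and the species conditional is
P(w|S) = (m(w,S)+P(w))/(M(S)+1), with words counted once per sequence.
Training leaves are species (the original tool trains at genus; this assay
is evaluated at species, so species is the leaf and genus/family/order
confidences roll up the lineage). Records identified only to genus train a
`"<genus> sp."` leaf so they still inform genus-level calls.

`classify_bayes()` finds the maximum-likelihood species over all of the
query's distinct words (ties broken lexicographically, for determinism),
then runs B = 100 bootstrap trials on ⌈W/8⌉ words sampled with
replacement. **A trial whose maximum score is shared by more than one
species abstains rather than tie-breaking.** This is a deliberate
departure from blanket lexicographic tie-breaking: a query sharing no
words with the training set scores identically for every species, and a
deterministic tie-break would then manufacture confidence 1.0 for the
alphabetically first taxon — precisely the failure mode the off-target
(arthropod) screen exists to prevent. With abstention, such queries earn
uniformly low confidence and fall out at any sensible threshold, while
ordinary queries are unaffected (score ties between real candidates are
measure-zero events under the log-likelihoods involved). Confidence at a
rank is the fraction of trials agreeing with the candidate at that rank,
hence non-decreasing from species toward order; the accepted rank is the
deepest one with confidence ≥ c. The default c = 0.8 is the assay's
operating point: a tradeoff between correctly classified sequences and
false-positive risk, and the threshold sweep (`threshold_sweep()`) lets a
study re-derive its own. The RNG seed is a mandatory parameter (default 1)
and calls are bit-reproducible given it.

`classify_tophit()` is the alignment-style alternative: best identity
against every reference, a tie set within `tie_epsilon` of the best, and
assignment at the deepest rank unanimous across the tie set. On novel
species (absent from training) it must assign *some* species and therefore
produces more species-level false positives than the Bayes classifier at
c = 0.8 — a property the tests assert, and the reason the Bayes classifier
is the default for fecal samples.

## The pooled-sample read pipeline

Reads carry a fixed universal tail on each primer (UT1 forward, UT2
reverse) from the two-step indexed amplification. `strip_primers_tails()`
searches the first few offsets (default window 3 nt) of each mate for
tail+primer at weighted score ≤ 1.0 and removes them; pairs missing either
primer are rejected (configurable). Reads are short enough relative to the
tailed amplicon that read-through into the opposite adapter cannot occur,
so no 3' trimming is performed.

`merge_pairs()` aligns the reverse complement of the reverse mate against
the forward mate at all overlaps ≥ 20 nt, maximizing matching columns
(ties: fewer mismatches), and fails pairs whose best overlap exceeds a 10%
mismatch rate. Consensus on agreement keeps the base at quality
min(Q1+Q2, 45); on conflict it keeps the higher-quality base at quality
|Q1−Q2| — the standard contig-assembly consensus rule; the upstream tools
specify only their names, so the rule is stated here explicitly and
asserted in tests with planted conflicts.

`screen_dereplicate()` drops reads containing ambiguous bases or outside
`l_expected ± 10` nt (the expected insert length derives from the active
primer pair: 154 nt for the default pair) and collapses exact duplicates
with abundances. `flag_chimeras()` is a deliberately simplified two-parent
(bimera) model: candidate parents are same-length uniques at ≥ 2× the
query's abundance; over ordered parent pairs and crossover points, the
best chimeric model must beat the best single parent by ≥ 3 matching
positions and reach ≥ 99% identity to the query. These parameters are
documented, configurable, and validated on constructed bimeras only — the
goal is to remove obvious PCR artifacts from profiles, not to reproduce
any particular tool's decision boundary.

`profile_pool()` classifies each unique at c = 0.8 and aggregates
abundances per species. The detection rule — a species is reported when it
has ≥ 10 classified reads *and* ≥ 0.1% of kept reads — is an explicit
stand-in: the source workflow reports "small proportions" without a
numeric criterion, so the defaults are chosen to sit well below the rare
species of a 1:192 mixture at 20,000 read pairs (~104 expected reads,
~0.5%) while excluding stray misclassifications; both knobs are
configurable and echoed in every profile. Off-target screening classifies
the same uniques against separate (e.g. arthropod) models; a hit is a call
accepted at genus rank or deeper, since an order-level match against a
single-order reference carries no detection information.

## Evaluation framework

`leave_out_eval()` follows the standard leave-out design: dereplicate the
trimmed library at 100% identity, hold out 5% uniformly at random, train
on the rest, classify the held-out sequences, and score each at each rank
as **correct** (classified at the rank to its true taxon), **false
positive** (classified at the rank to another taxon) or **false negative**
(not classified at the rank) — a strict partition, so the three
percentages sum to 100 in every cell. Held-out sequences whose species
vanished from training stay in the denominator: that is the
incomplete-database realism the assay faces in production. Whether the
original subsample was drawn per-cluster or uniformly is not documented;
uniform seeded sampling is adopted. `threshold_sweep()` computes bootstrap
confidences once per query and re-thresholds them over 0.5–1.0 (step 0.05,
a choice — only the range is prescribed), which makes false positives
non-increasing and false negatives non-decreasing in the threshold by
construction.

`panel_resolution()` scores a one-barcode-per-species panel leave-self-out:
a species is *species-resolved* iff no other species carries an identical
barcode; otherwise it is *congener-shared* when all sharers are of its
genus, else *cross-genus-shared*. The three categories partition the
panel. The original exercise also consulted external databases for
ambiguous cases, which is out of scope here — within-panel comparison is
the reproducible core, and the acceptance tolerance on the published panel
reflects that difference.

`detection_metrics()` scores a profile against a truth set: sensitivity is
the percentage of truly present species detected; specificity is 100 iff
no detected species lies outside the truth (otherwise the percentage of
detections that are true) — a species-list notion appropriate to presence
surveys, where a single spurious species is the failure that matters.

## The synthetic data generator

`simulate_reference_world()` emulates what makes COI barcoding work in
bats: low intraspecific variation against high interspecific divergence,
protein-coding constraint, and conserved primer sites. A random stop-free
coding root (vertebrate mitochondrial code; stops TAA, TAG, AGA, AGG) gets
exact resolutions of the primer pair's footprints planted at the canonical
positions; genus, species and individual sequences then derive by
hierarchical mutation with branch rates set so expected pairwise
divergences hit the targets (defaults: 12% between genera, 5% between
congeners, 0.5% within species — typical COI figures for mammals).
Substitutions avoid footprints, never create frame-0 stops, and favor
third codon positions 3:1 for coding realism; the substitution model is
deliberately simple (uniform base choice, no transition bias, no rate
heterogeneity, no indels) because no acceptance property depends on it.
Realized divergences are reported on the object and their ordering is
asserted in tests.

`simulate_pooled_reads()` draws read pairs multinomially from the planted
pair's amplicons with tails prepended, applies a constant-quality
substitution error model (default Q33, matching the average read quality
context of the real pooled-guano runs; error rate 10^(-Q/10), no indels),
and is byte-deterministic per seed. What the generator does **not**
emulate — PCR amplification bias, quality decay along reads, indel errors,
co-amplified prey DNA, haplotype sharing between real sister species —
bounds what passing tests show: they validate the machinery and its
statistics, not field performance on real guano.

Two deliberate consequences for the evaluation properties:

* The leave-out accuracy property uses an evaluation library with several
  haplotypes per species (6 sequences per species at 1% within-species
  divergence). Real reference databases carry dozens of sequences per
  species, so a 5% holdout virtually never removes a species' entire
  representation; a minimal 3-sequence world, by contrast, often collapses
  a species to a single 154 nt haplotype at dereplication, turning a
  holdout into a guaranteed miss and measuring database completeness
  rather than classifier quality.
* Real *Myotis* sister pairs share mini-barcodes; the generator's species
  do not (divergence targets keep them apart), so panel-resolution on
  synthetic worlds scores 100% species-resolved and the published ~92%
  figure can only be checked against the real panel data.

## Problem sizes and numerical choices

The shipped tests run on worlds of 2–4 genera × 3 species × 3–6 sequences
(27–72 records, 154 nt inserts), pools of 300–20,000 read pairs, and 100
randomized brute-force oracle cases for the site scanner; the full suite
completes in well under a minute and the acceptance computation (20,000
pairs end-to-end) in seconds. Floating-point comparisons in monotonicity
checks use 1e-9 slack; identity thresholds are compared with ≥ / ≤
directly since identities here are exact rationals of small denominators.
Ties anywhere (site scans, cluster visiting order, candidate species) are
broken by position or lexicographic order so that every result is
reproducible bit-for-bit given the seeds.

## Known limitations

* Gapless primer matching cannot represent indel-containing binding sites
  (irrelevant for mammalian COI, wrong for loci with length variation).
* The chimera flagger models two-parent crossovers only, on equal-length
  uniques.
* The classifier's accuracy claims are calibrated on synthetic worlds;
  real-world accuracy is bounded by reference-database completeness and
  voucher quality, which the package can measure (leave-out evaluation)
  but not fix.
* External reference datasets (public barcode databases, the assay's
  published supplementary panels) are not redistributed; functions that
  evaluate against them expect the files to be supplied by the user.
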