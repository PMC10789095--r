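---
title: "Methods: linking dosage sensitivity and phase separation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking dosage sensitivity and phase separation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdosage)
```

This vignette is the package's own account of its models and of the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The scientific setting

Dosage-sensitive genes are those for which losing one copy
(haploinsufficiency) or gaining one (triplosensitivity) causes disease.
A mechanistic account runs through liquid–liquid phase separation:
condensate formation is concentration-dependent, so halving a protein's
supply — or truncating away its phase-separation-prone region — can push a
cell below the saturation threshold. The package operationalizes two sides
of this picture:

* **TruncPS** asks whether the region a truncating variant removes is
  phase-separation prone. It matters only for variants whose transcripts
  *escape* nonsense-mediated decay (NMD) — degraded transcripts make no
  protein — so the package also implements the rule-based NMD-escape
  classifier and the ClinVar-style variant triage that feeds it.
* **DosPS** inverts the logic: if dosage sensitivity and phase separation
  are coupled, constraint statistics estimated from population genetics
  (pLI, LOEUF) and from copy-number data (pHaplo, pTriplo) should predict
  phase-separating proteins without looking at the sequence at all.

## Sequence features

All features operate on uppercase amino-acid strings over the canonical
alphabet plus `X`. `X` is excluded from composition counts but kept in
denominators: ambiguity dilutes a proportion rather than inventing signal.

**Hydropathy** is the Kyte–Doolittle value rescaled to `[0, 1]` by
`(KD + 4.5) / 9` and averaged. **NCPR** is `(n_{K,R} − n_{D,E}) / L`.
Histidine is treated as neutral throughout — the convention at neutral pH
used by the charge-patterning literature and by localCIDER-style tools.

**Kappa** compares the observed charge asymmetry deviation `δ` (averaged
over sliding windows of 5 and 6 residues) against `δ_max`, the largest
deviation any rearrangement of the same composition can achieve. How to
compute `δ_max` is the one genuinely delicate numerical choice in this
module. Segregated block arrangements (`+` block, `−` block, neutral
block) are the textbook answer, but for short sequences they are *not*
optimal: with only a handful of sliding windows, boundary effects reward
arrangements that pad neutral residues around and between the charge
blocks. We therefore use two regimes:

1. when the composition admits at most 20 000 distinct charge
   arrangements (every sequence up to length 11, and sparse compositions
   beyond), `δ_max` is found by exhaustive enumeration — exact by
   construction;
2. otherwise we search the neutral-padded block family
   `0^a +^{n_+} 0^b −^{n_-} 0^c` over all `(a, b)` splits. We verified by
   brute force at lengths 12–14 (18 compositions) that the family attains
   the true maximum once the boundary regime ends. When the neutral count
   is large, the `(a, b)` grid is scanned at a coarse stride and refined
   locally; `δ_max` values are cached per composition.

Degenerate inputs return the sentinel `−1`: sequences shorter than 6
residues (no window statistics), chargeless sequences, and compositions
with a single arrangement (`δ_max = 0`). Downstream models receive the
sentinel literally plus a `kappa_defined` indicator, so tree models can
split on definedness instead of relying on silent imputation.

**Low complexity** uses the SEG scheme: Shannon entropy
`K2 = −Σ (n_i/W) log₂(n_i/W)` over sliding windows of `W = 12`, triggers
at `K2 ≤ 2.2` bits, extension of each trigger run over adjacent windows
with `K2 ≤ 2.5` bits, and the covered-residue union as the region. The
original algorithm's final minimal-probability refinement is omitted: the
toolkit consumes low-complexity content only as a coverage proportion, for
which the trigger/extension stage is the decisive part. Sequences shorter
than one window have proportion 0.

**Disorder** has two modes. `external` ingests per-residue `D`/`O` calls
from any predictor the user trusts (e.g. an ESpritz-style tool run at a 5%
false-positive threshold), validated against the sequence length. The
built-in `baseline` applies the Uversky charge–hydropathy boundary
locally: residue `i` is disordered when its centered 25-residue window has
`|NCPR| > 2.785·⟨hydropathy⟩ − 1.151`. This baseline is a transparent
stand-in with the right qualitative behaviour (charged, hydrophilic
stretches are disordered; hydrophobic cores are not); outputs carry a
`mode` tag so baseline calls are never mistaken for a trained predictor's.

## TruncPS

The training unit is a labelled region. Positives emulate curated
phase-separating regions; negatives are (a) the remainder regions of the
same proteins (longer than 20 aa) and (b) regions sampled from
non-phase-separating proteins with lengths drawn from the positive length
distribution, at 2 negatives per positive — the curation protocol of the
source datasets (93 positives, 56 remainder + 186 sampled negatives at
default scale). "Truncated region" means the wild-type residues lost,
`[first_lost_residue, L]`; the retained fragment is not scored, and a
truncation losing the whole protein is rejected as degenerate.

The classifier is gradient-boosted trees. Defaults: 150 rounds, depth 3,
learning rate 0.1, row subsampling 0.8, `min_child_weight` 8, `gamma` 1,
single-threaded with a derived seed, all exposed as arguments. The
coarse-leaf regularization (shallow depth, large minimum child weight)
deserves a note: with a few hundred training regions and six features,
deeper unregularized trees produce a jagged response surface between the
two class clouds — scores that oscillate along a path of smoothly changing
features. Held-out discrimination is unaffected (the cross-validated AUC
is the same to two decimals either way; the suite computes it), but
jagged scores would make single-protein truncation sweeps noisy. Coarser
leaves give piecewise-constant, near-monotone responses at no measurable
AUC cost, so they are the default.

Model selection and honesty checks use stratified 5-fold cross-validation
with rank-based AUC on held-out folds. The suite verifies that label
permutation collapses CV AUC to chance and that a leaked perfect feature
is recovered at AUC 1 — the usual guards that the CV plumbing neither
leaks nor destroys signal.

## NMD-escape rules and variant handling

PTC coordinates are 1-based cDNA positions of the *first nucleotide* of
the stop codon. The convention is a design choice (codon-start makes exon
containment unambiguous); the start-proximity rule measures from the first
nucleotide of the start codon for the same reason. The four rules are
taken literally: "last 50 nt" is inclusive at both ends, "< 150 nt" is
strict, "> 400 nt" is strict; rules combine by OR and all firing rules are
reported. A single-exon transcript fires the last-exon rule by
construction. When `cds_start` is unknown the classifier still answers if
any other rule fires, and errors (rather than guesses) when the verdict
would hinge on the start-proximity rule.

Nonsense PTCs are codon-aligned arithmetic,
`cds_start + 3⌊(pos − cds_start)/3⌋`, validated against the transcript
sequence when available. Frameshift PTCs come from applying the indel and
translating the shifted frame; a stop upstream of the indel keeps original
coordinates, one downstream is reported in mutated-transcript coordinates
and flagged. Frameshifts with no downstream stop are reported as
`no_stop` and excluded from NMD classification rather than guessed;
splice-disrupting variants have no defined transcript outcome and are
reported `NMD-undetermined`. Variant triage follows the ClinVar
conventions: pathogenic or likely pathogenic, no conflicting
interpretations, at least one review star; unknown significance terms are
dropped loudly, and the filter is idempotent.

The whole rule classifier has a second, deliberately plain implementation
(`nmd_rules_reference()`, a loop-based transcription of the four rules)
used to build simulated truth tables and as the opposing side of
dual-implementation agreement tests over hundreds of random gene models —
two code paths, one contract.

## DosPS

Training pools both phase-separating classes as positives (53 + 70 at the
emulated scale) and samples 282 negatives without replacement. Genes with
any missing feature are dropped at training — imputing a constraint score
would fabricate exactly the information the model is supposed to exploit —
and receive an explicit `NA` with a reason at prediction. Features are
z-standardized on training rows; means and SDs travel with the model. The
fit is ridge logistic regression (glmnet, `alpha = 0`), with the
conventional inverse-strength parametrization mapped as
`lambda = 1/(n·C)`. The grid over `C` (and, for provenance, over seeds —
they only move fold assignment and the negative draw) is scored by
stratified 5-fold CV AUC on the training set; the winner is refit on all
training rows. Whether to standardize and which selection criterion to
use were open choices; both are recorded in the serialized model so a
reader can reconstruct the preprocessing exactly.

## Evaluation machinery

AUC is computed from mid-ranks, `P(s⁺ > s⁻) + ½P(tie)` — exact, not
trapezoidal. The repeated-subsampling protocol draws `2 × n_pos` negatives
without replacement per repeat, independently across 50 repeats, and
reports all repeats plus the mean; with an exhaustible pool every repeat
degenerates to the same sample, which the tests assert. Stratified k-fold
splitting shuffles within class and deals round-robin, so per-fold class
counts are within one of proportionality.

DM normalization sorts genes by the confounder (ties broken by gene id for
determinism), forms windows of 50 genes advancing by 25, anchors the final
window to the end so every gene is covered, and takes each window's median
(even-sized windows: mean of the two central values). A gene covered by
several windows gets the *mean* of their medians — the per-gene assignment
is not specified by the defining equation, and the mean is symmetric,
deterministic, and reduces blockiness at window seams. Rows return in the
caller's original order.

## What the generators emulate — and what they do not

The synthetic generators are first-class, tested code; every quantitative
claim in the package is made on their output. They emulate the
*statistical shape* of the curated datasets: disordered, low-complexity,
charge-blocky positive regions versus folded hydrophobic negatives, with
class separation driven by a latent mixture weight whose distributions
overlap between classes (so no single feature is a perfect classifier and
combining features genuinely helps); curation-scale counts (93/56/186
regions, 53 + 70/282 training proteins); log-normal protein lengths with
median ≈ 400 aa; dosage scores as monotone maps of Gaussian latents, so a
planted shift of `d` standard deviations on one feature has the analytic
single-feature AUC `Φ(d/√2)` — the recovery target the tests check at
`d = 2` (`≈ 0.9214`) and `d = 0`.

They do **not** emulate: homology and phylogenetic correlation between
proteins, real secondary structure, the composition biases of specific
condensate families, genomic context (real exon-length and isoform
distributions), or correlated missingness in constraint tables. Embedding
vectors, when requested, are noise plus a class offset — a shape for
testing pooling and plumbing, not biology. Passing tests therefore
demonstrate that the machinery is correct and calibrated on data with
known answers; they do not certify performance on real proteomes.

The truncation-sweep protein is a *designed fixture*, not a random draw:
a 30-residue folded cap, a 250-residue phase-separation-prone core (a
low-entropy G/S/Q motif with balanced, blocky K and D runs), and a
120-residue tail in which hydrophobic residues are interleaved at a
linearly increasing rate via a golden-ratio low-discrepancy rule — no RNG
anywhere. The geometry makes the designed protein's weakest PS content
distal: each step of the truncation point toward the N-terminus adds
residues at least as PS-prone as those already lost, so the lost-region
score should be non-decreasing in lost length, and the sweep (step 4,
minimum lost length 21 — the training floor) measures exactly that as a
Spearman correlation. A stochastic fixture would have turned this check
into a lottery over draws; a fixed design tests the model, not the seed.

## Problem sizes and determinism

Default scales — 93 + 242 regions, a 400-residue sweep protein at step 4,
200/600 training and 200/2000 evaluation genes for the planted-shift
recovery, 500 gene models for the rule-agreement check, 50 subsampling
repeats — were chosen so that every Monte-Carlo tolerance in the tests is
comfortably wide at desk scale while the complete suite and the
acceptance script each run in about a minute on one CPU.

All randomness descends from a single integer seed through a splitting
function, so: identical seeds reproduce every table, model file and CLI
output byte for byte (asserted in the tests); different components draw
from decorrelated streams; and xgboost runs single-threaded with an
explicit seed. JSON model files store doubles with 17 significant digits,
which reparse to identical binaries.

## Known limitations

* The baseline disorder caller is a charge–hydropathy heuristic; for real
  analyses, supply an external predictor's per-residue file.
* `δ_max` for long mixed compositions relies on the block-family search;
  its exactness was verified at the lengths where brute force is feasible,
  and the coarse-grid refinement could in principle miss a razor-thin
  optimum for very long sequences (the cache and tests bound this risk at
  small n).
* The NMD rules are the standard positional heuristics; they do not model
  tissue-specific NMD efficiency or isoform choice, and splice-disrupting
  variants are counted but never assigned a PTC.
* DosPS accepts extra numeric score columns but deliberately does not
  re-implement any external sequence-based phase-separation predictor.
* Frameshift PTC positions downstream of the indel are reported in
  mutated-transcript coordinates (flagged); projecting them back through
  the indel would be ambiguous for insertions.
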