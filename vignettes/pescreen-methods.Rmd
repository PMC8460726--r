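---
title: "Quantifying prime-editing screens and modeling the fold increase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying prime-editing screens and modeling the fold increase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescreen)
```

## The problem

Prime editing writes small, programmable edits (substitutions, insertions,
deletions) without double-strand breaks. Its efficiency varies strongly with
the target sequence and the pegRNA design, so editor variants are compared on
*libraries* of pegRNA/target pairs integrated into cells, read out by amplicon
deep sequencing. `pescreen` implements the computational side of such a
screen for the comparison of a baseline prime editor (PE2) with a variant
carrying a single-strand-DNA-binding domain (hyPE2):

1. **Demultiplexing** — each integrated amplicon carries an 18-nt barcode;
   reads are assigned to pairs by exact match of a 22-nt key (the 4 nt
   immediately upstream of the barcode plus the barcode).
2. **Outcome classification** — the wide target (4-nt flank + 20-nt
   protospacer + NGG PAM + 20-nt flank, 47 nt) is excised from each read and
   compared with the unedited and edited references.
3. **Frequency statistics** — intended/unintended/indel frequencies, the
   coverage filter, and the pseudocounted fold change between editors.
4. **Featurization** — a fixed 1,820-feature encoding of each pair.
5. **Model selection** — seven learners over fixed hyperparameter grids,
   grouped fivefold cross-validation, Spearman evaluation on a grouped
   held-out set, tree-SHAP attribution, and PBS-melting-temperature binning.
6. **Simulation** — seed-deterministic generators for library designs, screen
   reads with planted outcome rates, and fold-change tables with a planted
   melting-temperature effect, so the whole chain is testable without any
   sequencing download.

## Read assignment and classification

Assignment is exact-match only: one mismatch anywhere in the 22-nt key, or an
N at any key position, leaves a read unassigned, and a read containing the
keys of two distinct pairs is treated as ambiguous and discarded, so ambiguity
never inflates a pair's denominator. We scan the whole read for the key rather
than anchoring at a fixed offset, which makes the result invariant to leading
adapter or pad sequence.

The wide-target region is located by exact match of the two constant 10-nt
anchor sequences that border it in the amplicon; reads in which either anchor
cannot be found are discarded and excluded from all denominators. The
classification rules are:

* **intended** — the region equals the edited reference exactly (the read
  contains the desired edit and no unintended mutation). An intended
  insertion or deletion alone is therefore *intended*, not an indel.
* **wild type** — the region equals the unedited reference exactly.
* **indel** — the region length differs from both references, or the region
  has the length of one reference but a global gapped alignment against it
  (match 1, mismatch −1, gap opening 2, gap extension 0.5) reports an
  insertion or deletion. The alignment step matters for pairs whose intended
  edit is itself a deletion: a stray deletion of the same length elsewhere
  restores the edited length and would otherwise be miscalled as
  substitutions.
* **unintended edit** — a substitution-only mismatch (same length, no gaps).

All internal coordinates are 0-based half-open; the one exception presented to
users is the edit/window offset convention relative to the nick site (between
protospacer positions 17 and 18, the Cas9 H840A nick): edit offsets are
1-based (offset 1 = first nucleotide 3′ of the nick), while the substitution
window includes offset 0 for that same base so that the documented −10..+25
window covers 36 positions ending at the last wide-target base. The source
wording calls this a "40-nt region" although the inclusive span is 36
positions; we implement the stated offsets and note the discrepancy rather
than guess. The per-position substitution counts are averaged **over
positions** (the other reading — over replicates — does not type-check
against a single sample), and a base counts as a substitution only in reads
that carry no indel, so nothing is double-counted against the indel
frequency.

## Frequencies and the pseudocounted fold change

All frequencies are `reads in class / total classified reads × 100`; pairs
with fewer than 100 reads are excluded (99 reads excluded, 100 retained).
The fold change between editors is pseudocounted,

$$\mathrm{fold} = \frac{\mathrm{hyPE2\ \%} + 0.1}{\mathrm{PE2\ \%} + 0.1},$$

which keeps the ratio defined at 0% PE2 efficiency and damps spurious fold
changes at very low efficiencies (0.015% → 0.15% gives 2.2-fold rather than
10-fold, while 1.5% → 15% gives 9.4-fold). Pairs with PE2 efficiency below
1% are stratified out of fold-change analyses as error-prone; the boundary
value 1.0% counts as *high* because the exclusion is phrased as "lower than
1%". Within the low stratum we also report the pairs whose hyPE2 efficiency
reaches 1% (the rescue statistic).

## The 1,820-feature encoding

The total feature count is fixed; the per-group breakdown is our own
registry (the groups are named in the source, their exact sizes are not):

| group | size |
|---|---|
| one-hot nucleotide per wide-target position | 47 × 4 = 188 |
| one-hot dinucleotide per wide-target position pair | 46 × 16 = 736 |
| one-hot nucleotide, 3′ extension (RT template + PBS), right-aligned in 42 nt | 42 × 4 = 168 |
| one-hot dinucleotide over the extension window | 41 × 16 = 656 |
| position-independent mono/di counts × (wide target, PBS, RT template) | 20 × 3 = 60 |
| scalars | 12 |

The 12 scalars are four melting temperatures (PBS:target duplex; RT template
in RNA/DNA-hybrid mode; full extension; PBS − RT difference), three GC counts
and three GC fractions (PBS, RT template, extension), the self-folding
minimum free energy of the extension, and an on-target activity score. The
layout is serialized (with an md5 checksum) alongside every model, and an
alternative breakdown summing to 1,820 can be swapped without touching the
learners.

**Melting temperatures** use the two-state nearest-neighbor model at its
widely used default setting: unified DNA/DNA stacking parameters with
terminal initiation terms, 50 mM Na⁺ with the entropy salt correction
0.368 (N−1) ln[Na⁺], 25 nM per strand. The RNA/DNA-hybrid mode uses the
Sugimoto hybrid table with its single initiation term. The implementation is
validated against independently computed reference values frozen into the
tests.

**Self-folding MFE** defaults to ViennaRNA's `RNAfold` when it is on the
`PATH`. The bundled fallback is a deliberately small stacking model (GC/AU/GU
pairs, minimum hairpin loop 3, only stacked pairs carry energy,
−(s₁+s₂)/2 per stack with s = 3/2/1 kcal/mol for GC/AU/GU) whose dynamic
program is verified against exhaustive enumeration of all secondary
structures on short sequences. Isolated pairs are energetically neutral, so
sequences with no complementary stretch of length ≥ 2 fold to 0.

**On-target score.** The external deep on-target model is pluggable, not
bundled: scores come from a user-supplied table; otherwise the column is a
documented constant (default 0) with a manifest warning. A constant column is
inert in every learner used here.

## Model selection

The data unit is the pegRNA (barcode replicates collapse); the response is
the adjusted fold change. The train/test split samples whole *groups* —
connected components of pairs sharing a spacer or a target sequence, so a
PAM-silent variant always travels with its parent — until the test side
reaches the requested fraction; partition sizes are exact up to one group.
Cross-validation folds are group-aware for the same reason: the source does
not state whether its folds were, but fold leakage would undermine the same
invariant the split enforces.

The seven learners and their grids are fixed: boosted trees (two variants)
over {50, 100} estimators × {5, 10} depth × {1, 2} min leaf × {0.1, 0.2}
learning rate (16 configurations); random forest over the same tree grid
without the learning rate, crossed with three max-features rules — all, √p,
log₂p — giving 24 configurations (the source text says 16 for every learner;
we enumerate the full 24 and record the discrepancy in run manifests); L1,
L2 and L1L2 linear regression over 16 penalties log-even in [10⁻⁶, 10⁶]; an
RBF-kernel SVM over 4 × 4 values of C and γ log-even in [10⁻³, 10³]. Linear
and SVM learners are trained on the log fold change with features
standardized on training statistics only; tree ensembles use the raw target
(Spearman evaluation is invariant to the monotone transform). Both boosted
learners use histogram split finding, which is exact on this one-hot
dominated matrix; the classic-GBM variant differs from the XGBoost variant
by dropping the leaf-weight regularization. Ties in the CV score break
toward the smallest grid index. The winner is the learner with the highest
mean CV Spearman ρ; the held-out test ρ is computed once per learner, after
selection, and influences nothing.

Attribution uses exact tree SHAP on the boosted-tree model (the attributions
sum to prediction − expected value; the additivity residual is asserted in
tests) with features ranked by mean |attribution|. Although the original
figure labels the attribution model a "classifier", the prediction task is a
regression and we attribute the regressor. The fold increase is also
summarized in PBS-Tm bins <20, [20,30), [30,40), [40,50), ≥50 °C with
median, quartiles, and 10th/90th percentiles.

## What the simulators emulate — and what they do not

`designLibrary()` mirrors the screening-library arithmetic: with defaults it
creates 507 base pegRNAs (25% deletion-, 25% insertion-, 50%
substitution-inducing), a 158/507 fraction of PAM-silent variants (the
parent's edit plus an NGG→NGA change on the same target), and 3 barcodes per
pegRNA — 665 pegRNAs, 1,995 oligos. Barcodes are unique with pairwise
Hamming distance ≥ 3. PBS lengths are drawn from 7–17 nt and RT-template
lengths from 10–23 nt, typical pegRNA design ranges. The eight-stratum
efficiency sampling used to pick the original pegRNAs needs the original
screen data and is emulated only as the PE2-efficiency mixture below.

`simulateReads()` draws each pair's reads from a multinomial over (intended,
indel, unintended substitution, wild type) and embeds the region in the
amplicon structure pad–anchor–region–anchor–upstream4–barcode–pad.
Sequencing errors (default 0.1% per base) are placed outside the 22-nt key
so demultiplexing truth stays exact; an opt-in mode puts them in the key to
measure assignment loss. The error model is uniform — no Illumina quality
profiles, no PCR bias — so tests validate the quantification chain, not
robustness to realistic noise.

`simulateFoldTable()` plants the headline effect: log fold = 2.4 − 0.05 ·
Tm(PBS) + N(0, 0.2), i.e. roughly 4-fold at 20 °C decaying to ~1-fold near
50 °C, with PE2 efficiencies from a mixture containing a 15% sub-1% stratum
(uniform on [0,1)%) and a log-uniform [1,40]% remainder. The slope sign and
the decade over which the effect decays mirror the observed binned trend;
the noise level is chosen so the trend is clear but individual pairs scatter
visibly. Because these defaults are the study conditions for the acceptance
properties, they are fixed here and not adjusted elsewhere.

**Validation studies.** `runPlantedRateStudy()` (100 pairs × 5,000 reads)
runs the full chain and reports the mean absolute error between planted and
estimated intended percentages; sequencing error is off in this study so the
planted multinomial proportions are exactly the generation probabilities and
the comparison isolates the pipeline. `runFoldIncreaseStudy()` (480 base
pegRNAs + 25% variants = 600 pegRNAs, 15% test fraction) runs featurization,
the grouped split, the full seven-learner selection, SHAP, and binning. The
problem sizes match the scale of the real library; a single run takes a few
minutes on one CPU. Passing these studies shows the machinery recovers
planted structure at screen scale — it does not show that real screens are
this clean, that the error model is realistic, or that the planted
Tm effect has the real data's effect size.

## Numerical and degenerate-input choices

* Efficiency of a zero-read pair is undefined (`NA`), and the pair is
  excluded downstream, never silently 0.
* `adjustedFoldChange(0, 0)` = 1 by the pseudocount; negative efficiencies
  are an error.
* Constant predictions (e.g. an over-regularized linear model) get Spearman
  ρ recorded as 0 with a warning instead of `NA`.
* Reads shorter than the 22-nt key are unassigned, not an error; an empty
  read set tallies to all-zero counts.
* Tm requires ≥ 2 nt (a stack needs two); MFE of sequences shorter than the
  minimal hairpin is 0.
* All stochastic steps take an explicit integer seed, restore the caller's
  RNG state, and are reproducible byte-for-byte given (data, seed).

## Known limitations

* Exact-match demultiplexing discards reads with any key-region error —
  conservative by design; no mismatch-tolerant rescue is attempted.
* Anchor-based wide-target localization assumes the constant amplicon
  backbone; amplicon designs with different anchors must pass them
  explicitly.
* The gapped-alignment refinement only examines reads whose region length
  matches a reference; balanced insertion+deletion events that restore the
  length *and* align gap-free as few substitutions would be called
  substitutions.
* The bundled folding model is a teaching-grade stacking model, not the
  Turner model; use the ViennaRNA engine for production feature extraction.
* The on-target score is a lookup, not a bundled network; with no table the
  column is constant and carries no information.
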