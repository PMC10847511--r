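---
title: "Scoring homologous recombination deficiency and testing its drug-response associations"
author: "hrdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring homologous recombination deficiency and testing its drug-response associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdscreen)
```

## The problem

Homologous recombination deficiency (HRD) leaves two kinds of measurable
footprints in a tumor genome: structural "scars" in the copy-number
landscape, and a characteristic single-base-substitution pattern
(signature 3). In clinical tumors both footprints predict sensitivity to
platinum agents and PARP inhibitors. `hrdscreen` implements the full
analysis chain needed to ask whether a cell-line screen shows the same
association: scar scoring, signature similarity, HR-gene alteration
annotation, and per-assay drug-response statistics. Because the real
inputs are large external downloads, the package also ships a synthetic
cohort generator with exact ground truth; this vignette explains the
model, the parameters, and the design choices, and what the validation
does and does not establish.

## Scar scores from allele-specific segments

The unit of input is an allele-specific copy-number segment: an interval
with total, major (`a_cn`) and minor (`b_cn`) copy number, `a_cn >= b_cn`
enforced at read time (swapped with a warning if needed, since the three
rules are allele-order agnostic — downstream logic only ever inspects
`b_cn`). Coordinates are 1-based inclusive. Chromosome geometry comes from
an arm table (lengths plus centromere intervals); the packaged
`toy_genome()` (3 x 100 Mb, centromere 45–55 Mb) is used throughout the
tests so every expected count can be derived by hand.

The three components, with all constants exposed in `scar_config()`:

* **Genomic LOH** (`loh_min_len = 15` Mb): count segments with
  `b_cn == 0` and `total_cn >= 1` longer than 15 Mb. Abutting LOH
  segments are treated as one region for the whole-chromosome exclusion:
  a region reaching both chromosome ends contributes nothing (such
  chromosome-scale LOH arises from whole-chromosome loss, not from the
  recombination-repair defect the score targets).
* **TAI** (`tai_min_len = 11` Mb): count segments with `a_cn != b_cn`,
  length at least 11 Mb, that touch a chromosome end and do not extend
  strictly into both arms. "Touching" is `start <= 1 + t` or
  `end >= chrom_length - t` with `telomere_tolerance` t = 0 by default;
  real segment tables rarely reach literal base 1, so t is configurable.
  "Crossing the centromere" is operationalised as
  `start < centromere_start && end > centromere_end`; a segment that
  merely overlaps part of the centromere interval is not penalised,
  since segmentation output over the unmappable centromere is arbitrary.
* **LST** (`lst_min_seg = 10` Mb, `lst_smooth_len = 3` Mb): per arm,
  clip segments to the arm, drop pieces shorter than 3 Mb, fuse
  same-state neighbours (state = the `(total_cn, b_cn)` pair, since an
  allele-specific transition is a transition) separated by at most 3 Mb,
  then count junctions between different-state neighbours that are each
  at least 10 Mb with a gap of at most 3 Mb. Fusion is deliberately
  limited to gaps within the smoothing scale: a same-state pair separated
  by a larger uncovered gap stays separate, and junctions across such
  gaps never count, so sparse segment tables do not manufacture
  transitions.

The **HRD score** is the plain sum TAI + LST + LOH; no ploidy adjustment
and no dichotomisation at a clinical cutoff are applied — the association
layer analyses the continuous score. Sex chromosomes are scored if present
in both the profile and the arm table; behavior follows the inputs.

The defining semantics of each rule are locked by independent brute-force
enumerators in the test-suite (literal loops over the rule text, written
in a different style from the vectorised implementations); 100 random
profiles per run must agree exactly.

## Signature-3 similarity

Each sample's SNVs are counted into the standard 96 pyrimidine-centred
trinucleotide channels (substitution class major; 5' then 3' flank minor;
purine-reference records reverse-complemented; indels/MNVs dropped with a
logged count). The reported quantity is the plain cosine similarity
between the raw count spectrum and reference signature 3. This is a
deliberate simplification of likelihood-based signature tools: the cosine
is the quantity of interest here, is scale-invariant, and requires no
fitted exposures. A per-channel `weights` hook is exposed for users who
want exome-coverage normalisation; raw counts are the default.

The package cannot redistribute the COSMIC v2 matrix, so it ships a
synthetic, clearly labelled stand-in (`synthetic_signature_set()`):
"Signature 1" caricatures CpG deamination (60% of mass on the four
`N[C>T]G` channels), "Signature 3" is flat except for zero mass on those
four channels, "Signature 5" is uniform. The zero channels give an exact
orthogonality test case and make the two mixture components
distinguishable. Every packaged check (self-cosine = 1, monotone recovery
of the mixture weight) is independent of the specific values, so
substituting the genuine COSMIC file changes results only in the obvious
way.

## Alteration annotation

Deleterious mutations are selected by one of two dataset dialects: a
single dataset annotation equal to `"damaging"` (case-sensitive — the
label is a controlled vocabulary, not free text), or truncating variants
plus missense variants called deleterious/damaging by *all ten*
functional-impact predictors (SIFT, Polyphen2, LRT, MutationTaster,
MutationAssessor, FATHMM, PROVEAN, MetaSVM, MetaLR, M-CAP). A missense
variant with any missing predictor call is dropped with a warning: absent
evidence cannot satisfy an all-of-ten requirement.

Locus-specific LOH comes from the minor-allele copy number at the mutated
locus: 0 means the wild-type allele is lost, 1 or more means it is
retained, unknown values fall back to the companion dataset's estimate,
and a sample whose only panel mutations remain unknown is excluded from
group comparisons rather than guessed.

*BRCA1* methylation silencing uses both promoter-region beta values
(> 0.3) with expression below the 10th percentile, or, in the array
dialect, at least 15 of 17 probes with beta > 0.2 and expression below
the 30th percentile. "Expression below x%" is interpreted as a percentile
rank across the cohort: the thresholds come without units, and percentile
rank is the only scale-free reading that works for both RNA-seq and
array expression. Methylation criteria for HR genes other than *BRCA1*
are not hard-coded (no published thresholds exist); the generic per-probe
rule is exposed so users can configure their own.

Samples are then grouped: `BRCA_altered` (BRCA1/2 mutation with LOH, or
*BRCA1* methylation), `HRR_LOH_pos` / `HRR_LOH_neg` (other panel-gene
mutation with/without LOH), `WT` (no deleterious panel mutation), or
`excluded`. The two comparison schemes draw on these groups:
BRCA-altered vs WT, and HR-altered vs WT. For the latter the package
defaults to requiring LOH for non-BRCA genes (mirroring the BRCA
definition); the LOH-free reading is available via
`require_loh_for_hrr = FALSE`, since published descriptions of the
HR-altered set are ambiguous on this point. Gene symbols are matched
case-insensitively after whitespace stripping, and mutations outside the
29-gene panel never influence grouping.

## Association statistics

AUC (area under the dose-response curve; higher = more resistant) is used
rather than IC50, missing values are dropped pairwise and never imputed,
and each assay is analysed separately even when the same drug appears in
several screens. Assays with fewer than `min_altered = 10` altered
samples having an AUC are excluded up front and recorded in a
machine-readable exclusion table, so exclusion counts are auditable.

Group comparisons use the two-sided Mann-Whitney test with effect
summarised as the median AUC difference (altered − wild-type);
`stats::wilcox.test` supplies the exact null distribution for small
tie-free groups and the tie- and continuity-corrected normal
approximation otherwise. Score associations use Spearman rank correlation
with the two-sided p from the t-approximation on rho with average-rank
ties (`exact = FALSE` always, so behavior is uniform across tied and
untied inputs). The Holm step-down correction is applied within the
family of all assays analysed in one invocation — correction families
follow analysis runs, matching per-figure families in screening reports;
`trend` flags unadjusted p < 0.05 and `significant` flags Holm-adjusted
p < 0.05 (alpha configurable). Ranked direction-split summaries
(`summarize_panel()`) order the positive panel by ascending p and the
negative panel by descending p so the strongest effects sit at the outer
ends, and tally trend/significant counts per drug class.

## The synthetic cohort generator

`simulate_cohort()` draws a latent HRD status per sample
(`hrd_prevalence = 0.3`) and lets it drive every data type:

* **Scar events**: per-component Poisson counts with means
  `(tai, lst, loh) = (1.5, 1.5, 2)` for HRD-positive and
  `(0.3, 0.3, 0.3)` for HRD-negative samples — modest values that put the
  two groups' score distributions in clearly overlapping but separable
  ranges on a toy genome. An event grammar places each event so that it
  satisfies its rule exactly and cannot create incidental events: TAI
  events are 12 Mb imbalanced telomere-anchored segments, LOH events
  16 Mb interstitial minor-allele-zero segments, LST events abutting
  12 Mb pairs of different balanced states, and every feature is isolated
  by a 5 Mb uncovered buffer (wider than the 3 Mb smoothing scale), with
  balanced diploid background filling the remaining arm. Planted counts
  are therefore *exact* ground truth, and the central oracle of the
  package is strict equality between the generator ledger and
  `score_cohort()` output. The generator's default genome is
  `toy_genome(8)` — eight 100 Mb chromosomes, i.e. 16 telomeric and 32
  interstitial slots — so Poisson draws essentially never exceed
  placement capacity; genuinely infeasible configurations error rather
  than silently truncate, preserving the declared distribution.
* **SNVs**: per-sample counts are negative-binomial (mean 200,
  dispersion 5); channels are multinomial draws from
  `w * sig3 + (1-w) * sig1` with `w = 0.7` (HRD+) vs `0.1` (HRD−);
  contexts are emitted inline and each record lands on a random strand,
  exercising the reverse-complement path.
* **Alteration mechanisms**: an HRD-positive sample is *BRCA1*-methylated
  with probability 0.2, otherwise carries a deleterious BRCA1/2 (60%) or
  other panel-gene mutation with LOH; 10% of HRD-negative samples carry a
  panel mutation without LOH, passenger mutations in non-panel genes and
  silent panel-gene rows are sprinkled in so the filters have real work,
  and 10% of minor-allele copy numbers are only available through the
  companion-dataset fallback.
* **AUC**: `baseline + auc_effect * auc_noise_sd * z(HRD score) + noise`,
  with the effect applied in the Platinum and PARP-inhibitor classes only
  (5 assays in each of 4 classes by default). The sign of `auc_effect` is
  deliberately configurable: positive emulates a resistance association,
  negative the clinically expected sensitivity, since distinguishing the
  two is exactly what the analysis is for.

One seed fixes the whole cohort bit for bit; each data type draws from
its own sub-stream (`stage_seed()`), so adding assays never perturbs the
segment simulation.

What the generator does *not* emulate: real marginal distributions of
CCLE-like copy-number profiles (real segments are not isolated by clean
buffers), linkage between scar events and the mutated genes, tissue
effects, or cross-screen batch structure. Passing tests therefore
demonstrate that the counting rules, annotation logic and statistics are
implemented correctly and calibrated — not that the pipeline's biological
conclusions transfer to any particular real dataset.

## Numerical choices and validation sizes

* Exact vs approximate tests follow R's standard conventions
  (`wilcox.test` exact for tie-free groups below 50; Spearman p always
  via the t-approximation).
* Holm adjustment delegates to `stats::p.adjust(method = "holm")` behind
  the `holm_adjust()` surface; a literal step-down implementation in the
  test helpers checks it on 1,000 random vectors per run.
* Statistical validation sizes, chosen to give tight Monte-Carlo
  intervals while keeping the default suite comfortably fast: 100 random
  profiles for the scar oracles; 200-sample cohorts (seeds 1–3) for
  ledger equality; 20 replicates per mixture weight at 5,000 SNVs for
  monotone recovery; 500 null replicates of a 20-assay, 200-sample
  family (SNV mean reduced to 50 there — SNV load is orthogonal to the
  association null) for the type-I/FWER checks, judged against the exact
  binomial 99% band around 0.05 and a 3-SE Holm margin; 100 replicates
  for recovery of a planted `auc_effect = 0.5` resistance shift.
* Degenerate inputs error early and specifically: empty spectra have no
  defined cosine (callers decide on exclusion), constant score or AUC
  vectors have no defined correlation (the assay is skipped with a
  logged reason), p-values outside [0, 1] are refused, and malformed
  segment rows are reported with their line number.

## Known limitations

* The scar constants are the conventional defaults; published scar
  pipelines differ in sub-variants (e.g. ploidy-conditional TAI filters),
  so absolute scores are comparable only under a stated `scar_config()`.
* The packaged signatures are synthetic; real signature-3 values require
  the genuine COSMIC v2 matrix.
* Methylation silencing calls for non-BRCA1 genes, germline/somatic
  distinction, reversion mutations, dose-response curve fitting and
  cross-screen AUC harmonisation are out of scope; inputs are assumed
  already segmented, called and curve-summarised.
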