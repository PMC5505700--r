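---
title: "Methods: the Tsc2 loss-of-function signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Tsc2 loss-of-function signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsc2sig)
```

## The problem

Inactivation of *TSC1* or *TSC2* releases mTORC1 from inhibition and drives
tumor formation in tuberous sclerosis complex and in a subset of cancers,
notably bladder carcinoma.  Given expression profiles of Tsc2-knockout (KO)
and wild-type (WT) mouse dermal fibroblasts, with and without the mTORC1
inhibitor sirolimus, the pipeline in this package

1. calls genes differentially expressed between KO and WT (the *Tsc2
   loss-of-function signature*, each gene tagged +1 or -1),
2. quantifies how much of that signature sirolimus reverses (a check that
   the dysregulation is mTORC1-dependent),
3. screens the reversed genes against annotation categories (a local
   stand-in for an ontology portal) to nominate secreted signaling
   candidates such as *Lgals3* / galectin-3, and
4. projects the signature onto a human tumor cohort as a per-tumor *TSC2
   expression score* and asks whether tumors with non-silent *TSC1/TSC2*
   mutations score higher.

Alongside, it implements the clinical association statistics used with the
galectin-3 measurements: Pearson and BMI-adjusted partial correlation with
lung function, factorial simple main effects of angiomyolipoma status,
group percent changes, Kaplan-Meier estimation and the log-rank test.

All analyses operate on `log2(x + 1)`-transformed non-negative abundances
(FPKM-like for the fibroblasts, normalized-RSEM-like for the tumors).

## SAM differential expression

Differential expression uses the SAM moderated statistic.  Unpaired
two-class (KO vs WT, KO the test class):

$$d_g = \frac{\bar y_{g,KO} - \bar y_{g,WT}}{s_g + s_0},\qquad
s_g = \sqrt{a\,(SS_{WT} + SS_{KO})},\quad
a = \frac{1/n_1 + 1/n_2}{n_1 + n_2 - 2},$$

so that $d_g$ at $s_0 = 0$ is exactly the pooled-variance t statistic (a
frozen oracle test asserts agreement to 1e-12).  Paired two-class
(sirolimus vs vehicle within a genotype) uses per-line differences
$z_j$ with $d_g = \bar z / (s_g + s_0)$,
$s_g = \sqrt{\sum_j (z_j - \bar z)^2 / (n(n-1))}$.

**Fudge factor.**  $s_0$ is selected over the percentiles
$0, 5, \dots, 100$ of the $s_g$ distribution by minimizing the coefficient
of variation of the median absolute deviations of $d$ within 100
$s$-quantile windows; ties break toward the smallest candidate, and fewer
than 100 genes fall back to the 5th percentile.  The selection is
deterministic given the data.

**Permutation null.**  Designs at the study's size are enumerated
exhaustively, including the observed assignment: all
$\binom{n_1+n_2}{n_1}$ relabelings (20 for 3 vs 3) and all $2^n$ sign-flip
patterns of the pair differences (8 for 3 pairs).  Larger designs are
sampled with an explicit seed.  Each permutation's $d$ vector is sorted and
the expected order statistics $\bar d_{(i)}$ are rank-wise means.

**Calling and FDR.**  For each threshold $\Delta$ the asymmetric rule
applies: the positive cut is the smallest positive $d_{(i)}$ with
$d_{(i)} - \bar d_{(i)} > \Delta$ (mirrored for negatives) and genes beyond
a cut are called.  The estimated FDR at $\Delta$ is
$\pi_0 \cdot \overline{\#\{\text{null } d \text{ beyond the cuts}\}} /
\#\text{called}$, with
$\pi_0 = \min(1, \#\{d \in [q_{25}, q_{75}]\ \text{of null}\} / (m/2))$.
Two deliberate choices here:

* The *mean* count of null exceedances is used by default rather than the
  median of the later samr implementation.  With 20 permutations the median
  is 0 whenever half the permutation rows are less extreme than the
  observed one, so the estimate claims 0% FDR for the top genes of a pure
  null dataset and calls them; the mean does not have this failure mode.
  The median remains available (`sam_config(fdr_stat = "median")`).
* The observed partition — in both label orientations (identity and
  mirror; the all-$+1$ and all-$-1$ sign patterns for paired designs) — is
  excluded from the false-count aggregation, while remaining in the
  enumeration and in $\bar d_{(i)}$.  It is not a draw from the null: with
  planted signal it leaks the full observed effect into the counts and
  imposes an FDR floor of about $2\pi_0/\text{#perms}$ (~0.085 at 20
  permutations), which at a 10% target suppresses genuinely regulated
  genes.

With these choices, null simulations at the default target (10%) leave the
median realized false discovery proportion at 0 over 50 replicates, and the
planted-effect recovery simulations reach mean recall above 0.9 with mean
FDP below 0.15 — both recomputed by the test suite.

The smallest grid $\Delta$ reaching the target is used (largest, with a
warning and possibly zero calls, if none does).  Per-gene q-values are the
smallest estimated FDR at which the gene enters a call set, monotonized
along the $|d - \bar d|$ ranking by a running minimum from the weak end, so
called genes never exceed the target.  Genes with zero variance everywhere
get $d = 0$ and are never called.  With 20 (or 8) permutations the
attainable FDR values are coarse; estimates are reported exactly as
computed, without interpolation.

## Signature, reversal, screen

The signature is simply every called KO-vs-WT gene with direction
$\mathrm{sign}(d)$.  A signature up-gene counts as *reversed* only when the
paired sirolimus comparison calls it significantly in the opposite
direction — intersecting two FDR-controlled lists, not merely checking the
sign of $d$.  Percentages are rounded half up, and the report always
recomputes them from its own counts.  The annotation screen keeps genes
belonging to *all* required categories (e.g. "extracellular region" and
"signaling") using a user-supplied gene-to-category table; it composes,
so filtering by a union of categories equals sequential filtering.

At the study design (3 lines per genotype, 8 sign-flip patterns) the
paired comparison has limited power for the minority direction, so realized
reversal percentages on simulated data sit below the planted fractions;
with 4 lines they track the planted 92%/80% up to the ~10% FDR
contamination of the signature.  This is a property of the design, not of
the estimator.

## TSC2 expression score

For the human cohort: $y = \log_2(x+1)$; per gene, z-scores across **all**
tumors with the sample ($n-1$) standard deviation; down-genes multiplied by
-1; a tumor's score is the mean of the direction-aligned z-scores over the
signature genes present.  Standardizing over all tumors (mutants included)
is the literal reading of the source procedure, which mentions no
subsetting; the sample rather than population denominator is a choice the
score is insensitive to (it cancels in the z-score up to a constant factor
common to all tumors — the affine-invariance test covers this).  Signature
genes absent from the matrix or with zero variance are dropped and counted,
so the score stays a mean of what was actually used.  Mouse-to-human
mapping goes through an explicit two-column ortholog table; colliding
orthologs with conflicting directions drop the human gene with a warning.

Mutant status is one-or-more mutation records in *TSC1*/*TSC2* with a
variant classification in the non-silent whitelist (missense, nonsense,
frameshift ins/del, splice site, in-frame ins/del, nonstop, translation
start site, 5'UTR — the MAF spellings of the prose categories;
configurable).  The default group comparison is a two-sided Mann-Whitney U
with normal approximation and tie correction (the source shows boxplots
with a p-value and no test name; Welch t is available).

## Clinical statistics

* Pearson r with two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$, df $n-2$.
* One-covariate partial correlation
  $r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
  \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$, df $n-3$.
* Two-way factorial ANOVA (Type III omnibus via sum-to-zero contrasts) with
  simple main effects of one factor at each level of the other, as
  cell-mean contrasts against the pooled residual variance of the full
  interaction model.  Values of %FEV1 exactly 80 belong to the mild
  (`> 80`) stratum.
* Percent change $100(\bar x_{alt} - \bar x_{ref})/\bar x_{ref}$ with a
  Welch t p-value.
* Kaplan-Meier curves via the survival package, median = smallest observed
  time with $S(t) \le 0.5$ (a 1e-9 tolerance absorbs floating-point error
  in the product at an exact 0.5 step), and the two-group log-rank test.

## Synthetic data: what it emulates, and what it does not

The generators produce data with the statistical structure the analysis
assumes, plus ground truth, so every stage is testable offline.

**Fibroblast experiment.**  3 WT and 3 KO lines, each with a vehicle and a
sirolimus sample paired within line.  Expression is Gaussian on the
log2 scale — baseline $\mathcal N(3, 1.5^2)$ per gene, a per-line intercept
(sd 0.2) shared by the two samples of a line, planted KO effects of
$\pm 2$ log2 units on 10% (up) and 5% (down) of genes, and noise sd 0.5 —
then back-transformed by $2^y - 1$ floored at zero.  Sirolimus removes the
KO effect for 92% of up-genes and 80% of down-genes (the planted reversal
fractions), shifts a shared treatment gene set in both genotypes (10%
down, 1% up of background genes), and an additional KO-only set (10%),
emulating a WT response that is nearly a subset of the much larger KO
response.  Planted-set sizes round half up, so counts are exact.
Noise is Gaussian on the transformed scale rather than negative-binomial
on counts because the entire analysis surface operates on transformed
FPKM/RSEM values; the generator does not emulate library-size or GC
artifacts, batch effects, count discreteness, or real fibroblast
co-expression structure — so passing tests demonstrate correctness of the
statistical machinery, not performance on real RNA-seq.

**Tumor cohort.**  391 tumors, 43 of them (11%, rounded half up from the
requested fraction) with one non-silent TSC1/TSC2 record; signature genes
shift by direction $\times$ 0.5 log2 units in mutants over a
$\mathcal N(5, 1.5^2)$ baseline with noise sd 1.  A fraction of wild-type
tumors carries a silent TSC1/TSC2 record and some tumors carry non-silent
records in decoy genes, exercising the classifier.  Real tumor
heterogeneity (subtypes, purity, co-mutation) is not modeled.

**Clinical and survival tables.**  These stand in for patient-level source
data that are not redistributable here and are *calibrated to the reported
designs*: 64 untreated patients with r(Gal-3, %FEV1) = -0.32,
r(Gal-3, BMI) = 0.315 and r(%FEV1, BMI) = 0.083 — the last solved from the
partial-correlation identity so the BMI-adjusted partial correlation
centers on -0.366; 72 treated patients at r = 0.066; measurement groups
with planted percent changes of +67, -25 and -35 at the reported group
sizes; and survival arms of 22 male / 24 female knockouts with target KM
medians 28 and 24 weeks against 28 fully-censored controls.  For survival,
the target is the *Kaplan-Meier* median: under the
smallest-time-with-$S \le 0.5$ convention the estimator equals the
$\lceil n/2 \rceil$-th order statistic, whose sampling median at these
group sizes sits 6-10% below the true exponential median, so the
exponential rate is set (via the Beta median of that order statistic) to
make the estimator median-unbiased for the target.  The follow-up horizon
of 41 weeks reproduces the reported censored fractions (8/22 and 9/24).

## Reproducibility and problem sizes

Every generator takes an explicit integer seed and equal seeds give
byte-identical outputs; the pipeline derives per-stage seeds from one
global seed so stage-level reruns match full runs, and the manifest records
an MD5 checksum per artifact (rerunning a configuration reproduces every
checksum).  The simulation studies in the tests and in
`scripts/acceptance.R` use 2000-gene fibroblast matrices, 200-gene null
matrices, the full 391-tumor cohort, and 100-400 Monte-Carlo replicates for
the clinical summaries — sizes chosen so the whole suite runs in a few
minutes on one CPU while keeping Monte-Carlo error a fraction of the
tolerances used.

## Known limitations

* With 20 (unpaired) or 8 (paired) permutations, FDR estimates take few
  distinct values; a requested 10% target is met conservatively or not at
  all in a given dataset.
* The paired 3-line design has limited power for minority-direction calls
  (see reversal section).
* The annotation screen is a set-membership filter, not an
  over-representation test; it does not reproduce any particular ontology
  snapshot.
* The score treats signature genes equally; no weighting by effect size or
  refinement for co-mutations is attempted.
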