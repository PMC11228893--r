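---
title: "Estimating 47S rDNA copy number from aligned reads and screening cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating 47S rDNA copy number from aligned reads and screening cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocn)
```

## The problem

The 47S ribosomal DNA (rDNA) unit encodes the 18S, 5.8S and 28S rRNAs and is
present at roughly 100-600 copies per diploid human genome, spread across the
acrocentric chromosomes. It is absent from genotyping arrays and exome
capture, so its copy number (CN) is invisible to most association studies.
High-coverage whole-genome sequencing makes CN estimable from read depth, but
realigning hundreds of thousands of cohort genomes to a tailored assembly
containing an rDNA contig is impractical. `ribocn` implements a proxy
estimator that works directly on standard reference-aligned data, plus the
cohort machinery needed to analyse the resulting estimates at biobank scale:
batch adjustment, relatedness handling, derived phenotypes, and association
screens. Everything is testable end to end on synthetic data with known
ground truth.

## The 18S Ratio estimator

Standard assemblies retain several high-identity analogues of the 18S
subunit (on chromosome 21 and on unplaced scaffolds). Reads originating from
any genomic rDNA copy pile onto those analogue intervals, so the quantity

$$\mathrm{18S\ Ratio} = \frac{\#\{\text{reads overlapping 18S analogue regions}\}}
{\#\{\text{reads mapped to chromosomes 1--22}\}}$$

is proportional to rDNA CN. Counting is count-once-across-regions: a record
overlapping two analogue intervals contributes one. The default
record-inclusion policy counts every mapped record (mirroring a plain
counting command); `policy = "primary_only"` drops secondary, supplementary
and duplicate records. The ratio is converted to an absolute diploid CN
equivalent by

$$\mathrm{CN} = \mathrm{Ratio} \times \frac{G}{L},$$

with $G = 2{,}875{,}001{,}522$ the summed length of the numbered Hg38
chromosomes and $L = 1{,}871$ the 18S subunit size. Note a documented quirk:
the 18S query itself (unit positions 3658-5526) spans 1,869 bases while the
conventional subunit constant is 1,871; both are configurable through
`conversion_constants()` and the default keeps the published constant.

Two auxiliary constructions support the estimator:

* `loop_rdna_reference()` rotates the rDNA unit so the sequence breaks 2,120
  bases upstream of the transcription start site rather than at the
  promoter, avoiding artificial coverage loss at the unit boundary in
  tailored alignments.
* `find_analogue_regions()` locates 18S analogues in an assembly by an
  ungapped seed-and-extend search (exact k-mer seeds, default word size 11;
  maximal diagonal segments with identity at least `min_identity` over at
  least `min_length` bases, both strands, merged forward-coordinate
  intervals). No aligner parameters for the original discovery were
  published, so `min_identity = 0.90` and `min_length = 100` are exposed as
  configuration; a fixture BED can always be supplied instead of running
  discovery, which decouples counting from aligner drift. The search is
  deliberately ungapped: the real analogue regions are high-identity copies,
  and the contract is validated against an exhaustive sliding-window scan in
  the test suite.

The prior published estimator -- twice the mean 18S depth over the mean
filtered-exome depth, `tailored_cn_estimate()` -- is implemented for
cross-validation. On synthetic panels spanning CN 100-600 the two methods
correlate at Pearson R above 0.95, mirroring the published validation
design.

## Batch structure and relatedness

Coverage-derived estimates shift systematically between sequencing centers.
`center_adjust()` fits `ratio ~ center` on all supplied samples (the global
fit matches how the adjustment was defined; per-subset refits are possible
but off by default) and subtracts each non-reference coefficient, after
which every center mean equals the reference mean to numerical precision;
the operation is idempotent. Center labels come from the sample manifest;
`sniff_center()` optionally applies the first-release read-group heuristic
(`CN:SC` / `Main Phase`) for compatible files.

Relative pairs are classified from KING kinship estimates: monozygotic twins
above 0.4, first degree 0.177-0.354, second degree down to the configurable
second/third boundary, third degree down to 0.0442. The published band edges
overlap in print (0.0844 vs 0.0884); the default boundary is 0.0884, the
canonical KING cutoff $2^{-3.5}$, and the alternative reading is available
through `kinship_thresholds()`. Lower band edges are inclusive, upper
exclusive, so classification is total and disjoint. First-degree pairs split
into parental (IBS0 below 0.0012) and fraternal; putatively parental pairs
with birth years under 10 years apart, or with missing birth years, are
discarded as unverifiable. Families are the connected components of the pair
graph (`build_families()`, deterministic numbering by smallest member id),
and `select_unrelated()` keeps singletons plus the oldest member per family,
ties broken by lexicographically smallest id for cross-run determinism.

## Derived phenotypes

Blood-count ratios NLR, PLR, LMR and SII are computed by
`blood_ratios()`; none of them are calculated for individuals with a zero
lymphocyte or monocyte count (avoiding infinities), and missing inputs
propagate. The methods-section SII formula $N \times P / L$ is implemented;
the main-text rendering "(N x L/P)" is a typographical slip and is noted
here rather than silently resolved.

`blood_composition_pcs()` computes unit-variance-scaled principal components
of the five nucleated white-cell percentages after excluding anyone with
nucleated red blood cells recorded. Because the five percentages are
compositional (they sum to 100), the data have rank at most four and the
first four components carry over 99.99% of the variance -- the package
asserts this property rather than assuming it.

eGFR is computed by the sex-specific piecewise power formulas from
creatinine, cystatin C, or both (`egfr()`), with every coefficient
configurable through `egfr_coefficients()`. Three deliberate fidelity
decisions, each with an escape hatch:

* The printed below-knot creatinine exponent (0.9 male / 0.7 female,
  duplicating the knot $\kappa$) is the default even though it differs from
  the canonical CKD-EPI exponent and is *positive*, which makes eGFR
  non-monotone in creatinine below the knot. Monotonicity therefore holds on
  the above-knot branch, in age, and in cystatin C.
* The printed cystatin-only formula evaluates its above-knot term on
  creatinine; the default here uses cystatin C for internal consistency,
  with `strict_as_printed = TRUE` reproducing the printed form verbatim.
* The creatinine unit conversion defaults to the printed 0.0133 (umol/L to
  mg/dL) rather than the conventional 1/88.42.

Renal disease groups (glomerular disease N00-N08, kidney failure N17-N18,
urolithiasis N20-N23) are built from first-report dates; the special-meaning
sentinel date 1903-03-03 is treated as missing, and a participant is a
control for a group only when no member code carries a valid date.

Cohort quality-control subsets nest: `FILTERED` (blood cancers/disorders,
pregnancy, leukocytes > 200, hemoglobin > 20 g/dL, hematocrit > 60%,
platelets > 1000, processing delay > 36 h), then `FILTERED_UNMEDICATED`
(listed medications, other prescriptions), then `HEALTHY` (any recorded
illness, congenital codes, current smoking, BMI > 30). The engine is the
method; the disease/medication code lists are study-specific configuration
supplied through `cohort_filter_rules()` (the defaults ship empty, editable
placeholders). Missing values never trigger an exclusion on their own: a
participant is excluded only on positive evidence against a rule.

## Association machinery

`fit_association()` standardizes every continuous variable (response
included, in the linear family) before fitting, so linear effects are
standardized betas and logistic effects are log-odds per SD of exposure,
reported with Wald p-values, t-based (linear) or Wald (logistic) 95%
intervals, and $e^\beta$ odds ratios. Categorical covariates enter as
indicators with the most frequent level as reference. The phenome screen
applies the published eligibility filters -- at least 200 cases for binary
phenotypes and measurement in at least half the cohort -- and controls
Benjamini-Hochberg FDR across the eligible set per invocation; the full
PHESANT variable-type decision tree is deliberately not reproduced
(phenotype types are declared in the manifest). Supporting statistics:
genomic inflation $\lambda = \mathrm{median}(\chi^2_{1-p,1}) /
\chi^2_{0.5,1}$, standard errors recovered from beta and p by inverting the
two-sided Wald test, fixed-effect inverse-variance-weighted Mendelian
randomization (reducing to the Wald ratio for one instrument; random-effects
IVW, MR-Egger, clumping and harmonization are out of scope), effect-size
profile correlation over FDR-significant features, equal-count quantile
trends with t-based intervals, and Wilcoxon rank tests for center
comparisons.

## What the synthetic generators emulate

The generators exist so every estimator property is checkable against known
truth; each returns a truth table alongside the data, and all are
bit-reproducible given a seed.

* **Reads** (`simulate_alignment()`): each read falls in the rDNA
  compartment with probability $cL/(cL+G)$ for true CN $c$, toy subunit
  length $L$ and background size $G$, and is placed uniformly within an
  analogue region; background placements are uniform over the background
  excluding the analogue intervals, keeping the two compartments disjoint as
  the binomial model assumes. Records are placement-only (no base calls or
  quality strings) because the estimator consumes placements; sequencing
  error, GC bias and mappability structure of real data are *not* emulated,
  so passing tests validate counting semantics and the ratio algebra, not
  robustness to alignment artifacts. Default configurations declare two
  100 Mb background contigs in the SAM header (no sequence is needed for
  counting), so the analogue self-contribution to the numbered baseline,
  $cL/G$, stays far below sampling noise, as in the real genome.
* **Counting-level panels** (`simulate_sample_counts()`) draw region counts
  binomially at full genome scale (about 6e8 reads, 30x) for many samples
  cheaply; `simulate_depth_pairs()` feeds the tailored estimator with
  Poisson-scale depth noise.
* **Kinship** (`simulate_kinship()`) builds families as chains of pairs with
  kinship inside the requested band, IBS0 and birth years consistent with
  the parental rules, plus unrelated filler pairs.
* **Cohorts** (`simulate_cohort()`): true CN is Gaussian, mean 315, sd 80,
  truncated to 50-800 (matching the population range of roughly 100-600
  copies); families share a latent component,
  $\mathrm{CN} = \sqrt{\rho}\,z_{\mathrm{fam}} +
  \sqrt{1-\rho}\,z_{\mathrm{ind}}$, giving intra-family correlation $\rho$
  exactly in expectation. The observed ratio is $\mathrm{CN}\,L/G$ plus a
  per-center offset (default: a positive Sanger-vs-deCODE shift sized well
  below one association SE once center is a covariate, so the adjustment
  path is exercised without dominating) and measurement noise (default sd
  2e-6 on the ratio scale, about 3 copies, the order of binomial counting
  noise at 30x). Continuous traits are built so the generating standardized
  beta is the regression target; binary traits use a logistic link at 8%
  baseline prevalence. A seasonal trait fluctuates with month while CN does
  not, emulating the reverse-causality null battery.

## Numerical choices and problem sizes

Tolerances and sizes used by the validation suite (chosen as realistic desk
scale for the estimator's statistics):

* Alignment-level recovery runs at CN 100/300/600 with 1e5 reads against a
  2 x 1e8 base background and asserts recovery within 3 binomial standard
  errors; the million-read regime changes nothing but runtime.
* The proxy-vs-tailored concordance panel uses 94 samples (the size of the
  original validation population) and requires Pearson R of at least 0.95.
* Screen calibration uses 20,000 participants by 100 phenotypes, with
  planted effects at about 11 standard errors.
* Parameter-recovery checks run 50 replicates at n = 150,000 with the
  published-scale anchors (standardized beta 0.0273; kidney-failure
  log-odds ln 1.04). With calibrated 95% intervals the per-endpoint
  coverage over 50 replicates is itself binomially distributed; a
  400-replicate diagnostic of the same machinery measures 94-95% empirical
  coverage.
* Genomic inflation is checked analytically at p = 0.5 and within 0.01 of 1
  on one million uniform p-values.
* Center adjustment must equalise means within 1e-10; family clustering is
  compared against an independent union-find oracle over 200 random graphs.

Degenerate inputs follow one rule: flag, do not guess. Zero baselines flag
the sample rather than aborting the batch; all-missing birth years resolve
deterministically and are flagged; unparseable dates, non-positive
biomarkers and non-binary logistic responses are errors naming the record or
column.

## Known limitations

The analogue search is ungapped and toy-scale; it is not a replacement for a
production aligner on a full assembly (no e-values or bit scores, no
assembly masking). CRAM support follows what the alignment I/O layer
provides; reference-requiring decoding is the caller's configuration. GC and
mappability correction and within-rDNA variant genotyping are out of scope.
The synthetic cohort is a linear-logistic world: passing recovery tests
demonstrates correctness of the fitting and filtering machinery, not that
real biobank confounding behaves this simply.
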