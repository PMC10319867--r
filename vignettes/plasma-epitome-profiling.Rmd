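---
title: "Plasma epitome profiling with pepscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma epitome profiling with pepscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

# The measurement model

Plasma epitome profiling reads the relative abundance of immunogenic
epitopes with libraries of monoclonal antibodies (mAbs) printed on
biochips. The readout is a single-binder capture inhibition assay: the
immobilized mAb captures a biotinylated pooled-plasma tracer, and
unlabelled analyte in the sample competes the tracer away. The assay is
therefore *inverse*: the more epitope a sample carries, the lower the
chemiluminescent signal (relative light units, RLU).

Two chip layouts are supported. A QP69 run holds 18 positions of which two
are reserved for tracer-only (no sample) measurements of the maximal
signal RLUmax; those two are averaged per mAb before normalization. A
QP300 run holds three positions, one tracer-only and two samples, and the
single RLUmax is used directly. Normalization is strictly per run — no
information crosses run boundaries, which makes the normalized scale
robust against run-level gain drift and is asserted as a scale-invariance
property in the tests. The normalized value is expressed in percent,

$$\mathrm{BSI} = 100 \cdot \mathrm{RLU} / \mathrm{RLU_{max}},$$

replicates are averaged, and the averaged value is capped at 120. The cap
is applied *after* averaging: the cap belongs to the final analysis
variable, not to individual replicates, so a single outlier replicate is
tempered by the mean before the cap can bite. A run whose RLUmax is zero
marks that mAb missing for the run rather than producing infinities;
missingness then propagates through the pairwise-complete correlation and
training-fold imputation policies downstream.

# The synthetic-data generator

Every stage of the pipeline is exercised against synthetic data with known
ground truth, because the clinical measurement tables behind the original
cohorts are not publicly distributable. The generator emulates:

- **Latent epitope abundance**: log-normal per mAb
  (`baseline_log_mean = 0`, `baseline_log_sd = 0.5` by default — a
  mid-range biological spread for plasma analytes). A planted case effect
  $e$ multiplies case abundances by $\exp(e)$; confounder effects do the
  same for any metadata level (COPD grade, BMI class, smoking class, sex),
  using the categorical codings of a cross-sectional lung-cancer cohort
  (COPD A–D, BMI A–C, smoking pack-year classes, histology codes 0–10) so
  subgroup analyses are exercisable.
- **The competition transfer function**: the assay literature does not fix
  a functional form for how abundance maps to signal, so the generator
  uses the simplest monotone saturating one-site competitive form,
  $\mathrm{RLU} = \mathrm{RLU_{max}} / (1 + a/k_{50})$ with $k_{50} = 1$
  on the latent abundance scale. Zero abundance returns RLUmax exactly,
  which pins the assay-physics limit used in the tests.
- **Noise**: four independent multiplicative log-normal components
  (within-run, run-to-run, operator, reagent lot), each with unit mean so
  that a fractional CV parameter is reproduced exactly in expectation.
  Quantitative noise magnitudes are not published beyond the CV < 20%
  acceptance gate; the defaults (`cv_intra = 0.08`, others `0.05`) were
  chosen once as a realistic mid-range for chemiluminescent microarrays —
  comfortably inside the gate but far from noise-free — and are not
  revisited. Setting all components to zero yields bitwise-identical
  replicates, the basis of several exactness tests.
- **Mimotope sets**: each mAb gets 12 (or more) phage clones over a small
  number of unique 12-mer peptides drawn uniformly from the 20-letter
  alphabet; planted pairs share one peptide verbatim at a configurable
  clone fraction $s$, so the planted redundancy is $\approx s^2 \times 100$.
- **Inhibition curves and sensorgrams**: exact 4PL and two-state model
  evaluations plus optional noise, used for round-trip fitting tests.

What the generator does **not** emulate: spot-level image artefacts,
background correction (inputs are assumed background-corrected), plate
edge effects, batch-correlated missingness, or real plasma protein
concentrations. Passing tests therefore demonstrate the correctness and
calibration of the *statistical pipeline*, not the analytical performance
of any physical assay.

# Analytical QC

CVs use the sample (n−1) standard deviation over the mean, reported in
percent; the definition leaves the denominator unspecified in most assay
write-ups and n−1 is the conventional choice. The intra-run component is
the pooled repeatability (square root of the mean within-run,
within-sample variance over the grand mean), which is nearly unbiased even
with two replicates per run, unlike a mean of tiny per-run CV estimates.
Inter-run, operator and lot components are computed per sample across
groups and then averaged, so biological sample-to-sample spread does not
masquerade as analytical variability. Components with fewer than two
levels are reported missing, never zero. The qualification gate requires
*every* available component strictly below 20%; the published pass rates
report components separately, so the composite rule is this package's
qualification convention, and both the per-mAb worst component and the
pass fraction are returned.

# Assay qualification (4PL)

Inhibition curves are fitted with the four-parameter logistic Hill-slope
model on the log10-dilution axis, since dilution series span decades.
Initialization is fixed (a = max y, d = min y, c = geometric mean of x,
b = 1, with a mirrored start at b = −1), making qualification decisions
reproducible; the (a, d, b) sign ambiguity of the 4PL is canonicalized to
a ≥ d. "Linear inhibitory curves" is interpreted as goodness of the 4PL
fit — R² of the 4PL model against the observed responses, unweighted — and
a log-linear R² is reported alongside for transparency. The gate is
strictly R² > 0.9, and a non-converged fit carries R² = −∞ so it can never
qualify. mAbs qualifying with the total-plasma tracer are assigned to the
QP69 library, with the depleted-plasma tracer to QP300, dual qualifiers to
both (flagged).

# Mimotope redundancy

For mAbs X and Y the redundancy score is the sum over common peptides of
the product of their within-mAb clone frequencies, times 100. Peptide
identity is exact string equality (uppercased on input); motif-level
collapsing is not implemented because no motif-matching rule is published,
and alignment-tolerant comparison is out of scope. The diagonal of the
redundancy matrix is the Simpson concentration of each set (×100), is
reported, and is excluded from all threshold summaries. The "mAbs with a
partner above threshold" count is per mAb — a mAb counts once however many
partners exceed the threshold — with the per-pair count reported
alongside; where several pairs attain the maximum, all are listed. The
implementation is checked against an independent brute-force double loop,
and the Cauchy–Schwarz bound (the score is an inner product of frequency
vectors) is asserted over random sets. The full-scale synthetic library
used in the acceptance checks (173 mAbs; one pair constructed at exactly
92%, five pairs and a triple above 40%, disjoint background) is a planted
stand-in whose summary is exact by construction.

# Pooled screening and correlation structure

The differential rule selects a mAb when |case − control| strictly exceeds
30% of the control value. The published wording says "difference" without
sign and the reported panels mix up- and down-regulated epitopes, so the
absolute-difference reading is the primary rule, with signed up/down
subsets reported. mAbs with a zero or missing control value cannot be
screened and are skipped with notice. Venn regions are counted per exact
membership combination; "shared" means selected in at least two contrasts.

Pearson correlations between mAb columns use observations complete for
each pair ("pairwise"), with a strict listwise mode available; for QP69
data only the 100-fold-dilution subset enters the correlation analysis,
mirroring how the two dilutions are kept as separate variables throughout.
Histogram bins over [−1, 1] have width 0.1 and are right-closed, and the
headline high-correlation fraction counts r ≥ 0.8, so the top reporting
bin [0.8, 1.0] is a single contiguous region. Clustering is Ward on
Euclidean distances (`ward.D2`); rows are sorted by name before clustering
so results are invariant to input order.

# Biomarker panels

Feature screening is nonparametric: the Mann–Whitney U statistic is
computed with midranks and oriented to the case group, so the identity
AUC = U/(n₁n₂) holds exactly and is asserted over random datasets.
P-values use exact enumeration for small samples without ties
(n₁n₂ ≤ 400) and the tie-corrected normal approximation otherwise. FDR
control is Benjamini–Hochberg — the default in the statistical
environments this style of report comes from — with selection at q < 0.01
ranked by |AUC − 0.5|, treating inhibition-inverted markers (AUC below
0.5) symmetrically with positive ones.

The panel model is unpenalized maximum-likelihood logistic regression,
reported per variable as B, S.E., Wald = (B/SE)² on 1 df, its chi-square
p-value, and Exp(B), with the intercept ("Constant") row last. The report
arithmetic is self-consistent by construction (Exp(B) = exp(B),
Wald = (B/SE)² before rounding) and is what the acceptance script applies
to printed coefficient tables. Quasi-complete separation is detected from
the fitting warning and flagged rather than hidden.

Evaluation follows a fixed protocol object: one stratified train/test
split (70/30 by default; 66/34 is a supported convention), model fitting
with stratified k-fold cross-validation repeated on the training set only
(10 folds × 3 repeats by default), and a single ROC on the untouched test
set. Stratification is the package default — plain random splits are
available — because it stabilizes class balance at the cohort sizes used
here. Missing feature cells are mean-imputed from training data only
(per fold inside the CV). SVM, kNN and random-forest model kinds are
invoked through their standard implementations as interchangeable
scorers; only the logistic report is produced in-house. Subgroup ROC
computes scores once and re-evaluates the ROC within each metadata level,
skipping (and reporting) levels that lack a class.

# SPR kinetics

The two-state (conformation change) model is
$$A + L \rightleftharpoons AL \rightleftharpoons AL^{*},$$
with response AL + AL*. With the analyte concentration held constant
within a phase the system is linear, so sensorgrams are evaluated in
closed form from the 2×2 matrix exponential (Putzer's eigenvalue form,
including the defective repeated-eigenvalue case that arises at ka₂ = 0
with kd₁ = kd₂); an independent adaptive ODE integration serves as the
oracle in the tests. The apparent affinity is
K = (ka₁/kd₁)(1 + ka₂/kd₂) and K_D = 1/K, which reduces exactly to the
1:1 Langmuir affinity at ka₂ = 0. Kinetic fitting is global least squares
over the standard concentration series (666–13 nM), on log-scaled rates
from a fixed multi-start grid so the result is deterministic; a
per-concentration mode that averages the apparent K across traces is also
provided, matching the averaging convention of vendor software reports.
Reference-cell subtraction, bulk refractive-index jumps and baseline
drift are not modelled. Competition IC₅₀ uses the same 4PL machinery on
the log-level axis; the competition signal is read at the first
dissociation-phase point, zero competitor levels are dropped before the
log-axis fit, and the result is flagged when extrapolated beyond the
tested range or when the fitted curve does not decrease (no inhibition).

# Problem sizes and numerical tolerances

The test and acceptance suites run at sizes chosen to make their
statistical assertions sharp while staying fast at a desk: 400-sample
cohorts for power/null calibration (held-out AUC > 0.85 on planted
effects of 1.0 natural-log units; 20 label permutations with held-out AUC
expected in [0.4, 0.6]), 1000-replicate Monte-Carlo runs for noise
calibration (3 standard errors), 100–200 random datasets for the exact
identities, 100 seeded curves for 4PL inflection recovery (median within
15% at 5% noise), and 6 noisy sensorgram series for K_D recovery (median
|log10 ratio| < 0.1 at 2 RU noise). Noise-free round trips are asserted
to 1e-6 relative for the 4PL and 1% for the two-state K_D.

# Known limitations

- Real-cohort performance figures (held-out AUCs near 0.84–0.92 on
  clinical lung-cancer data, the 6.69% high-correlation fraction, the
  86%/84% analytical pass rates) depend on unreleased clinical
  measurements and are *not* reproduced here; the synthetic calibration
  suites verify the machinery that would compute them.
- The abundance → RLU link and the noise magnitudes are modelling choices
  (stated above), not measured properties of any instrument.
- Peptide comparison is exact-match only; no panning simulation, no
  mismatch-tolerant alignment.
- No REML variance-component modelling behind the CV decomposition; plain
  CVs are what the qualification convention uses.
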