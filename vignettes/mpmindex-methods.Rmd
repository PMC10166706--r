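---
title: "Scoring microbiome protein metabolism: models, assumptions and design choices"
author: "mpmindex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microbiome protein metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmindex)
```

## The problem

Undigested protein reaching the ceca of broiler chickens is fermented by the
resident microbiome. Depending on which enzymatic routes dominate, that
fermentation is either *assimilative* — feeding amino-acid carbon and
nitrogen into polyamine synthesis, short- and branched-chain fatty acid
production and the urea cycle — or *putrefactive*, releasing ammonia,
hydrogen sulfide, indoles and other metabolites that damage the intestinal
epithelium. `mpmindex` implements a functional-metagenomic scoring of that
balance, the **Microbiome Protein Metabolism Index (MPMI)**, together with
the profiling, classification, qPCR-assay and growth-performance analyses
that surround it in a production trial of a glycan feed supplement
("precision biotic", PB).

## Functional profiles

The analysis starts from KEGG-Orthology-annotated gene counts (samples ×
KO). Counts are **summed and regrouped by Enzyme Commission number**: a KO
annotated to several EC reactions contributes its full count to each of
them. That full-count policy is the package default because regrouping is a
summation over annotations, not a partition of reads; a fractional split
(dividing the count across the mapped reactions) is available via
`regroupKoToEc(split = "fractional")` for sensitivity analyses. Unmapped KO
mass is reported, never silently dropped.

Each sample's EC counts are then **internally normalized** by the summed
counts of a housekeeping reference set — the glycolysis/TCA-cycle module —
which makes profiles invariant to sequencing depth (a property the test
suite asserts over random depth rescalings). The reference membership is not
fixed by the index definition, so the package ships a default list of 18
canonical glycolysis and TCA-cycle reactions (`glycolysisTcaSet()`) and
accepts any user-supplied EC set. Samples whose reference total is zero fail
fast by name; a `pseudocount` switch (+1 on the reference total) exists for
robustness experiments only.

## The index

For sample $j$ with normalized abundances $C_i$,

$$\mathrm{MPMI}_j \;=\; 100 \, a \,
  \frac{\sum_{i \in N} w_i\, C_{ij}}{\sum_{i \in D} w_i\, C_{ij}}$$

where $N$ is the set of 12 numerator (assimilative) marker reactions, $D$
the 10 denominator (putrefactive) reactions, $w_i$ per-reaction
stoichiometric weights and $a$ a global stoichiometric constant. The
embedded catalog (`loadCatalog()`) fixes the 22 reactions and their roles;
four of them double as qPCR markers. Two conventions close the definition:

* **$a = 1$ and $w_i = 1$ by default.** No per-reaction stoichiometry is
  tabulated for the index, so the package adopts the convention that equal
  weighted sums score exactly 100 — the balance point between favorable and
  unfavorable protein metabolism. Both $a$ and the weights are configurable
  (weights through a catalog override TSV) for sensitivity analysis.
* One catalog KO identifier (`K0194`, on the urea-carboxylase row) does not
  match the `K#####` pattern; it is stored verbatim and flagged
  `suspect_kegg` rather than silently "corrected".

The index is scale-invariant per sample and strictly monotone: raising any
numerator reaction's abundance raises it, raising any denominator reaction
lowers it. A sample with zero denominator abundance is flagged with an
undefined index, never dropped.

**Outlier exclusion** before group comparisons removes values outside
$[Q_1 - k\,\mathrm{IQR},\; Q_3 + k\,\mathrm{IQR}]$ with $k = 2$, quartiles
by the linear-interpolation convention (`quantile` type 7). The phrase
"outside the interquartile range (2×)" admits a second reading — a fence of
width $k\,\mathrm{IQR}$ centered on the median — available as
`method = "median"`. Exclusion is applied per group by default; pooled
exclusion before splitting is the caller's choice, as the original analysis
does not state which was used. Group contrasts use the two-sided Wilcoxon
rank-sum test (exact null when both groups have $\le 8$ untied observations)
or the Kruskal–Wallis test for three or more groups.

## Discriminant analysis

`rankFeatures()` trains a random-forest classifier (`randomForest`,
`mtry = 2`, 10,000 trees by default) on the normalized EC profiles and ranks
features by **mean decrease in accuracy** — out-of-bag permutation
importance, unscaled, with lexicographic tie-breaking so rankings are fully
deterministic under a fixed seed. `mtry = 2` is retained as the procedure's
stated setting despite being small for a 30-feature space; it is
configurable. The ranking is truncated to the 30 most important features and
the forest retrained on that submatrix (`truncateAndRetrain()`), limiting
overfitting to the 2,000-odd EC dimensions of a real profile.
`ensembleValidate()` repeats rank-truncate-retrain on independent stratified
60% subsamples and scores each model on its held-out complement, reporting
held-out accuracies and per-EC selection frequencies.

`lfdaEmbed()` projects samples to two dimensions by **local Fisher
discriminant analysis**, written in-package: a local-scaling affinity
(kernel width = distance to the 7th within-class neighbor) weights the
classical between/within scatter matrices, and the generalized eigenproblem
is solved with a small ridge on the within-scatter so wide submatrices
remain usable. The embedding is fitted on the truncated 30-feature space,
consistent with the overfitting-minimization intent; "top-2 coordinates" is
the reading adopted for converting the transform into plot coordinates. The
neighborhood size (7) and ridge ($10^{-6}$ of the mean within-scatter
diagonal) are fixed defaults, stated here because the method's description
names no parameters. One caution the tests encode: any supervised embedding
finds spurious class separation when the feature count approaches the sample
count, so chance-level behavior under permuted labels is only expected — and
only asserted — at dimension well below $n$.

`pathwayImportance()` maps ranked enzymes back to their (at most five)
annotated KEGG pathways with the same full-count policy as the regrouping
step, and signs contributions by the treatment-minus-control mean abundance
difference so the control baseline sits at zero.

## The qPCR estimator (qMPMI)

Four marker reactions (2.3.1.109 and 2.6.1.19 in the numerator, 3.5.3.12 and
2.8.3.18 in the denominator) have blended primer sets — four pairs each,
embedded in the package with the universal 16S pair. Calibration fits the
log-linear model $Ct = m \log_{10} D + b + s(S)$ per primer set on serial
dilutions spanning four orders of magnitude, with additive per-source
offsets absorbing template-source bias (`fitCalibration()`, backed by
`lm`). Relative abundance of marker $i$ in a sample is

$$A_i = 10^{\,Ct_i/m_i - Ct_{16S}/m_{16S}}$$

computed per PCR replicate and averaged on the abundance scale (the assay
runs in duplicate), and

$$\mathrm{qMPMI} = \frac{A_{2.3.1.109} + A_{2.6.1.19}}
                        {A_{3.5.3.12} + A_{2.8.3.18}}.$$

Three numerical points:

* $A_i$ ignores the calibration intercepts, so it equals the true template
  ratio exactly only when all primer sets share a common $b/m$ (equivalent:
  equal efficiency and a common Ct at unit template). Otherwise $A_i$ is
  proportional to the truth with a marker-specific constant — which cancels
  in any within-marker group contrast and in treatment ratios of the index.
  The synthetic generator's defaults use equal $b/m$ so that exactness is
  testable to numerical precision.
* qMPMI is invariant to uniform dilution of the template (both Ct terms
  shift along their calibration lines) and strictly monotone in each
  marker's concentration, mirroring the sequencing-based index.
* **Non-detects.** A well that never crosses threshold within 40 cycles has
  no Ct. The default policy assigns the floor abundance implied by
  $Ct = 40$, keeping the index finite and preserving ordering — the
  situation arises in practice because one numerator marker can be absent
  from untreated ceca entirely. `"censor"` (drop the replicate, flag) and
  `"zero"` are selectable. A failed 16S well voids the sample's wells under
  every policy.

## Growth performance

Per-pen metrics over the 0–42 d grow-out: BWG per bird, ADG, feed
conversion FCR = pen feed intake / mortality-adjusted gain (dead birds
credited at recorded removal weight, else at half the per-bird gain —
deaths assumed uniform in time), corrected FCR with a linear target-weight
adjustment, and

$$\mathrm{EPEF} = \frac{\mathrm{ADG}}{\mathrm{FCR} \times 10}
  \times \mathrm{livability}\,(\%).$$

"Livability" is the standard reading of the efficiency factor's mortality
term. The target-BW correction coefficient is 0 by default — no strain
coefficient is published alongside the index, and the reported acceptance
quantities use printed group means directly, so nothing is guessed. Treatment
contrasts run as one-way ANOVA on pen means (optional block term), with SEM
reported as the pooled residual standard error of a treatment mean.

## The synthetic-data generator

Every input the pipeline consumes can be generated
(`simulateCounts/Qpcr/Pens/Scfa`), with seed determinism contractual: each
generator saves and restores the caller's RNG state and is a pure function
of its `simulationConfig()`. Defaults encode the study conditions: 21
samples per treatment, duplicate wells, 4-order dilution series from two
template sources, 21 pens × 40 birds, +75 g BWG and −0.069 FCR treatment
shifts with between-pen SDs back-computed from standard errors of 17.59 g
and 0.01 at $n = 21$, ~3% mortality. The KO-count model is a depth-scaled
log-normal composition with Poisson sampling; the treatment effect
multiplies numerator-marker KOs (a 3-fold default, detectable but not
trivial at $n = 21$/group) **at the KO level**, so recovery tests exercise
the regrouping logic, not just the index arithmetic. This is deliberately a
stand-in, not an ecological model: no strain dynamics, no compositional
closure beyond the shared depth, no overdispersion beyond the log-normal
baseline — so green tests demonstrate algorithmic correctness and
statistical calibration, not realism of cecal communities.

Problem sizes in the shipped tests are desk-scale by design (40–100 EC
features, 6–21 samples per group, 200-replicate power runs), chosen so the
whole suite exercises every stage in well under a minute of forest training.

One power note: at the SEM-matched pen dispersion, the BWG endpoint alone
has analytic two-sample power ≈ 0.84 at 21 pens/treatment, while the
conversion-ratio endpoint has ≈ 0.997. The detection contract the package
tests — "the trial detects the treatment effect" — is therefore evaluated at
the experiment level, significant on either primary endpoint, which is also
how the original trial reads (its conversion-ratio contrast is far below
α = 0.05).

## Known limitations

* The 2,000+-EC universe of a real gene catalog is not reproducible here;
  synthetic universes are smaller and the package makes no claim of matching
  any particular catalog's EC count or ranking.
* The glycolysis/TCA reference list is a package default, not a KEGG export;
  users with a KEGG license should supply their module's membership.
* LFDA coordinates are defined up to sign and scale; comparisons across
  runs should use geometry (distances, silhouettes), not raw coordinates.
* The qPCR model assumes constant amplification efficiency across the
  4-order dilution range; efficiency drift outside that range is not
  modeled, and melt-curve QC is out of scope.
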