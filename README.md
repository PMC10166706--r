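# mpmindex

Functional-metagenomic scoring of microbial protein metabolism in the
broiler cecum, for poultry-microbiome researchers evaluating dietary
interventions such as precision-biotic glycans.

Undigested protein that reaches the ceca is fermented by the microbiome
either assimilatively (polyamines, short-chain fatty acids, urea-cycle
injection) or putrefactively (ammonia, hydrogen sulfide, indoles). The
package quantifies that balance per bird as the **Microbiome Protein
Metabolism Index**: from KEGG-Orthology-annotated gene counts regrouped by
Enzyme Commission number and internally normalized by the glycolysis/TCA
module,

```
MPMI = 100 · a · ( Σ_{i∈N} w_i C_i ) / ( Σ_{i∈D} w_i C_i )
```

with `N` the 12 embedded assimilative marker reactions, `D` the 10
putrefactive ones, unit weights and `a = 1` by default, so MPMI = 100 marks
the balance point. Around the index the package provides:

- **profiles** — KO→EC regrouping with unmapped-mass reporting, per-sample
  internal normalization (`ECAbundanceMatrix`, a `SummarizedExperiment`),
  KEGG pathway annotation (top 5 per EC);
- **discriminant** — random-forest feature ranking by mean decrease in
  accuracy (`mtry = 2`, 10,000 trees), truncation to the top 30 ECs,
  retraining, ensemble robustness on 60% subsamples, local Fisher
  discriminant embedding, and pathway-level importance aggregation;
- **qMPMI** — the targeted qPCR estimator of the index: embedded primer
  catalog (4 blended pairs per marker reaction + universal 16S), log-linear
  calibration `Ct = m·log10(D) + b + s(source)`, 16S-normalized relative
  abundances `A_i = 10^(Ct_i/m_i − Ct_16S/m_16S)` with replicate averaging
  and non-detect policies;
- **performance** — BWG, ADG, mortality-corrected FCR, cFCR, EPEF, percent
  improvements and pen-level ANOVA;
- **simulate** — seed-deterministic generators for counts, qPCR plates,
  calibration series, pen records and SCFA tables, so the whole pipeline is
  testable with no external data;
- **runPipeline()** — YAML-configurable end-to-end orchestration with
  provenance headers on every artifact.

## Worked example

```r
library(mpmindex)

cat22 <- loadCatalog()
cat22
#> MarkerCatalog with 22 marker reactions ( 12 N / 10 D ), 4 qPCR markers, 17 primer pairs

## synthetic trial: 10 birds/treatment, 100 EC features, 3-fold enrichment
## of assimilative marker genes under treatment
sim      <- simulateCounts(simulationConfig(seed = 42, nSamplesPerGroup = 10, nEc = 100))
rg       <- regroupKoToEc(sim$counts, sim$koToEc)
profiles <- normalizeAbundance(rg$counts, sim$normalizationEcs)
profiles
#> ECAbundanceMatrix: 100 EC numbers x 20 samples
#>   normalization denominators: median 8947  range [ 3713 , 19810 ]

idx <- computeMpmi(profiles, cat22, a = 1)
round(tapply(idx$mpmi, sim$labels, median), 1)
#> Control      PB
#>   231.8   690.4
compareGroups(idx$mpmi, sim$labels)
#>      test_name group_a group_b statistic      p_value
#> 1 mann_whitney Control      PB         0 0.0001826718
```

The treated birds' median index is ~3× the control median — the generating
enrichment — and the rank-sum test flags the shift. The same run extends to
pens:

```r
pens <- simulatePens(simulationConfig(seed = 42))   # 21 pens x 40 birds per arm
pm   <- penMetrics(pens)
an   <- treatmentAnova(pm$cfcr, pm$treatment, pens$block)
#> cFCR: Control 1.846 vs PB 1.784 (P = 0.0016), improvement 3.4%
```

## Documentation

The methods vignette (`vignettes/mpmindex-methods.Rmd`) documents the model
and its assumptions: index conventions, the full-count regrouping policy,
outlier-fence and tie-break conventions, LFDA parameters, qPCR non-detect
policies, what the synthetic generator does and does not emulate, and known
limitations.
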