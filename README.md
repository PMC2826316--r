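# pbfuse

Integrated metabolomic–transcriptomic analysis of designed dose-response
studies, modelled on dietary phenobarbital exposure in the rat (4 doses ×
4 necropsy days × 5 animals). Phenobarbital is the classical non-genotoxic
carcinogen: it reprograms hepatic metabolism (glycogen loss, succinate
accumulation, glutathione induction) and transcription (massive induction of
CYP2B-family xenobiotic metabolism) without damaging DNA. The package is for
toxicologists and computational biologists who want the complete analysis
chain for such studies as tested, reusable R functions — from raw 1D NMR
spectra and probeset-level microarray tables to validated multivariate
models and gene–metabolite correlates — together with a synthetic-data
generator that reproduces the statistical structure of the design so every
stage can be exercised and benchmarked without downloading anything.

## What it computes

**Spectral processing.** 1D ¹H-NMR spectra are integrated into fixed-width
chemical-shift buckets (presets: 0.01 ppm over 0.20–9.95 ppm for liver
extracts, 0.02 ppm over 0.60–8.00 ppm for plasma CPMG, 0.04 ppm over
0.50–5.60 ppm for HRMAS, each excluding its residual-water region); each
spectrum is normalized to a total integral of 10000, optionally
renormalized after excluding the dominant glucose/glycogen resonances
(3.35–4.05, 4.60–4.72, 5.20–5.55 ppm). GC-MS peak tables get the same
constant-total treatment.

**Chemometrics.** PCA and NIPALS partial least squares with the field's
scaling conventions (Pareto for NMR buckets, unit variance for peak tables
and expression). Model robustness uses the cross-validated predictive
ability

    Q² = 1 − PRESS / SS,

where PRESS is the prediction error sum of squares over 7 round-robin
held-out segments ("every 7th sample") and SS the residual sum of squares
of the previous component. Models are additionally validated by Y
permutation (a credible model's Q² must exceed the whole permuted
distribution) and by leave-out dose prediction.

**Expression cascade.** Arrays are globally normalized to mean 500, floored
at 0.01 and per-gene median normalized; probesets must have ≥ 3 present
flags and ≥ 3 samples at ≥ 90 units; a ≥ 1.5-fold change against the
time-matched control median in some (dose, day) cell; then a per-gene
two-way ANOVA (day, dose, interaction) with Benjamini–Hochberg FDR < 0.05
on the treatment effect. Survivors are expressed as ratios to time-matched
control medians, clustered by 1 − Pearson distance, and tested for GO/KEGG
over-representation with exact hypergeometric p-values.

**Data fusion.** Each metabolite's normalized bucket integrals become the
single Y of a PLS regression on the transcriptome X block; a metabolite is
accepted as a significant correlate only if Q² > 0.40 **and** the real Q²
beats all 30 Y-permutation models. Component-1 weights, ranked by
magnitude, name the transcripts tracking that metabolite. Univariate
endpoints (organ weights, Ki67 labeling) are tested by one-way ANOVA with
two-sided Dunnett many-to-one comparisons — computable from raw data or
directly from printed mean ± SD summaries — and lipidomic change lists are
tallied per fatty acid and headgroup class.

## Worked example

```r
library(pbfuse)
design  <- make_design()                     # 80 samples: 4 doses x 4 days x 5 reps
truth   <- default_truth(seed = 7)
spectra <- simulate_spectra(design, truth)
buckets <- normalize_total(bucket_spectra(spectra, bucket_preset("liver_extract")))
renorm  <- renormalize_excluding(buckets, list(c(3.35, 4.05), c(4.60, 4.72), c(5.20, 5.55)))

# dose-regression model of the spectral profile, with permutation validation
val <- permutation_validate(buckets$values, design$dose, n_components = 1,
                            n_permutations = 20, seed = 7)
print(val)
#> permutation validation: real R2 = 0.721, real Q2 = 0.711
#> 20 permutations: max permuted Q2 = 0.004 (real beats 20/20)

# expression cascade on a simulated probeset x sample block
succinate <- metabolite_table_from_buckets(renorm, list(succinate = c(2.39, 2.43)))
expr    <- simulate_expression(design, truth, n_null_genes = 500,
                               metabolite_table = succinate)
cascade <- de_cascade(expr)
#> detected 513 -> fold-changed 186 -> significant 17 probesets

# per-metabolite transcriptome fusion
fused <- fuse_metabolite(t(expr$values), succinate[, "succinate"],
                         "succinate", fusion_config(seed = 7))
print(fused)
#> fusion_result 'succinate': Q2 = 0.536 (threshold-and-permutation PASS)
#>   max permuted Q2 (30 perms) = 0.091; top correlates: succinate_tracker,
#>   CYP2B2, UDP_glucuronosyltransferase_PB
```

The dose model's Q² of 0.71 sits in the range typical of these designs
(0.4–0.7 per day-wise model); the fusion result shows the planted
succinate-tracking gene recovered as the top-ranked correlate, with the
strongly dose-responsive xenobiotic-metabolism genes behind it, and the
acceptance rule satisfied (Q² = 0.54 > 0.40, above all 30 permutations).
`run_pipeline(pipeline_config(seed = 7), "out/")` executes the same chain
end-to-end and writes every stage table plus a deterministic JSON-lines run
log; reruns are byte-identical.

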