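# restflow

Source-space directed connectivity analysis of resting-state
high-density EEG, with a seeded synthetic-cohort generator for
validation.

## What problem this addresses

Epilepsy surgery removes the seizure onset zone (SOZ), yet a third of
patients keep having seizures. A candidate non-invasive biomarker of
surgical outcome is the *resting-state network signature* of the region
containing the SOZ: how much directed influence flows into and out of
it per EEG frequency band, and how locally structured the network
around it is. `restflow` implements that analysis end to end for
researchers working with multichannel resting EEG and a source model,
and — because clinical recordings of this kind are confidential — ships
a generator of synthetic cohorts with known ground-truth networks so
the whole chain is verifiable.

## The method in brief

Per patient: zero-phase 0.5 Hz high-pass → robust bad-channel removal →
seeded ICA subtraction of blink/ECG-like components → ten artifact-free
5 s epochs → weighted minimum-norm source estimation
`K = R Gᵀ (G R Gᵀ + λ²C)⁻¹` with depth weighting `R_ii = ‖g_i‖^(−2γ)` →
sign-aligned averaging into 12 anatomical regions → per-epoch MVAR(40)
fits by the Nuttall-Strand lattice algorithm (unbiased covariance) →
partial directed coherence

    π_ij(f) = |Ā_ij(f)| / sqrt(Σ_k |Ā_kj(f)|²),
    Ā(f) = I − Σ_r A_r e^(−i2πfr/fs)

→ |PDC| averaged over the delta/theta/alpha/beta bands and over epochs
→ region-wise inflow/outflow (off-diagonal row/column means) and, after
proportional thresholding (density 0.15), six node metrics: degree,
cost, clustering, local efficiency, betweenness, average path length.

Cohort level: for each measure × band, SOZ-region values are compared
between seizure-free and non-seizure-free patients with a two-sided
rank-sum test (exact for ≤ 12 per group without ties), uncorrected,
giving a 32-row statistics table plus boxplot summaries.

The methods vignette (`vignettes/restflow-methods.Rmd`) documents the
model, every tunable default and the design decisions.

## Worked example

Generate a small synthetic cohort (both archetypes), run the pipeline
in memory, and look at the delta band:

```r
library(restflow)

spec <- cohort_spec(n_per_group = 10, n_regions = 12, fs_hz = 200,
                    n_epochs = 6, epoch_s = 5, n_sensors = 64,
                    artifacts = FALSE, seed = 42)
cohort <- generate_cohort(spec)
res <- analyze_cohort(cohort, config = list(target_fs_hz = 200))
print(subset(res$stats, band == "delta",
             select = c(measure, median_sf, median_nsf, p_value,
                        direction_sf)),
      digits = 3, row.names = FALSE)
```

```
          measure median_sf median_nsf  p_value direction_sf
           inflow    0.2036     0.2563 2.17e-05        lower
          outflow    0.2441     0.2314 1.50e-03       higher
           degree    3.0000     4.5000 5.95e-03        lower
             cost    0.2727     0.4091 5.95e-03        lower
       clustering    0.3333     0.0278 5.78e-03       higher
 local_efficiency    0.4250     0.0278 4.13e-03       higher
      betweenness    0.0545     0.3136 6.60e-04        lower
  avg_path_length    2.1875     1.4286 2.47e-02       higher
```

Reading it: in the seizure-free archetype the SOZ region receives less
directed influence in the delta band (median inflow 0.204 vs 0.256,
p = 2e-05) and sits in a more clustered local neighbourhood
(clustering 0.33 vs 0.03, local efficiency 0.43 vs 0.03), while the
non-seizure-free archetype's SOZ is a high-degree, well-shortcut hub
(higher degree and betweenness, shorter paths) — the qualitative
pattern the pipeline is designed to detect. Ground truth is available per patient
(`cohort$patients[[k]]$truth`), so such contrasts can always be traced
back to the generating networks.

File-based use mirrors this: `write_cohort()` emits EDF recordings, a
manifest, lead field and truth tensors; `run_pipeline(manifest,
leadfield, source_map, out_dir, config)` writes per-patient band
connectivity matrices, `features.tsv`, the 32-row `group_stats.tsv`,
`boxplots.json` and a frozen config copy. A thin command-line wrapper
lives at `inst/cli/restflow.R` (`simulate`, `run-all`).

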