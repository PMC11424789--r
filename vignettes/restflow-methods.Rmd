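---
title: "Resting-state directed connectivity and SOZ network biomarkers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state directed connectivity and SOZ network biomarkers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

In presurgical epilepsy evaluation, one would like to predict from
non-invasive data whether resecting the seizure onset zone (SOZ) will
leave the patient seizure free. `restflow` implements a resting-state
HD-EEG analysis built on the premise that the epileptic network is
abnormally wired even between discharges: sensor recordings are
projected into source space, collapsed to 12 anatomical regions,
directed interactions between regions are estimated per frequency band,
and the SOZ region's inflow, outflow and local graph properties are
compared between patients who became seizure free after surgery and
those who did not.

Because clinical recordings of this kind cannot be redistributed, the
package ships a synthetic-cohort generator that produces sensor-level
recordings from *known* directed source networks. Every stage of the
pipeline can therefore be validated by parameter recovery, direction
recovery and calibration studies rather than by eyeballing plots.

## Directed connectivity model

Each 5 s epoch of the 12 region time courses \(x_t \in \mathbb{R}^{12}\)
is modelled as a multivariate autoregression (MVAR):

\[ x_t = \sum_{r=1}^{p} A_r\, x_{t-r} + e_t, \qquad e_t \sim N(0, \Sigma), \]

with order \(p = 40\). The coefficients are estimated per epoch with the
Nuttall-Strand lattice algorithm (a multichannel Burg-type recursion).
At stage \(m\) the empirical forward/backward error moments
\(\hat P_f, \hat P_b, \hat\Delta\) and the recursion error covariances
\(P_f, P_b\) determine the partial cross-correlation \(\Delta\) through
the Sylvester equation

\[ \hat P_f P_f^{-1} \Delta + \Delta P_b^{-1} \hat P_b = 2 \hat\Delta , \]

which minimises the sum of normalised forward and backward prediction
error powers; reflection matrices \(K_f = \Delta P_b^{-1}\),
\(K_b = \Delta^\top P_f^{-1}\) then update coefficients (Whittle
recursion) and error covariances. All stage moments use unbiased
normalisation (sums divided by the number of available lagged pairs).
Lattice estimation has two properties that matter here: it works on
short epochs, and the resulting models are stable in practice — both
verified in the test suite against an ordinary-least-squares oracle and
by companion-matrix eigenvalues.

From a fitted model, partial directed coherence (PDC) is

\[ \bar A(f) = I - \sum_{r=1}^{p} A_r e^{-i 2\pi f r / f_s}, \qquad
   \pi_{ij}(f) = \frac{|\bar A_{ij}(f)|}{\sqrt{\sum_k |\bar A_{kj}(f)|^2}} , \]

the column-normalised magnitude variant, so that
\(\sum_i \pi_{ij}(f)^2 = 1\) for every source \(j\): \(\pi_{ij}\)
quantifies the directed influence of region \(j\) on region \(i\)
relative to everything \(j\) sends out. The generalised (`gpdc`) and
squared (`sq`) variants are available behind a config switch but the
pipeline default is the original PDC.

|PDC| is averaged over the grid frequencies inside each closed band —
delta 1–4 Hz, theta 5–8 Hz, alpha 9–12 Hz, beta 13–30 Hz, on a 0.5 Hz
grid from 0.5 to 45 Hz; grid points between band edges (e.g. 4.5 Hz)
belong to no band — first within epochs, then across the ten epochs.
Inflow and outflow of region \(i\) in a band are the means of the
band-averaged PDC over the off-diagonal entries of row \(i\) (edges into
\(i\)) and column \(i\) (edges out of \(i\)); means rather than sums keep
the measures in \([0,1]\) and invariant to region count.

### Epochs, sampling rate and model order

The pipeline fits one MVAR per epoch and averages |PDC| across epochs,
rather than averaging coefficients or concatenating epochs:
concatenation introduces boundary transients, and PDC averaging is the
convention the flow measures are defined on. An order-40 model at
1000 Hz spans only 40 ms of history, marginal for delta-band dynamics,
so the default pipeline decimates region series to 250 Hz (zero-phase
8th-order Butterworth anti-alias at 80% of the target Nyquist, then
subsampling) before fitting, which stretches the model memory to
160 ms. A `literal_fs = TRUE` switch fits at the native rate instead
for users who want the acquisition-rate behaviour exactly.

## Preprocessing

* **High-pass filter**: 4th-order Butterworth at 0.5 Hz applied
  forward-backward (zero phase, effective 8th order). Phase
  preservation is not cosmetic here: directed connectivity estimates
  are phase-sensitive.
* **Bad channels**: a channel is flagged when its log-variance is a
  robust outlier (|z| > 4 on median/MAD) or when it is essentially
  flat. Flagged channels are dropped, not interpolated — interpolated
  channels are linear combinations of the others and make the region
  covariance rank deficient, which the MVAR stage would reject.
* **Artifact removal**: deflationary FastICA (tanh contrast) on a
  whitened representation of at most 20 components; any component whose
  absolute correlation with a reference waveform (EOG/ECG-like) exceeds
  0.7 is subtracted from the data. Deflation is stopped at the first
  non-converging component: in resting EEG only the artifact directions
  are strongly non-Gaussian, and the near-Gaussian background subspace
  admits no unique rotation, so stopping there removes what is
  identifiable and leaves the rest bit-identical. The decomposition is
  seeded and reproducible.
* **Epochs**: the earliest ten disjoint 5 s windows whose samples are
  all marked clean, scanned left to right (the clinical analysis
  selected epochs visually; automated earliest-first selection is
  deterministic and reproducible).

## Source estimation and region aggregation

Sensor data are mapped to sources with a weighted minimum-norm kernel

\[ K = R\,G^\top (G R G^\top + \lambda^2 C)^{-1}, \qquad
   R_{ii} = \lVert g_i \rVert^{-2\gamma}, \]

with depth weighting \(\gamma = 0.5\) by default (\(\gamma = 0\)
disables it), identity noise covariance \(C\) unless one is supplied,
and \(\lambda^2 = \mathrm{tr}(G R G^\top) / (9\,\mathrm{tr}(C))\) — the
standard choice corresponding to an assumed power SNR of 3 — unless
\(\lambda\) is given. Head-model construction is out of scope: the lead
field is supplied (or synthesized by the cohort generator), and the
packaged parcellation table maps 104 fine parcels onto the 12 macro
regions (frontal, temporomedial, temporolateral, parietal, occipital,
thalamus; right/left). The shipped table is a synthetic stand-in with
atlas-style names; users with a real forward model substitute their own.

A region's representative time course is the per-sample *signed* mean
of its sources after sign alignment: each source is flipped so its
correlation with the region's first principal temporal component is
nonnegative, and the component's own arbitrary sign is fixed by
majority (first source wins ties). "Average source strength" could also
be read as a mean of magnitudes, but rectification destroys phase and
zero-mean structure, which the MVAR stage requires; the signed
convention is therefore used deliberately.

## Graphs and node metrics

Band connectivity is symmetrized by \(w_{ij} = \max(c_{ij}, c_{ji})\)
and binarized by proportional thresholding: the strongest
\(\mathrm{round}(d\,n(n-1)/2)\) edges are kept, default density
\(d = 0.15\), ties broken deterministically (weight descending, then
row, then column). The source analysis toolchain this emulates does not
print its threshold, so density is an explicit config parameter meant
to be swept (0.05–0.5) when checking robustness of findings.

Per node: degree; cost (degree/(n−1)); clustering coefficient (edges
among neighbours over possible); local efficiency (Latora–Marchiori,
mean inverse shortest-path length inside the neighbour-induced
subgraph, unreachable pairs contributing 0); betweenness centrality
(fraction of all-pairs shortest paths through the node, normalised by
\((n-1)(n-2)/2\)); and average path length (mean distance to *reachable*
nodes, with the reachable fraction reported separately, so disconnected
graphs never propagate infinities — an isolated node has `NA` path
length and drops out of that row's group comparison). All six metrics
are verified exhaustively against brute-force enumeration on every
graph with up to 5 nodes and against igraph on random 12-node graphs.
One convention note: igraph's `local_efficiency()` permits shortest
paths through non-neighbours; this package follows the neighbour-
subgraph convention, and the igraph cross-check constructs the induced
subgraph explicitly.

## Group statistics

For each of the 8 measures × 4 bands, SOZ-region values are compared
between groups with the two-sided rank-sum (Wilcoxon–Mann–Whitney)
test: exact null distribution when the pooled sample is tie-free and
both groups have at most 12 patients (exact at the target cohort size
of 10 vs 10, bounded runtime beyond), otherwise the normal
approximation with tie and continuity correction; a fully tied pooled
sample yields p = 1. P-values are deliberately *not* corrected for
multiple testing, matching the reporting convention of the analysis
this package reimplements (a correction can always be applied
downstream to the 32-row table). Boxplot summaries use type-7
(linear-interpolation) quartiles and Tukey 1.5·IQR whiskers — stated
because the numbers depend on the convention.

## The synthetic cohort generator

The generator emulates the acquisition conditions of the emulated
study: two outcome groups of 10 patients, 12 source regions, 1000 Hz
sampling, ten artifact-free 5 s epochs per patient, 64 sensors by
default (256 available via `n_sensors`), sensor SNR 10 dB.

Ground truth for each patient is a stationary MVAR(2) network. Each
region's diagonal block is a damped AR(2) resonator with pole modulus
0.96, tuned round-robin to 2.5, 6.5, 10.5 or 21.5 Hz so every analysis
band has spectral content; the SOZ region itself is set to the delta
centre (pathological slowing). Cross-couplings are two-tap kernels
`gain * (0.6, 0.4)` placed by archetype:

* `isolated_soz` (seizure-free group): weak edges into the SOZ
  (gain 0.05) from a small adjacent cluster, moderate edges out of the
  SOZ (0.25), dense couplings among the three cluster members (0.35) —
  a structured, clustered epileptic network.
* `diffuse_soz` (non-seizure-free group): strong edges into the SOZ
  (0.35) from eight scattered regions, no cluster — an extensive,
  scattered network.

Weak background couplings (gain 0.10, probability 0.15 per ordered
pair) and per-edge log-normal gain jitter (sd 0.2) provide
across-patient variability. Stability is enforced by geometric
down-scaling of all cross-couplings (factor 0.95, at most 200
iterations) until the companion spectral radius is at most 0.97; the
archetypes' inflow ordering survives scaling because scaling is
proportional. Effect sizes are configuration, not facts from the
emulated study, which reports no generative model; they operationalise
its qualitative conclusion (weakly fed-in, well-clustered SOZ networks
in seizure-free patients; strongly fed-in, scattered ones otherwise).

Blink-like (~1 Hz Gaussian transients) and ECG-like (~1.2 Hz biphasic
spikes) artifacts are injected on fixed random topographies inside
flagged 1 s segments between epoch blocks, and the reference waveforms
travel with the recording, so artifact removal is testable against
ground truth. Every random choice flows through seeds derived
deterministically from the cohort seed: a cohort is a pure function of
its spec.

### What the generator does not emulate

Linear random lead fields instead of a BEM head model (no realistic
field spread or depth bias); Gaussian innovations (real EEG has
heavy-tailed transients, and background sources here are
ICA-unidentifiable by construction); no interictal discharges (epochs
in the emulated study were selected free of them); no inter-patient
anatomy differences (one montage per cohort). Passing the validation
studies therefore demonstrates correctness of the estimation machinery
under the stated model, not clinical performance on real recordings.

## Validation studies and problem sizes

Three study functions back the acceptance checks; their problem sizes
are the package's own tractability choices for single-core runs and are
stated here once:

* `run_direction_recovery_study()` — a 3-region network with one
  unidirectional alpha-band coupling, ten 5 s epochs at 200 Hz per
  replicate, 100 replicates: the estimated alpha-band PDC must point
  the right way in at least 95% of replicates.
* `run_null_calibration_study()` — 200 cohorts in which both groups use
  the same archetype, so labels are exchangeable and every one of the
  32 rows must reject at close to the nominal 5% rate. Cohorts use 10
  regions, 20 sensors, two 2.5 s epochs at 100 Hz, order 20, graph
  density 0.4; exchangeability (hence validity) is independent of these
  sizes, and the denser graphs keep node-metric distributions away from
  degenerate all-tied values. Note that rows whose metric is heavily
  tied (degree, cost) rely on the tie-corrected normal approximation,
  whose discrete null can sit slightly below the nominal level.
* `run_group_contrast_study()` — 100 cohorts of 10 vs 10 patients at
  64 sensors with the default archetype pair, generated at 200 Hz with
  six 5 s epochs (pilot power margins are large; see the README's
  worked example for typical p-values): delta-band SOZ inflow must be
  significantly lower in the seizure-free group in at least 90% of
  cohorts, and delta-band clustering and local efficiency higher in the
  majority — the directional pattern of the emulated study, not its
  printed p-values, which came from confidential recordings and are not
  reproducible.

## Numerical choices and degenerate inputs

* Stationarity margin for generated networks: companion spectral radius
  ≤ 0.97; simulation refuses non-stationary models outright.
* The Nuttall-Strand stage solves its Sylvester equation by Schur
  decomposition and refuses models whose prediction-error covariance
  falls below reciprocal condition 1e-12 (the practical symptom of
  duplicated or constant channels).
* PDC normalisation is exact by construction; the test suite enforces
  the column identity to 1e-8 on estimated models and 1e-12 on the
  closed-form example.
* Thresholding errors out when the requested density keeps zero edges;
  clustering and local efficiency are defined as 0 for degree < 2;
  betweenness of graphs with n ≤ 2 is 0.
* EDF output quantizes to 16 bits per channel with per-channel
  symmetric physical ranges re-parsed from their 8-character ASCII
  header form, so writer and any conformant reader use identical
  scaling; round-trip error is bounded by one quantization step.
* FastICA convergence tolerance 1e-5, at most 200 iterations per
  component; failing on the very first component raises an error.

## Limitations

The pipeline inherits the identifiability limits of its ingredients:
wMNE with a random synthetic lead field mixes regions (spatial
leakage), so absolute PDC values are biased even when group contrasts
are recovered; thalamic sources are included because the emulated
analysis includes them, not because scalp EEG resolves them well; and
rank tests on strongly discrete node metrics are conservative at n = 10
per group. The group comparison reports uncorrected p-values by design;
users testing many hypotheses should correct downstream.
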