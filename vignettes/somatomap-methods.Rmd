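---
title: "somatomap: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somatomap: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatomap)
```

# The scientific problem

Classical somatotopy describes the precentral gyrus as a continuous
homunculus running from foot (dorsal) to face (ventral) representations.
Precision functional mapping instead suggests an *interdigitated*
organization: three effector-specific zones (foot, hand, mouth) alternate
with three inter-effector regions that are strongly interconnected, are
coupled to the cingulo-opercular network (CON), carry later infra-slow
signals, are structurally thinner, respond broadly (unselectively) to many
movements, and are more active during action planning than execution.
Movement activation profiles along the dorsal–ventral axis are then better
described by two Gaussian peaks (concentric zones) than by one.

somatomap implements each of these statistics on a 1-D cortical strip
abstraction, together with a synthetic-data generator that injects all of
the above patterns with known ground truth, so that the full analysis chain
can be validated without any imaging data.

# The data abstraction

A `CorticalStrip` is a set of vertices with 2-D coordinates, an ordered
dorsal→ventral axis line at consecutive integer positions 0..L−1, and one
region label per vertex, in the interdigitated order foot, superior
inter-effector, hand, middle inter-effector, mouth, inferior
inter-effector; CON, adjacent S1 and background cortex sit off the strip.
The 1-D axis stands in for the 2-D cortical sheet: every statistic in scope
is defined either along the dorsal–ventral axis or on region sets, so
geodesic distance reduces to an axis-index difference. A `BoldRun` (a
`SummarizedExperiment` subclass) holds the vertex × frame matrix plus the
repetition time and run type.

# The synthetic generator

**Resting state.** Each region r has a signal
s_r(t) = w_g·g(t − d_r) + w_n·ℓ_{net(r)}(t − d_r), where g is a global
latent shared by all regions, ℓ_net is the region's network latent (the
three inter-effector regions and the CON share one by default), d_r is the
region's injected delay, w_g = 0.6 and w_n = √(1 − w_g²) so the signal has
unit variance. Latents are infra-slow: white Gaussian spectra brick-wall
limited to < 0.1 Hz, constructed directly in the Fourier domain. Because
they are strictly band-limited and periodic, fractional delays are injected
*exactly* by phase rotation, which is what makes sub-TR parabolic
interpolation testable. Each vertex receives its region signal plus white
noise (`noiseSd`, default 1). The global latent keeps all region pairs
weakly correlated (r ≈ 0.36), as in real BOLD; without it, pairs in
different networks would have no cross-covariance peak and the lag
estimator would have nothing to interpolate.

Default delays are 0 s (effector regions and S1/background), 0.4 s
(inter-effector) and 0.8 s (CON) — magnitudes chosen to be comfortably
sub-TR (TR = 1.1 s) yet resolvable, matching the qualitative ordering of
the infra-slow lag finding.

**Tasks.** The response amplitude of vertex v to movement m is the true
spatial profile a₁·exp(−((x_v−b₁)/c₁)²) (+ optional second peak) at v's
axis position, plus region-level amplitudes (broad weak inter-effector
responses to every movement; planning responses in inter-effector/CON;
execution responses in effector regions). The time course is amplitude ×
(stimulus ∘ HRF) + noise, built with the same regressor construction the
GLM uses, so zero-noise recovery is exact. Block runs copy the battery
structure: a 2.2 s cue plus 12 paced movements at 1.1 s spacing, 15.4 s per
block, two blocks per condition per run. Event runs use duration-0
planning/execution events. Default peak amplitudes (0.25–0.6 in signal
units against noise sd 1) were chosen so that second-level Z-scores land in
a realistic 2–5 range rather than saturating the |Z| ≤ 8.2 clamp —
selectivity and winner-take-all margins are meaningless on saturated maps.

**Structure.** Per-vertex normal draws per region and metric; thickness
defaults: 2.3 mm (inter-effector) vs 2.7 mm (elsewhere), sd 0.15 mm.
Myelin is additionally normalized by its mean over the motor strip, so the
normalized map has mean exactly 1 there.

**What the generator does not emulate:** 2-D/volumetric geometry,
physiological (non-white, autocorrelated) noise, motion artefacts,
inter-subject anatomical variability. Passing tests therefore demonstrate
the correctness and calibration of the estimators under the stated model,
not robustness to every property of real fMRI.

# Estimators and numerical choices

**Connectivity.** Pearson correlation of vertex time courses, r clipped to
±(1 − 1e−7) before atanh so perfectly correlated pairs stay finite;
zero-variance vertices are masked with a warning; the diagonal is excluded.
Region connectivity is the correlation of region-*mean* time courses
(mean-then-correlate), not the mean of pairwise vertex correlations — the
two differ and the former is what the group analyses use. With several
runs, time courses are standardized per run before concatenation.
Percentile thresholding keeps values equal to the threshold, so a constant
map survives in full. Group seed maps average Fisher-z values across
subjects rather than recomputing from averaged matrices.

**Lags.** The lagged cross-covariance of internally standardized series is
computed on a ±8 frame window (biased 1/n normalization, so |CCF| ≤ 1); the
extremum is taken as the *maximum* (in-scope signal pairs are positively
correlated), refined by three-point parabolic interpolation. Pairs whose
peak |CCF| falls below 0.3, or whose extremum sits at the window edge, are
invalid. The TD matrix computes one triangle and negates it, making
antisymmetry exact by construction; session matrices are averaged over the
sessions in which each pair was valid. The sign convention is
td[i, j] > 0 ⇔ i's signal occurs later than j's, so a positive region
projection means a *lagging* region.

**Task GLM.** Boxcars (or impulse trains) are sampled at frame-onset times
and convolved with a double-gamma HRF (gamma-density modes at 6 s and 16 s,
undershoot ratio 1/6, peak normalized to 1). Estimation is ordinary least
squares with no autocorrelation prewhitening — the synthetic noise is
white, and the null-calibration suite verifies that vertexwise Z is
standard normal under exactly this model. t→Z conversion goes through
log-space tail probabilities and clamps |Z| at 8.2, where the double
normal tail underflows. Second-level cells with zero between-run variance
and non-zero mean are flagged degenerate and excluded rather than given
infinite t. The drift regressor exists but defaults to off (the generator
injects no drift). Smoothing is a 1-D Gaussian (default σ = 2.55 axis
units) with whole-sample symmetric reflection at the boundaries, which
conserves the map mean exactly.

**Peak models.** Profiles are unweighted per-position means of vertex
Z-scores (vertex counts per position are uniform on the synthetic strip;
weighting is a possible extension for irregular real geometry). Fit masks
are axis-fraction exclusions: lower-extremity movements exclude the ventral
third, face movements the dorsal third. Fitting is bounded
Levenberg–Marquardt (minpack.lm) under a ≥ 0, b within the masked range,
c ∈ [minWidth, range], from a deterministic multi-start grid (centre
candidates at quantiles of the masked range, several width starts) plus a
*nested start* that seeds the two-peak model with the one-peak solution and
a zero-amplitude second peak — this guarantees SSE₂ ≤ SSE₁, the nesting the
F-test assumes. Two-peak fits are canonicalized to b₁ ≤ b₂ and flagged
"collapsed" when |b₂ − b₁| < 1 axis unit. Degrees of freedom are
n_masked_points − n_params (3 or 6).

The minimum peak width deserves emphasis. A width floor near zero lets the
second Gaussian collapse onto single noisy positions; the resulting SSE
reduction behaves nothing like three regression parameters and the nested
F-test rejects a true one-peak model at ~4–5× its nominal level. The
default floor of 4 axis units (FWHM ≈ 7 sampled positions) was set by null
calibration: across floors {3, 4, 5} the empirical rejection rate at
α = 0.05 was ≈ {0.063, 0.040, 0.028}, and 4 is the smallest floor that
keeps the test reliably near its nominal level while remaining far narrower
than any peak of scientific interest. It is configurable per analysis.

**A known limitation of the F-test.** Under the one-peak null the two-peak
model's extra amplitude sits on the boundary (a₂ = 0) with (b₂, c₂)
unidentified, the classical setting in which the likelihood-ratio/F
reference distribution is only an approximation. Empirically the α = 0.05
tail is well calibrated with the default width floor, but the *full* null
p-value distribution is measurably non-uniform (stochastically smaller in
the bulk), and a Kolmogorov–Smirnov uniformity check at n = 500 fails at
any width floor we examined. Users should treat small F-test p-values as
calibrated and the bulk of the distribution as conservative-approximate;
the calibration suite reports both numbers rather than hiding the effect.

**Paired tests.** Two-tailed paired t (df = n − 1) with BH q-values over
the *declared* family size (e.g. 3 effector comparisons, 10 network
comparisons), so unreported tests still count. All-zero differences give
t = 0, p = 1; constant non-zero differences are degenerate (flagged, not
significant); subjects with missing cells are dropped pairwise.

**Winner-take-all and selectivity.** Argmax of Z across conditions with
exact ties going to the lowest condition index (flagged); selectivity is
best minus second-best Z; the display mask keeps the top 1% most activated
vertices by default. Coactivation profiles correlate region-mean
activation signatures across movements; constant profiles are masked.
LOWESS curves use tricube locally weighted linear regression with one
robustness iteration.

# The pipeline and its study conditions

`runPipeline()` chains simulate → connectivity → lags → GLM → somatotopy →
report deterministically from one root seed (all per-run seeds are derived
by fixed offsets; the full report is reproducible byte for byte). The
default study conditions, also used by the acceptance suite: 20 simulated
subjects; per subject two 480-frame resting runs (TR 1.1 s), four
block-battery runs of six movements (toes, abdominal, hand, eyelid,
tongue, swallowing; TR 2.2 s), four planning/execution event runs, and one
set of structural maps. These sizes were chosen as the smallest that give
the group statistics comfortable margins over their sampling noise; single
subjects show visibly noisy lag projections, which is faithful to how the
statistic behaves.

Calibration problem sizes: 500 null profiles and 200 two-peak profiles of
60 positions for the F-test; 100 runs of 800 frames at SNR 2 for lag
recovery (injected shifts 0.5/1.0/1.5 s); 10 000 vertices for GLM null
calibration; 10 000 replicates at n = 7 for paired-t type-I error, with
1 000 all-null BH families of 3.

Negative control: `defaultPipelineConfig(conCoupled = FALSE)` removes the
CON from the inter-effector latent, and the CON's network
minimum-difference advantage disappears — the pipeline detects structure
only when it is injected.

# Interfaces

Runs are exchanged as TSV matrices with a JSON sidecar ({tr, runType});
strips as JSON; every report table as TSV. `scripts/pipeline.R` exposes the
pipeline on the command line (exit codes: 0 ok, 1 analysis failure, 2
configuration error); `scripts/acceptance.R` reruns the calibration suite
and writes its numbers as JSON. Ingestion of CIFTI/GIFTI/NIfTI files is
deliberately out of scope; upstream tooling should export vertex × frame
text matrices.
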