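---
title: "Unsupervised flow-typing of TCD beat waveforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised flow-typing of TCD beat waveforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdflow)
```

# The problem

Transcranial Doppler (TCD) ultrasound records cerebral blood flow velocity
(CBFV) in the large arteries of the brain as a pulsatile waveform. The shape
of one beat — a systolic upstroke followed by up to three peaks (P1, P2, P3)
and a diastolic decay — carries diagnostic information: large vessel
occlusion (LVO) of the middle cerebral artery blunts or distorts this
morphology. Clinical grading of that morphology (e.g. the TIBI flow-grade
scale) is subjective; `tcdflow` implements an objective alternative: an
unsupervised flow-typing analysis that reduces each recording to a single
normalized beat, summarizes it with three morphological features, and lets
the data decide how many morphological categories exist.

The pipeline is

1. **Beat pipeline** — segment a 30-second per-depth recording into beats,
   reject outlier beats, average, smooth, and normalize to a 100-sample
   beat in $[0, 1]$.
2. **Morphological features** — `onset`, `canopy`, `peaks` per beat.
3. **Clustering** — z-score the $N \times 3$ feature matrix, spectral
   clustering, gap-statistic selection of the cluster count $k$.
4. **Archetypes** — per-cluster exemplar, 5-member archetype waveform, and
   subject-group composition.

A synthetic waveform generator with four planted flow types provides ground
truth for validation, since clinical TCD recordings of this kind are not
publicly deposited.

# Beat pipeline

**Segmentation.** Beat onsets are feet of systolic upstrokes. The detector
searches the lightly smoothed first difference for runs above half its 98th
percentile, merges candidates closer than a 0.3 s refractory period, and
walks back from each upstroke to the preceding local minimum. The quantile
threshold (rather than a fraction of the global maximum) keeps a single
3&times; amplitude artifact beat from masking ordinary upstrokes. On clean
synthetic recordings onsets land within 3 samples of ground truth.

**Outlier rejection.** Iterated Tukey fences
($[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, multiplier
configurable) on two comparators: beat length, and the maximum normalized
cross-correlation of each beat against the current ensemble mean (lags up
to 10% of the beat length; a zero-variance beat is assigned $-1$ and is
always rejected). Iteration stops at a fixed point or at a floor of three
beats. Exact-tie ensembles (IQR $= 0$) are protected by a relative-epsilon
guard so identical beats are never spuriously rejected.

**Averaging.** Accepted beats — each starting at its own onset — are padded
with their final value to the length of the longest accepted beat and
averaged element-wise. A recording is included only if at least 15 beats
survive rejection; this minimum, like every other threshold here, is a
named configuration parameter.

**Standardization.** In order: (1) recordings acquired at 400 Hz are
resampled to 125 Hz — a zero-phase FIR anti-aliasing filter with cutoff at
the 62.5 Hz target Nyquist frequency, then interpolation onto the 125 Hz
grid (a delay-compensating design; a plain polyphase resampler at ratio
5/16 leaves a fractional delay that breaks cross-rate agreement);
(2) convolution with a unit-sum 90 ms Hanning window (11 samples at 125 Hz,
odd length to preserve alignment, reflection edge handling), suppressing
noise above the ~10 Hz band of the relevant hemodynamics; (3) velocity
normalization: subtract the minimum, divide by the resulting maximum;
(4) time normalization: cubic-spline resampling to exactly 100 samples. A
final exact min/max rescale guarantees the $[0,1]$ invariant to machine
precision, since spline interpolation between the original nodes need not
preserve the extremes exactly.

**Exam inclusion.** Only subjects with at least one qualifying recording
(depth 45–60 mm, $\ge 15$ accepted beats) in *each* hemisphere are
retained; this bilateral requirement prevents an absent temporal acoustic
window from masquerading as absent flow.

# Morphological features

For a normalized beat $x(t_0), \dots, x(t_{99})$:

* **onset** — the (0-based) index of the earliest maximal sample: where in
  the cardiac cycle maximal velocity is attained. Blunted flow attains its
  maximum late.
* **canopy** — the number of samples with
  $x(t_i) > x(t_0) + 0.25\,(x(t_\mathrm{systolic}) - x(t_\mathrm{diastolic}))$,
  the length of the systolic complex. The baseline is the first sample
  $x(t_0)$, taken verbatim from the feature's defining equation even though
  min-normalization may place the global minimum elsewhere; with beats cut
  at the systolic foot the two rarely differ.
* **peaks** — a weighted peak/trough count. *True peaks* are canopy samples
  where the successive-sample difference changes sign; each counts 1. A
  maximal run of exactly-zero differences (a plateau, vanishing discrete
  derivative) counts once, at its midpoint. *Pseudo-peaks* are maximal runs
  of adjacent canopy samples whose difference magnitude is below a critical
  threshold (default 0.01) and that contain no true peak; each contributes
  its flattest sample with weight $1 - |\Delta x| / 0.01$, so a run whose
  smallest difference is 0.001 contributes 0.9. As the threshold shrinks
  the feature approaches the bare true-peak count. Pseudo-peak runs are
  confined to the canopy, mirroring the true-peak definition, and runs
  containing a true peak are suppressed to avoid double counting.

Tie-breaks (earliest index for the onset maximum; earliest flattest sample
within a pseudo-run) are fixed so the features are deterministic. All three
features are invariant to velocity scale exactly, and to heart rate up to
the residual effect of the fixed 90 ms smoothing window (see *Limitations*).

# Clustering and cluster-count selection

Features are z-scored across observations (sample standard deviation,
denominator $N-1$; the choice is immaterial at realistic $N$ but fixed for
reproducibility). Spectral clustering uses a radial-basis affinity
$\exp(-\gamma d^2)$ with $\gamma = 1$ on z-scored features (the default of
the reference implementation the analysis follows), symmetric normalized
spectral embedding, row normalization, and k-means with 10 restarts on the
leading $k$ eigenvectors. All stochastic steps take explicit seeds.

The cluster count is selected by the gap statistic over $k = 2, \dots, 7$:
$G_k = \mathbb{E}^*[\log W_k] - \log W_k$, where
$W_k = \sum_r D_r / (2 n_r)$ is the pooled intra-cluster dispersion
($D_r$ the sum of ordered-pair squared Euclidean distances within cluster
$r$ — algebraically the within-cluster sum of squared distances to
centroids, an identity the tests exploit as an oracle). The reference
distribution is uniform over the range of the data rotated by its right
singular vectors, back-rotated to feature space; $B = 1000$ reference
samples by default (tests use smaller $B$ with fixed seeds). The
simulation-corrected spread is $S_k = \mathrm{sd}_b(\log W^*_{kb})
\sqrt{1 + 1/B}$, and the selected count is the smallest $k$ with
$G_k > G_{k+1} - S_{k+1}$; if no $k$ qualifies the largest $k$ is returned
with a `no_elbow` flag. Reference samples are clustered with the same
spectral algorithm as the observed data; because the affinity matrix does
not depend on $k$, the embedding is computed once per dataset and shared
across the whole $k$ range, which keeps the $B \times 6$ clusterings per
profile affordable.

# Archetypes and reporting

Within each cluster, members are ranked by mean squared Euclidean distance
to the other members — computed on the 100-sample waveforms, not the
3-vector features, so the summary is a waveform, and excluding
self-distance (denominator $n-1$; ties broken by waveform id). The rank-1
member is the cluster *exemplar*; the element-wise mean of the five
best-ranked members (all members, if fewer than five) is the cluster
*archetype*. Group composition is reported per cluster as integer
percentages of LVO / in-hospital control (IHC) / out-of-hospital control
(OHC) waveforms, with raw fractions alongside.

# The synthetic generator

Each beat is a sum of positive gamma-shaped bumps over a diastolic floor:
bump $j$ contributes $a_j (u/c_j)^{\alpha_j} e^{-\alpha_j (u/c_j - 1)}$ at
beat phase $u \in [0, 1)$. The bump is exactly zero at $u = 0$, so the
systolic foot is the global minimum at the first sample by construction,
and it peaks at $u = c_j$ with sharpness $\alpha_j$. Four fixed,
versioned parameter sets define the flow types:

```{r flow-types}
str(flow_type_library(), max.level = 1)
```

* **I** (normal-like): dominant P1 at phase ~0.18, resolvable P2/P3,
  wide canopy (~65 samples), `peaks` $\ge 3$.
* **II** (late-onset): maximum shifted to P2 (~0.41), otherwise strong
  structure.
* **III** (narrow-spike): single early spike plus a small shoulder, canopy
  roughly half that of types I/II, weak peaks, low diastolic flow.
* **IV** (blunted): one broad delayed mound (~0.48), no secondary
  structure, high relative diastolic flow.

Bump widths correspond to systolic rise times of tens of milliseconds —
sharp enough to be physiological, broad enough that the waveform is
bandlimited well below the 62.5 Hz Nyquist frequency of the 125 Hz target
rate and only mildly affected by the 90 ms smoothing window at any heart
rate in 50–100 bpm. Much sharper shapes would make the normalized beat
depend visibly on heart rate (fixed-time smoothing is not scale invariant)
and would alias when generated natively at 125 Hz.

Recordings concatenate beats whose durations follow $60/\mathrm{HR}$ with
HR drawn i.i.d. from a normal truncated to [40, 180] bpm — the simplest
variability model consistent with the pipeline's onset-alignment
assumptions. Artifact beats (probability `artifact_beat_rate`) are either
flatlines or 3&times; amplitude spikes, exercising both the correlation
and the length comparators of the rejection step. Additive white noise is
scaled to the pulse amplitude. Ground truth (onset indices, artifact
flags, flow type) travels beside the signal and never enters the analysis
path. Cohort simulation assigns each group a mixture over flow types;
the default mixture makes types I/II dominate the control groups and
III/IV the LVO group, so that cluster composition reports have the
group-separating structure the method is meant to expose. The planted
feature clouds used to validate cluster-count selection place unit-variance
isotropic groups on tetrahedral cube corners at a configurable separation,
so the planted structure spans all three feature dimensions.

# Numerical choices and degenerate inputs

* Constant recordings or constant average beats are excluded with a log
  entry, never an exception, matching how a batch pipeline must behave.
* $\log W$ is floored at the smallest positive double before logging, so a
  cluster of numerically identical points cannot produce $-\infty$.
* In the spectral embedding, $k = N$ bypasses k-means: every point is its
  own cluster by definition.
* `kmeans` ties and restarts are controlled by explicit seeds
  (`withr::with_seed`), and the orchestration layer derives stage seeds
  from one master seed (simulation: `seed`; clustering: `seed + 1`).
* Exact-tie Tukey fences carry a relative epsilon, as noted above.

# Validation scale

The bundled validation uses desk-scale problem sizes chosen to exercise
every code path with comfortable statistical margins: planted feature
clouds of $4 \times 60$ points with $B = 100$ reference samples over 20
seeds for cluster-count recovery; an end-to-end noise-free cohort of 32
recordings per flow type (128 recordings of 30 s at 125 Hz); and 1000
random waveforms for brute-force oracle comparison of the features. The
demonstration pipeline in the README simulates 10 subjects per group.

# Limitations

* **Heart-rate invariance is approximate.** Smoothing happens at a fixed
  90 ms time scale *before* time normalization, so a beat's normalized
  shape retains a small heart-rate dependence (bounded by ~0.05 max-abs
  across 50–100 bpm for the bundled morphologies, and larger for shapes
  with faster transients). This is a property of the method's stated order
  of operations, not of the generator.
* **Gap selection needs continuous dispersion.** On noise-free synthetic
  cohorts the onset and canopy features are integer-valued and within-type
  dispersion is nearly a point mass; splitting such clusters keeps
  collapsing $\log W$, the gap curve never elbows, and selection runs to
  the top of the $k$ range. With measurement noise (or any continuous
  within-cluster spread, as in the planted clouds and in real data) the
  selection rule behaves as intended. The end-to-end partition-recovery
  check therefore clusters at the known $k = 4$.
* **The generator is not a hemodynamic model.** It reproduces the beat
  morphologies the analysis distinguishes, with heart-rate variability,
  noise, and artifacts — not Doppler spectra, M-mode, probe physics, or
  absent/minimal flow states (which are too weakly pulsatile to yield an
  average beat at all). Passing tests demonstrate that the analysis
  recovers structure *of the kind it assumes*; they cannot certify
  performance on clinical recordings.
* **Composition percentages are synthetic.** Reported group compositions
  reflect the configured mixture, not clinical prevalence.
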