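# tcdflow

Unsupervised flow-typing of transcranial Doppler (TCD) beat waveforms.

TCD ultrasound records cerebral blood flow velocity in the large arteries
of the brain as a pulsatile waveform whose per-beat morphology — a systolic
upstroke followed by up to three peaks (P1/P2/P3) and a diastolic decay —
changes characteristically under large vessel occlusion (LVO). Clinical
morphology grading is subjective; `tcdflow` implements an objective,
data-driven alternative for researchers working with per-depth CBFV
recordings from stroke and control cohorts:

1. **Beat pipeline.** Each 30-second recording is segmented into beats at
   systolic-upstroke feet, cleaned by iterated interquartile-range
   rejection (comparators: beat length and normalized cross-correlation
   against the ensemble mean), onset-aligned, end-padded, averaged,
   smoothed with a 90 ms Hanning window, and normalized to a 100-sample
   beat spanning [0, 1] (125 Hz reference rate; 400 Hz input is resampled).
   Recordings need ≥ 15 accepted beats, depths 45–60 mm, and a bilateral
   pair of qualifying scans per subject.
2. **Morphological features.** For each normalized beat `x(t_0..t_99)`:
   * `onset` — index of the earliest maximal sample,
   * `canopy` — #{ i : x(t_i) > x(t_0) + 0.25 (x(t_sys) − x(t_dia)) },
   * `peaks` — |TP| + Σ_{k∈PP} (1 − |x(t_k) − x(t_k−1)| / 0.01), where TP
     are canopy samples at sign changes of the successive difference
     (weight 1) and PP are flattest samples of sub-threshold runs
     (weights in (0, 1)).
3. **Clustering.** The N×3 feature matrix is z-scored and partitioned by
   spectral clustering (RBF affinity `exp(−γ d²)`, γ = 1). The cluster
   count k ∈ {2..7} is chosen by the gap statistic
   `G_k = E*[log W_k] − log W_k` with an SVD-range uniform reference
   (B = 1000 bootstrap samples), selecting the smallest k with
   `G_k > G_{k+1} − S_{k+1}`.
4. **Archetypes.** Cluster members are ranked by mean intra-cluster squared
   distance over the waveforms; the rank-1 member is the exemplar and the
   mean of the five best-ranked members is the archetype. Group composition
   (LVO / in-hospital control / out-of-hospital control) is reported per
   cluster.

Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic generator with four planted flow types
(normal-like, late-onset, narrow-spike, blunted), heart-rate variability,
noise and artifact beats, carrying ground truth for validation.

## Worked example

```r
library(tcdflow)
cfg <- default_run_config(seed = 17, B = 100)   # 10 subjects per group
res <- run_flowtyping(cfg, "demo_run")
res$selection
#> $k
#> [1] 5
#> $no_elbow
#> [1] FALSE
res$report
#> <tcd_report> 5 cluster(s), 170 waveform(s)
#>   cluster size pct_LVO pct_IHC pct_OHC
#> 1       1   14      93       7       0
#> 2       2   20       5      45      50
#> 3       3   36       6      42      53
#> 4       4   52      63      12      25
#> 5       5   48      17      62      21
#> exemplars: cluster_1=LVO06_right_46.9mm, cluster_2=IHC07_right_56.1mm,
#>   cluster_3=OHC06_right_49.8mm, cluster_4=LVO04_left_57.6mm,
#>   cluster_5=IHC06_right_51.3mm
```

Reading the output: 170 of the simulated recordings survived the inclusion
rules and were flow-typed into five clusters. Cluster 1 (93% LVO) is the
narrow-spike type and cluster 4 (63% LVO) the blunted type — the two
pathological morphologies land in LVO-dominated clusters — while the
control-dominated clusters 2/3/5 hold the normal-like and late-onset
types. Checking against the generator's ground truth, clusters map
one-to-one onto the planted types except that the normal-like type splits
across clusters 2 and 3: noise-free synthetic features are quantized
(onset and canopy are sample counts), so within-type dispersion is nearly
degenerate and the gap criterion prefers the finer split (see the methods
vignette, *Limitations*). The run directory holds every stage's output
(`recordings/`, `beats.csv`, `features.csv`, `clusters.json`, `report/`)
plus `manifest.json` with seeds, configuration hash and row counts;
re-running the same configuration reproduces identical outputs.

Single waveforms work the same way without the orchestration:

```r
spec <- flow_type_library()$IV                  # blunted morphology
w <- standardize_beat(generate_beat(spec, 0.8, 125, noise_sd = 0), 125)
c(onset = beat_onset(w), canopy = beat_canopy(w), peaks = beat_peaks(w))
#>  onset canopy  peaks
#>     48     54      1
```

A blunted beat attains maximal velocity mid-beat (onset 48 of 100) with a
single unresolved peak, versus onset ~18 and `peaks` ≥ 3 for the
normal-like type.

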