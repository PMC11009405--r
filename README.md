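# spiralburst

Analysis pipeline for subthalamic **beta bursts during spiral drawing** in
Parkinson's disease, with and without deep brain stimulation (DBS), plus a
synthetic cohort generator with known ground truth so every stage of the
pipeline can be validated without access to patient recordings.

## The scientific problem

Beta-band (13–30 Hz) oscillations in the subthalamic nucleus (STN) come and
go in transient *bursts*. Their amplitude and duration are linked to motor
impairment in Parkinson's disease, and DBS suppresses them. This package
implements the analysis needed to ask whether bursts that occur *during* a
fine, continuous movement — drawing an Archimedean spiral, freely or on a
template — coincide with immediate slowing of the pen, and whether DBS
changes that relationship.

The core quantities:

* **Burst detection.** The LFP is band-passed around a subject-specific
  beta peak f<sub>β</sub> ± 2 Hz, rectified, and smoothed with a 200 ms
  moving average to give the envelope *e(t)*. A burst is a maximal run of
  *e(t) > θ* lasting ≥ 100 ms, with
  θ = 75th percentile of the envelope over the condition's rest intervals.
* **Spiral kinematics.** The pen trace (x, y) is low-pass filtered (4th
  order Butterworth, 10 Hz), converted to tangential velocity
  v = √(ẋ² + ẏ²), and to the radius–angle representation, where an ideal
  Archimedean spiral r = bθ is a straight line; the fitted slope b and the
  RMSE quantify spiral size growth and shape accuracy (first revolution
  excluded).
* **Peri-burst acceleration.** For each burst onset t₀, the mean
  acceleration in [t₀−0.25 s, t₀) and [t₀, t₀+0.25 s) is
  (v(end) − v(start))/0.25; the contrast Δa = a_post − a_pre measures the
  burst-locked change in velocity dynamics. Two null constructions —
  onsets on a fixed 50 ms grid, and within-trial shuffled onsets — certify
  that Δa ≈ 0 in the absence of burst-locked coupling.
* **Time–frequency statistics.** Morlet maps (width 7, 4–100 Hz, 1 Hz /
  20 ms grid) are time-warped to 50 rest + 100 draw samples so trials of
  different durations average cleanly, baseline-normalized
  ((P−B)/B), and compared with one-sided cluster-based permutation tests
  (cluster-forming α = 0.05, 5000 within-subject sign flips).
* **Trial statistics.** Linear mixed-effects models (lme4) with subject
  random intercepts for log velocity, RMSE, slope, band power and burst
  metrics; Bonferroni post hocs; Spearman correlations of DBS-related
  burst-amplitude change against clinical limb-score improvement.

## Worked example

Simulate a small cohort and run the full pipeline (≈1 minute):

```r
library(spiralburst)
cfg <- simulation_config(n_subjects = 6, trials_per_condition = 8,
                         fs_lfp = 512, seed = 42)
ds  <- simulate_cohort(cfg, root = "demo")
st  <- run_pipeline(root = "demo", out_dir = "demo-results",
                    seed = 42, n_perm = 1000)

merge(st$beta_peaks, unique(ds$trials[, c("subject", "f_beta")]))
#>   subject f_peak f_beta        <- every injected beta peak recovered
#> 1     S01     27     27
#> 2     S02     27     27
#> 3     S03     19     19
#> 4     S04     26     26
#> 5     S05     23     23
#> 6     S06     22     22

st$stats$velocity[, c("term", "estimate", "se", "p")]
#>                     term estimate     se        p
#> 1            (Intercept)  0.98125 0.0564 1.10e-67
#> 2        drawingtemplate -0.19041 0.0205 1.58e-20
#> 3                 stimon  0.04771 0.0205 2.00e-02
#> 4 drawingtemplate:stimon -0.00463 0.0290 8.73e-01
```

The generator injected a template-vs-free slowdown of −0.22 log₁₀ units
and a stimulation speed-up of +0.05; the model recovers −0.190 (p ≈ 2e-20)
and +0.048 (p = 0.02). Mean burst duration drops from 0.445 s at rest to
0.328 s during drawing (injected ratio 0.7 before envelope-smoothing
bias), and the burst rate from 0.59 to 0.44 bursts/s — bursts persist
during movement but are shorter and rarer, while the linear-grid control
Δa stays at ≈0.003 cm/s² (no spurious burst-locked slowing).

## Command line

```sh
inst/cli/spiralburst simulate --root=dataset --seed=7
inst/cli/spiralburst all --root=dataset --out=results --seed=7
inst/cli/spiralburst stats --root=dataset --out=results --drop-inaccurate
```

Stages cache on content-stamped parameters: rerunning with an unchanged
configuration recomputes nothing; changing one stage's parameters reruns
only that stage and those downstream.
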