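# phagomotion

Motion-state analysis of intracellular cargo transport, built around
bead-phagosome tracking in macrophages.

Phagosomes mature by being carried along microtubules toward lysosomes.
In live-cell recordings (810 nm beads imaged by DIC at 20 frames/s,
27.6 nm/pixel), a phagosome alternates between **directed** motion, driven
by kinesin/dynein motors, and **diffusive** motion when motors are inactive
or detached. Comparing conditions (e.g. control macrophages vs cells
overexpressing the endosomal Na+/H+ exchanger NHE9) requires turning raw
bead trajectories into transport statistics: percent time in directed
motion, run length, run velocity, and the dissociation rate at which cargo
leaves the motor-bound state. This package implements that pipeline as
reusable, tested R functions plus a simulator that generates labelled
ground-truth trajectories, so every stage can be validated without any
microscope data.

## Method

1. **Simulation** (`sim_config`, `simulate_trajectory`, `simulate_cohort`,
   `render_image_stack`): a two-state continuous-time Markov model. The
   cargo leaves the motor-bound state at rate `k_off` and re-engages at
   rate `k_on`; each run has a constant speed drawn from a truncated
   normal on [50, 1500] nm/s along a persistent direction (reversal
   probability per new run), plus a small motor-bound positional jitter;
   diffusive intervals are Brownian with diffusion constant `D`. Observed
   positions add the 9.8 nm localization-noise floor. Trajectories can be
   rendered into TIFF movies of a Gaussian spot.
2. **Tracking** (`localize_centroid`, `track_stack`): sub-pixel,
   background-subtracted intensity-weighted centroid, frame-to-frame
   linking gated by a maximum step.
3. **Motion-state classification** (`fit_windows`,
   `fit_alpha_distribution`, `label_segments`): each trajectory is scanned
   with a 2.0 s (40-frame) sliding window; each window's time-averaged MSD
   is fitted with

   MSD(t) = 4D·t^α + 2σ², σ fixed at 9.8 nm,

   where the scaling exponent α ≈ 1 indicates diffusion and α ≈ 2 directed
   motion. The pooled α distribution is fitted with a two-Gaussian
   mixture; the cutoff between the component means splits the frames into
   directed and diffusive segments.
4. **Run parsing** (`stitch_directed`, `parse_constant_velocity`,
   `classify_runs`): directed segments are stitched across short diffusive
   gaps and parsed into constant-velocity pieces by penalized
   change-point detection (exact dynamic programming on the
   principal-direction displacement, with a velocity-equivalence pruning
   step). Pieces with net displacement > 200 nm, speed > 50 nm/s and
   duration ≥ 0.25 s are runs; pieces slower than 50 nm/s are pauses.
5. **Transport statistics** (`percent_motion`, `run_length_stats`,
   `velocity_stats`, `dissociation_rate`, `compare_groups`): per-bead
   percent directed/diffusive motion, run length and velocity over runs,
   dissociation rate = run terminations per unit motor-bound time
   (recording-end censored), each mean ± SEM, compared between groups with
   Welch two-sample t-tests (stars: * p<0.05, ** p<0.01, *** p<0.001,
   **** p<0.0001).

`analyze_group` / `analyze_two_groups` run stages 3–5 in memory;
`run_pipeline` does the same from directories of trajectory files and
writes a seed-stamped report bundle.

## Worked example

The `analysis/` directory is a numbered workflow over the package: `01`
simulates a control cohort and an impaired-transport cohort (63 beads
each, 150 s at 20 frames/s; the treated group has 3× higher `k_off` and 2×
lower `k_on`), `02` demonstrates the imaging arm (render → track), `03`
classifies motion states, `04` parses runs, `05` compares the groups.

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_track_demo.R
Rscript analysis/03_segment_motion.R
Rscript analysis/04_parse_runs.R
Rscript analysis/05_transport_summary.R
```

Step 05 prints (seeds as committed):

```
Transport summary -- control
  beads: 63   runs: 2163
  percent directed:   47.95 +/- 1.19 %
  percent diffusive:  52.05 +/- 1.19 %
  run length:         1054 +/- 19 nm
  velocity:           534.5 +/- 3.9 nm/s
  dissociation rate:  0.1719 +/- 0.00655 1/s
Transport summary -- treated
  beads: 63   runs: 661
  percent directed:   11.77 +/- 0.627 %
  percent diffusive:  88.23 +/- 0.627 %
  run length:         839.3 +/- 23.6 nm
  velocity:           564.7 +/- 7.01 nm/s
  dissociation rate:  0.4676 +/- 0.0249 1/s
```

Reading this: the control group spends ~48% of frames in directed motion
(the generating stationary fraction is 50%) and its recovered dissociation
rate 0.172 /s matches the generating `k_off` = 1/6 /s; the impaired group
shows less directed motion, shorter runs and a higher dissociation rate —
and a slightly *higher* mean run velocity, the same counterintuitive shift
seen when motor engagement is reduced in cells. All four contrasts are
significant by Welch t-tests (`results/05_comparisons.tsv`). Step 03 also
writes the mixture report (cutoff α = 1.61 for these cohorts) and the
separation check: class-averaged MSD exponents 0.99 (diffusive) and 1.97
(directed).

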