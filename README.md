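# resphase

Respiration phase-resolved analysis of perception and neural dynamics in R.

Slow bodily rhythms shape what we perceive: during a breathing cycle,
detection thresholds for near-threshold visual stimuli, oscillatory alpha/beta
power, and directed cortical information flow all wax and wane with
respiratory phase. `resphase` implements the full analysis chain needed to
quantify these effects in a cued visual detection experiment with simultaneous
respiration, pupil, and ROI-level neural recordings — together with a
synthetic-data generator with known ground truth, so that every stage can be
validated by parameter recovery without access to restricted participant data.

The package is aimed at researchers in cognitive/computational neuroscience
and psychophysics who work with physiological phase variables.

## What it computes

* **Respiratory phase** (`normalize_and_clip`, `detect_extrema`,
  `interpolate_phase`, `phase_at_events`): belt traces are z-scored, sighs
  (|z| > 2.5) clipped by linear interpolation, inspiratory peaks / expiratory
  troughs detected with prominence ≥ 1, and phase interpolated linearly from
  trough to peak (−π → 0) and peak to trough (0 → π), so cycles are centred
  on peak inspiration (phase 0).
* **QUEST psychometrics** (`quest_propose`, `quest_update`,
  `fit_psychometric`, `phase_resolved_thresholds`): a Bayesian adaptive
  staircase holds the hit rate at μ_HR = 0.60; the psychometric function
  Ψ(c) = γ + (1 − γ − λ)Φ((c − m)/σ) with γ = 1/3 is fitted by MAP on a grid,
  then refitted in 60 moving phase windows (step π/30, half-width π/10) with
  priors from the overall fit, yielding a z-scored threshold-by-phase profile.
* **Circular statistics** (`rayleigh_test`, `hodges_ajne_test`,
  `circ_linear_corr`, `phase_regression`, `circ_diff_test`,
  `bin_by_phase`).
* **Spectra** (`multitaper_psd`, `whiten_derivative`, `phase_binned_power`,
  `power_phase_regression`, `motion_glm_clean`): DPSS multitaper power of the
  prestimulus [−1600, 0] ms window (2 Hz smoothing), first-difference
  spectral whitening, and power per 30 respiration-phase bins regressed on
  sine/cosine of phase.
* **Directed connectivity** (`csd_multitaper`, `wilson_factorize`,
  `block_gc`, `dai`, `phase_resolved_gc`, `gc_phase_regression`):
  nonparametric blockwise spectral Granger causality between 3-component ROI
  blocks via Wilson spectral matrix factorization S(f) = H(f)ΣH(f)*, the
  directed asymmetry index
  DAI = (mGC(A→B) − mGC(B→A)) / (mGC(A→B) + mGC(B→A)),
  and the same chain repeated per respiration-phase bin with a first-level
  phase regression of the GC spectra.
* **Inference** (`cluster_perm_test`, `fdr_bh`, `mi_model_compare`,
  `coeff_threshold_correlation`): cluster-based permutation statistics
  (sum of |t|, label permutation, re-clustering per permutation),
  Benjamini–Hochberg FDR, and Gaussian-copula mutual information model
  comparison for single-trial outcome prediction.
* **Synthetic sessions** (`gen_design`, `gen_respiration`,
  `simulate_session`, `gen_roi_timeseries`, `gen_pupil`, `run_pipeline`,
  `validate_against_truth`): a 6-run × 120-trial 2×2 cue/timing design,
  quasi-periodic respiration with sighs, a detection observer whose threshold
  is sinusoidally modulated by respiratory phase
  (m(θ) = m₀ + A·cos(θ − φ₀)), phase-modulated ROI oscillations over 1/f
  background, and phase-gain-modulated directed VAR coupling.

## Worked example

```r
library(resphase)

res <- run_pipeline(rs_config(seed = 1))
res$psychometrics$overall_fit
#> <psych_fit> m = 0.4685 (sd 0.0440), sigma = 0.0736, lambda = 0.000, gamma = 0.333, n = 660
res$psychometrics$hit_rate
#> [1] 0.5954545
res$psychometrics$modulation$min_phase      # phase of best sensitivity (rad)
#> [1] -1.042062
validate_against_truth(res)[, c("check", "truth", "estimate", "pass")]
#>                     check     truth    estimate pass
#> 1      breathing_rate_bpm 15.000000  14.9421476 TRUE
#> 2          quest_hit_rate  0.600000   0.5954545 TRUE
#> 3 threshold_min_phase_rad -1.047198  -1.0420615 TRUE
#> 4         power_mod_depth  0.200000   0.1629456 TRUE
#> 5     power_mod_phase_rad  1.570796   1.6990407 TRUE
#> 6    gc_mod_dai_direction  1.000000   0.9272671 TRUE
#> 7   gc_mod_band_elevation        NA 104.4999555 TRUE
```

The run simulates a full session (720 trials; the first 10 per run are
discarded), extracts respiratory phase, drives the observer through the QUEST
staircase (hit rate 0.595, criterion 0.60), refits the psychometric function
across 60 phase windows (the threshold minimum lands at −1.04 rad, i.e. mid
inspiration, within 0.3° of the generator's ground truth of −π/3), recovers
the planted 0.2 power-modulation depth at the 10 Hz band (0.16 after noise
dilution) and its phase, and identifies the direction of the phase-modulated
A→B coupling (DAI of the modulation ≈ +0.93, strongly band-elevated).

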