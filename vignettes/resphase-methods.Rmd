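---
title: "Methods: respiration phase-resolved analysis in resphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration phase-resolved analysis in resphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`resphase` quantifies how the respiratory cycle modulates perception and
neural population dynamics. This vignette documents the models and estimators
the package implements, the choices made where the design was genuinely open,
the numerical conventions, what the synthetic-data generator does and does not
emulate, and the problem sizes the validation suite runs at.

## The respiratory phase variable

Respiration belt traces are z-scored and high-amplitude excursions
(|z| > 2.5, typically sighs) are replaced by linear interpolation between the
nearest retained samples, so that sighs do not distort the subsequent
prominence-based peak detection (`normalize_and_clip`). The z-score/clip pair
is iterated to a fixed point *within one call*: a single pass would leave the
trace with a standard deviation below one after clipping, and re-standardizing
could push new samples over the threshold. Iterating makes the operation
exactly idempotent — a useful invariant for pipelines that may normalize
twice. Runs of clipped samples touching the recording edges have no anchor on
one side and are held at the nearest retained value.

Inspiratory peaks are detected on the normalized trace and expiratory troughs
on its negation, both with a minimal topographic prominence of 1 (z units).
Strict alternation is enforced by keeping the most extreme sample within any
run of same-type extrema. Phase is interpolated linearly from trough to peak
(−π → 0, inspiration) and peak to trough (0 → π, expiration), which centres
each cycle on peak inspiration (phase 0). Two conventions resolve the
endpoint ambiguity deterministically: trough samples carry −π (the start of
inspiration), and samples before the first / after the last extremum are
undefined (`NA`) rather than extrapolated; events that fall there are
excluded and counted in the log. Breathing rate is 60 divided by the mean
inter-peak interval in seconds.

Pupil area traces are converted to diameter (`2*sqrt(area/pi)`, linearizing
the measure), blink samples (dropout floor plus a robust velocity criterion,
padded ±100 ms) are linearly interpolated, a relaxed second artifact pass at
z = 6 catches residuals, an optional canonical blink response — a
double-gamma-style kernel convolved with blink onsets, with its time constant
and amplitude fitted per recording by least squares — is regressed out, and
the trace is band-pass filtered 0.01–10 Hz with a second-order Butterworth
cascade applied forward–reverse (zero phase), then robust z-scored
((x − median)/(1.4826·MAD)). The blink-response estimator is toggleable
because its parametric form is a modelling choice, not a measurement.

## Psychometrics and the QUEST staircase

The observer model is a cumulative Gaussian with guess and lapse asymptotes,
Ψ(c) = γ + (1 − γ − λ)Φ((c − m)/σ), with γ fixed at 1/3 (three-response
single-interval task treated as 3AFC). Contrast is dimensionless in [0, 1].
The threshold is reported at the midpoint of the unscaled sigmoid (c = m).

The QUEST staircase maintains a posterior over log10 threshold on a grid
(default [−2.5, 0], 251 points) with an internal model
p(hit | c, T) = γ + (1 − γ − δ)Φ(β(log10 c − T)), β = 3.5, δ = 0.01.
Placement uses the posterior *mean* of the log threshold (the stable choice
in the Watson–Pelli family) and proposes the contrast at which the internal
function equals the target probability 0.60 ∈ (γ, 1 − δ). A posterior mode
on the grid edge raises a divergence warning. The grid update is exactly a
Bayes product, which the test suite verifies against an independently coded
brute-force replay to 1e−10. With a stationary observer the empirical hit
rate settles at 0.60 ± 0.03 over a 720-trial session even though the
internal model (Gaussian in log contrast) deliberately differs from the
observer (Gaussian in linear contrast) — the staircase's fixed point is the
contrast at which the *observer* produces the target rate.

Fitting is MAP on a (threshold, log-width, lapse) grid with flat priors on m
and log σ and a Beta(1, 20)-shaped prior on λ over [0, 0.2]. Credible
intervals come from the grid marginals. Degenerate data (all hits, all
misses, a single contrast level) are flagged, not rejected.

The phase-resolved profile walks window centres in steps of π/30 around the
cycle (60 windows) and refits the trials whose phase lies within ±π/10 of
the centre, so every trial supports (2·π/10)/(π/30) = 6 windows. The window
refits put Gaussian priors on threshold and log-slope centred on the overall
fit with SD = 2 × the overall marginal posterior SD — weakly informative
around the global estimate, since no exact prior width is canonical — and
hold the lapse at the overall MAP (the refit priors concern threshold and
slope). Windows with fewer than 10 trials are skipped and logged. Thresholds
are z-scored across defined windows per participant, and the group-level
test is a per-window two-sided one-sample t against 0 with
Benjamini–Hochberg FDR across windows (q = 0.05).

## Circular statistics

The circular–linear correlation uses the standard two-harmonic formula
ρ² = (r²cx + r²sx − 2 rcx rsx rcs)/(1 − r²cs) with the χ²₂ approximation for
n·ρ² (a permutation option exists for small n). The Rayleigh statistic is
z = nR̄² with the usual finite-n series correction. The Hodges–Ajne statistic
m is the minimum count in any closed half-circle, and its tail probability
is the exact combinatorial form 2^(1−n)(n − 2m)C(n, m) for n ≤ 50 (capped at
1; a normal-style approximation above). Because m is discrete, the test's
attainable significance levels near 0.05 are sparse; the calibration suite
therefore checks its empirical rejection rate against the exact attainable
level α*(n) ≤ 0.05 rather than against 0.05 itself, which no discrete test
can match. Bin edges are right-closed ((−π, π] partition) for determinism;
the paired test of circular differences against zero is a sign-flip
permutation on |Σ sin dᵢ| (exact enumeration below n = 5), cross-checked
against a t-test on the sine components for concentrated samples.

## Spectral estimation

Epochs cover [−1.85, 0.75] s around target onset at 300 Hz (780 samples);
analyses use the prestimulus [−1600, 0] ms. DPSS tapers are computed from
the tridiagonal eigenproblem with concentrations from the sinc kernel, using
floor(2·NW) − 1 tapers for a half-bandwidth smoothing of 2 Hz, and
eigenvalue-weighted averaging. `multitaper_psd` returns one-sided density
(units²/Hz; integrating it recovers the variance — a Parseval check in the
tests), whereas `csd_multitaper` returns two-sided density so that a VAR
process with transfer function H and innovation covariance Σ satisfies
S(f) = HΣH*/fs exactly — the convention the factorization and the analytic
VAR oracles rely on.

Spectral whitening is the first difference per trial and channel, a
time-domain filter with gain 2·sin(πf/fs) that suppresses the low-frequency
aperiodic component (its squared gain rises as f² and exactly inverts a
1/f² power slope); epochs shorten by one sample and spectra are computed on
the shortened epoch. Head-motion cleanup regresses out the 6 rigid-body
signals and their derivatives, each expanded to polynomial orders 1–3 (36
regressors), plus a third-order polynomial drift, with a ridge fallback for
rank-deficient designs.

Phase-binned power uses 30 moving window centres (spacing 2π/30) with
half-width π/10, mirroring the behavioural windows, since no canonical width
exists for the moving mode; a non-overlapping 30-bin mode is also provided.
Bin means per ROI and frequency are regressed on sine/cosine of the bin
centre; the modulation depth is the first-harmonic amplitude divided by the
intercept. The additive noise floor (channel noise, residual background)
attenuates this ratio slightly below the generative depth — the recovery
tolerance of ±0.05 absorbs this known bias rather than hiding it with an ad
hoc floor subtraction.

## Blockwise spectral Granger causality and the DAI

Each ROI contributes its first three principal components (computed across
trial-concatenated time series; fewer with a warning if the data are rank
deficient). The 6-channel CSD on the full DC-to-Nyquist grid is diagonally
loaded by 1e−8 × the mean power and factorized with Wilson's iterative
algorithm; the causal-part operator is applied in the lag domain via FFT,
halving both the zero lag and the shared Nyquist lag (the latter is its own
mirror on the circular grid — keeping it whole leaves a small irreducible
residual). Convergence is declared when the relative reconstruction
residual falls below 1e−8 (at most 100 iterations; non-convergence is an
error reporting the final residual). The lag-0 coefficient A₀ gives
Σ = A₀A₀ᵀ·fs and H = ψA₀⁻¹.

Directed influence between blocks follows Geweke:
f_{A→B}(f) = ln det S_BB / det(S_BB − H_BA Σ_{AA|B} H_BA*), with the
partialized innovation covariance Σ_{AA|B} = Σ_AA − Σ_AB Σ_BB⁻¹ Σ_BA, clamped
at 0. The DC bin is excluded from returned GC spectra by default (demeaning
leaves it ill-conditioned and uninterpretable). The directed asymmetry index
DAI = (GC_{A→B} − GC_{B→A})/(GC_{A→B} + GC_{B→A}) is antisymmetric and
bounded in [−1, 1]; frequencies where the summed GC falls below a floor are
returned as NA rather than amplifying noise.

Phase-resolved GC repeats the full CSD → factorization → block-GC chain per
respiration-phase bin (30 non-overlapping bins by default, minimum 15 trials
per bin; undersized or failed bins are skipped and logged). The per-bin GC
spectra are regressed on sine/cosine of the bin centre per frequency and
direction. Because the raw sine/cosine weights are signed, the DAI of the
*modulation* is computed on the two directions' modulation magnitudes
√(b²sin + b²cos), which are nonnegative and keep the DAI denominator well
defined — the magnitude is also the phase-invariant summary of how strongly
respiration modulates each direction. GC is evaluated on the 0–150 Hz grid;
phase-regression statistics are typically restricted to 0–40 Hz.

One property of this generative family deserves emphasis: an AR(2) resonator
driven through a lag-1 cross-coefficient produces a *broadband* GC spectrum
(the log-ratio saturates wherever the source transfer gain is high), so the
"coupled band" manifests as a band-limited *elevation* of the
modulation-amplitude spectrum over the high-frequency floor, not as a narrow
peak exactly at the resonance. Recovery checks therefore test band
containment (elevation ≥ 3× the floor ≥ 20 Hz above the band) and the DAI
sign, not peak position.

## Cluster permutation and mutual information

The cluster test computes a two-tailed t per feature (participants ×
frequencies, or frequency × time grids), thresholds at p = 0.05, groups
adjacent same-sign suprathreshold points (chain adjacency over frequency,
4-neighbour grids, or a user adjacency list), sums |t| per cluster, and
builds the null from sign-flip permutations with re-thresholding and
re-clustering per permutation (default 5000). Two quantities are reported:
the raw permutation p per cluster, p = (1 + #{null ≥ stat})/(nperm + 1),
which is the calibrated quantity (family-wise FPR = α when rejecting at
p ≤ α — verified on smooth null simulations), and a significance flag at the
97.5th percentile of the null distribution, the stricter reporting
convention used with two-tailed point thresholds. Brain–behaviour
correlation spectra (Spearman by default, for robustness across monotone
scalings) are cluster-corrected by permuting the participant pairing.

Mutual information model comparison uses a Gaussian-copula estimator with a
discrete target: continuous predictors are rank-transformed to normal
scores, binary cue regressors enter as 0/1 columns, and
I = H(X) − Σ_y p_y H(X|y) with Gaussian entropies (bits). Constant or
linearly dependent columns are dropped with a warning. Estimator bias is
removed by subtracting the mean over 50 shuffled-outcome surrogates and
flooring at zero; ΔMI is the difference between the corrected full and base
models, tested across participants with a two-sided t.

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the experiment's structure: 6 runs × 120 trials
(30 per 2×2 cue/timing condition, sides balanced within condition and run);
1600 ms fixation, 50 ms target, 500 ms response delay, 1.2–2.0 s residual
inter-trial interval (chosen so the mean trial duration matches a ~450 s
run); respiration at 15 breaths/min with log-normal cycle-period jitter
(SD 0.1) and amplitude jitter (SD 0.1), and 2% per-cycle sighs at 2.5–3×
amplitude; a QUEST-driven observer with m₀ = 0.5, σ = 0.15, λ = 0.02,
modulation amplitude A = 0.08 at φ₀ = +2π/3 (so sensitivity peaks at −π/3,
mid-inspiration); ROI oscillations at 10 Hz whose power follows
P₀(1 + 0.2·cos(θ − π/2)) over 1/f background and white channel noise; and a
directed VAR(2) coupling A→B whose gain is 1 + cos(θ − π/2), pole radius
0.95, baseline cross-coefficient 0.5. The envelope scaling uses the phase at
*target onset* per trial, matching the trial-sorting logic of the analyses.

Deliberate simplifications: the respiration waveform is a symmetric cosine
per cycle (real breathing has asymmetric inspiration/expiration durations,
which would make time-uniform events non-uniform in phase); pupil dynamics
are slow filtered noise with rectangular dropouts, not a physiological
model; ROI channels share a single latent per ROI (no dipole geometry or
leakage); and no MEG sensor physics, eye movements, or cardiac signals are
simulated. Passing recovery tests therefore demonstrates that the
*estimators* are correct and calibrated under realistic noise levels — not
that real recordings satisfy the generative assumptions.

## Numerical choices and problem sizes

Seeds: every generator derives its RNG stream deterministically from a
single master seed; identical configuration plus seed reproduces every
output bit for bit. Tolerances: Wilson residual 1e−8; diagonal loading
1e−8 × mean power; GC clamped at 0; DAI floor 1e−12. Degenerate inputs are
flagged (degenerate psychometric data, rank-deficient ROI blocks, constant
MI predictors) rather than silently fixed.

The validation suite runs, per check, at the sizes a desk-scale replication
supports: full 720-trial sessions for staircase convergence and
threshold-profile recovery; 660 trials (post-discard count) for the
phase-binned power and phase-resolved GC recoveries, giving ~22 trials per
non-overlapping GC bin; 20 seeded session replicates for the end-to-end
directionality check; 120 replicates at 500 permutations for the
cluster-test calibration; and 5000 null draws for the circular-test
calibrations. The GC oracle comparison uses a 2-channel VAR(2) at 100 Hz
with a broad resonance (pole radius 0.8) so that the 1-Hz multitaper
smoothing does not bias the peak — against sharper spectra the smoothing
bias, not the factorization, dominates the comparison.

## Known limitations

Adaptive staircases concentrate tested contrasts near threshold, so the
psychometric *slope* is only weakly constrained by session data and its MAP
estimate can be attenuated; the threshold and the phase-resolved profile are
unaffected, since the window refits take their priors from the same overall
fit. The Hodges–Ajne p-value is conservative between attainable levels; the
phase-resolved threshold profile inherits smoothing from the overlapping
windows (adjacent windows share 2/3 of their trials, so profile noise is
correlated across neighbouring centres); the GC estimator is biased upward
at very low trial counts per bin (hence the 15-trial minimum); depth
estimates from binned power are attenuated by additive noise; and directed
GC cannot distinguish true coupling from common input — the package reports
statistical predictability, not anatomical causation.
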