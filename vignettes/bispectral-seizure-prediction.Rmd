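---
title: "Bispectral features for seizure prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral features for seizure prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In drug-refractory epilepsy, a reliable warning minutes to an hour before a
seizure would allow protective intervention. The analysis implemented here
asks whether *quadratic phase coupling* (QPC) between oscillatory components
of intracranial EEG (iEEG) changes in the hour before seizure onset — the
**preictal** state — relative to baseline recordings far from any seizure —
the **interictal** state.

Ordinary spectral band power is blind to this question: it measures energy
per frequency and discards all cross-frequency phase relationships. The
**bispectrum**

$$B(f_1, f_2) \;=\; E\!\left[\,X(f_1)\,X(f_2)\,X^{*}(f_1+f_2)\,\right]$$

(where $X(f)$ is the Fourier transform of the windowed signal and $E$ the
average over estimation segments) is the lowest-order statistic that is not.
If the component at $f_1+f_2$ carries the phase sum $\phi_1+\phi_2$ —
quadratic coupling — the triple product accumulates coherently and $|B|$
peaks at $(f_1, f_2)$; if the phases are unrelated, the product averages
toward zero at rate $1/\sqrt{K}$ in the number of averaged segments $K$.
For a real signal all distinct information lies in the principal domain
$\Omega = \{f_2 \le f_1,\ f_1+f_2 \le f_s/2\}$, here additionally
intersected with the analysis band $[0.5, 180]$ Hz (all boundaries
inclusive).

Three scalar features summarize each bispectrum:

* **Mave** $= \frac{1}{L}\sum_{\Omega}|B|$ — mean bispectral magnitude over
  the $L$ bins of $\Omega$;
* **P1** $= -\sum_n p_n \ln p_n$ with $p_n = |B|/\sum_\Omega|B|$ —
  normalized bispectral entropy;
* **P2** $= -\sum_i q_i \ln q_i$ with $q_i = |B|^2/\sum_\Omega|B|^2$ —
  normalized squared bispectral entropy.

Entropies are reported in nats (natural logarithm; a base-2 option exists
but nats are the tested default — with thousands of bins the observed
4–5 nat range is the natural-log scale). One frequency pair is one bin; no
histogram re-binning is applied. P1 and P2 lie in $[0, \ln L]$, are
invariant to signal amplitude, and satisfy $P2 \le P1$ (squaring the
weights forms an escort distribution, which always sharpens). Strong
coupling concentrates the bispectrum and *lowers* the entropies; Mave
scales as the cube of signal amplitude.

## Pipeline

1. **Preprocess** (`zero_phase_filter`, `segment_windows`): 60 Hz notch
   (biquad, Q = 30) and 4th-order Butterworth band-pass [0.5, 180] Hz, both
   applied forward–backward so the net phase shift is zero — the features
   live on phase relationships, which filtering must not distort. Whole
   1-hour segments are filtered once, then cut into non-overlapping 30-s
   windows (120 per hour); a trailing partial window is dropped.
2. **Estimate** (`direct_bispectrum`): direct FFT method per window and
   channel. Defaults: 512-sample segments (1.28 s at 400 Hz, 23 segments
   per window), Hann taper, no overlap, per-segment mean subtraction,
   per-segment FFTs scaled by $1/\mathrm{seg\_len}$ so magnitudes are
   comparable across FFT lengths. The implemented product convention
   $E[X(f_1)X(f_2)X^*(f_1+f_2)]$ is the complex conjugate of the equivalent
   $E[X(f_1+f_2)X^*(f_1)X^*(f_2)]$ form; magnitudes — all that the features
   consume — are identical for real signals.
3. **Features** (`extract_features_dataset`): one (Mave, P1, P2) triple per
   window × channel, in a tidy table keyed by subject, seizure, state,
   window and channel. All-zero (degenerate) windows are dropped and
   counted, not imputed.
4. **Statistics** (`global_anova`, `per_seizure_tests`,
   `predictability_map`): a global per-subject one-way ANOVA per feature
   (preictal vs interictal pooled over seizures), and per-seizure,
   per-channel two-sided Mann–Whitney tests of 120 preictal against 120
   interictal windows. The map reports, per channel × feature, the percent
   of seizures significant at $\alpha = 0.05$ — raw p-values, no
   multiple-testing correction (a localization display, not a family-wise
   claim; a correction flag exists but defaults off, matching the raw
   $p < 0.05$ convention of this analysis design).
5. **Classifier** (`split_by_seizure`, `train_mlp`): a 5-layer MLP
   (16 → 30 → 60 → 30 → 2, ReLU hidden units, softmax cross-entropy) per
   subject and per feature, whose input is that feature across the 16
   channels for one window. Training uses plain SGD (momentum 0), learning
   rate 0.001, batches of 200, up to 10,000 epochs, checkpointing every 10
   epochs.

### Seizure-wise splitting

Windows from the same hour are strongly dependent; splitting them across
train/validation/test would let the network learn temporal correlation
instead of state and overstate accuracy. Seizures — not windows — are
therefore shuffled and partitioned 40/30/30 by largest-remainder rounding
(ties and remainders resolved train > validation > test, so 17 seizures
split 7/5/5), and every window of a seizure, preictal and interictal, lands
in exactly one partition. The leakage-freedom invariant is asserted on
every training and evaluation run.

### Checkpoint selection

"The latest model before validation loss starts increasing" is ambiguous
when the validation curve is noisy — the first uptick is often a
fluctuation. The default rule is therefore the checkpoint with the *global
minimum* validation loss; a strict `first_increase` mode is available. With
a monotone curve the two coincide.

### Input standardization

Raw Mave values sit at magnitudes where SGD at learning rate 0.001
effectively stalls, so inputs are z-scored per channel — using training
partition statistics only, to keep the held-out partitions untouched.
Weights are initialized fan-in-scaled uniform
($\pm\sqrt{6/\mathrm{fan\_in}}$), seeded; analytic gradients are verified
against central finite differences in the test suite. Classes are balanced
by construction (one interictal hour per preictal hour), so no reweighting
is applied.

## The synthetic-data generator

Real chronic canine iEEG (16 channels at 400 Hz) is not redistributable
with a package, so the generator emulates the *design* of such a study:
per seizure, one 1-hour preictal and one independently generated 1-hour
interictal segment, 16 channels. Each channel is a sum of three cosines at
$f_1 = 40$, $f_2 = 30$ and $f_1+f_2 = 70$ Hz over 1/f-shaped Gaussian
noise, with all phases redrawn uniformly every 1-s sub-epoch. The coupling
strength $\lambda \in [0,1]$ splits the harmonic's amplitude between a
phase-coupled part (phase $\phi_1+\phi_2$) and an independent-phase part:

* $\lambda$ affects third-order structure only — the power spectrum of
  $\lambda = 0$ and $\lambda = 1$ signals is identical in expectation
  ("spectral stealth", verified in the tests). The bispectrum, not band
  power, must carry the class signal.
* Phases must decorrelate across estimator segments (hence the 1-s
  sub-epoch), otherwise an uncoupled harmonic with a fixed random phase
  would masquerade as coupled within a window.

Channels in `coupled_channels` (default: 4 of 16) switch from
$\lambda_{\text{inter}} = 0.1$ to $\lambda_{\text{pre}} = 0.8$ in the
preictal state; all others stay at $\lambda_{\text{inter}}$ always. Free
parameters were fixed once at what a surrogate-data study would call
plausible: unit amplitudes for the three components and noise standard
deviation 0.5, i.e. line components comparable to the broadband
background; 40/30 Hz keeps the harmonic clear of the 60 Hz notch. The
interictal coupling level 0.1 is a free design choice of the generator,
not an inference about real recordings.

What the generator deliberately does **not** emulate: seizure morphology,
spikes, high-frequency oscillations, artifacts, non-stationary drift,
inter-channel correlation, or circadian structure. Passing tests therefore
demonstrate that the pipeline detects and classifies state-dependent QPC
under realistic noise — not that real preictal iEEG carries such coupling.

## Numerical choices and degenerate inputs

* **Oracle**: the direct-FFT estimator is cross-checked against an
  independent time-domain implementation (explicit circular triple
  correlation + 2-D DFT) to $10^{-8}$ relative error on small inputs.
* **Filter edge handling**: before the forward–backward passes the signal
  is extended at each end by three periods of the lowest passband
  frequency (0.5 Hz → 6 s) via stable Burg AR extrapolation fitted to the
  adjacent samples. Reflection padding was rejected: any reflection leaves
  a value- or derivative-discontinuity whose broadband edge energy
  dominates the notch residual; AR extension continues oscillations
  phase-coherently and leaves residuals orders of magnitude below the
  5% attenuation contract the tests assert.
* **Entropy conventions**: $0 \ln 0 = 0$; an all-zero bispectrum makes
  $p_n$ undefined, so P1/P2 return `NA` and the window is dropped and
  logged rather than aborting a run.
* **ANOVA/MWU**: the two-group ANOVA uses the classical pooled-variance
  decomposition (equal to the squared pooled t statistic, asserted in
  tests); zero pooled variance is a classed degenerate-input error.
  Mann–Whitney uses midrank ties, exact enumeration below 8 observations
  per group and the tie- and continuity-corrected normal approximation
  otherwise (the per-seizure tests compare 120 vs 120 windows).
* **Channel collapse for the global ANOVA**: the global test operates on
  one value per window; features are averaged across channels per window
  (configurable mean/median). This is a declared convention — with per
  window × channel values pooled instead, the degrees of freedom would not
  match the per-window design of the rest of the analysis.
* **Determinism**: every stochastic stage draws from a sub-stream derived
  by hashing a global seed with stage labels (`derive_seed`), so a run
  config reproduces artifacts bit-for-bit and single stages can be re-run
  in isolation.

## Problem sizes used in the shipped tests

The full design — 3 subjects, 45 seizures, 16 channels, paired 1-hour
segments — is the generator's default and runs unchanged; the shipped test
suite and the acceptance script exercise the identical code paths at sizes
chosen to keep a complete run at laptop scale: calibration of the
channel-wise tests on 100 null seizures × 3 channels of 15-minute segments
(300 channel-seizure tests), the power run on full 1-hour segments
(120 windows per state, 10 seizures × 4 channels), and classifier tasks on
12 seizures × 16 channels of 10-minute segments with 2,000 training epochs
under checkpoint selection. Window-count and degrees-of-freedom arithmetic
is verified at the full 45-seizure, 1-hour scale.

## Known limitations

* Quantities that depend on real recordings — absolute feature magnitudes,
  subject-level F statistics, achievable real-data classification
  accuracies — are not reproducible from synthetic data and are not
  targets of this package's tests.
* The uncoupled-harmonic peak at $(f_1, f_2)$ retains a finite-sample
  fluctuation of order $a_1a_2a_3/8/\sqrt{K}$ set by the line amplitudes;
  without bicoherence-style normalization (out of scope) it does not sink
  to the median background level, which bounds how "invisible" absent
  coupling can look to the raw-magnitude features.
* EDF support reads continuous, single-rate recordings only; no resampling
  is performed (a rate mismatch is an error by design).
* The MLP is a faithful small network, not a tuned classifier;
  improvements (momentum, schedules, regularization) are deliberately out
  of scope.
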