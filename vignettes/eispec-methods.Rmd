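---
title: "Methods: E/I-sensitive EEG biomarkers and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: E/I-sensitive EEG biomarkers and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

eispec implements a sensor-level resting-state EEG pipeline built around four
biomarkers that are sensitive, in different ways, to the balance of
excitation and inhibition in cortical networks: band-limited spectral power,
the DFA exponent of narrowband amplitude envelopes (long-range temporal
correlations, LRTC), the functional excitation/inhibition ratio (fE/I), and
the aperiodic (1/f) exponent of the power spectrum. This vignette describes
the models and procedures, the tunable parameters, the synthetic-data
generator used to validate every estimator against ground truth, and the
numerical choices and limitations a careful user should know about.

## Preprocessing chain

`preprocess_recording()` applies, in order:

1. **Band-pass filtering**, 1–45 Hz, Hamming-window FIR with 1-Hz transition
   bands, applied zero-phase (the linear-phase kernel's group delay is
   compensated exactly in the frequency domain), so filtered samples stay
   aligned with raw time.
2. **Bad-channel detection.** A channel is flagged when the across-channel
   z-score of any of three statistics exceeds 3: sample kurtosis; the mean
   negative log-probability of the channel's samples under a Gaussian
   kernel-density estimate of its own amplitude distribution (bandwidth by
   Silverman's rule) — our operationalization of the classic "joint
   probability" statistic, which toolboxes name without a formula; and the
   mean log band power over 1–45 Hz. Flat (zero-variance) channels are
   always flagged. Detection is single-pass; we do not re-detect after
   interpolation, which keeps the procedure reproducible and order-free.
3. **Spherical-spline interpolation** of flagged channels (order m = 4,
   Legendre series truncated at 50 terms, ridge 1e-5 on the spline system
   diagonal) using idealized unit-sphere 10–20 electrode positions shipped
   with the package. The spline reproduces constant fields exactly;
   leave-one-out error on smooth analytic fields at 19 sites is below 15%.
4. **Average re-referencing** (idempotent; per-sample channel mean becomes
   zero) and **selection of the 19 common 10–20 channels** in a fixed
   canonical order, with T7/T8/P7/P8 accepted as aliases of T3/T4/T5/T6.
5. **1-s epoching with amplitude rejection**: an epoch is rejected when any
   sample on any channel exceeds ±150 µV (a per-recording override of
   ±500 µV is available for recordings whose artifact-free amplitude range
   is genuinely larger). Rejection is applied before ICA and not repeated
   afterwards; epochs kept at a strict limit are always a subset of those
   kept at a looser one.
6. **ICA-based ocular artifact removal.** Kept epochs are concatenated, the
   data reduced by PCA to its numerical rank (so interpolated channels do
   not inflate the decomposition), and unmixed with FastICA (symmetric
   orthogonalization, logcosh contrast, fixed seed). A component is called
   ocular when more than 60% of its variance lies below 5 Hz *and* its mean
   absolute topography weight over Fp1/Fp2/F7/F8 exceeds twice the
   all-channel mean. This documented heuristic replaces crowd-trained
   classifiers, which are out of scope; both thresholds are arguments.
   Expert visual review cannot be reproduced in software; an optional
   external keep-mask can be AND-ed into the rejection mask instead.

Recordings with less than 100 s of clean signal after cleaning are excluded
from group analysis; `run_pipeline()` quarantines them with a reason.

## Spectral power

`welch_psd()` uses Welch's method with 2-s Hamming segments and 50% overlap.
The FFT length is `sampling_rate / 0.125` (segments are zero-padded), which
fixes the frequency resolution at 0.125 Hz for every sampling rate, so bins
align across recordings acquired at different rates; 1–45 Hz then contains
exactly 353 bins. Density scaling is used (the integral of the PSD over
frequency approximates the signal variance); log10 is taken only at the
statistics layer. With epoched input, Welch segments are drawn only from
contiguous runs of kept epochs, so no segment spans a rejection gap. Band
summaries average bins inclusively; a printed band edge that is off the
0.125-Hz grid at printed precision (such as 4.63 Hz) is snapped to the
nearest grid point (4.625 Hz). Whole-brain values are arithmetic means over
the 19 electrodes; for power we average log10 power across electrodes (the
alternative order — log of the mean — is not what we use, and the choice is
stated here because it is ambiguous in common practice).

## DFA of amplitude envelopes

For each electrode and each 1-Hz analysis bin between 1 and 45 Hz (44 bins),
the signal is band-passed with a Hamming FIR filter (1-Hz transition bands,
zero-phase), the amplitude envelope taken as the modulus of the analytic
signal, and DFA applied: the demeaned envelope is integrated into a
cumulative-sum profile; for each of 15 logarithmically spaced window sizes
the profile is split into 50%-overlapping windows, each window linearly
detrended, and the fluctuation taken as the mean per-window SD. The DFA
exponent is the least-squares slope of log10 fluctuation vs log10 scale.
Scales span 2–20 s for bins starting at or above 8 Hz and 4–20 s below
(short scales are biased by the narrowband filter's impulse response; the
boundary bin 8–9 Hz is assigned to the high-frequency rule). An exponent of
0.5 indicates an uncorrelated envelope; 0.5–1 indicates LRTC.

Two numerical notes. First, the overlapping-window implementation agrees
with a naive non-overlapping brute-force DFA to within 0.02 on long fGn
inputs (this is a regression test). Second, the envelope of *any* signal
confined to a 1-Hz bin carries correlations induced by the filter itself,
so at 2–20 s scales even white noise yields bin-level exponents well above
0.5 (a crossover effect we verified independently with a scipy
implementation). Bin-level exponents should therefore be compared between
conditions, not read as absolute Hurst values; the package's white-noise
null (exponent 0.5) applies to the envelope itself, before narrowband
filtering, and is asserted in the acceptance tests.

## fE/I

`fei_value()` splits the envelope into 5-s windows with 80% overlap. Per
window, wAmp is the mean envelope, and wDNF is the SD of the linearly
detrended cumulative sum of the window's envelope divided by wAmp — an
amplitude-normalized fluctuation. fE/I = 1 − Pearson(wAmp, wDNF): positive
amplitude–fluctuation coupling gives fE/I < 1 (inhibition-dominated),
negative coupling fE/I > 1, no coupling ≈ 1. Because wDNF is normalized by
wAmp, fE/I is invariant to amplitude scaling. Windows never span rejection
gaps (window statistics are pooled across contiguous clean runs before the
final correlation). The estimator is flagged invalid when the in-bin DFA
exponent does not exceed 0.6 (without LRTC the statistic is uninformative);
the rule is ON by default but switchable, and the validity mask is always
emitted, since whether the threshold should gate downstream averages is a
judgment call — band summaries therefore use all bins by default and expose
`valid_only = TRUE`. Among the two normalization orders that the verbal
definition admits (normalize the envelope then re-integrate, vs normalize
the integrated profile), we normalize the window's envelope by wAmp and
rebuild the window profile; both orders give fE/I = 1 under zero coupling,
which the surrogate test asserts.

## Aperiodic exponent

`fit_spectral_model()` decomposes a log10 power spectrum over 1–30 Hz into
an aperiodic line (offset − β·log10 f, "fixed" mode, no knee) plus up to 6
Gaussian peaks: robust initial line fit (points above the 97.5th percentile
of residuals are dropped and the line refit); iterative extraction of
residual maxima exceeding both 0.05 log10 units and 1.5 residual SDs, with
peak SDs constrained to 0.5–3 Hz (half the 1–6 Hz width limits); edge peaks
(center within one SD of a range edge) dropped and overlapping peaks closer
than 0.75 SD merged keeping the taller; joint bounded Levenberg–Marquardt
refit of all Gaussians (500 iterations, tolerance 1e-8); final line refit on
the peak-removed spectrum. R² is computed between the full model and the
log10 spectrum. A 5–30 Hz sensitivity refit is available through
`fit_range`. Pure power laws round-trip essentially exactly; β is recovered
within ±0.1 on in-family spectra with up to 3 peaks and 5% multiplicative
noise.

## Group statistics

`ancova_group_age()` fits the equal-slopes model y = b0 + b1·group + b2·age
(group coded 0/1, age centered — centering only conditions the solve, it
does not change F) and tests the group term with the nested-model F
statistic on (1, n−3) degrees of freedom; the implementation is checked
against an explicit two-`lm()` oracle to 1e-10 on random instances.
Per-bin spectra use Bonferroni families of 353 (power) or 44 (DFA/fE/I)
bins; topographies use 19 electrodes. Partial correlations with clinical
scales residualize both variables on age and use n−3 degrees of freedom,
with pairwise deletion of missing scores. Age slopes are per-group OLS
fits; setup comparisons use Welch's unequal-variance t test (the plain
"independent-samples t test" description leaves the variance assumption
open, and Welch is the safer default). Recording site is not modeled: in
this design it is perfectly collinear with group.

## The synthetic cohort generator

No clinical recordings are distributable, so the generator is the package's
ground-truth instrument. It emulates the statistical structure the four
estimators measure, not biophysics:

- **fGn by circulant embedding** (`generate_fgn()`): exact autocovariance,
  verified against the closed form; exactness is what makes tight recovery
  tests possible.
- **Oscillations** (`generate_band_signal()`): a stochastic narrowband
  carrier, normalized to unit instantaneous amplitude so that its phase
  keeps narrowband-noise statistics while the envelope equals exactly
  `exp(s·z)` with z the fGn — a strictly positive log-normal envelope whose
  DFA exponent approximates the requested Hurst parameter (recovered within
  ±0.05 over 0.55–0.85 at the generation band; the narrow-bin crossover
  discussed above applies downstream). Carriers can be FIR-band or
  Gaussian-spectrum shaped; the cohort uses Gaussian shapes and confines
  each component's modulation sidebands to its band so spectral humps stay
  within the family the aperiodic model can absorb.
- **Coupling** (`generate_coupled_signal()`): the envelope is
  `exp(mu)·(1 + sigma(t)·q)`, with mu a window-scale-smoothed full-variance
  fGn level process, q a bounded zero-mean fluctuation process band-limited
  between the filter timescale and the 5-s analysis window, and the local
  volatility sigma(t) a linear function of the standardized level plus
  independent window-scale noise. Because wDNF measures exactly this local
  normalized fluctuation and wAmp follows the level, the imposed
  level–volatility correlation becomes the wAmp–wDNF correlation the fE/I
  estimator computes. Simpler designs (direct window-gain rescaling) biased
  fE/I through within-window gain curvature and were rejected. The measured
  correlation is attenuated relative to the target (roughly half, from
  carrier envelope noise); calibration is therefore asserted where it
  matters: fE/I = 1 ± 0.05 at zero coupling, sign recovery for
  |rho| ≥ 0.3, and fE/I < 1 at rho = +0.6.
- **Cohorts** (`generate_cohort()`): 19-channel recordings with a 1/f^β
  background (offset 1.3 log10 µV²/Hz), a frontally weighted delta
  oscillation whose power follows a declining developmental age trajectory,
  a posterior-dominant alpha oscillation, a low-beta (11–18 Hz) oscillation
  carrying the envelope Hurst exponent, and a beta (18–24 Hz) oscillation
  carrying the amplitude–fluctuation coupling. Patients (default 14 vs 50
  controls) receive offsets scaled by a per-subject severity factor
  (uniform 0.6–1.4): delta power ×2.2, Hurst +0.12, coupling +0.55,
  aperiodic exponent +0.55 — chosen once to reproduce the four effect
  *directions* at sample sizes of 14 vs 50; clinical effect magnitudes are
  unknowable from published group statistics and are not claimed. Patients'
  flat delta-age trajectory is tied to the delta effect, so a cohort with
  all-zero effects is a true null (the basis of the family-wise-error
  calibration). Synthetic clinical scores (1–5) increase monotonically with
  the severity factor, with one scale partially missing to exercise
  pairwise deletion. One global seed expands to per-recording and
  per-channel seeds by a counter, so cohorts are bit-reproducible.
- **Artifacts** (`inject_artifacts()`): biphasic sub-4-Hz blink waveforms
  projected with frontally dominant weights, ±170–400 µV transient bursts
  on single channels, and optionally one flat channel, all logged with
  sample indices. Defaults are artifact-free; artifacts are injected
  explicitly when the cleaning chain is under test.

What the generator does *not* emulate: volume conduction and realistic
cross-channel correlation (channels are independent), neural-mass dynamics,
sleep/arousal state changes, or realistic eye-movement dynamics beyond the
stereotyped blink. Passing tests therefore demonstrate estimator
correctness and pipeline sensitivity under known ground truth — not
clinical validity on real EEG. Relatedly, the cohort's oscillation-to-
background ratios are deliberately higher than typical clinical EEG
(envelope ground truth cannot be recovered from a bin dominated by
background noise), which makes the cohort's Welch spectra more strongly
peaked than real data; the 0.95 spectral-fit R² benchmark is reproduced on
in-family spectra (1/f plus Gaussian peaks plus 5% multiplicative noise),
while cohort spectra fit at R² ≈ 0.6.

## Numerical choices and problem sizes

All FFT-based convolutions pad to 5-smooth lengths. DFA and fE/I inner
window loops are compiled (Rcpp), with the detrended SD computed from
centered single-pass sums. Integer-ratio downsampling uses a zero-phase FIR
anti-alias filter followed by subsampling (the generic polyphase resampler
left small delay/ripple artifacts that measurably depressed cross-rate DFA
agreement); non-integer ratios fall back on polyphase resampling. The test
and acceptance suites run at desk scale chosen once: 300-s single-channel
signals for estimator calibration; a 300-s, 19-channel, 1000-Hz recording
for the resampling robustness check; 20 replicate null cohorts of 6 + 6
subjects with 30-s recordings for family-wise error; and three full
default cohorts (50 + 14 subjects, 120-s recordings at 200 Hz) for the
headline-contrast power check, which detects all four effects at
Bonferroni-corrected thresholds in every seed.

## Known limitations

- The generator's channels are statistically independent; topographic tests
  on synthetic cohorts overstate spatial degrees of freedom relative to
  volume-conducted EEG.
- Bin-level DFA exponents carry the narrowband-filter crossover floor; only
  contrasts, not absolute values, are interpretable at 1-Hz resolution.
- The ocular-component heuristic is a deliberately simple stand-in for
  trained classifiers and is validated only against the generator's blink
  model.
- The coupled generator targets the sign and ordering of fE/I effects; the
  magnitude mapping from the imposed coupling to measured fE/I is
  estimator- and band-dependent.
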