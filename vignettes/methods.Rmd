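---
title: "Criticality and excitation-inhibition metrics for resting-state EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality and excitation-inhibition metrics for resting-state EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocrit)
```

## The scientific problem

The criticality hypothesis holds that healthy cortex operates near a phase
transition between low-activity (inhibition-dominated) and high-activity
(excitation-dominated) regimes, where dynamic range and information
capacity are maximal. Distance from that critical point is presumed to be
tuned by the excitation-inhibition (E/I) balance. In resting-state EEG,
proximity to criticality leaves quantitative fingerprints in the amplitude
envelopes of band-limited oscillations:

* **Long-range temporal correlations (LRTC)** — near criticality the
  envelope autocorrelation decays as a power law; the DFA exponent
  (an estimator of the Hurst exponent) exceeds 0.5.
* **Bistability** — spontaneous switching between low- and high-power
  oscillatory states makes the envelope power distribution bimodal
  (a two-component exponential mixture) rather than single-exponential.
* **Amplitude-fluctuation coupling** — the functional E/I ratio (fE/I)
  summarizes how envelope fluctuation scaling covaries with envelope
  amplitude; balanced dynamics give values near 1.
* **Signal irregularity** — Lempel-Ziv complexity of the binarized
  broadband signal.

This package implements the full analysis chain — epoch harmonization,
13-band decomposition, the six metrics, covariate-adjusted group
statistics, and a sparse logistic classifier — together with a synthetic
cohort generator that makes every stage testable without access to
clinical recordings.

## Harmonization

All metrics assume one fixed epoch layout per subject: a 4.65-minute
(278.8 s) eyes-closed series. Healthy-control recordings arrive as five
60-s eyes-closed epochs that are concatenated in order; patient
recordings arrive as one continuous eyes-closed record that is split into
five 60-s epochs and reordered 1-3-5-2-4 before concatenation, so that
temporally adjacent epochs do not sit next to each other in only one of
the groups. Both paths then trim 10.6 s from each end, leaving segment
lengths of (49.4, 60, 60, 60, 49.4) s — reported as 49/60/60/60/49 s.
Every windowed computation below treats the five segments as separate
realizations: no filter, envelope, DFA window or fE/I window ever crosses
a segment join, because the joins are artificial.

## Frequency bands

Thirteen bins span 1-73 Hz: one delta bin (1-4 Hz) followed by twelve
geometric bins from 4 to 73 Hz with common ratio $(73/4)^{1/12} \approx
1.274$. Adjacent bins share edges exactly; edges are displayed rounded to
0.1 Hz. This is the unique simple log-spacing scheme that reproduces all
the interval labels the analysis reports (5.1, 6.5, 8.3, 10.5, 13.4,
17.1, 21.8, 27.7, 35.3, 45, 57.3 Hz) to display precision.

```{r}
make_bands()
```

## Band envelopes

Each channel is band-passed with an order-4 recursive (Butterworth)
filter applied forward-backward for zero phase (`signal::butter(2, ...)`;
band-pass design doubles the prototype order), per segment. The amplitude
envelope is the magnitude of the analytic signal (FFT Hilbert transform),
and 1 s is trimmed from each end of every segment to remove filter and
Hilbert edge transients. The 1-s trim is a design choice: with the
order-4 filter the worst-case residual edge ripple on a pure sinusoid is
below 1%.

## Metrics

### DFA exponent

Per segment the envelope is demeaned and cumulatively summed into a
profile; windows of length $s$ advance with 50% overlap; each window is
linearly detrended and the fluctuation function $F(s)$ is the RMS of the
residuals pooled over all windows and segments. The exponent $\alpha$ is
the least-squares slope of $\log_{10} F$ on $\log_{10} s$ over 10
geometrically spaced window lengths in $[S_{\min}, 30\,\mathrm{s}]$, with
$S_{\min} = \max(1, 8/f_{lo})$ s so the smallest window holds at least
eight cycles of the band's slowest component. At the 30-s window length
the five segments supply 8 independent (non-overlapping) windows —
deliberately at the lower edge of common DFA guidelines, which is why DFA
carries a reliability caveat throughout.

### Biexponential envelope power model: BiS, E/I_HLP, E+I_HLS

Envelope power is defined as the squared Hilbert amplitude,
$p(t) = A(t)^2$ — for narrowband Gaussian noise $p$ is exponentially
distributed, which anchors the model. Power samples are thinned to one
per 50 ms before fitting because the fit is compared by BIC, and BIC
assumes independent samples while envelopes are strongly autocorrelated
at the sample rate.

Two models are fit: a single exponential (closed-form MLE) and a
two-component exponential mixture via EM. The mixture likelihood is
multimodal, so EM restarts from 20 quantile-based initializations; each
restart is ranked by a short EM pass on a coarse subsample and the best
is run to convergence (relative log-likelihood tolerance $10^{-8}$, at
most 500 iterations). Components are ordered so $\mu_{lo} < \mu_{hi}$.

Three indices derive from the fits, each isolated behind its own
function so an alternative formula can be swapped in:

* `bistability_index()`: $\mathrm{BiS} = \mathrm{BIC}_1 - \mathrm{BIC}_2$,
  a BIC-based evidence approximation for bimodality. Positive values
  favour two states; the index is unbounded and is 0 (flagged) when the
  mixture collapses.
* `ei_hlp()`: $w_{hi}/w_{lo}$, the occupancy ratio of the high- over the
  low-power mode.
* `ei_hls()`: $\log_{10}(\mu_{hi}/\mu_{lo})$, the separation of the mode
  mean powers.

All three are invariant to positive rescaling of the envelope, which the
tests verify at scale factors 0.1 and 10. Where a fit collapses
(unimodal data), the metric table records the degenerate values
$\mathrm{E/I_{HLP}} = 1$ and $\mathrm{E{+}I_{HLS}} = 0$ — "one state
blurs into the other" — so that missingness in the table remains confined
to the DFA-gated fE/I cells.

### fE/I

Fixed 5-s windows advance with 80% overlap, never crossing segment
joins. Per window $i$: the mean amplitude $wAmp_i$; the amplitude
normalized by $wAmp_i$, integrated into a profile (cumulative sum of
normalized amplitude minus one), linearly detrended, and summarized by
its RMS, $wDNF_i$. Then

$$\mathrm{fE/I} = 1 - \mathrm{corr}(wAmp, wDNF)$$

with Pearson correlation pooled over all windows. Values near 1 indicate
balanced dynamics; above/below 1, excitation/inhibition dominance. The
estimate is only meaningful when LRTC are present, so it is gated on the
DFA exponent: $\alpha \le 0.6$ invalidates the cell (recorded as `NA`
with the reason).

### Lempel-Ziv complexity

The broadband signal (1-45 Hz, zero-phase, per segment) is binarized at
its median — a threshold choice that makes the measure amplitude-robust —
and parsed with the LZ76 exhaustive-history scheme (implemented in C++,
verified exhaustively against a brute-force R parser on all binary
strings up to length 12). The normalized complexity is
$C = c(n)\log_2(n)/n$, approaching 1 for an i.i.d. fair-coin sequence.
Per-channel complexities are averaged.

## Group statistics

For every metric $\times$ band cell, channel-averaged subject values are
compared between groups with the full inferential record:

* Welch's unequal-variance $t$ with Satterthwaite df, and a 95% CI on the
  mean difference from the same SE and df;
* Cohen's $d$ (pooled SD with $n-1$ weights) with the Hedges-Olkin
  large-sample variance $\frac{n_x+n_y}{n_x n_y} + \frac{d^2}{2(n_x+n_y)}$;
* Benjamini-Hochberg FDR, applied within each metric's 13-band family
  (textbook step-up, `p.adjust`);
* a covariate-adjusted robust regression of the metric on group, z-scored
  age, and sex (male = 1): IRLS with Tukey bisquare weights (tuning
  constant 4.685), scale $= \mathrm{MAD}/0.6745$, iterated to relative
  coefficient change $< 10^{-8}$; standard errors use the classical
  M-estimator covariance with Huber's small-sample correction and $t$
  reference with $n-p$ df;
* a Freedman-Lane permutation $p$ for the group coefficient: residuals of
  the reduced (age + sex) model are permuted, added back to the reduced
  fitted values, and the full model refit per permutation; two-sided with
  the add-one estimator $(1 + \#\{|t^*| \ge |t_{obs}|\})/(1 + B)$. Both
  reduced and full models use the robust fit by default (switchable to
  OLS), keeping the scheme internally consistent.

Broadband LZC additionally gets a Mann-Whitney U test and a label-swap
permutation test on the difference of means. fE/I cells drop gated
subjects cell-wise and report per-cell group sizes.

## Classification

Features are the four envelope indices (BiS, E/I_HLP, fE/I, E+I_HLS) over
the ten bands whose upper edge does not exceed 35.2 Hz at display
precision — the mid/high-gamma bins are excluded as muscle-artifact-prone
— plus broadband LZC, age and sex: 43 columns. DFA features are excluded
by default over the segment-length reliability concern and can be
re-enabled (`include_dfa = TRUE`, 53 columns).

The workflow is strictly training-isolated: stratified 70/30 split;
fE/I gaps imputed with training-column means; z-scoring by training
statistics; a 100-point geometric $\lambda$ grid descending four decades
from $\lambda_{\max} = \max_j |x_j^\top(y-\bar y)|/n$; LASSO logistic
path by coordinate descent (glmnet, convergence $10^{-7}$, intercept
unpenalized); $\lambda$ chosen by 10-fold stratified cross-validated
binomial deviance with the 1-SE rule (largest $\lambda$ within one
standard error of the minimum — the simplest model statistically
indistinguishable from the best). Held-out evaluation reports AUC (rank
statistic with tie correction), accuracy, sensitivity and specificity at
probability threshold 0.5, and ROC / precision-recall point lists. A
leakage test verifies that perturbing held-out rows cannot change any
training-derived state.

## The synthetic-data generator

The generator exists so that every claim above is testable. It does not
aim at biophysical realism (no neural-mass model, no volume conduction,
no artifacts); it aims to produce signals whose envelope dynamics have
*known* LRTC, bistability and coupling, which the pipeline must then
recover.

**Carrier.** Each band component is a sinusoid at the band's geometric
centre with random initial phase, multiplied by the programmed envelope.
A stochastic narrowband carrier would contribute its own Rayleigh
envelope fluctuations and confound the programmed dynamics; the pure-tone
carrier keeps the generator's knobs in one-to-one correspondence with the
metrics. The programmed envelope is low-passed at half the band width
before modulation so that modulation sidebands stay inside the band
instead of leaking into neighbouring analysis bands (leakage measurably
diluted implanted effects in adjacent bands before this was added).
Summed band components ride on a spectrally synthesized 1/f background
20 dB below the oscillatory power.

**Profiles.** Three single-purpose envelope profiles:

* *fractional*: lognormal envelope $\exp(\sigma g_H(t))$ driven by
  exact (circulant-embedding) fractional Gaussian noise — steers DFA;
* *bistable*: a two-state continuous-time Markov chain on power levels
  with exponential dwell times and exponentially distributed within-mode
  power (correlation time 0.1 s), giving exactly the bimodal exponential
  mixture the BiS model assumes;
* *coupled*: 10-s blocks whose levels carry LRTC and whose within-block
  lognormal jitter gain is built to have an exact target sample
  correlation $\rho$ with the block level, so fE/I is steered towards
  $1 - \rho\kappa$ (the transmission $\kappa < 1$ reflects window
  misalignment and is symmetric in $\pm\rho$).

**Composite profile (cohorts).** Cohort subjects need all knobs active at
once, which required three departures from naive composition, each driven
by a measured failure: (1) mode switching comes from threshold crossings
of dwell-smoothed fGn($H$) rather than an exponential-clock Markov chain,
so that switching inherits the subject's persistence and DFA remains
steerable while bistability is active (Gaussian subordination of Hermite
rank 1 preserves the long-memory exponent); (2) amplitude-fluctuation
coupling scales the deviations of the *full* log-envelope within 10-s
windows (with the lognormal mean correction $(g^2-1)s^2/2$ so gain cannot
leak into window means), because a separate multiplicative coupled factor
is drowned by switching fluctuations; (3) the baseline dwell time is
0.4 s, the centre of the monotone sensitive range of BiS given the
analysis filter's envelope smoothing.

**Effect maps.** `cohort_spec()` implants group differences per band and
metric axis as standardized effects *on the metric scale*: each axis maps
to one generator knob (H, log dwell, logit occupancy, log separation,
coupling $\rho$) with a between-subject SD, and the requested Cohen's d
is converted to a knob-mean shift through per-axis transmission gains
(0.34, 0.25, 0.35, 1.21, -0.44) calibrated once by simulation at the
baseline parameters and frozen. Transmission varies somewhat across
bands, so realized effects carry roughly 25% calibration uncertainty.
Ages are Normal(47, 16) truncated to 18-80 years; sex is Bernoulli(0.4
male); both distributions are identical across groups so demographic
covariates are non-confounding by construction.

**Determinism.** A master seed spawns per-subject, per-stage child seeds
by stable hashing (`child_seed()`), so any subject is reproducible in
isolation and cohort assembly order is irrelevant.

## Numerical and design choices

* Sampling rate 200 Hz for synthetic cohorts (Nyquist comfortably above
  the 73-Hz band edge); one channel per synthetic subject by default —
  channels are i.i.d. given the subject's parameters, so extra channels
  only average estimator noise.
* EM degenerate inputs (constant power) return the single model with the
  mixture flagged non-identified; `bistability_index()` is then 0.
* The fE/I gate uses $\alpha > 0.6$ strictly; gated cells are `NA` with a
  recorded reason, and group contrasts drop them cell-wise.
* Permutation p-values use the add-one estimator and are therefore never
  exactly zero; the floor is $1/(B+1)$.
* `robust_fit()` falls back to the OLS covariance when the residual scale
  collapses (near-exact fits), and stops weight iteration if the
  redescending weights would zero out more rows than the rank requires.
* Band-limited filtering near Nyquist: bands are rejected when the upper
  edge reaches $f_s/2$, and the generator refuses band signals shorter
  than 10 cycles of $f_{lo}$.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to keep the full run in
the tens of minutes on one CPU while leaving Monte-Carlo margins
comfortable: recovery checks use 278.8-s single-subject equivalents with
10-20 replicates; null calibrations use 200 replicates at $B = 500$
permutations; mixture recovery uses $n = 50{,}000$ power samples; and the
end-to-end cohort uses 100 subjects per group with effects implanted at
$d = 0.8$ on eight metric $\times$ band cells. The acceptance script
recomputes the self-contained quantities (band count; fE/I calibration at
$\rho = 0$ over 20 seeds) from scratch at run time.

## What passing tests do and do not show

The generator produces clean, stationary, single-source oscillations with
exactly the statistical structure the metrics assume. Real EEG adds
volume conduction, non-stationarity, eye/muscle artifacts, channel
covariance and preprocessing residue, none of which are emulated. Passing
the suite therefore demonstrates the *estimators and inference machinery*
are correct and calibrated — not that the metrics separate clinical
groups in real data. DFA at 278.8 s sits at the short end of its own
guidelines (8 independent 30-s windows), which is precisely why the
classifier's default feature set excludes it.
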