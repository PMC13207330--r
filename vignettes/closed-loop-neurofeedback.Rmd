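---
title: "Closed-loop qEEG neurofeedback: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop qEEG neurofeedback: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaloop)
```

## The problem

In mild cognitive impairment (MCI) the resting EEG slows: the individual
alpha peak frequency (i-APF) drifts from the normative 10-12 Hz range down
toward 8-9 Hz, theta power rises relative to alpha, and the aperiodic
(1/f) background steepens. Closed-loop neurofeedback protocols try to
reverse this drift by rewarding the brain whenever a feedback statistic
(a band power or a Theta/Alpha ratio) crosses an adaptive threshold.
`alphaloop` implements the whole loop as testable software: a synthetic
EEG generator with known spectral ground truth, the measurement layer
(Welch spectra, aperiodic/periodic decomposition, i-APF), normative
deviation metrics (the Clinical Deviation Index, CDI), a toy-scale
standardized source localizer (sLORETA), the adaptive Bayesian reward
controller with its 70% operating point, and synaptic plasticity models
that make the simulated subject respond to training.

Everything is driven by explicit seeds, so every session, every program
and every figure is exactly reproducible.

## The spectral model

The generator and the fitter share one parametric form for the one-sided
power spectral density:

$$P(f) = L + k f^{-x} + \sum_i a_i
  \exp\!\left(-\frac{(f - f_i)^2}{2\sigma_i^2}\right)$$

with a white-noise floor $L$ (power units), aperiodic offset $k$ and
exponent $x$ (the 1/f slope), and Gaussian oscillatory peaks
$(f_i, a_i, \sigma_i)$. The printed source form of the aperiodic term is
ambiguous about the sign of the exponent; because $x$ is described as the
1/f *slope* we implement $k f^{-x}$, and we read the leading constant as
an additive noise floor. Time series are synthesized by spectral shaping
of complex Gaussian noise (inverse FFT with random phases), not by
summing sinusoids, so simulated epochs have realistic phase randomness
and the expected Welch spectrum equals the model exactly.

What the generator does *not* emulate: volume-conduction mixing between
channels (channels are drawn independently; the forward model lives in
the source-localization module), ocular/muscle artifacts, line noise,
non-stationarity within an epoch, and cross-frequency coupling. Passing
recovery tests on this generator therefore demonstrates correctness of
the estimators under the stated model, not robustness to artifactual
real-world EEG.

## Measurement layer

* **Welch spectra** — 2 s Hann windows, 50% overlap (0.5 Hz resolution)
  by default. Densities are one-sided, Parseval-consistent, in
  µV²/Hz.
* **Aperiodic fit** — robust log-log regression with iterative masking of
  bins more than 2.5 SD above the running fit (so oscillatory peaks do
  not bias the slope), then an optional nonlinear refinement that adds
  the noise floor $L$ only when BIC clearly favors it (ΔBIC > 2). Fewer
  than 10 usable bins is an error, and an exactly-fitting model stops the
  masking loop (degenerate-input guard).
* **Peak extraction** — greedy Gaussian fits on the flattened spectrum,
  largest residual first, each subtracted before the next; equal maxima
  resolve to the lower frequency (deterministic tie rule); bandwidths are
  constrained to 0.25-4 Hz to keep fits physiological.
* **Joint refinement** (`fit_spectral_model`) — all parameters re-fitted
  simultaneously on log power by Levenberg-Marquardt. The sequential pass
  inherits a small (~0.01 Hz) centre bias from the sloping background
  beneath each peak; the joint fit removes it. Precision validation uses
  this estimator on the channel-pooled spectrum.
* **i-APF** — two rules, both exported: the centre of gravity
  $\sum f \tilde P(f) / \sum \tilde P(f)$ of the flattened spectrum over
  the alpha search band (default 7-13 Hz), which is the "pure" i-APF in
  the sense that the aperiodic background has been removed; and the
  clinical top-3 rule, the mean of the three highest per-channel alpha
  peak frequencies among the posterior nodes O1, O2, Oz, P3, P4, Pz.
  The CoG can optionally be weighted by the MCI-cohort Gaussian prior
  (mean 9.2 Hz, SD 1.2 Hz); the default is unweighted so the estimator
  stays unbiased. Per-channel CoG values are averaged (the alternative -
  CoG of the averaged spectrum - is available by pooling first).
* **Coherence** — band-averaged magnitude-squared coherence from Welch
  cross-spectra; the triple-channel variant averages the three pairwise
  values over C3/C4/Cz.

## Deviation metrics

Observed metrics are standardized against a normative database
($z = (x - \mu)/\sigma$), with the clinical flags: $|z| \le 1.5$
normative, $|z| > 1.5$ target, $|z| > 2.0$ pathological (strict
inequality at 2.0 is the documented tie rule). Two non-equivalent CDI
forms are deliberately kept separate rather than reconciled:

* `cdi_euclidean` — $\sqrt{\sum_i z_i^2}$, a norm over any selection of
  (channel, band, metric) entries, usable per ROI;
* `cdi_percent` — $(f_0 - \mathrm{iAPF})/f_0 \times 100$ with normative
  alpha centre $f_0$ (default 10.25 Hz, a configurable parameter because
  norms are population-dependent). The value is signed: negative when the
  subject's alpha runs faster than the norm. Full precision is retained;
  the two-decimal clinical report form truncates toward zero, the
  convention of the clinical worked example (0.47/10.25 × 100 reported
  as 4.58%).

The spider map is the radar representation of $|z|$ per axis in a stable
axis order; "CDI subtraction" appears as radii shrinking toward the
centre, and $\sqrt{\sum r_i^2}$ equals the Euclidean CDI by construction.

The packaged normative CSV is synthetic (means derived from the package's
healthy spectral model, SD = 30% of mean, two age strata) and exists so
that examples and tests run without clinical data; it must not be used
for any clinical purpose.

## Toy sLORETA

The head model is deliberately minimal: 19 sensors at idealized 10-20
positions on the unit sphere, voxels on an inner shell (radius 0.7) of
the upper hemisphere, and the exact homogeneous-sphere analytic gain for
radial dipoles, $V(\gamma) \propto \sum_{n\ge1}(2n+1) b^{n-1}
P_n(\cos\gamma)$. A single conducting shell (rather than a three-layer
skull/scalp model) keeps the analytic oracle exact while preserving
every property the module is tested for; layered conductivities rescale
gains without changing the geometry of the argmax. Voxels are restricted
to the upper hemisphere because the radial-dipole potential has a
negative far lobe: gains are monotone in angle only on the near side, and
a brain voxel below the sensor cap would be unphysical anyway.

Two estimators are kept distinct on purpose. `inverse_minimum_norm`
solves the smoothness-penalized problem
$\min_J \|V - LJ\|^2 + \alpha\|BJ\|^2$ with $B$ the voxel graph
Laplacian (closed form via the normal equations; pseudoinverse fallback
at $\alpha = 0$; $\alpha$ selected by the L-curve corner when not
given). `sloreta_standardize` implements the classic standardized map:
with $T = L^\top(LL^\top + \alpha I)^{-1}$ and resolution matrix
$R = TL$, scores are $(TV)_j^2 / R_{jj}$. Because $R$ is symmetric
positive semidefinite, Cauchy-Schwarz gives
$R_{jv}^2 \le R_{jj}R_{vv}$, so a noiseless single source at voxel $v$
always attains the maximum at $v$: the zero-localization-error property,
exact and tested for every voxel. The Laplacian-weighted estimator and
the classic standardization are *not* the same operator; conflating them
breaks the exactness proof, which is why standardization recomputes from
the stored data vector rather than rescaling the penalized estimate.
Ties at the maximum resolve to the lowest voxel index and all tied
indices are reported. Average reference is enforced on data and
lead-field columns throughout.

Under pure noise the peak voxel is *approximately* uniform across
voxels; exactly uniform it is not, because voxels weakly correlated with
their neighbours in $R$ are intrinsically favoured. The no-bias test
therefore compares the pipeline's peak distribution against a
first-principles Monte-Carlo null with the model covariance
$LL^\top + \alpha I$, not against strict uniformity.

## The adaptive reward controller

The controller holds the rewarded-epoch fraction at a target
$\rho^\ast$. The clinical default is the 70% rule: the 85% optimum for
healthy learners minus a 15% clinical safety offset
(`operating_point(0.85, 0.15)`), which keeps the reward prediction error
large enough to drive potentiation without exhausting an impaired
subject; `information_gain` quantifies the argument
($H(0.70) > H(0.85)$ bits).

The recursive belief update is deliberately conjugate: a
normal-inverse-gamma posterior on $\log y$ (power ratios are positive
and approximately log-normal, and the conjugate form is closed-form and
fast; the observation model itself is a design choice). After each epoch the
reward threshold is reset to the posterior-predictive (Student-t)
quantile that yields success probability $\rho^\ast$ under the
configured direction — the $\rho^\ast$ quantile when suppressing the
signal, the $(1-\rho^\ast)$ quantile when enhancing. Equality at the
threshold never rewards. The sufficient statistics are discounted by a
forgetting factor (default 0.99, an effective memory of roughly 100
epochs): without forgetting a conjugate recursion adapts to a
distributional step change only at $O(1/n)$ and a static world is
assumed forever; with it, the controller re-converges within a few
hundred epochs while still holding ±3 percentage points on stationary
streams. A distribution-free backend (sliding-window empirical quantile)
is provided as a cross-check; both backends pass the same set-point
tests at 0.70 and 0.85.

Tier assignment maps the BDWS score (posterior-mean success percentage
over the assessment window) to the protocol's training tiers:
[85, 100] high-performance (one continuous 20-30 min block, encoded as
25 min), [75, 85) medium (20 min), below 75 high-intensity training
(5 min active / 5 min rest / 5 min active). The tier bounds overlap
at exactly 75 and 85; boundaries resolve upward. The HRV cross-looping
gate raises the *effective* target by `ease_step` (default 0.05, capped
at 0.9) whenever the autonomic metric drops more than `drop_fraction`
(default 20%) below baseline — easing difficulty under physiological
stress.

## Plasticity models and the digital twin

* **Hopfield attractors** — energy
  $E = -\tfrac12\sum_{ij} w_{ij}s_is_j + \sum_i \theta_i s_i$ (the
  pairwise form $-\sum_{i<j} w_{ij}s_is_j$ coincides at zero
  thresholds; both accessors exist and tests pin their equality).
  Asynchronous updates with $\mathrm{sign}(0) \to +1$ never increase the
  energy; `hebbian_store` averages outer products over patterns (so a
  pattern and its negation store identically); `reinforce_weights` is
  the basin-deepening step, strictly lowering the target's energy. For
  $n \le 16$ a brute-force enumerator provides fixed points and basins
  as an oracle.
* **BCM** — $\dot w = \phi(y, \theta_m)\,x$ with the classic quadratic
  $\phi = y(y - \theta_m)$ (only the sign behaviour is prescribed by the
  plasticity window; the quadratic is the minimal function satisfying it), and the standard
  sliding threshold $\theta_m = \overline{y^2}/y_0$, whose closed loop
  settles at $y^\ast = y_0$.
* **Homeostatic scaling** — $\dot G = \gamma(R_\mathrm{target} - R)$.
* **STDP** — exponential kernel with a hard 40 ms pairing window:
  outside $|\Delta t| < 40$ ms (and at exactly $\Delta t = 0$) the
  weight change is zero; additive over disjoint spike trains.
* **Digital twin** — 76 sigmoidal rate units coupled through a synthetic
  distance-dependent connectome (generated in code, clearly not an
  atlas), Euler-integrated at 1 ms for 2000 ms with coupling strength
  $G = 0.015$ and sigmoid slope scale $d = 0.3$ (a Hill-type gain
  coefficient, implemented as the logistic slope scale, which is what a
  rate-network reading supports). Settling is declared when the mean absolute per-ms
  drift over the final 10% falls below $10^{-3}$ — a drift tolerance
  stands in for a formal stability statistic, and the report says which
  criterion was used.
  Divergence is flagged in the report, never thrown.

## The closed loop

Each 1 s epoch: the virtual subject's current spectral model generates
EEG on the target channels (default C3/C4/Cz, the sensorimotor training
loci); a 30-epoch sliding buffer yields the Welch spectrum; the feedback
signal is the Theta/Alpha ratio (suppress mode) or the 9.78-10.25 Hz
high-precision training-band power (enhance mode); the controller
rewards against its current threshold, then updates; the subject takes a
plasticity step — rewarded epochs move i-APF, alpha/theta amplitudes and
the aperiodic exponent toward normative targets by
`responsiveness × (target − current)`, unrewarded epochs relax toward
baseline at one fifth of that rate. No empirical model of a trainee's
response dynamics exists here; the exponential-approach rule is a
stand-in chosen as the minimal monotone model, and results that depend
on its shape (e.g. trajectory curvature) should not be over-read.
Defaults chosen once: responsiveness 0.002 per rewarded epoch, target
i-APF 10.5 Hz with ceiling 10.5 Hz (the acceleration target named for
recovered subjects), MCI draws from Normal(9.2, 1.2²) truncated to
(7, 12) Hz.

Because consecutive epochs share 29/30 of their buffer, the feedback
series is strongly autocorrelated (correlation time on the order of the
buffer length). The controller still holds the set point in long-run
average — the tests assert ±0.10 over 600 trailing epochs of a static
subject — but the tight ±0.03 set-point guarantee applies to the
controller fed with independent epochs, which is how the acceptance
check runs it.

Longitudinal programs chain sessions with carried-over subject state and
report the per-session endpoint trajectory; the program-level "CDI
subtraction" criterion is median end-of-session CDI% over the last three
sessions below the median over the first three.

## Validation problem sizes

The test suite and acceptance checks use these scales, chosen to make
each property measurable without excess: 120 s single-channel recordings
for the exponent/amplitude recovery grid (4 exponents × 2 amplitudes ×
10 seeds, ≥95% within ±0.15 exponent and ±0.25 Hz centre); a 7200 s
19-channel recording with 16 s Welch windows for the CDI% end-to-end
precision check (a long synthetic integration isolates pipeline bias,
~0.002 Hz estimator SD, from the ±0.005 Hz budget that ±0.05 percentage
points implies); 5000-epoch streams with 2000-epoch trailing windows for
the controller set point; all 60 voxels for zero-localization; 100
random networks (n = 4-10) against brute-force enumeration; 16-session
programs of 120 epochs for the longitudinal trend.

## Known limitations

Single-channel independence at generation time (no leakage, no reference
effects); a toy source space that supports coarse DMN-hub targeting
only; no artifact model, so preprocessing robustness is untested here;
the subject model is a stand-in; tier plans are emitted but sessions do
not yet re-schedule themselves mid-block; no sex stratification in the
normative schema (column reserved); phase-amplitude coupling has no
computable definition in this framework and is deliberately absent.
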