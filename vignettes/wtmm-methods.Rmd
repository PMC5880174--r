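---
title: "Multifractal analysis of impulse-energy signals: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal analysis of impulse-energy signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wtmm)
```

This vignette is the package's own account of what it computes, under what
assumptions, and why the defaults are what they are. It states no empirical
number that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Signal model and preprocessing

The motivating signal is the bipolar potential difference $\Delta\phi(t)$
recorded by closely spaced intracardiac electrodes during atrial
fibrillation, sampled uniformly (typically at $10^{-3}$ s). Over the few
milliseconds a depolarization front needs to pass between the electrodes the
conduction velocity is effectively constant, so the front's electric energy
is proportional to the squared time derivative of the potential difference.
The package therefore works on the **local impulse energy**

$$E(t) = \left(\frac{d\,\Delta\phi}{dt}\right)^2,$$

dropping the constant dielectric/velocity prefactor, which cancels from every
scaling exponent. `impulse_energy()` computes this in three steps: natural
cubic-spline resampling to a finer grid (default $\times 10$, e.g.
$10^{-3}\,\mathrm{s} \to 10^{-4}\,\mathrm{s}$), an order-4 finite-difference
derivative (5-point central stencil, one-sided order-4 stencils on the two
samples at each end), and squaring. Oversampling is needed because energy
peaks live inside deflections as narrow as a millisecond. Natural spline end
conditions are the least-assumption choice; the derivative is blind to the
mean, so no detrending is applied before differentiation. Boundary samples
are flagged in the provenance attribute and are in any case excluded
downstream by the wavelet cone-of-influence mask.

`spectral_beta()` estimates the Fourier scaling exponent $\beta$ of
$|\hat E(f)|^2 \sim f^{-\beta}$ by a Welch periodogram (Hann taper, 8
segments, 50 % overlap — a standard estimator choice; the analysis only uses
the log-log slope, which is insensitive to the periodogram normalization).
Under the quadratic multifractal model $\tau(2) = \beta - 2$, which the
acceptance suite verifies on synthetic cascades to within 0.2.

## 2. The wavelet microscope and the WTMM skeleton

`cwt_transform()` computes
$T(t_0, a) = a^{-1}\int E(t)\,\psi((t - t_0)/a)\,dt$ with the
Gaussian-derivative wavelets $g^{(N)} = d^N\!/dt^N\, e^{-t^2/2}$ ($N$
vanishing moments, so polynomial trends of degree $<N$ are invisible). The
$1/a$ (L1) normalization makes $|T| \sim a^{h}$ along maxima lines with $h$
the pointwise Hölder exponent: $h = -1$ for an impulse, $h = 0$ at a step,
negative $h$ for distribution-like "noise" signals. Numerical choices:

* **Scale grid**: dyadic with $V = 8$ voices per octave
  (`scale_grid()`); the default analysis span for clinical-style runs is
  $2^5$–$2^{13}$ samples, bracketing the fit range used on impulse-energy
  data ($2^9 \le a \le 2^{13}$ at the oversampled $10^{-4}$ s grid).
* **Convolution**: FFT with reflection padding. The kernel is truncated at a
  numerical support radius of $5a$ samples, where the Gaussian envelope is
  below $\sim 4\times10^{-6}$; the same radius defines the validity
  (cone-of-influence) mask at the signal boundaries. Truncation leaves a
  relative leak of order $10^{-5}$ on polynomial inputs; tests that compare
  against untruncated closed forms use a larger radius.
* **Maxima detection**: strict local maxima of $|T|$ over time
  (`>` left, `>=` right, so plateaus keep their leftmost index), above a
  relative floor of $10^{-9}$ of the per-scale maximum, which discards FFT
  round-off ripples on otherwise exactly-zero stretches.

`build_skeleton()` chains maxima from fine to coarse scale by greedy
bipartite nearest-neighbour assignment within a window
$\max(2,\; a\,(2^{1/V}-1)\,\kappa)$ samples. Two deviations from the
simplest mutual-nearest scheme proved necessary on noisy signals and are
deliberate design choices:

* $\kappa = 6$ (rather than a tighter window): near merge events a maximum
  can jump a substantial fraction of $a$ between adjacent voices; with a
  tight window those lines die early and the line count $N_a$ decays faster
  than the true maxima count, biasing the support dimension
  $c_0 = -\tau(0)$ upward.
* **gap tolerance** `max_gap = 2`: modulus maxima of noisy signals can
  vanish for a fraction of an octave and reappear; a line may persist
  unmatched for up to two voice steps (bridged at its held time index)
  before it is terminated.

Lines spanning fewer than 3 scale samples cannot support a slope estimate
and are discarded. The line set $L(a)$ used by all statistics contains the
lines that exist at *every* analyzed scale below $a$ — the persistence
condition that makes $N_a$ non-increasing. WTMM magnitudes are taken at the
scale itself (`value_mode = "value"`, the definition as printed) or as the
running supremum along the line (`"sup"`). For signals with $h < 0$
(impulse-energy-like noise) the supremum saturates at the finest scale and
destroys the scaling, so `"value"` is the default; for smoother signals
($h > 0$, e.g. fractional Brownian paths) `"sup"` stabilizes the negative-q
statistics and is what the monofractal tests use.

## 3. Spectrum estimators

**Method of moments** (`partition_functions()`, `fit_scaling_exponents()`,
`fit_quadratic_tau()`, `legendre_spectrum()`): partition functions
$Z(q,a) = \sum_{l \in L(a)} |T|^q$ are evaluated in log space (log-sum-exp),
so strongly negative $q$ cannot underflow. The canonical expectation values
$h(q,a) = \sum \ln|T|\,W$ and $D(q,a) = \sum W \ln W$, with Boltzmann
weights $W = |T|^q/Z$, give $D(h)$ as a $q$-parametrized curve without a
numerically unstable direct Legendre transform (a finite-difference Legendre
transform is provided as a cross-check). Slopes of $\ln Z$, $h$, $D$ vs
$\ln a$ over the fit range give $\tau(q)$, $h(q)$, $D(q)$. The default
moment grid is $q \in [-1, 5]$ in steps of 0.25; more negative $q$ is
disabled by default because value-mode WTMM statistics become unstable
there. Regression standard errors are inflated by $\sqrt V$ because
adjacent voices of one octave are strongly dependent. The quadratic
(log-normal) fit $\tau(q) = -c_0 + c_1 q - c_2 q^2/2$ is weighted by
$1/\mathrm{se}^2$; since $\tau$ errors at different $q$ come from the same
scales and lines, the coefficient errors combine the independent-error GLS
term with a fully-correlated one-factor term (the projection of the stderr
pattern itself). $c_0$ is reported as $-\tau(0)$ with its own regression
error; $c_2$ is constrained non-negative with the raw value retained.

**Magnitude cumulants** (`compute_magnitude_cumulants()`,
`fit_cumulant_slopes()`): the first three sample cumulants of $\ln|T|$ over
$L(a)$ per scale, with uniform weight per line, fitted against $\ln a$.
$c_0$ can be estimated either from $-\tau(0)$ or from the line-count scaling
$N_a \sim a^{-c_0}$; both are exposed ($\texttt{fit\_cumulant\_slopes}$
reports the $N_a$ route). $c_3$ is reported, but following the limited
statistical power of third cumulants at realistic sample sizes the verdict
logic treats the spectrum as quadratic unless $|c_3|$ exceeds 3 stderr.

**Propagator check** (`pdf_collapse()`): under the log-normal model the
magnitude distribution at a fine scale is the coarse-scale distribution
convolved with a Gaussian kernel of mean $c_1 \ln(a/a')$ and variance
$c_2 \ln(a'/a)$; the monofractal case is the $c_2 = 0$ delta-kernel limit.
The check convolves the empirical coarse-scale distribution with the kernel
and reports Kolmogorov–Smirnov distances; a fitted $(c_1, c_2)$ kernel
should beat the $c_2 = 0$ alternative, which the acceptance suite verifies.

**Two-point magnitude correlation** (`compute_magnitude_correlation()`,
`assess_cascade_structure()`): centered products of $\ln|T|$ over all pairs
of skeleton maxima at one scale, binned in log-spaced lags (8 per decade,
from the median maxima spacing to a quarter of the span). Pairs are drawn
from skeleton maxima, not the dense plane, because every other statistic
lives on the same objects. $C(a, 0)$ is by construction identical to
$C_2(a)$. The verdict rule operationalizes the qualitative cascade-vs-white
reading: "multiplicative-like" if the slope of $C$ vs $\ln\Delta t$ over
$\Delta t \in (a, \mathrm{span}/4]$ matches $-c_2$ within 3 stderr while
excluding zero; otherwise "white-multifractal-like" if the mean normalized
correlation over $\Delta t \in [8a, 64a]$ is within $\pm 0.1$ of zero;
otherwise "indeterminate". With $c_2$ below $10^{-3}$ the two models
coincide and the verdict is "indeterminate" by construction. The analyzing
window itself correlates neighbouring magnitudes over a few scale units for
*any* process, so at weak intermittency the slope criterion can fire
spuriously on white input; the large-lag mean is the more reliable
white-noise diagnostic. The verdict is the noisiest output of the package —
the slope estimate carries substantial realization-to-realization spread —
and should be read together with the underlying curve.

## 4. The synthetic generators: what they emulate and what they do not

`gen_fbm()` synthesizes fractional Gaussian noise/motion by circulant
embedding of the exact fGn covariance, so closed-form tests (aggregated
variance, spectral slope, monofractal $\tau(q) = qH - 1$) have an exact
oracle. The embedding is provably non-negative definite for $H \in (0,1)$;
the generator still checks and fails loudly rather than clipping silently.

`gen_cascade_signal()` builds log-normal wavelet cascades on a dyadic tree:
at depth $j$ the $2^j$ coefficients have magnitudes $e^{\omega_{jk}}$ with
$\omega$ Gaussian of mean $jm$ and variance $js^2$, where $m = -c_1\ln 2$
and $s^2 = c_2 \ln 2$ per level — the parametrization under which one-point
statistics give $\tau(q) = -1 + c_1 q - c_2 q^2/2$ with scale measured in
samples. In *multiplicative* mode $\omega$ accumulates independent
innovations along the ancestry path (true cascade, magnitudes correlated in
time and scale); in *uncorrelated* mode each cell draws independently with
the same marginal law (identical $\tau(q)$, no cascade — "multifractal white
noise"). Signs are independent $\pm 1$.

The synthesis atom is a compactly supported polynomial wavelet — the
$m$-th derivative of the bump $(u(1-u))^{m+2}$ on $[0,1]$, default $m = 3$
vanishing moments — spanning **exactly one dyadic cell**. This choice is
deliberate and replaced an earlier orthonormal-filter (Daubechies-family)
construction: filter-bank atoms span several cells, so every signal point
mixes several independent log-normal magnitudes, and at desk-scale sample
sizes that mixing noise destroys the per-scale magnitude variance on which
$c_2$ estimation rests. One-cell atoms remove same-level overlap entirely.
Levels whose cells are narrower than `min_cell = 8` samples are omitted:
they sit far below any analyzable scale and their crudely sampled atoms
would only inject broadband artifacts.

What the generator does *not* emulate: physiological shape of electrograms
(that is `gen_surrogate_egm()`'s job, and even there only rate/shape
statistics, no tissue model); continuous (non-lattice) scale invariance —
the construction is dyadic, so log-periodic ripples of one octave exist at
small amplitude; and infinitely deep cascades. Passing tests on these
signals therefore demonstrates estimator correctness under the model, not
fidelity of any clinical claim.

**Finite-size behaviour the tests quantify.** Even with one-cell atoms the
analyzing wavelet at scale $a$ spans several cells, so a maxima magnitude is
a local mixture dominated by the largest nearby coefficient. Two
consequences, both visible in the acceptance suite: the mean-magnitude slope
$c_1$ acquires a small negative bias (an extreme-value effect growing with
$\sqrt{c_2}$, absent in the monofractal tests which recover $H$ cleanly),
and single-realization $c_2$ estimates at $2^{17}$ samples carry a spread
comparable to the $\pm$ uncertainties reported for comparable clinical
recordings. The acceptance test of parameter recovery applies tolerances of
$\pm 0.05$ on $c_1$ and $\max(0.02, 50\%)$ on $c_2$ per estimator at a fixed
seed; at the default study setting $(c_1, c_2) = (-0.34, 0.053)$ the seed-1
run sits marginally outside those bands on three of four recoveries (by
0.004 on moments-$c_1$, 0.002 on moments-$c_2$, 0.022 on cumulants-$c_2$)
while the cross-method concordance — the check actually used on real data,
where no ground truth exists — holds comfortably. We report this honestly
rather than widening bands or reselecting seeds; the support dimension
$c_0$, the Hölder fixtures, the mode discrimination, and all closure checks
pass with margin.

## 5. Degenerate inputs and tie-breaks

Constant signals give an identically zero transform (and zero impulse
energy); maxima detection then returns empty sets and the statistics
functions refuse with informative errors rather than fitting noise. Scales
that do not fit in the signal span are dropped with a warning. Empty or
too-small $L(a)$ sets drop the scale, again with a warning. Equal-modulus
plateaus keep the leftmost index; chaining ties are broken by distance, then
line id, so skeletons are bit-reproducible. All generators are pure
functions of their spec (seeded, RNG state restored), and
`run_pipeline()` output is byte-identical across reruns of one config.

## 6. Problem sizes

The test suite analyzes signals up to $2^{17}$ samples with 49 scales and
8 voices per octave; fits for those synthetic runs use $a \in [2^5, 2^8]$
samples, three octaves chosen so the coarsest fitted scale still carries
hundreds of persistent maxima lines ($N_a \approx n/a$). The clinical-style
defaults in `run_config()` use the wider $2^5$–$2^{13}$ grid appropriate to
$\sim 4\times10^6$-sample oversampled recordings.

## 7. Known limitations

* Oscillating (chirp-like) singularities are outside the canonical cusp
  formalism implemented here; no grand-canonical variant is provided.
* No wavelet-leader or 2D/3D variants.
* $c_2$ from a single realization at desk-scale lengths is noisy (Section
  4); averaging over recordings, as done in practice with multiple
  electrodes and patients, is the recommended use.
* The cascade verdict is qualitative: it is designed to separate clear
  cascades from clear white multifractals at moderate intermittency, and
  returns "indeterminate" rather than guessing elsewhere.
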