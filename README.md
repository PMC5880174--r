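# wtmm — multifractal analysis of impulse-energy time series

`wtmm` is an R implementation of wavelet-based multifractal analysis for rough
1D signals, built around the signal class that motivated it: the **local
impulse energy** E(t) = (d&Delta;&phi;/dt)&sup2; of bipolar intracardiac
electrograms recorded during atrial fibrillation. Electro-physiologists (and
anyone analyzing intermittent "1/f"-type noise) can use it to ask two
questions about a signal:

1. **How intermittent is it?** Estimate the multifractal spectrum — the
   scaling exponents &tau;(q) of the partition function and the singularity
   spectrum D(h) — and summarize them by the log-normal coefficients
   (c&#8320;, c&#8321;, c&#8322;).
2. **Is there a cascade underneath?** Test whether the intermittency comes
   with a multiplicative time-scale structure (long-range magnitude
   correlations) or is "multifractal white noise" with the same one-point
   statistics but no correlation across scales.

## The method in brief

The continuous wavelet transform with Gaussian-derivative analyzing wavelets
g^(N) = d&#7475;/dt&#7475; e^(&minus;t&sup2;/2),

T(t&#8320;, a) = (1/a) &int; E(t) &psi;((t &minus; t&#8320;)/a) dt,

behaves as |T| ~ a^h(t&#8320;) at small scale, with h the pointwise Hölder
exponent (h = &minus;1 for an impulse, h = 0 at a step). Local maxima of |T|
chained across scales form the *skeleton*; statistics over the maxima-line
set L(a) give, along two independent routes,

* **method of moments**: Z(q, a) = &Sigma;&#8343; |T|^q ~ a^&tau;(q), with the
  canonical expectation values h(q, a), D(q, a) stabilizing the Legendre
  transform D(h) = min&#8321;[qh &minus; &tau;(q)];
* **magnitude cumulants**: C&#8321;(a) ~ c&#8321; ln a,
  C&#8322;(a) ~ &minus;c&#8322; ln a, C&#8323;(a) ~ c&#8323; ln a, giving
  &tau;(q) = &minus;c&#8320; + c&#8321;q &minus; c&#8322;q&sup2;/2 (+ c&#8323;q&sup3;/6)
  from three linear regressions.

c&#8320; is the fractal dimension of the singularity support, c&#8321; the
typical Hölder exponent, and c&#8322; the intermittency coefficient (zero for
monofractals). The two-point magnitude correlation
C(a, &Delta;t) = &lang;&delta;ln|T(t)| &centerdot; &delta;ln|T(t + &Delta;t)|&rang;
discriminates mechanisms: a multiplicative cascade predicts
C ~ &minus;c&#8322; ln &Delta;t for &Delta;t &gt; a, while uncorrelated
("white") multifractal noise drops to zero.

Because clinical recordings cannot ship with the package, a synthetic module
generates signals with known spectra — exact fractional Gaussian noise
(circulant embedding), log-normal wavelet cascades on a dyadic tree in
*multiplicative* and *uncorrelated* variants, deterministic fixtures, and
surrogate AF electrograms — so every estimator is testable by parameter
recovery.

## Worked example

Generate a multiplicative log-normal cascade with c&#8321; = &minus;0.34,
c&#8322; = 0.053 (the intermittency range typical of impulse-energy
recordings), analyze it with the third-order wavelet, and test for cascade
structure:

```r
library(wtmm)

spec  <- cascade_spec(c1_target = -0.34, c2_target = 0.053, n_octaves = 17,
                      mode = "multiplicative", seed = 1)
noise <- gen_cascade_signal(spec)
plane <- cwt_transform(noise, scale_grid(2^4, 2^10, voices = 8), order = 3)
skel  <- build_skeleton(plane)

ens  <- partition_functions(skel, q = seq(-1, 5, by = 0.25))
fit  <- fit_scaling_exponents(ens, fit_range = c(2^5, 2^8))
fit_quadratic_tau(fit)
#> <quadratic_spectrum> [moments] c0 = 0.986 +- 0.040, c1 = -0.394 +- 0.030, c2 = 0.025 +- 0.022

cum <- compute_magnitude_cumulants(skel)
fit_cumulant_slopes(cum, fit_range = c(2^5, 2^8))
#> <quadratic_spectrum> [cumulants] c0 = 0.986 +- 0.040, c1 = -0.374 +- 0.096, c2 = 0.101 +- 0.160
#>   c3 = 0.1854 +- 0.2873

corr <- compute_magnitude_correlation(skel, which.min(abs(skel$scales - 2^5)))
assess_cascade_structure(corr, c2 = 0.053)
#> <cascade_verdict> multiplicative-like (slope = -0.0443 +- 0.0073, expected -0.0530; mean C_norm[8a,64a] = 0.092)
#>   slope matches -c2 and excludes 0 at 3 stderr
```

Reading the output: the singularity support fills the line (c&#8320; &asymp; 1),
the typical Hölder exponent is negative (a noise-like signal, c&#8321; &asymp;
&minus;0.37 to &minus;0.39 across the two estimators), and both methods see
finite intermittency, though with substantial single-realization spread
around the generator's c&#8322; = 0.053 (see the methods vignette for why
c&#8322; is the hardest coefficient at this sample size). The magnitude
correlation decays logarithmically with the predicted slope &minus;c&#8322;,
so the verdict is "multiplicative-like"; rerunning with
`mode = "uncorrelated"` flips it to "white-multifractal-like" even though
&tau;(q) is unchanged — the package's central diagnostic contrast.

For recorded electrograms, start from `read_signal_trace()` and
`impulse_energy()` (cubic-spline oversampling, order-4 finite-difference
derivative, squaring), or drive everything from one `run_config()` +
`run_pipeline()` + `write_report()` call.

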