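---
title: "Quantifying neural complexity with q-statistics: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neural complexity with q-statistics: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroq)
```

## The model

`neuroq` estimates a scalar complexity index for multichannel EEG-like
signals. The working hypothesis is that the *regularity* of the signal —
summarized by the distribution of waiting times between amplitude
events — carries information about the correlation structure of the
underlying dynamics. For an uncorrelated (purely chaotic) process the
inter-event intervals should follow Boltzmann–Gibbs (BG) statistics, a
stretched-exponential law

$$y_{BG}(x) = a_{BG}\, x^{c}\, e^{-b x^{h}},$$

whereas a system with long-range correlations is described by the
nonextensive generalization, the q-exponential probability function

$$y_q(x) = \frac{a\, x^{c}}{\left[1 + (q-1)\, b\, x^{h}\right]^{1/(q-1)}},$$

whose entropic index $q$ indexes the departure from extensivity:
$q \to 1$ recovers the BG law exactly, and larger $q$ means heavier
power-law tails, i.e. stronger temporal correlation. The two entropy
functionals behind these laws,
$S_{BG} = -k\sum_i p_i \ln p_i$ and
$S_q = \frac{k}{q-1}\left(1 - \sum_i p_i^q\right)$,
are exposed as `entropy_bg()` and `entropy_tsallis()`; $S_q \to S_{BG}$
as $q \to 1$, and the package always routes $q = 1$ through the analytic
limit rather than evaluating a $0/0$ form.

A note on the sign convention: the q-exponential is sometimes written
with a positive exponent $+1/(q-1)$, but that branch grows without bound
and cannot be a probability density. The package implements the decaying
branch (exponent $-1/(q-1)$), which is the one that reduces continuously
to the BG law as $q \to 1^{+}$; the near-1 regime is computed through
`log1p` so the reduction is numerically exact to ~1e-5 already at
$q = 1 + 10^{-9}$.

### Normalization is analytic, never fitted

Both laws are probability densities: their leading constant is slaved to
the shape parameters. Substituting $t = (q-1) b x^{h}$ turns the area
integral into a Beta function, giving

$$a = \frac{h\,[(q-1) b]^{(c+1)/h}}
          {B\!\left(\frac{c+1}{h},\; \frac{1}{q-1} - \frac{c+1}{h}\right)},
\qquad
a_{BG} = \frac{h\, b^{(c+1)/h}}{\Gamma\!\left(\frac{c+1}{h}\right)},$$

valid exactly when $1/(q-1) > (c+1)/h$; outside that region the density
has infinite area and `normalize_qexp()` refuses with an error naming
the violated inequality. This closed form was verified against adaptive
quadrature (|area − 1| < 1e-6 over random parameter draws; the test
suite re-checks it on every run). Slaving $a$ removes one optimizer
dimension and guarantees that every candidate during fitting is a true
density.

## Event extraction

For each channel independently:

1. The **negative part** is the subset of samples strictly below zero
   (not the rectified signal). This makes the threshold well defined for
   zero-mean signals. Channels with fewer than two negative samples are
   unusable and are skipped with a warning.
2. The threshold is $T = \mu_{neg} - n_{sd}\,\sigma_{neg}$ with
   $n_{sd} = 1$ by default. The one-standard-deviation depth targets the
   regime where Gaussian and heavy-tailed statistics diverge — events
   beyond the central bulk are the informative ones. $\sigma$ is the
   population standard deviation (divisor $n$); at recording lengths the
   difference from the sample SD is negligible, but fixing it keeps
   results exactly reproducible.
3. An **event** is a maximal contiguous run of samples strictly below
   $T$, stamped at its first sample (the downward crossing), in ms. The
   run convention means a single 5-sample excursion is one event, not
   five. Stamping the crossing avoids interpolation; the run minimum is
   available via `event_time = "minimum"` for sensitivity analyses.
4. Intervals are successive differences of event times within a channel;
   channel statistics are never pooled at this stage.

No artifact rejection or band filtering is applied — artifact treatment
has not shown a significant influence on fitted q at the histogram
configurations used here — but since `detect_events()` accepts any
`eeg_signal`, callers can pre-filter with their tool of choice.

## The empirical distribution

Intervals are binned into equal-width, left-closed right-open classes on
$[t_{min}, t_{max})$; the canonical configurations are 100, 500 and 1000
classes on [0, 1000) ms, with 500 the default. Probabilities are
relative frequencies among **in-range** intervals; out-of-range
intervals are discarded (never clipped — clipping would pile spurious
mass into the last bin and distort the fitted tail) and reported in
`n_discarded`. Pooled mode concatenates the intervals of all channels
before binning; per-channel mode keeps one distribution per channel.
Both the class count and the range are explicit arguments because the
fitted q is inherently relative to this configuration: comparisons
across studies are only meaningful at matched binning.

## Fitting

`fit_qexp()` minimizes

$$\sum_{j} \left(p_j - w\, y_q(x_j)\right)^2$$

over $(b, c, h, q)$, where $p_j$ is the empirical per-bin probability,
$x_j$ the bin center and $w$ the bin width — least squares on raw
probabilities, taken literally. A log-space loss (`loss = "log"`) is
available to emphasize the tail, but with multinomial counting noise the
sparse tail bins dominate a log loss, so linear remains the default.
Zero-probability bins stay in the loss by default: they penalize mass
misplaced beyond the observed support.

Numerical choices that matter:

- **Parameterization.** The optimizer works in
  $\theta = (\log b,\; c,\; \log h,\; \mathrm{logit}\, s)$ with
  $q = 1 + s\, h/(c+1)$, $s \in (0, 1)$. Every iterate is
  normalizable by construction; no penalty terms are needed.
- **Bounds.** $b \in [10^{-6}, 10]$, $c \in [-0.99, 10]$,
  $h \in [0.1, 5]$; the published worked-example values sit well inside.
  Bounds are configurable, and reported q values should always be read
  relative to them.
- **Multi-start.** The (b, h, q) directions of the loss surface are
  nearly degenerate, so single starts are unreliable. Starts are drawn
  by Latin hypercube over the $\theta$ box (seeded: identical inputs and
  seed give bit-identical results) plus two moment-matched starts from a
  gamma-density approximation of the histogram. Each start runs bounded
  L-BFGS-B; the best solution is polished with a high-precision L-BFGS-B
  pass and a long Nelder–Mead simplex, which handles the degenerate
  directions that finite-difference gradients miss. Default
  `n_starts = 32`; noiseless round trips recover all four parameters to
  ~1e-6 and validation experiments use 8–16 starts for speed.
- **Model comparison.** `compare_models()` fits both laws to identical
  bins and prefers the smaller SSE. Because the q-exponential family
  nests the null at its $q \to 1$ boundary, its SSE cannot be
  meaningfully larger; on BG-generated data the fitted q pins at its
  lower bound and `delta_sse` is numerical noise.

### Quantization alignment

Event times live on the sampling grid, so measured intervals are integer
multiples of $\delta = 1000/f_s$ ms. A histogram bin $[e, e+w)$ of
integer-valued data therefore collects the continuous-law mass of
$[e - \delta/2,\, e + w - \delta/2)$, whose midpoint is the bin center
minus $\delta/2$ — a systematic half-sample misalignment between data
and model abscissa. The fitters accept `center_offset`;
`run_pipeline()` passes $-500/f_s$ ms automatically. At
$f_s = 1000$ Hz and 2 ms bins the correction is worth about 0.03 in
recovered q. For unbinned, unquantized data (e.g. model-implied
distributions) the offset is zero and round trips are exact.

### Truncation bias

The histogram is renormalized over $[0, 1000)$ ms while the fitted model
is the untruncated density — the literal reading of the least-squares
contract. For laws with visible mass beyond the range this leaves a
small, deterministic downward bias in recovered q: at the worked-example
law (1.1% of mass beyond 1000 ms) the bias is about −0.02. It could be
removed by fitting the truncated-renormalized model, but that would
break exactness on model-implied distributions and change what q means
relative to the published configuration, so the convention is kept and
the bias documented instead.

## The surrogate generator

`synthesize_signal()` builds signals whose only structure is the
structure the method consumes: event times are cumulative sums of
intervals drawn from a ground-truth q-exponential law (seeded numerical
inverse-CDF; the CDF grid is power-spaced with $10^5$ points, extended
until the untabulated tail mass is below $10^{-6}$, keeping sampler bias
far below fitting tolerances), and the signal is Gaussian noise
(`noise_sd`, default 1) plus a single-sample pulse (`pulse_amplitude`,
default −50) at each event and a constant baseline of $-\sigma_{noise}$
that keeps the negative part populated at low noise. With
$|A_{pulse}| > 5\sigma_{noise}$ the pulses are provably the only
sub-threshold excursions, so detection recovers the planted times
exactly; single-sample pulses make each excursion one run, matching the
event convention.

The canonical validation conditions (`surrogate_conditions()`) are
20-channel recordings with $10^4$ events per channel at 1000 Hz —
roughly 10–20 minutes of signal, the scale at which the pooled
histogram supports a stable four-parameter fit. Twenty channels pooled
is the montage convention of the whole-head analysis this package
implements, and it matters statistically: the linearized standard
deviation of the least-squares q estimator at $10^4$ intervals alone is
≈ 0.07 (and ≈ 0.04 even for an inverse-variance-weighted variant), so
recovery to ±0.05 is only achievable at the pooled scale of
~$2 \times 10^5$ intervals. The three ground-truth laws are q = 1.10 and
q = 1.22 at the published worked-example shape (b = 0.14, c = 2.24,
h = 1.07), and q = 1.40 at (b = 2·10⁻⁵, c = 1.0, h = 2.4). The last has
its own shape because normalizability caps q at $1 + h/(c+1) = 1.33$
for the worked-example shape; its parameters were chosen for a finite
mean, an EEG-like mean interval (~110 ms) and >99.9% of mass inside the
canonical range, so that truncation bias stays negligible.

What the surrogates deliberately do **not** emulate: oscillatory bands,
1/f background spectra, artifacts, inter-channel correlation, or
nonstationarity. Passing the validation suite therefore demonstrates
that the estimator chain is correct and unbiased under its own model
assumptions — not that real EEG follows a q-exponential interval law,
which is an empirical claim the package can test but not guarantee.

The logistic map `logistic_map()` ($x_{t+1} = r x_t (1 - x_t)$) is
included as the canonical deterministic-chaos exemplar: a fixed point at
$1 - 1/r$ for $r < 3$, period doubling beyond, and full chaos at
$r = 4$, where trajectories separated by $10^{-12}$ diverge to O(1)
within ~45 iterations. The test suite uses it to pin down what "purely
chaotic" means operationally.

## Degenerate inputs and tie-breaks

- Channels without a usable negative part, or with no sub-threshold
  excursion, contribute zero events; wholly unusable channels are
  skipped, warned about, and listed in the report.
- Distributions need ≥ 8 nonzero bins for the 4-parameter fit (≥ 6 for
  the 3-parameter null); fewer is an explicit error, not a silent
  extrapolation.
- An interval exactly at $t_{max}$ is out of range (half-open bins).
- Model preference ties (equal SSE) resolve to the null, so the
  q-exponential is only preferred when it strictly improves the fit.
- `q = 1` in any entropy or density call is routed through the BG limit;
  division by $q - 1$ never occurs at the boundary.

## Problem sizes in the shipped tests

The test suite validates at desk scale: noiseless 500-bin round trips
(20 random laws plus the worked example), 40–100-draw normalization
sweeps, $10^5$-sample sampler checks, and surrogate recoveries at
$10^4$ events × 20 channels with a 50-replicate stochastic version at
the worked-example condition. The full suite runs in a few minutes on a
single CPU; all randomness is seeded.

## Known limitations

- Absolute q values depend on the histogram configuration, the fit
  bounds and the loss; only matched-configuration comparisons are
  meaningful.
- The untruncated-model convention biases q by ≈ −0.02 for laws with
  ~1% of mass beyond the histogram range (see above).
- The EDF writer/reader implements the plain 16-bit variant only (no
  EDF+ annotations, no mixed per-channel rates).
- Per-channel fits at typical single-channel event counts carry
  substantially larger stochastic error than pooled fits; the package
  reports them but pooled mode is the supported inference path.
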