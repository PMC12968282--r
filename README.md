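# neuroq

Quantify the complexity of EEG-like signals with nonextensive (Tsallis)
statistics.

Brain electrical activity is neither periodic clockwork nor white noise:
it shows long-range correlations that classical Boltzmann–Gibbs (BG)
statistics does not capture. `neuroq` implements a complexity index built
on Tsallis q-statistics: negative-going amplitude events are extracted
from each channel, the time intervals between successive events are
collected into an empirical probability distribution, and a four-parameter
q-exponential probability function is fitted to it. The entropic index *q*
of the best fit is the complexity estimate — *q* → 1 indicates dynamics
compatible with an uncorrelated (purely chaotic) process, while *q* > 1
indicates nonextensive, correlated dynamics. The package is aimed at
researchers in computational neuroscience and nonlinear physiology who
want a reproducible, scriptable implementation of this analysis, together
with the synthetic benchmarks needed to validate it.

## The model

Events are amplitude excursions below a per-channel threshold placed one
standard deviation below the mean of the *negative part* of the signal
(both statistics computed over the samples < 0 only). The inter-event
intervals x (ms) are binned into an equal-width histogram — canonically
100, 500 or 1000 classes on [0, 1000) ms — and the per-bin relative
frequencies are fitted by bounded multi-start least squares with the
q-exponential law

    y(x) = a x^c / [1 + (q-1) b x^h]^(1/(q-1))

against the stretched-exponential BG null

    y_BG(x) = a_BG x^c / exp(b x^h),

which the q-exponential family contains as its q → 1 limit. In both
models the normalization a is never a free parameter: it is tied
analytically to (b, c, h, q) through a gamma-function expression,

    a = h [(q-1) b]^((c+1)/h) / B((c+1)/h, 1/(q-1) - (c+1)/h),

so that the density integrates to 1 on [0, ∞). Normalizability requires
1/(q-1) > (c+1)/h, and the fitter keeps every iterate inside that region
by construction.

The package also provides the two entropy functionals behind the theory
(`entropy_bg()`, `entropy_tsallis()`), a logistic-map generator for
chaotic test signals, a seeded q-exponential interval sampler, a surrogate
EEG-like signal synthesizer with planted ground truth, delimited-text and
16-bit EDF signal IO, and a command-line tool (`exec/neuroq`).

## Worked example

Simulate a 20-channel surrogate recording whose inter-event intervals
follow a known q-exponential law (q = 1.22, the published worked-example
parameters), then run the full pipeline:

```r
library(neuroq)

truth <- surrogate_conditions()[["1.22"]]   # b=0.14, c=2.24, h=1.07, q=1.22
sig <- synthesize_signal(truth, n_events = 5000, n_channels = 20, seed = 42)
sig
#> <eeg_signal> 20 channels x 654343 samples @ 1000 Hz (654.343 s)

rep <- run_pipeline(sig, seed = 1)
rep
#> <neuroq_report>
#>   channels: 20 used, 0 skipped; intervals discarded: 1162
#> <model_comparison>  preferred = qexp  delta_sse = 5.268e-05
#>   qexp: q = 1.1927, sse = 1.084e-05
#>   bg:   sse = 6.352e-05

glance(rep$comparison$qexp)
#> # A tibble: 1 × 6
#>   model     q       sse    r2 n_bins_used converged
#>   <chr> <dbl>     <dbl> <dbl>       <int> <lgl>
#> 1 qexp   1.19 0.0000108 0.999         500 TRUE
```

The fitted q of 1.19 recovers the planted 1.22 to within the stochastic
tolerance at this sample size (about 10^5 pooled intervals); the
q-exponential model is preferred over the BG null, whose sum of squared
errors is ~6× larger. `rep$comparison$qexp` supports `tidy()`, `glance()`
and `autoplot()`; `run_pipeline(..., output = "report.json")` writes the
full comparison, per-channel counts, configuration and seed as JSON.

The same pipeline runs from the shell:

```sh
./exec/neuroq simulate -o rec.csv --q 1.22 --events 5000 --channels 20 --seed 42
./exec/neuroq fit -i rec.csv -o report.json
```

Real recordings are read with `read_signal()` (CSV/TSV with a
sampling-rate sidecar, or 16-bit EDF).

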