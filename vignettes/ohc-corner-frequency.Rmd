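---
title: "Identifying the OHC motile low-pass filter from distortion products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying the OHC motile low-pass filter from distortion products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwuisdp)
```

## The model

The package treats the motile pathway of an outer hair cell (OHC) as a
sandwich: a per-frequency complex gain shaping the drive that reaches the
hair bundle (middle-ear and intracochlear transfer), a memoryless
rectifying nonlinearity (bundle transduction), and a first-order low-pass
filter

$$H(f) = \frac{1}{1 + i f/f_c},$$

whose corner $f_c$ is the quantity of interest: it bounds the frequency up
to which motility can follow the stimulus cycle by cycle. The recorded
displacement adds a linear (non-rectified) vibration path and a flat
Gaussian noise floor. None of these stages is observable in isolation; the
analysis identifies the sandwich from the second-order distortion products
(DP2s) that the rectifier unavoidably creates.

For a zwuis stimulus with components at $f_k = n_k f_0$ ($n_k$ distinct
integers, $f_0$ the reciprocal of the analysis window), a quadratic
rectifier produces DP2s at every $f_k \pm f_m$. Three exact consequences
carry the whole analysis:

* **Bilinearity.** The DP2 amplitude is proportional to the product of its
  parents' amplitudes, so in dB $D_{km} = C + L_k + L_m + F(f_{km})$, with
  $L_k$ the effective input levels and $F$ the filter magnitude. Levels and
  filter separate additively and can be solved by linear least squares.
* **Combinatorial deficit.** Cross terms of the squared sum occur twice,
  square terms once: second harmonics sit exactly $20\log_{10} 2 =
  6.02$ dB below mixed DP2s for equal inputs. The package corrects by this
  exact factor (the experimental literature rounds to 6 dB).
* **Phase additivity.** DP2 phases are $\varphi_k \pm \varphi_m$ plus the
  filter phase $-\arctan(f/f_c)/2\pi$; negative-going rectification
  contributes a constant half cycle, which is why the low-frequency phase
  residual pins at 0.5 cycles.

## Stimulus design and the uniqueness rule

`design_zwuis()` draws integer multiples within the requested band by
seeded greedy search with restarts. A candidate is accepted only if, with
the current set, (i) all order-2 combination frequencies remain mutually
distinct and distinct from every primary, and (ii) all order-3 combinations
avoid the primaries. A *strict* mode additionally requires the order-3 set
to be internally distinct and disjoint from the order-2 set.

The default is the relaxed rule, and this is a deliberate design choice.
Unambiguous *DP2* attribution — the only property the analysis consumes —
needs exactly (i) and (ii). The strict rule is a Sidon-set-like condition
whose feasible density collapses quickly: at 12 components in 2–12 kHz with
a 1-Hz base frequency, the ~1300 order-$\le 3$ combination frequencies must
all be distinct within a ~36 000-slot range, and the expected number of
collisions of any candidate set is far above one, so no amount of search
succeeds. Strict mode remains available (and tested) for sparser designs,
e.g. 6 components on a 0.5-Hz base.

Two further conventions: components are placed at the exact band edges
first, so a designed stimulus genuinely spans its nominal band (a
43-component design over 0.4–30 kHz then has a mean adjacent spacing of
$(30000-400)/42 = 704.8$ Hz); and when a characteristic frequency is given,
primaries are capped at CF/2, which keeps both primaries and DP2s in the
fast-traveling-wave regime where distributed-generation interference is
negligible. Interference itself (the second cause of DP2 scatter in vivo)
is *not* modelled — it is avoided by this band limit, which is also why the
synthetic cochlea needs no traveling-wave machinery.

## What the synthetic cochlea does and does not emulate

`simulate_recording()` reproduces the statistical structure the analysis
assumes: coherent multitone drive, an unknown smooth input shaping (flat,
dB/octave tilt, or tabulated), a rectifier of configurable shape and
polarity, the first-order motile filter, a linear path with its own
(possibly different) shaping, and a flat displacement noise floor with
one-sided density 30 pm/√Hz — the measurement floor of in vivo optical
vibrometry. Defaults: 111.6 kHz sampling, 12-s records, corner 2.5 kHz,
negative polarity, quadratic nonlinearity, 60-dB SPL stimuli scaled so
primary displacements are of order 1 nm and low-frequency DP2s a few nm.

The quadratic-plus-linear rectifier is the default because the DP2 analysis
is blind to higher-order structure; half-wave and Boltzmann options exist
to check that the first-order-filter conclusion does not depend on the
rectifier's shape. The in vivo rectifier form is not known, and the
simulator treats it as a free model family. Note that a Boltzmann
(two-state) transfer biased at its symmetric midpoint does not rectify at
all — its default operating point is therefore offset.

The filter is applied analytically in the frequency domain (each DFT bin
multiplied by $H(f)$), not as a time-domain IIR. On coherent records this
realizes the textbook magnitude and phase exactly, bin by bin, with no
start-up transient — a bit-reproducible contract the tests rely on.

What passing tests on this generator show about real data is limited in
three ways: there is no traveling-wave interference (handled only by the
CF/2 rule), no slow physiological drift across presentations (noise is
stationary and white), and the rectifier truly is memoryless. The pipeline
is validated as an *estimator of the model it assumes*; its application to
recordings stands on the model's plausibility, not on these tests.

## Spectral analysis

All spectra are computed at stimulus-locked bins only; off-bin frequencies
are rejected rather than windowed, because leakage from neighbouring
primaries would contaminate DP2 estimates irreparably at these dynamic
ranges. Significance uses Rayleigh phase-stability across $M = 12$ coherent
segments (1-s blocks of a 12-s record; every zwuis component completes an
integer number of cycles per block when the base frequency is $\ge 1$ Hz).
The large-sample approximation $p = \exp(-M R^2)$ is the default; the
finite-$M$ Greenwood–Durand correction is available behind `exact = TRUE`.
At $M = 12$ the approximation is slightly anti-conservative, but its
measured type-I error stays below $1.2\alpha$, which the suite asserts on
$>10^4$ null bins. The default $\alpha = 0.001$ is applied per component
with no multiplicity correction — DP2 significance is reported
per-component in the experimental convention; users scanning many bins
should tighten $\alpha$ accordingly.

## Retrieval, equalization, and the two filter proxies

`fit_bilinear_levels()` solves $D_{km} = C + L_k + L_m + F(f_{km})$ by
weighted least squares over Rayleigh-significant, combinatorially corrected
DP2s, weights proportional to squared segment-phasor SNR. Identifiability
requires two anchors, both stated in every report: $\mathrm{mean}(L_k)$ is
pinned (default: mean stimulus level) and $F = 0$ in the lowest band.

$F$ can be represented two ways. The default *octave-band* proxy
(piecewise-constant offsets) makes no assumption about the filter's shape,
at the cost of letting within-band filter curvature leak a few tenths of a
dB into the $L_k$. The *parametric* mode instead sets $F =
-10\log_{10}(1+(f/f_c)^2)$ and profiles $f_c$ on a log grid, which is exact
when the model holds. The same choice exists for the phase fit, with one
important asymmetry: piecewise-constant phase offsets alias the smooth
filter phase into the per-primary phase estimates strongly enough to bias
the corner of the final joint fit upward, so the pipeline's phase retrieval
defaults to the parametric mode while the level retrieval keeps the
nonparametric bands.

Equalization subtracts the retrieved inequality from the stimulus levels
(unit gain by default, halved automatically if the inequality grows twice
in a row) and renormalizes the mean dB SPL. One noiseless step flattens a
static tilt exactly; with the default noise, the loop reaches the 1-dB
tolerance in one to two adjustments, comfortably inside the experimental
budget of four.

The retrieved input is deliberately *not* the recorded primary motion: a
simulation in the suite gives the linear path a different shaping from the
effective input and checks that the retrieval follows the latter. Recorded
motion is not a proxy for OHC input.

## The joint fit

After the post-hoc correction $D_{km} \leftarrow D_{km} - (L_k - \bar L) -
(L_m - \bar L)$ (phases untouched), `fit_first_order_lpf()` minimizes

$$\sum_i w_i\big[D_i - K + 10\log_{10}(1+(f_i/f_c)^2)\big]^2
 + \sum_i w_i\, s^2 \big[\psi_i + \tfrac{1}{2\pi}\arctan(f_i/f_c)\big]^2$$

over $(f_c, K)$, with $s$ converting cycles to dB-equivalent units. The
experimental papers do not state their magnitude/phase weighting; the
default $s = 40$ dB/cycle (0.025 cycle ≡ 1 dB) is exposed in the
configuration and reported with every fit, and the corner estimate moves by
well under 2 % when $s$ is doubled. The optimization is one-dimensional:
$K$ is profiled analytically, $\log_2 f_c$ is searched on an octave grid
from 0.25 to 16 kHz and refined by `optimize()`; fits need at least four
points spanning 1.5 octaves. The half-cycle polarity offset of the phase
data is detected by trying both offsets and keeping the better objective.
Explained variance is reported twice — jointly on the weighted stacked
residuals and magnitude-only — because the experimental definition is
unstated; on the default synthetic cohort both land in the high 80s to
high 90s of percent. Omitting the post-hoc correction under a declining
input tilt biases the corner downward, as the correction's absence makes
the magnitudes fall faster than the filter alone.

## Problem sizes and numerical conventions

The tests and the acceptance script run the generator at `scale = 0.1`:
1.2-s records (12 segments of 0.1 s, base frequency 10 Hz) instead of the
full 12 s. This preserves every structural property — coherence, segment
counts, the CF/2 band, the noise floor — while the per-bin noise rises only
by $\sqrt{10}$; the chosen gains keep DP2s comfortably above it, and the
full-scale configuration remains the default of `sim_config()` and
`run_config()`. Phase residuals are wrapped to $(-0.5, 0.5]$ with the
boundary mapped positive, so the negative-polarity half-cycle limit has a
stable sign. Ties at the CF/2 boundary are kept (closed boundary). The
equalization loop treats `max_iter = 0` as "measure once, adjust never".

## Known limitations

* No traveling-wave or multi-site interference model; the CF/2 rule is
  assumed sufficient, as it is in the experiments.
* Third-order products are enumerated for design only; they are never
  fitted, and under the default (relaxed) uniqueness rule a DP3 of a
  *foreign* stimulus could in principle land on a DP2 bin. The quadratic
  simulator generates none.
* The Rayleigh p-value is approximate at small $M$; use `exact = TRUE`
  below $M \approx 10$ if calibrated p-values matter.
* Absolute levels are conventional: retrieval fixes the mean effective
  level at the mean stimulus level, so only level *shapes* are physical.
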