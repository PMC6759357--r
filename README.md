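# zwuisdp

Distortion-product system identification of outer-hair-cell (OHC) motility.

## The problem

Outer hair cells amplify sound-evoked vibrations in the cochlea through
voltage-driven somatic length changes (electromotility). Because the cell
membrane acts as an RC circuit, the AC receptor potential — and with it the
motile response — is expected to roll off at 6 dB/octave above a corner
frequency of at most a few kilohertz, far below the characteristic
frequencies (CFs) that basal OHCs are supposed to amplify (the "RC
problem"). Whether motility in the intact, high-frequency cochlea is really
band-limited in this way is a question about a transfer function buried
behind a rectifying nonlinearity, and it can be answered from vibration
recordings alone.

The key observation is that hair-bundle transduction rectifies. A rectifier
driven by a multitone complex produces second-order distortion products
(DP2s) at every sum and difference of its input frequencies, and these DP2s
are carried through whatever filter sits between rectification and the
recorded motile displacement. The DP2 spectrum is therefore a probe of that
filter.

`zwuisdp` implements the full analysis chain as a tested R package plus a
small analysis workflow:

1. **Stimulus design** (`design_zwuis`): *zwuis* multitone complexes whose
   component frequencies are integer multiples `n_k` of a base frequency,
   chosen so that all intermodulation products up to 3rd order are
   unambiguous — every DP2 at `f_k ± f_m` attributes to a unique parent
   pair. An `N`-tone zwuis yields exactly `N²` distinct DP2s.
2. **Synthetic cochlea** (`simulate_recording`): shaped input → memoryless
   rectifier (quadratic, half-wave, or Boltzmann; negative-going by
   default) → first-order low-pass `H(f) = 1/(1 + i f/f_c)` → motile
   displacement, plus a linear vibration path and a flat ~30 pm/√Hz noise
   floor. Ground truth is kept in a ledger for recovery testing.
3. **Coherent spectral analysis** (`component_spectrum`): leakage-free DFT
   at stimulus-locked bins with Rayleigh phase-stability tests
   (`p = exp(-M R²)` over `M` coherent segments).
4. **DP2 catalogue and corrections** (`measure_dp2`,
   `correct_combinatorial`, `predict_phase`, `apply_band_limit`): parent
   attribution, the exact `20·log10(2)` second-harmonic ("combinatorial")
   correction, phase predictions `φ_k ± φ_m` (+½ cycle for negative
   polarity), and the CF/2 band limit that avoids traveling-wave
   interference.
5. **Effective-input retrieval** (`fit_bilinear_levels`,
   `fit_primary_phases`, `run_equalization_loop`): DP2 amplitudes are
   bilinear in their parents, so in dB
   `D_km = C + L_k + L_m + F(f_km)`; weighted least squares retrieves the
   per-primary effective levels `L_k` (and phases), and an iterated
   stimulus adjustment equalizes the input actually reaching the OHCs.
6. **Corner-frequency estimation** (`posthoc_input_correction`,
   `fit_first_order_lpf`, `corner_vs_cf_report`): after correcting residual
   input inequality, a first-order low-pass filter is fitted jointly to DP2
   magnitudes and phase residuals, yielding the motile corner frequency
   `f_c`, its gain, the rectifier polarity offset, and the explained
   variance.

## Worked example

```r
library(zwuisdp)

cfg <- run_config(seed = 1, scale = 0.1)  # 1.2-s records, 12-tone stimulus
rep <- run_all(cfg)
print(rep)
```

```
closed-loop OHC corner-frequency pipeline
  fitted corner 2554 Hz (truth 2500 Hz), EV 92.4%
  2.65 octaves below the 16-kHz CF
equalization loop: 2 measurement(s), converged (tol 1 dB)
  input inequality (dB): 14.58 -> 0.94 
  DP2 scatter (dB):      7.50 -> 1.35 
```

Reading the output: the synthetic cochlea hid a 2.5-kHz motile corner
behind a −4 dB/octave input shaping. One equalization step flattened the
effective OHC input from 14.6 dB of inequality to under 1 dB, collapsing
the within-band DP2 scatter from 7.5 to 1.4 dB; the joint magnitude/phase
fit then recovered the corner to within 2 % with 92 % explained variance,
placing it 2.65 octaves below the site's CF — the band-limited,
envelope-detector regime rather than cycle-by-cycle amplification.

The numbered scripts under `analysis/` run the same machinery as a
narrative: stimulus design (43-tone broad-band complex, 0.4–30 kHz, mean
spacing 704.8 Hz), the two-tone rectification demo, the scatter
corrections (6.0206-dB harmonic deficit; bilinear doubling of input
inequality), the equalization loop, and a five-cochlea cohort whose fitted
corners come out 2.7 ± 0.1 octaves below CF with explained variances of
86–98 %. Each writes its tables under `results/`.

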