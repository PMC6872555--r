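# mwibeam

Radar-based microwave breast imaging reconstruction in R: rotation-subtraction
skin-artifact removal, confocal delay-and-sum (DAS) and
delay-multiply-and-sum (DMAS) beamforming, and an **iteratively corrected
DMAS (IC-DMAS)** refinement, together with a synthetic multistatic
S-parameter simulator that stands in for the antenna-array/VNA hardware so
the whole chain runs at desk scale.

## The problem

Microwave imaging probes the breast with an ultra-wideband radar signal
(here 2.7–8.0 GHz) from a cylindrical array of interleaved transmit/receive
antennas that rotates around the target. Malignant tissue has a strong
dielectric contrast to fat, so a tumor backscatters energy that a confocal
beamformer can focus voxel by voxel. Two obstacles dominate: the air–skin
reflection is orders of magnitude stronger than any tumor response, and the
average dielectric constant of the interior is unknown, so geometric delays
computed for the assumed background are slightly too short. This package
implements a processing chain addressing both, for researchers prototyping
reconstruction algorithms against controlled synthetic scenes.

## The method

Acquisition yields a complex S-parameter cube `S(f, tx, rx, φ)` over
frequency, transmit antenna, receive antenna and rotation position.

1. **Rotation subtraction.** The rotation positions are split into odd
   ("original") and even ("offset") sets and differenced,
   `S_sub = S_odd − S_even`. Reflections that are invariant under rotation —
   the skin interface — cancel exactly; localized scatterers persist.
2. **Time conversion.** Each channel is converted to a time signal
   `Γ(t, tx, rx, φ_odd)` by a band-limited inverse Fourier transform
   (Hann window, 4× oversampling by default).
3. **Delay tables.** For every voxel `i` the round-trip delay is
   `τ(i, tx, rx, φ_odd) = √ε_b (P_Tx→i + P_i→Rx) / c` with `ε_b` the assumed
   background permittivity (air by default).
4. **Beamforming.** DAS integrates the squared coherent sum of the aligned
   signals; DMAS integrates the sum over all unordered distinct channel
   pairs of products of aligned signals,
   `ϒ(i) = ∫ Σ_{k<k'} x_k(t) x_k'(t) dt`, rewarding inter-channel coherence.
5. **Iterative correction (IC-DMAS).** A bright voxel suggests dense, slow
   tissue, i.e. an underestimated delay. Each iteration smooths the map with
   an inverse-distance kernel `w ∝ 1/(1 + p(i,j))`, converts the normalized
   smoothed intensity into extra delay `τ' = τ + s·ϒ̂'(i)/c` (a configurable
   path length `s` per unit intensity), re-beamforms, and stops when the L1
   distance between consecutive peak-normalized maps falls below `10⁻⁵`
   (at most 7 iterations).
6. **Metrics.** Image quality is summarized by the signal-to-mean ratio
   `SMR = 10 log₁₀(tumor energy / mean energy)` in dB (peak or region-mean
   variant) and by localization error against ground truth.

A small side module provides the closed-form LC circuit model of the
metasurface unit cell used by the hardware antennas: `f = 1/(π√(LC))`,
the split capacitance `C = ε₀ε_r A/d`, and the microstrip inductance with
substrate correction factor `K_g`.

## Worked example

```r
library(mwibeam)

ph   <- make_phantom("B", seed = 1)          # one tumor at (10, 0, 0) mm
geom <- build_cylindrical_array(4, 4, 0.1, 50, 7.2)
ds   <- simulate_scatter_dataset(ph, geom, default_freqs(101))
rec  <- reconstruct(ds, algorithm = "icdmas")
summary(rec, true_positions = c(0.010, 0, 0))
```

```
ICDMAS reconstruction over 1681 voxels
  intensity range [-2.03e-09, 3.81e-07], argmax at (0.010, 0.008, 0.000) m
  4 iteration(s), final E = 2.85e-07
  SMR: 9.491 dB (peak), 4.550 dB (region mean)
  localization errors (mm): 8.00; missed: 0
```

The loop converged in 4 of the 7 allowed iterations (E history 4.56 →
0.0153 → 6.45e-05 → 2.85e-07). The argmax sits 8 mm from the true tumor —
the cross-range blob width of this reduced 4×4 aperture — and the same
phantom reconstructed with plain `algorithm = "dmas"` gives 9.288 dB peak
SMR, so the iterative correction buys ~0.13 dB here. `plot(rec)` displays
the map; `run_pipeline()` runs simulate → preprocess → DAS/DMAS/IC-DMAS →
metrics end to end and writes plain-text datasets, images, PGM rasters and
a JSON summary. A command-line interface with the same stages is in
`inst/cli/mwibeam.R`.

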