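---
title: "Methods: confocal radar reconstruction and the iteratively corrected DMAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confocal radar reconstruction and the iteratively corrected DMAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A cylindrical array of `n_tx` transmit and `n_rx` receive antennas,
interleaved at half the transmit spacing, rotates in `n_phi` steps of
`phi_step` degrees around the imaging domain (the full product must be one
turn, and `n_phi` must be even because the skin-removal step pairs
consecutive positions). The instrument records the complex scattering
parameters `S(f, tx, rx, φ)` on a uniform frequency grid.

The package replaces the hardware with a scalar point-scatterer forward
model of Born type: each scatterer contributes
`ρ/d · exp(−i 2π f τ)` per channel, with `d` the two-way geometric path,
`τ = √ε · d/c` the propagation delay through a homogeneous effective medium
of relative permittivity `ε`, and `1/d` the free-space spreading of the
Green-function magnitude. The skin is not traced as a physical ring;
it enters as an additive term that is *identical across rotation
positions* — this is precisely the class of signal that rotation
subtraction is built to cancel, so the emulation is faithful to the
premise of the method rather than to skin electromagnetics. Noise is
i.i.d. circularly symmetric complex Gaussian per sample, driven by one
seed. Multiple scattering, dispersion of the propagation phase, antenna
transfer functions and mutual coupling are deliberately outside the model:
the reconstruction assumes geometric delays and nothing else, so this is
the smallest forward model that exercises every step of the chain.
A tissue-style complex permittivity helper
`ε(f) = ε_r + iσ/(ωε₀)` is provided for dielectric parameterization.

# Reconstruction chain

**Rotation subtraction.** `S_odd − S_even`, pairing rotation `2k−1` with
`2k`. The equation is a plain elementwise difference; rotation-invariant
content cancels exactly (the synthetic skin term cancels to machine zero,
which the tests assert). The residual is treated as data acquired at the
odd positions.

**Time conversion.** The band (2.7–8.0 GHz by default) is synthesized at
its true position on the frequency axis by a direct shifted-DFT: the band
start is generally not commensurate with the frequency spacing, so placing
it on a zero-based DFT grid would misplace every delay. The record spans
`1/Δf` seconds at `dt = 1/(pad · N_f · Δf)`; `pad = 4` oversamples the
carrier so that fractional-sample interpolation in the beamformer is
accurate. The default Hann window suppresses band-edge sidelobes that
otherwise leak into the DMAS clutter floor. The beamformer input `Γ` is the
*real part* of the analytic signal — the pairwise products of the DMAS sum
are signed quantities — and the envelope is applied only for display.
The time origin is placed at minus one eighth of the record so that a
focal echo sits mid-record with margin on both sides; delay corrections
(which only ever lengthen delays) can therefore never push an echo off the
sampled support. Energy conservation (a Parseval identity) holds exactly
for the analytic signal and is asserted there; for the retained real part
it holds only up to the usual analytic-signal cross term.

**Alignment convention.** "Delaying" a channel means advancing it:
`x_k(t) = Γ_k(t + τ_k(i))`, so the echo hypothesized at voxel `i` lands at
`t = 0` in every channel. Out-of-record samples are zero and fractional
shifts use linear interpolation (an integer shift reduces to exact index
slicing, which the tests check).

**DAS / DMAS.** DAS integrates the squared coherent sum. DMAS sums the
products over *all unordered distinct pairs* of the flattened channel set
`{(tx, rx, φ_odd)}`, computed through the identity
`Σ_{k<k'} x_k x_k' = ((Σ_k x_k)² − Σ_k x_k²)/2`. The printed triangular
index ranges of the original summation omit some cross terms if read
literally; the unordered-pair reading is the standard DMAS construction and
is the one that satisfies the identity above, which makes it the testable
contract. Both readings are implemented (`pairs = "literal"` keeps the
printed ranges) and an explicit O(K²) enumeration serves as the oracle in
the test suite. Negative map values are preserved — only display and the
energy metrics clamp at zero.

**Focal gating.** The operations integrate over the full record by
default, but the high-level `reconstruct()` and the pipeline use a focal
gate of half-width one inverse bandwidth around `t = 0`. The gate is what
gives the iterative correction leverage: the correction adds the *same*
extra delay to every channel of a voxel, and a common shift merely
translates the product integrand in time — over an unbounded record the
integral is invariant and the correction would be exactly inert. Restricted
to a fixed focal window, sampling later genuinely re-centres an echo that
arrives late relative to the assumed background delay. Gating the focal
pulse is standard confocal practice; the width equals the band-limited
pulse main lobe.

**Iterative correction.** Bright voxels indicate dense, slow tissue whose
true delay exceeds the geometric estimate. Each iteration:

1. smooths the previous map with the row-normalized inverse-distance
   kernel `w(i,j) ∝ 1/(1 + p(i,j))`, with inter-voxel distance measured in
   grid-spacing units so the unit offset is dimensionless. Smoothing keeps
   the correction insensitive to voxel-level noise; on a uniform map it is
   the identity and it always contracts the range;
2. clamps the smoothed map at zero, normalizes it to peak one, and adds
   `path_scale · ϒ̂'(i)/c` to every delay of voxel `i`, *always starting
   from the original geometric table* — corrections parameterize a state,
   they do not compound;
3. re-beamforms and evaluates `E = Σ_i |ϒ̂ⁿ(i) − ϒ̂ⁿ⁻¹(i)|` on
   peak-normalized maps. Raw intensities are scale-dependent (they carry
   the squared signal amplitude), so normalization is what makes the
   printed threshold `10⁻⁵` meaningful across inputs. The printed form of
   the criterion has an unclosed absolute-value bar; it is read as an L1
   norm. The loop stops at `E < threshold` or `max_iter = 7`.

The raw intensity-to-delay conversion needs a dimensional repair: an
intensity divided by `c` is not a time unless it carries length units.
The repair keeps the structure (more intensity → longer assumed path) and
makes the units explicit: the normalized intensity is scaled by
`path_scale` meters. The default is 0.003 m, the two-way excess path
`(√1.03 − 1) × 0.2 m` produced by the ~1.5% effective slow-down that the
preset phantoms emulate over a typical round trip — i.e. the correction is
sized to the miscalibration it is meant to compensate. With
`path_scale = 0`, the loop is the identity on the DMAS map and terminates
after one iteration with `E = 0` (a tested fixed point).

# Study conditions of the synthetic presets

The presets define the package's reference scenes and were fixed once:

* array radius 0.1 m (comfortably enclosing a breast-sized target;
  the source system does not state its radius), antennas and imaging slice
  at `z = 0`;
* desk-scale acquisition: 4 Tx × 4 Rx antennas, 50 rotation positions at
  7.2°, 101 frequency points over 2.7–8.0 GHz. The rotation step is kept at
  the instrument's 7.2° rather than being widened when the acquisition is
  scaled down: rotation subtraction turns every scatterer into a
  main + antiphase-ghost pair displaced by the rotation step. At 7.2° the
  ghost offset (~1.3 mm for a tumor 10 mm off axis) is far below the
  resolution cell and merges into the main blob; a widened step resolves
  the pair and its interference lobes dominate the image. The antenna count
  is halved instead, which costs aperture (wider cross-range blob) but
  keeps the image topology faithful;
* imaging grid: 2D slice, 80 mm square, 2 mm spacing (1681 voxels) —
  matching the planar result maps of such systems; a 3D grid is available;
* skin ring at 0.05 m with reflectivity 100 versus tumor reflectivity 1
  (the "orders of magnitude stronger in power" regime; the exact ratio is
  unstated in the source and 100:1 in amplitude is the package's choice);
* both preset-C tumors share reflectivity 1, as phantom inserts are made
  from the same tumor-mimicking material;
* propagation permittivity 1.03 in the phantom versus ε_b = 1 (air)
  assumed by the reconstruction. This deliberate mismatch emulates the
  under-estimated average dielectric constant that motivates the iterative
  correction; it is mild enough that the uncorrected beamformers still
  localize, and `path_scale` is matched to it (above);
* preset B is noiseless (parameter recovery is then deterministic);
  preset C adds complex Gaussian noise with σ = 0.5, about 10% of a tumor
  channel amplitude — moderate noise for a two-object detection scene.

What passing tests on these scenes demonstrate: exact skin cancellation,
correct geometric focusing, stable two-object detection, and a strictly
positive SMR benefit of the iterative correction under a known, mild
dielectric miscalibration. What they do not demonstrate: performance under
real skin refraction, tissue heterogeneity and dispersion, antenna
patterns, or mutual coupling — none of which the forward model contains.

# Numerical choices and degenerate inputs

* Delay tables are exact Euclidean computations; a vectorized table equals
  a scalar loop to a few ulp (tested at 1e-14 relative).
* Rotation indices wrap periodically (a full turn reproduces positions
  bit-exactly); indices below one are an error.
* `sample_delayed` rejects negative delays; out-of-record samples are zero.
* A zero or empty map: smoothing and normalization pass it through,
  `correct_delays` leaves delays untouched, the SMR is an explicit
  undefined-metric error, and peak detection reports an error rather than
  inventing maxima.
* Peak detection suppresses a disk of two grid spacings (configurable)
  around each accepted peak to avoid double-counting halo structure, and
  matches detections to truths greedily by global nearest distance; truths
  without a detection are *missed detections*, not exceptions.
* Text formats store full `%.17g` precision, so round trips are
  bit-exact; readers validate the format version, the full-turn rotation
  consistency, and complete duplicate-free index coverage, and report the
  first offending record.
* The convergence metric and all map comparisons are tolerance-based
  except where exactness is by construction (skin cancellation,
  √ε scaling, fixed points), which is asserted exactly.

# Problem sizes

The reference runs (tests and the acceptance script) use the preset scenes
at 101 frequency points and 1681 voxels; a full reconstruction with seven
allowed correction iterations completes in a few seconds. The oracle
comparisons (pair enumeration versus the fast DMAS form) run at up to 20
channels and 64 time samples, where the O(K²) enumeration is cheap. These
sizes are the package's reference configuration; all of them scale up
through the configuration file.

# Known limitations

* The forward model is scalar and single-scattering; claims about multiple
  reflections ("ghosting", "halo") can only be studied qualitatively here.
* The iterative correction is a heuristic recalibration, not a dielectric
  inversion: it cannot recover differential (channel-dependent) delay
  errors, only the common per-voxel component within the focal gate.
* With the reduced 4×4 aperture the cross-range blob width is ~8 mm at the
  2 mm grid, which bounds the achievable localization error of all three
  beamformers on the preset scenes.
* The CLI persists datasets and images only; the intermediate time-domain
  cube is recomputed on demand rather than serialized.
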