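---
title: "Coded-excitation air-coupled ultrasonic inspection of wood: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coded-excitation air-coupled ultrasonic inspection of wood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golayscan)
```

## The measurement problem

Air-coupled through-transmission ultrasound inspects a board without
couplant: a transmitter above the board, a receiver below, and the decoded
peak voltage at each scan point as the imaging feature. The obstacle is the
air/wood impedance mismatch. With characteristic impedances of roughly
400 Rayls for air and 1,600,000 Rayls for wood, the normal-incidence
pressure reflection coefficient

$$ r = \frac{Z_2 - Z_1}{Z_2 + Z_1} \approx 0.9995 $$

means that virtually all incident pressure reflects at each face; the
two-interface amplitude product $t_{aw}\,t_{wa} = 4 Z_1 Z_2/(Z_1+Z_2)^2$
is about $10^{-3}$. The transmitted signal is tiny and buried in noise, and
simply driving harder saturates the transducer's voltage rating.

Coded excitation attacks this with energy in time rather than amplitude: a
Golay complementary pair $A, B$ of length $N$ is transmitted as two phase
coded shots, each received trace is correlated with the matched filter
(time-reversed replica) of its own code, and the two outputs are summed.
The complementary property

$$ A(n) \star A(-n) + B(n) \star B(-n) = 2N\,\delta(n) $$

guarantees a single main lobe of height $2N$ (16 for the eight-bit pair)
with *exactly* zero sidelobes — not merely low ones, as with a Barker code —
and the cancellation survives any linear time-invariant channel, because
convolution commutes with the summation. Pulse compression therefore buys
$10\log_{10}(2N) \approx 12$ dB of peak SNR for the eight-bit pair without
raising the drive voltage, while keeping the axial resolution of a single
chip.

## The simulation chain

Because the physical scanner is not part of the package, every stage of the
bench is modeled so the full pipeline runs end to end on a virtual board:

1. **Codes** (`golay_pair()`, `barker7()`, `burst()`) — exact integer
   arithmetic; the pair is built by the append recursion
   $A' = A\|B,\; B' = A\|(-B)$ from $A=B=(1)$.
2. **Modulation** (`modulate_square_carrier()`, `modulate_wide_pulse()`) —
   chips become signed square-carrier cycles (or baseband wide pulses);
   chip boundaries align with carrier zero crossings, a $-1$ chip is a
   180° phase flip.
3. **Channel** (`simulate_received()`) — per scan point, one independent
   vertical ray: transmit transducer resonance, time-of-flight delay,
   amplitude scaling by the local through-transmission gain, receive
   transducer resonance, additive sensor-referred Gaussian noise, then the
   receiver chain (DC block, gain, 75 kHz / 14 kHz band-pass).
4. **Compression** (`golay_decode()`) — matched filtering per shot,
   complementary summation, envelope peak read-out.
5. **Scan** (`run_cscan()`, `classify_image()`, `coincidence()`) — raster
   the board, classify each point's peak voltage as knot / sound / pit,
   score the detected defect map against ground truth.

### Interface and defect physics

The local through-transmission amplitude gain at a point multiplies the
pressure transmission coefficients at entry and exit faces (using the local
impedance), power-law attenuation over the local wood thickness, the fixed
air-path attenuation, and any scattering loss:

* A **knot** is denser and irregular: impedance multiplier (default ×2) and
  an extra scattering loss (default 6 dB). Both push the transmitted peak
  *down* — knots image dark.
* A **pit** thins the board (default residual thickness fraction 0.6 for
  the reference board): less wood in the path, less attenuation, a *higher*
  peak — pits image light.

### Parameter choices where the bench leaves them open

* **Wood attenuation: 600 dB/m at 75 kHz, exponent 1.** Softwood across
  the grain at these frequencies is very lossy; 600 dB/m makes a 1 cm
  board cost 6 dB, and — the decisive consistency check — reproduces the
  observed pit/sound peak-voltage ratio on real pine
  (≈ 0.85 V / 0.64 V ≈ 1.32 ≈ 2.3 dB over the 4 mm of wood a pit removes).
* **Wood sound speed 1500 m/s**, air 343 m/s; the speeds only set arrival
  times, not amplitudes.
* **Transducer model: two-pole resonator, Q = 10, 75 kHz.** Gives the
  ring-down that motivates pulse cancelation; ring-down time scales with Q.
* **Receiver band-pass: second-order Butterworth section with geometric
  band edges about 75 kHz, 14 kHz apart**, so the designed −3 dB bandwidth
  equals the hardware specification by construction (the measured value on
  a fine frequency grid is the package's own check). A quality factor
  derived from these numbers would be $75/14 \approx 5.4$; a nominal
  "Q ≈ 2.7" is inconsistent with that bandwidth and the bandwidth figure
  governs here.
* **Air gaps 10 cm per side**, air absorption 2.6 dB/m at 75 kHz with a
  quadratic frequency law (small: ≈ 0.5 dB for both gaps).

### Chips must fit the system bandwidth

The default modulation uses **8 carrier cycles per chip** (chip period
107 µs). This is a deliberate bandwidth-matching rule, and the one place
where the package departs from the one-cycle-per-chip drive sketched for
wideband bench electronics. A binary phase code imposes its structure in a
bandwidth of roughly $1/T_{chip}$ around the carrier. The receiver passes
14 kHz; the transducers, as Q = 10 resonators, about 7.5 kHz each. At one
cycle per chip the chip rate equals the 75 kHz carrier, so nearly all code
energy falls outside the chain: the decoded main lobe smears to many chip
periods, the Barker code's ±1 sidelobes blur destructively into its main
lobe, and — most misleading of all — an uncoded on-carrier burst, whose
line spectrum sits entirely inside the passband, *beats* every coded method
in peak SNR because the narrowband chain integrates it coherently. With
eight-cycle chips the chip bandwidth (≈ 9 kHz) fits inside the receiver
band, the code survives the chain, and the time-bandwidth advantage of
coding is real rather than notional. One-cycle chips remain fully
supported (`modulation_spec(cycles_per_chip = 1)`) for modeling wideband
chains.

### Noise model and seeding

Noise is Gaussian, sensor-referred (added after the receive transducer,
before the receiver filter), with sigma in volts. "20 dB SNR" bench
conditions are realized by `calibrate_noise()`: a noiseless probe shot at a
sound point fixes the peak pre-filter signal amplitude, and sigma is set
20 dB below it. Every scan point draws its own stream from
`base_seed + n_shots * point_index` (row-major), so results are identical
for serpentine and raster traversal and bit-reproducible for a given base
seed.

## Classification and scoring

Thresholds are calibrated from sound-region peaks:
`knot_max = mean − k·35·sd`, `pit_min = mean + k·15·sd`. The asymmetric
scale factors place the bounds where a practitioner would draw them on
bench data whose sound-point scatter is about 1% of the mean — the knot
bound near 60% of the sound level and the pit bound near 115% — and the
same rule then transfers to simulated scans, whose scatter is set by the
noise model rather than by wood variability. With zero scatter the bounds
fall back to ±20% of the mean. Overlap against ground truth is reported
both truth-normalized (|detected ∩ truth| / |truth|, the headline
"coincidence") and as the Dice coefficient; the truth-normalized figure is
the one quoted, since the denominator convention of a "coincidence area"
is otherwise ambiguous.

## The reference board and the study conditions

`reference_specimen()` is the deterministic 6 cm × 6 cm, 1 cm thick
virtual pine board used by the validation runs: a circular knot (radius
8 mm, ×2 impedance, 6 dB scatter) at (1.8, 1.8) cm and a circular pit
(radius 6 mm, thickness fraction 0.6) at (4.2, 4.2) cm. Scans run at 1 mm
interval (61 × 61 points, inclusive endpoints) and 20 dB pre-filter SNR.
`reference_specimen(thick = TRUE)` is the penetration-limit case: the same
defect layout on a 1.5 cm board of denser, lossier pine (1000 dB/m at
75 kHz, i.e. 15 dB through the board against 6 dB for the reference),
probed with the *same instrument noise in volts* as the reference
condition — attenuation rises, the noise floor does not move. The value
1000 dB/m was chosen from the link budget so the thick board sits between
the collapse point of uncompressed envelope read-out and the margin of the
coded chain, which is precisely the regime the method comparison exists to
expose.

In `compare_excitations()` the uncoded baselines (eight-cycle burst, and
the burst-plus-antiphase-cancelation drive) are read out as the received
envelope peak: with no code transmitted there is nothing to compress.
Coded methods are matched-filtered. All methods share per-point seeds and
the same absolute noise sigma.

## What the generator does and does not emulate

The virtual board reproduces: interface transmission loss from impedance
mismatch, thickness- and frequency-dependent attenuation, transducer
resonance and ring-down, the receiver passband, sensor noise, and
defect-induced amplitude contrast with the correct sign and approximate
magnitude. It deliberately omits: diffraction and finite beam width (each
point is an independent ray, so defect edges are unrealistically sharp),
in-board reverberation between the faces (single-transit composition),
grain anisotropy and moisture gradients, surface roughness (the
front/back-face difference seen on real boards), and any time-variant or
nonlinear behavior. Passing tests therefore demonstrate that the decoding,
calibration and scoring logic is correct under the declared physics — not
that a physical scanner will reach the same overlap on real pine, where
beam width and material variability blur exactly the defect edges this
model keeps sharp.

## Numerical choices

* Correlation is exact direct convolution for small problems (all
  code-domain identities are integer-exact) and FFT-based with composite
  padding above $nm = 2^{18}$.
* Envelopes use the FFT analytic signal, zero-padded to a fast length.
* Peak ties break to the earliest lag; main-lobe width is FWHM with linear
  interpolation at the half-maximum crossings; all dB figures are
  $20\log_{10}$ on amplitudes.
* Degenerate inputs are defined, not errors, where a convention is
  natural: a constant feature grid renders mid-gray; zero noise makes the
  simulator seed-independent; `cancel_amplitude = 0` reduces the
  cancelation drive to a plain burst.

## Problem sizes in the shipped validation runs

The validation suite exercises the full 61 × 61 reference scan for the
headline overlap, the four-method comparison on the reference board plus
the two-method comparison on the thick board at the same grid, an
eight-point uniform-board spread check, and a 100-trial Monte-Carlo of the
compression gain at one sample per chip (trace length 256). Complementary
identities are checked exhaustively for orders 0–12.

```{r example, eval = FALSE}
# A minimal end-to-end run (a few minutes of CPU):
board <- reference_specimen()
plan <- scan_plan(0, 0, 0.06, 0.06, 0.001)
cfg <- inspection_config(plan = plan, base_seed = 42L)
probe <- modulate_square_carrier(golay_pair(3)$a, cfg$modulation)
cfg$noise_sigma <- calibrate_noise(probe, board, 0.03, 0.005,
                                   cfg$tx, cfg$rx, cfg$chain, cfg$channel,
                                   snr_db = 20)
img <- run_cscan(board, plan, cfg)
grid <- scan_grid(plan)
truth <- specimen_label_grid(board, grid$xs, grid$ys)
thr <- calibrate_thresholds(img$features[truth == "sound"])
coincidence(classify_image(img, thr)$labels, truth)
```

## Known limitations

* The per-point ray model makes boundary pixels binary; real beam spread
  would smooth the feature map and lower the overlap.
* The absolute decoded voltages are on an arbitrary scale; only orderings,
  ratios and spreads are meaningful.
* Knot scattering is a single dB penalty, not a waveform distortion.
* The two Golay shots assume a time-invariant channel between them; no
  drift correction is attempted.
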