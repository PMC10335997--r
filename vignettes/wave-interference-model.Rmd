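---
title: "Modelling DPOAE ratio functions by wave interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DPOAE ratio functions by wave interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When two tones at frequencies `f1 < f2` drive the cochlea, outer hair cell
(OHC) mechanotransduction distorts the superposed vibrations and emits energy
at combination frequencies, most prominently `2 f1 - f2`. Recorded in the ear
canal, this distortion-product otoacoustic emission (DPOAE) has a striking
property: as `f2/f1` is varied with `f2` fixed, its amplitude is bandpass,
peaking near `f2/f1 ~ 1.2-1.3` in the mouse and collapsing at smaller ratios —
even though the distortion measured *inside* the cochlea keeps growing as the
two tones approach each other. `dpoaewave` implements a deliberately minimal
model of this phenomenon: distortion is generated all along the basilar
membrane (BM), each local contribution travels back to the stapes as a wave,
and the ear-canal DPOAE is their vector sum. Bandpass tuning then emerges
from *wave interference* — spatial rotation of the summed phases — rather
than from any mechanical filter tuned to the DP frequency.

## Model structure

The pipeline chains five stages, each exposed as ordinary functions:

1. **Synthetic single-tone responses** (`generate_frequency_response()`):
   a parametric stand-in for averaged mouse BM measurements at an apical
   (CF 9 kHz) or middle-turn (CF 20 kHz) site.
2. **Scaling-symmetry extrapolation** (`spatial_response()`): the response of
   the place with characteristic frequency `CF(x)` to a tone at `f` is taken
   to equal the reference site's response at the equivalent frequency
   `f' = f * cf_ref / CF(x)`, using the log-linear mouse frequency-place map
   `position(%) = 156.5 - 82.5 log10(f/kHz)` over 0-5.13 mm (0.01 mm steps).
3. **Local DP generation** (`local_dp()`): at every position the two local
   displacement sinusoids drive a first-order Boltzmann transducer
   `y(x) = 1 / (1 + exp(a1 (x1 - x)))` with `a1 = 0.28 /nm`, `x1 = 2.6 nm`
   (time-domain simulation at 400 kHz over a 100 ms window; stimulus
   frequencies rounded to 10 Hz so the window holds integer cycles), and the
   `2 f1 - f2` Fourier component of the output — low-pass filtered by a
   single pole 2.36 octaves below the local CF — is the locally generated DP.
4. **Reverse propagation** (`propagate_to_stapes()`): in slow-wave mode each
   DP is weighted by the BM displacement a 40 dB SPL tone at the DP frequency
   would evoke at that position, and phase-shifted by the corresponding
   forward-traveling-wave phase (a lag); in fast-wave mode DPs reach the
   stapes unweighted and unshifted.
5. **Vector summation and sweeps** (`sum_dpoae()`, `ratio_function()`):
   complex summation over all positions, swept over `f2/f1 = 1.02-1.87` in
   0.025 steps and over stimulus level. A zero-phase control (all DP phases
   set to 0 before summing) isolates the role of interference.

Tuning of the resulting ratio functions is quantified against the DP
frequency with `Q10dB` (peak frequency over the 10 dB-down bandwidth, with
crossings interpolated linearly in dB versus log2 frequency) and with the
equivalent rectangular bandwidth (`QERB`), via `ratio_function_tuning()`.

```{r}
library(dpoaewave)

fr <- generate_frequency_response(apical_profile())
fr <- remove_middle_ear_delay(fr)
map <- place_map()
rf <- ratio_function(fr, map, f2 = 9000, level1 = 50)
ratio_function_tuning(rf)
```

## The synthetic generator: what it emulates

No animal data ship with the package; the generator stands in for the
averaged responses that drove the original analysis. It is deterministic and
calibrated, once, to the printed summary statistics of those measurements:

* compressive nonlinear gain of 41.1 dB between stimulus-normalized CF
  responses at 30 and 90 dB SPL (40.5 dB for the middle turn), produced by an
  active gain term declining linearly from full at 30 dB SPL to zero at
  90 dB SPL;
* `Q10dB` falling by a factor of ~2 between 40 and 75 dB SPL (realized:
  1.98);
* a slight downward peak glide with level (realized ~0.09 octaves on the
  default grid; the passive skirt peaks 0.15 octaves below CF);
* middle-turn `Q10dB` 1.5-1.8 times the apical value at matched levels,
  obtained by shrinking every bandwidth parameter by the sharpness
  multiplier `q_sharpness = 1.65`;
* CF displacements of 1.24 nm (apex) and 0.52 nm (middle turn) for 30 dB SPL
  tones, which set the operating range on the Boltzmann nonlinearity;
* monotone traveling-wave phase accumulation (~2.45 cycles at CF at low
  level), a separable pure middle-ear delay of 36 us, and tail phases that
  are level-insensitive below CF/2.

### Functional form

Magnitude in dB is a sum of a passive and an active term,

```
mag_dB(nu, L) = (L - 30) + P(nu) + G(L) * W(nu) + const,
nu = log2(f / cf_ref), G(L) = gain_max * clip((90 - L)/60, 0, 1),
```

with `P` a Huber-type skirt (quadratic cap near its peak at
`nu = -peak_shift`, linear far tails: 16 dB/oct^2 capping to ~6 dB/oct below,
300 dB/oct^2 capping to 120 dB/oct above) and `W` a unit-height asymmetric
Lorentzian window (`sigma` 0.50 oct below, 0.20 oct above CF). Two choices
matter for the interference model and were made deliberately after examining
the model's spatial structure:

* **heavy low-side shoulders** (Lorentzian rather than Gaussian): measured
  responses keep substantial amplitude half an octave to an octave below CF
  (~-20 to -30 dB re peak at 40 dB SPL). With thin Gaussian skirts the DP
  generation region becomes so narrow that destructive interference cannot
  cancel the rapidly growing distortion at small `f2/f1`, and the bandpass
  shape never forms;
* **a steep cliff above CF**: responses collapse above the local CF, which
  confines DP generation to locations at or basal to the `f2` place.

Phase (in cycles, lags negative) is

```
phi(nu, L) = -A * S(nu; L) - s_tail * max(nu - nu0, 0) - f * tau_me,
```

where `S` is a two-scale asymmetric tanh sigmoid rising from 0 in the tail
to 1 at CF (narrow component: widths 0.10/0.13 octaves below/above CF;
broad component: widths 3x larger), `s_tail = 0.3` cycles/oct is a small
baseline slope (traveling waves are never phase-frozen, even in the tail),
and `tau_me = 36` us is the middle-ear delay, removable with
`remove_middle_ear_delay()`. The near-CF slope of the narrow component
scales with the active gain, `slope ~ eps + (1 - eps) * G(L)/gain_max` with
a passive floor `eps = 0.4`: phase gradients are steepest at low level and
relax as gain recedes, which is what makes the modeled ratio-function tuning
and optimal ratio level-dependent. The two-scale slope profile mirrors the
gradual build-up of group delay toward CF; with a single-scale sigmoid the
phase field is too concentrated and the model's small-ratio flank develops
coherent revivals instead of a smooth decline.

The CF lag ships as `phase_cycles_at_cf = 2.45` cycles total (sigmoid plus
baseline); the underlying measurements do not tabulate this quantity, so it
is exposed as a profile parameter.

## Numerical choices

* **Commensurate windows**: `f1`, `f2` are rounded to the nearest 10 Hz
  (half-up), making every frequency of interest an integer number of cycles
  in the 100 ms analysis window; component extraction is then an exact
  projection. The effective (post-rounding) ratios are stored on the sweep
  grid so that `f_dp = 2 f2/ratio - f2` holds exactly.
* **Operating point**: the Boltzmann transducer rests at bundle position 0
  (resting open probability ~0.326). Stored RMS magnitudes are converted to
  peak amplitudes (`sqrt(2)`) before the time-domain drive.
* **Filter application**: the membrane low-pass is linear and
  time-invariant, so it is applied analytically to the extracted DP
  component.
* **Interpolation**: magnitudes in dB and unwrapped phases in cycles, both
  linear in log2 frequency, with straight-line extrapolation from the two
  nearest grid points beyond the reference span (the 1-15 kHz grid covers
  equivalent frequencies for most of the position grid at `f2 = 9 kHz`).
* **Tuning crossings**: interpolated in (dB, log2 f); curves that never fall
  10 dB below their peak on one side are flagged undefined rather than
  extrapolated. ERBs integrate squared normalized amplitudes over linear
  frequency by the trapezoid rule on the native grid.
* **Phase spread**: the generation region is the contiguous run of positions
  within 10 dB of the maximum `|DP_generated|`; the spread is the range of
  the unwrapped stapes-bound DP phase over that region. Ties in the optimal
  ratio go to the smallest ratio.
* **Kernel**: the per-position two-tone simulation is a small C++ loop (one
  `exp` per sample per position with precomputed trigonometric tables);
  a full sweep (35 ratios x 514 positions x 3 propagation variants) takes
  tens of seconds.

## What the default runs compute

`pipeline_reproduce()` regenerates everything from the default configuration
and recomputes: the apical nonlinear gain; the 40/75 dB SPL `Q10dB` ratio of
slow-wave model ratio functions; the mean `Q10dB` deficit of the model
versus the single-tone BM input over 40-70 dB SPL, and the same for direct
(fast-wave) summation; the extremes of the modeled optimal ratio across
level; the generation-region phase spread one grid step below the 50 dB SPL
optimum; the middle-turn optimal ratio (with generation truncated 0.32 mm
apical to the `f2` place); and the minimum middle-turn/apical vibratory
`Q10dB` ratio. The problem sizes are the defaults throughout: 35 ratios,
514 positions, four to five stimulus levels per sweep.

## Known limitations

* The model inherits the source framework's simplifications: single-tone
  responses stand in for two-tone spatial fields (no mutual suppression), and
  reverse propagation is a magnitude weight plus a phase shift — no
  middle-ear acoustics, no multiple internal reflections, no
  reflection-source component.
* The generator is a smooth parametric idealization. It reproduces the
  calibrated summary statistics, but not the irregularities of real averaged
  data; consequently the modeled optimal ratios sit slightly lower
  (1.12-1.24 across 40-70 dB SPL) than the measured-data model's 1.17-1.22,
  and the modeled phase spread at the optimum slightly exceeds the
  half-cycle rule of thumb (0.76 cycles at 50 dB SPL).
* The synthetic middle-turn site compresses the interference structure
  toward `f2/f1 = 1` more strongly than real middle-turn data do: its
  modeled ratio functions peak at the low edge of the standard ratio grid
  (~1.02-1.10) rather than at the measured ~1.14, and the 0.32 mm apical
  generation limit has essentially no effect (the dominant sources are
  basal to it, as in the original analysis).
* The modeled `Q10dB` values track the input BM tuning more closely than the
  original model tracked its measured inputs (mean deficit ~9% here versus
  ~15% there), and the fast-wave variant, while clearly broader than
  slow-wave at every level, is less degraded (~29% versus ~45% below the
  reference). Both gaps reflect the smoothness of the synthetic stand-in:
  passing the package's checks demonstrates the mechanism and its level
  dependence, not quantitative agreement with any particular animal data
  set.
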