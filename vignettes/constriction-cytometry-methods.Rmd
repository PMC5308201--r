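---
title: "Methods: electromechanical inversion of constriction-channel cytometry"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squeezecyto)
```

## The measurement and its raw streams

A constriction channel (default 10 × 10 µm cross-section, 200 µm long)
is narrower than the cells driven through it by a negative pressure of
0.5–1.2 kPa, so each cell must deform to enter and then travels along the
channel as an elongated plug. Two instruments observe every cell on their
own clocks: a high-speed camera at 200 frames/s yields the aspiration
length versus time, and a two-frequency lock-in impedance analyser at 25
points/s yields amplitude and phase at 1 kHz and 100 kHz. Five
*preliminary* markers are read off these streams — the amplitude ratios
`A_1kHz` and `A_100kHz` and the lengths `L_instantaneous`,
`L_transitional`, `L_elongation` — and two model inversions convert them
into the intrinsic markers `C_specific_membrane`, `sigma_cytoplasm` and
`E_instantaneous`. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic cohorts do and
do not establish.

## Electrical model and inversion

The unoccupied channel filled with culture medium is purely resistive,
`R_total = R_access + L/(σ_m·W·H)`. With a cell of elongated length
`L_elongation` inside, the occupied segment becomes
`R_leak ∥ (R_cytoplasm + 1/(jωC_membrane))` while the rest of the channel
stays medium-filled. The measured ratios are with-cell over baseline
impedance. The circuit is a reconstruction from its verbal description
(series membrane–cytoplasm branch, parallel seal leak, series unoccupied
remainder); all geometric factors are isolated in
`circuit_to_intrinsic()` so an alternative translation can be swapped in.

Inversion proceeds in the order the two frequencies suggest:

1. **Leak resistance.** At 1 kHz the membrane reactance (≈ 1.6 × 10⁸ Ω at
   1 pF) dwarfs everything else, so the occupied segment is ≈ `R_leak`
   and `R_leak = A_1kHz·R_total − R_rest` (`invert_leak_resistance()`).
   `A_1kHz ≤ R_rest/R_total` would imply a negative seal resistance and
   is rejected by name. Only the amplitude is used at 1 kHz; the deposited
   1 kHz phase is read but not needed.
2. **Cell branch.** At 100 kHz, amplitude *and* phase determine the
   complex occupied-segment impedance linearly, so `invert_cell_circuit()`
   solves by exact complex elimination —
   `Z_seg = A·e^{jφ}·Z_total − R_rest`, `1/Z_branch = 1/Z_seg − 1/R_leak` —
   rather than iteratively; the recovered pair must reproduce the inputs
   through the forward model to a relative residual below 10⁻⁸. A
   non-negative imaginary branch part (e.g. zero phase) leaves the
   capacitance unidentifiable and is an explicit error.
3. **Joint refinement.** The step-1 approximation is exact only as
   `ωC → 0`; at realistic capacitances it leaves a relative error of
   order `(R_leak·ωC·…)²` ≈ 10⁻⁴–10⁻³ that propagates into step 2.
   `invert_electrical()` therefore alternates the exact 100 kHz
   elimination with a scalar solve of the *full* 1 kHz amplitude equation
   until `R_leak` is stationary (relative tolerance 10⁻¹², typically 3–5
   iterations), after which the whole chain round-trips the forward model
   to better than 10⁻⁸.

The translation to intrinsic markers treats the lumped membrane
capacitance as the two cross-sectional caps (leading and trailing cell
faces) in series, `C_specific = 2·C_membrane/(W·H)`, and the cytoplasm as
a column of length `L_elongation`,
`σ = L_elongation/(R_cytoplasm·W·H)`. An alternative convention scaling
membrane area with the lateral wall contact (∝ `L_elongation`) is
conceivable but not used. Values outside 0.5–10 µF/cm² or 0.1–3 S/m
warn rather than fail.

The medium conductivity is not stated in the source data description;
the default is 1.5 S/m, typical for culture medium, and configurable via
`medium_model()` together with the access resistance (default 0; the
baseline resistance may equally be taken from the measured baseline
rather than nominal geometry by adjusting these two knobs).

## Mechanical model and its two-valued inversion

The entry relations (coefficients from finite-element simulation of an
incompressible viscoelastic solid entering a rigid channel, taken as
given) are linear in the pressure ratio `x = P_aspiration/E_instantaneous`
with quadratic-in-friction slopes and intercepts. With the default
coefficients both slope polynomials are sign-definite (negative
discriminants), so the instantaneous length always increases and the
transitional length always decreases with pressure.

`invert_entry()` eliminates `x` through the transitional relation and
finds the zeros of the scalar residual `g(f_c)` on a 2001-point grid over
the `f_c` search interval (default [0, 1]) with bisection to 10⁻¹⁰;
candidates with non-positive `x` are discarded, a root within one grid
spacing of an interval edge is flagged `out_of_domain`, and an empty root
set returns `no_solution` with `NA` values rather than numbers.

Two properties of the printed model deserve emphasis, both established
numerically to machine precision during development:

* **Restricted domain.** Ordered positive lengths
  (`0 < l_inst < l_trans`) exist only for roughly `0.03 < x < 0.27`
  (friction-dependent, widest near `f_c ≈ 0.42`). Measurements outside —
  including, notably, cohort-*mean* marker pairs at plausible pressures —
  have no solution, and the pipeline surfaces that honestly.
* **Two-valuedness.** Within the domain, almost every measurement pair is
  reproduced *exactly* by two `(E, f_c)` roots straddling a fold at
  `f_c ≈ 0.34–0.45` (position depends on `x`). The two roots are
  measurement-equivalent, so no estimator can tell them apart from the
  entry lengths alone. The solver reports
  `multiple_solutions_resolved` and breaks the tie by smallest residual,
  then smallest `f_c` (residuals below 10⁻⁸ count as exact ties): a
  reproducible, documented choice of the lower-friction branch.

```{r fold}
fw <- forward_entry_lengths(f_c = 0.40, x = 0.14)
s <- invert_entry(fw$l_inst * 10, fw$l_trans * 10, 10, P_aspiration = 0.7)
c(f_c = s$f_c, status = s$status)   # the exact lower-branch partner of 0.40
```

`D_channel`, the normalizing length, is not separately defined for a
square channel; the default is the channel width (10 µm), configurable in
`channel_geometry()`.

## Trace processing

No detection rules ship with the deposited data, so the extractors are
fully parameterized with conservative defaults:

* **Entry onset**: first frame whose single-frame length increment
  exceeds `jump_threshold` (default 2 µm — several times the camera noise
  yet well below any elastic jump).
* **Creep**: the post-jump segment up to the next jump (entry completion)
  is fitted by Levenberg–Marquardt to
  `L(t) = L_T − (L_T − L_I)·e^{−(t−t₀)/τ}` with `L_I` pinned to the onset
  length and `τ` log-parameterized to stay positive without box
  constraints; `L_transitional` is the asymptote and creep is declared
  over at 95% of the creep amplitude (`τ·log 20`). If the fit fails, a
  fallback takes the first frame whose centred three-frame slope drops
  below 2 µm/s; if that fails too the cell is flagged
  `creep_fit_failed`, never imputed.
* **Elongation**: median of the travel-plateau frames; a window whose SD
  exceeds 1 µm (no plateau) still returns the median but warns.
* **Amplitude ratios**: the event is found on the 1 kHz amplitude channel
  (largest contrast) as samples above the median + 5 MAD; the same window
  serves both frequencies so the two ratios stay time-aligned. Baseline
  and travel values are medians, the travel window being the central 80%
  of the event to exclude entry/exit transients. The camera and impedance
  clocks are never compared directly — each stream is aligned by its own
  event onset.

Marker-ordering violations (`L_inst ≤ L_trans ≤ L_elong`) and ratios
below 1 warn rather than error: on real data they flag doublets or
clogging, which downstream per-cell status handling is designed to carry.

## Synthetic cohorts: what they emulate, and what not

`simulate_cohort()` draws per-cell ground truth from truncated normals
centred on the published per-line cohort statistics (five presets:
H460, H446, A549, 95D, 95C). Derived quantities use the package's own
forward models: entry lengths from the mechanical relations, elongation
from volume conservation, impedance ratios from the lumped circuit.
Acquisition follows the instruments (200 frames/s, 25 points/s); noise is
additive Gaussian on lengths (0.25 µm, camera quantization) and
multiplicative Gaussian on amplitudes (1%, lock-in gain error), phases
noise-free. Aspiration pressure is uniform on 0.5–1.2 kPa.

Three generator choices are worth knowing:

* **Friction.** `f_c` is unreported; the preset (0.27 ± 0.03, truncated
  to [0.15, 0.33], all lines) sits on the lower, uniquely invertible
  branch of the two-valued entry model while keeping the widest feasible
  pressure-ratio window — the regime the one-root analysis workflow
  implicitly presumes. The creep time constant is likewise unreported;
  the default 0.05 ± 0.01 s completes creep within tens of frames at 200
  frames/s, consistent with the frame sequences shown for typical cells.
* **Leak resistance** is mapped from each line's published `A_1kHz` via
  the open-membrane relation at the line's mean elongation (≈ 2.8–3.5 MΩ).
* **Independence.** Real per-cell covariance between markers is unknown;
  parameters are sampled independently, which understates the correlation
  structure of real cohorts.

Simulated `A_100kHz` values come out near 1.6–1.7 rather than the
published ≈ 1.17: the reconstructed circuit plus the assumed medium
conductivity fix the contrast of the occupied segment, and the original
model's unpublished details evidently differ. The orderings
`A_1kHz > A_100kHz > 1` and `L_inst < L_trans < L_elong` hold cell by
cell regardless, and all round-trip validation is internal (generator →
pipeline), so this offset does not touch parameter recovery. Passing
recovery tests therefore demonstrates the *inversion chain* is correct
and noise-stable; they cannot certify the reconstructed circuit against
the original instrument, nor cover real-data pathologies (doublets,
partial clogging, drift) that the generator does not emulate. Draws whose
pressure ratio leaves the entry model's domain are skipped with a logged
reason — about 10–15% under the H460 preset, more for softer lines —
mirroring cells a real analysis would have to discard.

## Numerical choices and degenerate inputs

* Mechanical root finding: 2001-point bracketing grid, bisection to
  10⁻¹⁰ on `f_c`, residual ties below 10⁻⁸ broken by smallest `f_c`.
* Electrical refinement: fixed point on `R_leak` to relative 10⁻¹²,
  inner scalar solves by Brent's method on a bracket expanded around the
  open-membrane estimate.
* Creep fit: LM with analytic-free residuals, 200 iterations max,
  asymptote started at the segment's last value and `τ` at a third of the
  segment span; failure falls back to the slope rule, then to a flagged
  missing value.
* Degenerate inputs are named errors, not numbers: zero phase at 100 kHz
  (capacitance unidentifiable), amplitude below the feasibility bound
  (negative seal), empty creep segments, events touching trace edges.
* All randomness flows from one integer seed per cohort; identical seeds
  give bit-identical cohorts, traces and pipeline outputs.

## Problem sizes

The shipped tests validate the electrical chain on a 5 × 5 × 4 grid
spanning 1–3 µF/cm², 0.5–1.5 S/m and 1–10 MΩ; the mechanical round trip
on friction–pressure grids on both sides of the fold; and end-to-end
recovery on 300-cell cohorts (noisy and noiseless), where cohort means of
the three intrinsic markers return to the generating means within 0.5%
(noisy) and 10⁻¹⁰ (noiseless) in a few seconds of compute. The
`analysis/` scripts run the same 300-cell workflow in staged form with
tables written under `results/`.

## Known limitations

* The deposited raw layout lacks per-cell aspiration pressure, so
  `E_instantaneous` cannot be recomputed from raw streams alone; the
  pipeline accepts a cohort-level or per-cell pressure and otherwise
  reports E missing.
* Above the fold (`f_c ≳ 0.35`), entry measurements are intrinsically
  ambiguous between two `(E, f_c)` pairs; results there carry the
  `multiple_solutions_resolved` status and the lower-branch convention.
* The lumped circuit neglects ion channels and organelle membranes by
  construction; XLSX serialization of the deposited workbooks is not
  provided — the CSV mirrors carry the identical column layouts.
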