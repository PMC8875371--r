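---
title: "A segmental electromechanical model of LBBB strain patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A segmental electromechanical model of LBBB strain patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbbbsim)
```

This vignette is the package's own account of the model it implements: the
assumptions behind each sub-model, the parameters that matter and why their
defaults are what they are, what the synthetic patients do and do not
emulate, and the numerical and design choices made where the design was
genuinely open.

## The model in one paragraph

The heart is reduced to 19 wall segments — the 16 left-ventricular (LV)
segments of the standardized AHA segmentation plus three right-ventricular
(RV) layers — each an actively contracting fiber coupled to its ventricular
cavity through a hydraulic piston. A cellular-automata conduction system
decides *when* each segment is electrically activated; a Gaussian-driven
time-varying elastance represents each atrium; a lumped closed-loop
circulation with perfect-diode valves provides pre- and afterload. Left
bundle branch block (LBBB) is a purely topological change — the left
bundle's outgoing links are removed — after which the LV activates through
the right bundle and slow trans-septal myocardial spread. The deformation
phenotypes of LBBB (septal flash, septal rebound stretch, delayed lateral
contraction and their modification by scar) then *emerge* from the
interaction of activation delays, regional contractility, and the
trans-septal pressure coupling; none of them is prescribed by a curve
template.

## Conduction system

Each of the 26 automata cycles through slow diastolic depolarization (SDD),
upstroke depolarization (UDP), absolute refractory period (ARP) and
relative refractory period (RRP). A node stimulates its neighbours when its
UDP ends; stimuli arriving during ARP are ignored, and stimuli during the
RRP trigger an activation with a UDP shortened in proportion to the elapsed
RRP fraction (a classic automata convention; configurable to `"normal"`).
Only the sinoatrial node self-fires, and its SDD is derived from the
requested RR interval minus its other three phases, so the heart period
equals RR exactly and heart rate is a single input.

Events are processed on one global queue ordered by (time, source index),
which makes simultaneity deterministic: when two stimuli reach a node at
the same instant, the one from the lower-indexed source is processed first
and the second is absorbed by the refractory period.

Phase durations (UDP ~2 ms for working myocardium, ARP 250 ms, RRP 100 ms,
AV-nodal UDP 100 ms acting as the AV delay) were chosen once to place the
PR interval and baseline QRS in normal adult ranges; they are all exposed
in the configuration.

**Myocardial link delay.** Anatomically adjacent segments are connected by
slow cell-to-cell links with one uniform delay. In the *healthy* baseline
this delay defaults to 1 ms: with the left bundle inserting only into the
septal segments, any appreciable per-link delay would spread LV activation
over tens of milliseconds, and the segmental mechanics (which lack the
smoothing effect of tissue continuity) amplify even a 10 ms electrical
spread into a much larger dispersion of strain-minimum times. A
near-instantaneous transverse delay is the segment-level idealization of
the dense endocardial Purkinje delivery of a healthy heart. In LBBB
configurations the same parameter represents genuinely slow myocyte-to-
myocyte conduction and is raised to 29–36 ms per link, which calibrates the
measured QRS width to the three reference values (136, 157, 152 ms).

## Segment mechanics

Active tension is `T_a = k_act · T_max · u(t) · λ(l/l0)` with:

* `k_act` ∈ [0, 1], the segment's contractility as a fraction of the
  nominal healthy peak tension (reported as % in bull's-eye maps; scar
  means `k_act` near 0);
* `λ`, a clipped-linear length–tension factor, `λ(1) = 1`, slope 3,
  clipped to [0, 1.6] — the Frank–Starling sensitivity. The slope was set
  with the baseline calibration: steeper slopes synchronize end-systolic
  behaviour across walls but depress stroke volume;
* `u(t)`, the electromechanical drive: after an onset delay
  (`t_delay`, 30 ms) the twitch rises exponentially (`tau_c` = 40 ms)
  toward a systolic plateau lasting `t_plat` (180 ms for LV, 215 ms for RV
  so that RV ejection does not end before LV ejection), then relaxes
  exponentially (`tau_r` = 33 ms), normalized to peak 1. A piecewise
  double-exponential with a plateau was preferred over a single
  rise-times-decay product because the product form cannot both sustain a
  physiological ejection (~170–280 ms) and relax quickly enough to permit
  early diastolic filling; with it, either aortic diastolic pressure or
  diastolic re-lengthening was always wrong.

Passive tension is exponential in stretch and linear in compression,
`T_p = k_p1(e^{k_p2 ε} − 1)` for ε ≥ 0 and `k_p1 k_p2 ε` below, continuous
in value and slope at the slack length. A fairly steep exponent
(`k_p2` = 55 for LV) keeps end-diastolic stretch differences between
septal segments (loaded by the small trans-septal end-diastolic gradient)
and free-wall segments (loaded by full LV pressure) within ~2 % strain,
which is what makes healthy septal and free-wall strain curves similar.

**Piston coupling.** Wall tension converts to pressure through a fixed
geometric weight, `p_seg = (T_a + T_p)/area_w`, and the displaced blood
column obeys `l_h dq/dt = p_seg − p_load − r_h q`; fiber shortening is
`dl/dt = −q/area_w`. The per-segment `r_h` and `l_h` scale inversely with
`area_w` so that wall shortening *velocity* is the same for basal, mid,
apical and RV segments of equal drive — without this scaling, small-area
(apical) segments lag systole and large-area RV segments barely move.
Septal segments are loaded by `p_lv − p_rv`; all other LV segments by
`p_lv`; RV segments by `p_rv`. This asymmetric load is the mechanism that
permits pre-ejection septal shortening when RV pressure rises before LV
pressure, and its sign can be flipped off for diagnostics
(`mechanics$septal_coupling`).

Each ventricular cavity is a hydraulic node with a stiff elastance
(30 mmHg/mL for the LV) that absorbs the instantaneous imbalance between
wall displacement and valve flow. The *reported* cavity volume is
`V = V_node + Σ area_w·l − v_offset`, which is conserved exactly during
isovolumic phases and globally (total blood volume drifts < 1e-10 mL over
20 cycles, since the flow bookkeeping is a linear invariant that RK4
preserves to round-off). Strain is referenced per cycle to the fiber
length at the first ventricular activation of the cycle, mirroring R-wave
gating of speckle-tracking echo; the mechanical slack length `l0` is a
separate, material parameter.

## Circulation and calibration

The loop is LV → aorta → systemic arteries → systemic veins → vena cava →
RA → RV → pulmonary artery → capillaries → pulmonary veins → LA → LV, with
linear elastance chambers, resistive links, and valves as perfect diodes
(flow clamped to zero against the gradient inside the right-hand side; at
0.5 ms steps chattering is negligible). The baseline parameter set was
calibrated once, as a whole, so that the healthy simulation yields
systolic LV pressure ≈ 130 mmHg, aortic pressure ≈ 60–130 mmHg and LV
volume ≈ 40–90 mL with physiological valve-flow morphology; the three
independent constraints (mean pressure, pulse pressure, diastolic decay)
essentially pin systemic resistance and the two arterial elastances, and
`v_offset` places the volume range. These numbers are reproduced from
scratch by `scripts/acceptance.R`.

## Strain analysis and feature detection

Wall curves are unweighted means of the five septal and five lateral
segments. RMSE between curves is computed after linear resampling to a
200-point fraction-of-cycle grid, because observed and simulated beats
generally have different RR; resampling on absolute time is available. The
full cycle is used as the comparison support (the systole-only alternative
is a documented open choice).

The septal-flash detector takes the aortic ejection window from the
simulated valve events. Pre-ejection shortening is the magnitude of the
strain minimum reached before valve opening, *provided the curve actually
fell* at least 0.5 % below its value at cycle start — otherwise the
late-diastolic relaxation tail of the previous beat (which starts low and
rises) would masquerade as a dip. Rebound stretch is the maximal
re-lengthening above that early minimum before valve closure. The flash
flag requires both to exceed configurable thresholds (1.5 % and 1.0 %).

## Personalization

The fitting procedure encodes the manual one-parameter-at-a-time strategy
as deterministic cyclic coordinate descent: for each free parameter, in
the declared order (activation delays → contractility → driving time
constant → passive scale), the value on a fixed grid minimizing
septal + lateral wall RMSE is kept; sweeps stop when a full pass improves
the objective by < 0.05 % strain. Parameters are freed per wall group
(septal 5 / lateral 5 / remaining 6) by default — two target curves cannot
identify 16 independent segments — with per-segment freeing available when
16 traces exist. Failed simulations score `Inf` and are skipped, the
objective is non-increasing by construction, and identical inputs give
identical fits. An optional bounded 1-D polish (`refine = TRUE`) is off by
default. Objective evaluations run the model at 8 cycles and dt = 1 ms,
where the solution differs from the 0.5 ms reference by < 0.01 mmHg in
peak pressure.

## Synthetic patients

The four profiles are the package's stand-in for real strain exports (no
public traces exist) and double as ground truth for recovery tests.
`mode = "model"` runs the forward simulator with the preset parameters and
adds seeded i.i.d. Gaussian noise (0.6 % strain by default — the simplest
defensible surrogate for speckle-tracking noise); `mode = "template"`
composes analytic dip–rebound–plateau shapes for tests that must not
depend on the simulator. Fixtures are byte-reproducible from
(profile, seed).

* **healthy** — the baseline configuration (RR 900 ms).
* **lbbb_nonischemic** — left bundle disabled, 33 ms myocardial links
  (QRS ≈ 136 ms), globally depressed contractility with relative sparing
  of the lateral wall, and a brief early septal twitch. Raised systemic
  resistance represents the vasoconstricted low-output state; without it
  aortic diastolic pressure collapses and ejection starts too early for
  any pre-ejection septal motion to be visible.
* **lbbb_lateral_scar** — lateral contractility 0.10, septal 1.0, wider
  QRS (157 ms). The septum sustains contraction through systole: the flash
  flag is negative and septal deformation exceeds the non-ischemic case.
* **lbbb_anteroseptal_scar** — septal 0.3 and anteroapical 0.4
  contractility with a brief weak septal twitch: the flash and rebound
  persist at reduced septal amplitude.

RR intervals (900/860/880 ms) are plausible resting values; the reference
patient table gives QRS and ejection fraction but not RR. What passing the
pattern tests shows is that the *mechanisms* (delay + contractility + load
coupling) can produce, abolish, and modulate the flash as described; it
does not validate the model against any individual's measured strain.

## LGE scar module

Fuzzy c-means with two classes, fuzzifier 2, deterministic initialization
at the 25th/75th intensity percentiles, convergence at a 1e-5 center
shift; the Bezdek objective is asserted non-increasing at every iteration,
and the LGE class is always the higher-intensity center, making the result
invariant to initial ordering. Because an unsupervised two-class split
always exists — in scar-free tissue it would merely partition the noise —
voxels are only called enhanced when the bright/dark center ratio exceeds
a minimum contrast (1.25 by default). The flip side is a genuine
limitation: a myocardium that is enhanced *everywhere* has no reference
class and is reported as scar-free; real workflows resolve this with a
remote-myocardium reference, which a per-slice intensity clustering cannot
supply.

Per-segment transmurality casts radial chords endo→epi through each
angular position of a segment's sector and averages the LGE fraction of
each chord, weighting voxels by inverse radius so the chord is sampled
uniformly in wall depth (a polar voxel grid otherwise over-weights the
epicardial side and biases a 60 % band to ~54 %). Hardening uses the 0.5
membership level. Synthetic phantoms (annular slices, 6 angular sectors on
basal/mid rings, 4 apically, scar as a subendocardial band of the
requested radial fraction) are labelled by construction, sidestepping
slice-to-ring assignment for clinical stacks, which is out of scope.

## Numerical choices

* Fixed-step RK4 at dt = 0.5 ms, events quantized to the grid: bitwise
  reproducibility across runs and platforms was preferred over adaptive
  stepping. Halving dt changes peak LV pressure by < 0.001 mmHg.
* The stiffest modes (valve–cavity coupling, piston–cavity oscillation)
  have time constants ≥ 0.5 ms at the shipped parameters; dt = 1 ms
  remains stable and is used for fitting and most tests.
* 15 cycles with 5 discarded is the default horizon; beat-to-beat drift of
  peak LV pressure is < 0.5 % from cycle 10 onward. Tests use 8–20 cycles
  at dt = 1 ms, and fits use grids of 10–19 contractility values — sizes
  chosen to exercise the full pipelines at interactive runtimes.
* Ties in the fitter's grid scan resolve to the first (lowest) grid value;
  simultaneity in the event queue resolves by source index.

## Known limitations

Segmental mechanics have no fiber orientation, torsion, or mechanical
continuity between neighbours — segments interact only through cavity
pressures, so regional strain differences are sharper than in tissue. The
ECG is a template sum calibrated only in timing (QRS width), not in
amplitude or lead morphology. The atria are passive pressure sources with
no inter-atrial conduction detail. The fitter provides no identifiability
analysis: freeing all three parameter categories per wall can trade delay
against contractility, which is why the default frees delays first and
contractility second. Finally, the patient profiles are synthetic: their
contractility maps are design targets, not estimates from any individual.
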