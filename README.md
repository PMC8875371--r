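# lbbbsim

A closed-loop electromechanical heart simulator for studying the left
ventricular (LV) deformation patterns of left bundle branch block (LBBB),
written for cardiac modellers and echocardiography researchers who want to
relate segmental longitudinal strain morphology — septal flash, septal
rebound stretch, delayed lateral contraction — to regional contractility
and activation delay, and to myocardial scar seen with late gadolinium
enhancement (LGE) cMRI.

## The model

Four coupled sub-models:

1. **Conduction system** — 26 interacting cellular automata (sinoatrial
   node, atria, AV node, His bundle, bundle branches, 3 RV + 16 AHA LV wall
   segments). Each automaton cycles through the four action-potential
   phases SDD → UDP → ARP → RRP and stimulates its neighbours when its UDP
   ends; heart rate is set by a single RR input. Disabling the left bundle
   branch (`lbbb = TRUE`) forces LV activation through the right bundle and
   slow trans-septal myocardial links, producing the septal-to-lateral
   delay and wide QRS of LBBB. An ECG is synthesized from per-node
   waveform templates.
2. **Atria** — time-varying elastance with a Gaussian activation drive:
   `P = [e_min + g(t)(e_max − e_min)](V − V0)`.
3. **Multi-segment ventricles** — each of the 19 wall segments is a fiber
   with active tension `T_a = k_act · T_max · u(t) · λ(l/l0)` (twitch drive
   `u`, clipped-linear length–tension `λ`), exponential/linear passive
   tension, and a hydraulic piston (resistance + inertance) coupling wall
   tension to cavity pressure. Septal segments are loaded by the
   trans-septal gradient `P_lv − P_rv`, which is what permits pre-ejection
   septal motion when the septum activates early. Longitudinal strain is
   `100·(l − l_ref)/l_ref`, referenced per cycle at the first ventricular
   activation (negative = shortening, echo convention).
4. **Circulation** — lumped-parameter closed loop (aorta, systemic
   arteries/veins, vena cava, pulmonary artery/capillaries/veins) with
   linear elastance chambers, resistive links and perfect-diode valves.

The hybrid system is integrated with fixed-step RK4 (default 0.5 ms) after
the discrete-event conduction pass; the forward model is fully
deterministic.

On top of the simulator the package provides wall-level strain analysis
(septal/lateral five-segment averages, RMSE on a cycle-normalized grid,
septal-flash/rebound feature detection), deterministic one-parameter-at-a-
time personalization of per-wall contractility and activation delay against
target strain curves, synthetic patient generators for four phenotypes
(healthy, non-ischemic LBBB, LBBB + lateral scar, LBBB + anteroseptal
scar), and a fuzzy c-means LGE module that maps synthetic short-axis
phantoms to per-segment scar transmurality for concordance checks against
fitted contractility.

## Worked example

```r
library(lbbbsim)

res <- run_simulation(default_config())   # 15 cycles, dt = 0.5 ms
summarize_hemodynamics(res)
#> Peak LV pressure :  131.0 mmHg
#> Aortic pressure  :  128.7 / 58.5 mmHg
#> LV volume        :   91.4 / 39.4 mL (EDV/ESV)
#> Stroke volume    :   52.0 mL   EF 56.9 %
```

A non-ischemic LBBB patient (QRS 136 ms) and its septal wall features:

```r
fx <- make_strain_fixture("lbbb_nonischemic", seed = 3)
sw <- wall_average(fx$trace, "septal")
detect_features(sw, fx$ejection)
#> septal flash            : yes
#> pre-ejection shortening : 3.27 %
#> rebound stretch         : 6.27 %
#> peak strain             : -17.43 % at 281 ms
```

The pre-ejection septal shortening followed by re-lengthening (rebound
stretch) is the septal-flash morphology of LBBB; with a lateral scar
(`"lbbb_lateral_scar"`) the flash disappears and septal deformation is
exaggerated instead. Personalization against the septal and lateral wall
curves recovers the contractility map:

```r
targets <- list(septal = sw, lateral = wall_average(fx$trace, "lateral"))
fit <- fit_strain(base_config_for(fx), targets, fit_spec())
contractility_bullseye(fit)   # 16-segment map, % of nominal
```

A command-line interface wrapping these functions lives at
`inst/cli/lbbbsim` (subcommands `simulate`, `ecg`, `fixtures`, `fit`,
`lge`, `report`).

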