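---
title: "Methods: a desk-scale multi-scale model of ventilation-induced airway inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale multi-scale model of ventilation-induced airway inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventilam)
```

## The problem and the modelling strategy

Positive-pressure mechanical ventilation raises airway pressures above
physiological levels. The over-distended airway wall stretches, stretch
activates resident innate immune cells, the resulting inflammation kills and
scars epithelium, and scar tissue stiffens the wall — changing its mechanical
response to the next breath. The phenomenon spans organ, tissue and cellular
scales, and `ventilam` models it as three loosely coupled components, each a
"port" that passes a single summary quantity downstream:

1. **Organ scale** — a ventilator inflow waveform drives a symmetric
   bifurcating airway tree; the output is the peak-of-cycle lumen pressure of
   each generation.
2. **Tissue scale** — that pressure loads a three-layer axisymmetric airway
   wall; the output is the mean hoop strain of the epithelial layer.
3. **Cellular scale** — that strain activates a stochastic cellular-automata
   model of macrophages, fibroblasts, two cytokine fields and an epithelial
   sheet; the output is the time course of dead epithelial cells (the
   inflammation-severity readout) and the final fibrosis fraction.
4. **Feedback** — the fibrosis fraction stiffens the wall materials
   (`stiffen()`, mu' = mu (1 + alpha f)) and the tissue stage is re-solved
   once, quantifying the compliance loss.

The deliberate simplifications relative to a full 3-D fluid–structure
simulation are listed under *Limitations*.

## Organ scale: lumped Poiseuille tree

The tree is symmetric: generation g holds 2^g identical branches
(`build_airway_tree()`), with lumen dimensions from the classic Weibel
"model A" morphometry for generations 0–7
(`inst/extdata/weibel_morphology.csv`). Each branch is a rigid Poiseuille
resistor, dP = 8 mu L q / (pi r^4), with air viscosity 1.79e-5 kg/(m s);
the network is evaluated quasi-statically per time sample and lumen pressure
accumulates from the outlet (gauge 0 by default) upward. This reproduces the
generation-wise pressure drop expected along the airway tree; it deliberately
omits inertia, turbulence and moving walls.

The ventilator waveform (`ventilator_waveform()`) has inspiration time 0.4 s,
expiration time 2.0 s and tidal volume 420 ml. Inspiratory flow is a rising
exponential Q(t) = A (1 - exp(-t/tau)), tau = T_in/5, with A fixed in closed
form so the inspired volume is exactly the tidal volume. The expiratory
branch is Q(s) = (Q_e + B s/tau_ex) exp(-s/tau_ex): it is *continuous* with
the end-inspiratory flow Q_e at the transition, and B is solved in closed
form so the expired volume over the 2.0 s window equals the tidal volume
exactly. A single decaying exponential cannot satisfy continuity and volume
balance simultaneously; this two-term form satisfies both, which is why it
was chosen. Flow is positive into the lung during inspiration.

## Tissue scale: layered Neo-Hookean annulus on an elastic foundation

The wall is three concentric layers — epithelium, connective tissue, airway
smooth muscle (ASM) — with thicknesses 5 %, 10 % and 15 % of the lumen
radius (the morphometric source for lumen dimensions does not tabulate layer
thicknesses; these give a wall-to-lumen ratio typical of conducting
bronchioles and scale consistently across generations). The two inner layers
are Neo-Hookean, W = (mu/2)(I1 - 3) + (1/d)(J - 1)^2, with mu = 5 MPa for
the epithelium and an inner/middle stiffness ratio of 10 (so mu = 0.5 MPa
for connective tissue); the "inner stiffer" reading of that ratio was chosen
because the epithelial layer includes the basement membrane. The ASM is
linear elastic with E = 99 MPa (the organ-scale tissue modulus) and
nu = 0.45. No value is available for the incompressibility parameter d, so
d = 2/K with the bulk modulus K chosen for a near-incompressible small-strain
response (effective Poisson ratio 0.49) — soft tissue is water-rich.
The outer boundary is tethered by an elastic foundation with
k = 600 (traction -k u), modelling the alveolar attachments.

The solver (`solve_wall()`) discretizes the axisymmetric plane-strain
equilibrium (inertial term dropped: breathing is far below wall resonance)
with linear finite elements and midpoint quadrature on 200 radial nodes, and
Newton-iterates the nonlinear residual to a relative tolerance of 1e-10
(50 iteration cap). Two numerical choices matter:

* **Cancellation-free constitutive gradients.** At airway pressures of a few
  pascals the wall strains are of order 1e-7 while the volumetric modulus is
  of order 1e8 Pa, so evaluating (2/d)(J - 1) via `a*b - 1` loses nine
  digits and caps the attainable residual near 1e-8. The gradients are
  therefore written in the strain variables er, et, using
  J - 1 = er + et + er et exactly; the 1e-10 tolerance is then reached in
  2–3 Newton iterations.
* **Tangent by differencing the analytic gradient.** The element tangent is
  a central difference (step 1e-6) of the analytic gradient; Newton then
  converges linearly with a contraction of ~1e-6 per step, which is
  indistinguishable from quadratic at these tolerances and avoids a large
  second-derivative expression.

Verification: with all layers linearized the solver agrees with the layered
Lamé closed form (pressurized multi-layer cylinder with spring-modified outer
boundary, implemented independently in the test helpers) to machine precision
at the nodes — the 1-D discretization is nodally superconvergent — and the
hoop-strain *profile* converges at second order under grid refinement. An
incremental-loading test confirms that internal energy (strain energy plus
the foundation term) balances the external boundary work. Zero pressure
returns the exact zero solution without iterating.

## Cellular scale: stochastic cellular automata

A bounded 100 x 100 lattice (4-neighbour adjacency, no wrap-around) carries
one epithelial cell per site with states alive / dead / fibrosis. Fifty
macrophages and fifty fibroblasts perform chemotaxis-biased random walks:
each step an agent samples {stay, 4 neighbours} with weights
exp(beta C_TNF), beta = 0.5 (both kinds ascend the injury signal). TNF and
TGF concentrations obey explicit forward-Euler diffusion–decay,
dC/dt = D lap(C) - K C, with a 5-point Laplacian, zero-flux boundaries and
D dt/dx^2 = 0.1 (stability bound 0.25); the scheme conserves total mass
exactly up to the geometric decay factor per step. Release deposits a unit
bolus at the agent's site.

All "probability determined by concentration" rules are saturating
Michaelis–Menten forms, which keep probabilities bounded and monotone in the
stated direction:

* macrophage TNF release: p_tnf_max x gate(strain) x C_s/(C_s + TGF) —
  stretch-activated, suppressed by TGF;
* fibroblast TGF release: p_tgf_max x TNF/(C_d + TNF) — driven by TNF;
* alive -> dead: p_damage_max x TNF/(C_dam + TNF);
* dead -> alive: p_heal_max x TGF/(C_heal + TGF);
* dead -> fibrosis: probability p_fib once continuously dead for tau_fib
  steps under TGF above a low threshold; fibrosis is absorbing.

The update is synchronous with a fixed sub-step order (move, release,
diffuse, transition) so that a configuration plus a seed reproduces a run
byte-for-byte. Agents may share sites (no volume exclusion is stated or
needed). One RNG stream per replicate is derived as master seed + replicate
index.

### The activation gate and the fibrosis-relief closure

The strain gate is 0 at or below the activation threshold `eps_act`; just
above it, activation is all-or-nothing at a floor of 0.06, then ramps
(smoothstep) to 1 at `eps_sat`. Two further closures are the package's own
design (the source rules leave fibrosis dynamics open):

* **Strain relief.** The strain felt by immune cells is the input strain
  scaled by max(0, 1 - relief_gain x fibrosis fraction) (default gain 3), and
  fibrotic sites shield their occupants entirely. Stiff scar carries the
  load — this is the cell-scale reflection of the very
  inflammation-to-stiffening feedback the pipeline applies at tissue scale,
  and it is what lets a high-strain episode *terminate*: without it, the
  Michaelis–Menten suppression admits a smouldering nonzero steady state on
  a 10^4-site lattice, and the dead count never returns to zero.
* **The gate floor.** With a smooth gate the approach to the relief closure
  point is asymptotic (activation tends to zero exactly as fast as the
  fibrosis that would cross the threshold accrues — a Zeno tail). The
  all-or-nothing floor keeps the near-closure influx finite, so the closure
  point is crossed decisively and the episode ends in finite time, after
  which the gate is exactly zero forever (the fibrosis fraction never
  decreases).

Sub-threshold strain is absorbing quiescence with probability 1: no
macrophage can release, so TNF stays identically zero, so no transition can
ever fire — the agents simply random-walk.

### Calibration of the shipped defaults

The cellular parameter table of the source is not recoverable, and the
acceptance properties of the build act as the calibration constraints: under
the default three-airway case the G7 tissue must stay quiescent, the
G4-1-level ensemble must peak by step 2000 and resolve by step 10000, and
its peak must be about five times the G6-level peak. The default pipeline
strains are 6.98e-7 (G4-1), 3.59e-7 (G6) and 1.73e-7 (G7), so `eps_act` is
placed between the G7 and G6 strains and `eps_sat` below the G4-1 strain:
G7 is below threshold, G6 activates near the gate floor, G4-1 is fully
activated. The five-fold ratio is dominated by the gate ratio; its main
confound is that the heal/fibrosis exit rates depend on TGF, which itself
scales with activity and compresses the ratio — hence the small heal
half-saturation, which saturates healing at both activity levels. The
remaining rates were set so that the high-strain episode burns through its
relief-closure fibrosis budget within a few thousand steps. The calibrated
values are the documented defaults of `ca_params()`; they were fixed once
against these constraints and are asserted on the defaults by the test
suite. One CA step is abstract "simulation time", as in the source
framework; no real-time unit is assigned.

## The coupled case study

`run_case_study()` monitors the airways G4-1, G6 and G7 (labels address
branches as generation-index pairs; in a symmetric tree all branches of a
generation are identical, so G4-1 is simply a generation-4 branch). For each
airway it runs the CA at that airway's strain, summarises the trace
(`summarize_response()`: peak, peak step, resolution step, area under the
curve), computes the fibrosis fraction at the final step, stiffens the
Neo-Hookean layers, and re-solves the wall. Coupling is one-way with a
single feedback pass — no fixed-point iteration — matching the sequential
component architecture. The report carries both the immune-response fold
change across airways and the strain fold change after feedback, so the
qualitative claim that compliance changes less dramatically than immune
response can be checked as an inequality.

```{r case-study, eval = FALSE}
cfg <- default_config(seed = 1)
report <- run_case_study(cfg)
report
```

## What the synthetic world does and does not establish

There are no external data: the morphology fixture, the waveform and the
parameter defaults *are* the stated world. A green test establishes internal
correctness (the PDE update against the heat kernel, the wall solver against
the Lamé closed form, conservation and monotonicity properties, the
calibrated orderings) — not quantitative agreement with any patient or
bench measurement. Features of real data deliberately not emulated include:
airway asymmetry and patient geometry, turbulent and inertial pressure
losses (the lumped Poiseuille drops are of order 10 Pa, far below the
cmH2O-scale pressures of a clinical ventilator circuit, so the absolute
strain scale is correspondingly small and the activation threshold is
calibrated, not measured), mucosal folding and buckling of the wall,
viscoelasticity, additional cytokines, and any real-time calibration of the
CA step.

## Known limitations

* The G6-level episode in this calibration terminates early via the relief
  closure rather than oscillating for the whole window as the source
  narrative describes; only its ordering and magnitude relative to G4-1 and
  G7 are asserted.
* The fibrosis pathway (dead-residence time, TGF threshold, relief closure)
  is an invention documented above; other closures consistent with the
  qualitative rules exist.
* The feedback gain alpha is exposed as a free configuration parameter; the
  source does not quantify the loop magnitude.
* Pressures are gauge pressures relative to the outlet; only drops are
  physical in a Poiseuille network.
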