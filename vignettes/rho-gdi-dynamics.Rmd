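---
title: "Transient versus sustained Rho activation: the GDI-integrated cycle model"
author: "rhocycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient versus sustained Rho activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhocycle)
```

## The model

Rho GTPases are binary switches: GEFs catalyse GDP→GTP exchange (switch
on), GAPs stimulate GTP hydrolysis (switch off), and RhoGDI holds both
nucleotide states in cytosolic complexes. The classical picture treats GDI
purely as a sequestering buffer. `rhocycle` implements, alongside that
canonical cycle, a *GDI-integrated* cycle in which free
(non-GTPase-complexed) GDI additionally binds GEFs and GAPs directly and
suppresses their catalysis. Because an inhibitor that binds enzyme and
enzyme–substrate complex equally rescales only the maximal velocity, this
direct interaction is modelled as classical non-competitive inhibition:

$$v = \frac{k_\mathrm{cat}\,[E]\,[S]}{K_m + [S]}\cdot\frac{1}{1 + [\mathrm{GDI}]_\mathrm{free}/K_i}$$

with separate inhibition constants for the two enzymes, `Ki_GEF_GDI` and
`Ki_GAP_GDI` (μM). The eleven species and eight reactions are:

| id  | reaction | law |
|-----|----------|-----|
| re1 | GDI + GDP-Rho ⇌ GDI·GDP-Rho | mass action, reversible |
| re2 | GDI + GTP-Rho ⇌ GDI·GTP-Rho | mass action, reversible |
| re3 | GTP-Rho + Effector ⇌ GTP-Rho·Effector | mass action, reversible |
| re4 | GDP-Rho → GTP-Rho (enzyme: active GEF) | Michaelis–Menten, non-competitively inhibited by free GDI |
| re5 | GTP-Rho → GDP-Rho (enzyme: GAP) | Michaelis–Menten, non-competitively inhibited by free GDI |
| re6 | Stimulus + inactive GEF → active GEF | mass action, irreversible |
| re7 | active GEF → inactive GEF | first order |
| re8 | Stimulus → ∅ | first order |

The activation readout is the GTP-Rho/effector complex concentration
(re3's product). Five totals are conserved (Rho, GDI, GEF, GAP, effector);
the stimulus alone decays. The stimulus module re6–re8 is the simplest
mass-action mechanism that converts an impulse of stimulus at $t=0$ into a
decaying pulse of active GEF; the package models stimulation as an
initial-condition impulse (`Stimulus_0` added to the resting state), which
keeps the right-hand side autonomous and needs no event handling.

The four variants differ only in the inhibition constants: `canonical`
sets both to the `Inf` sentinel (factor ≡ 1), `gdi_integrated` keeps both
finite, `no_gdi_gef` / `no_gdi_gap` knock out one each. Using a sentinel
rather than deleting reactions means every variant runs the identical
code path, and the equivalence `canonical ≡ gdi_integrated(Ki = ∞)` is an
exact, testable identity.

## Why GDI/GAP inhibition sustains activation

After the GEF pulse subsides, active Rho decays at a rate proportional to
the uninhibited GAP flux times the fraction of active Rho that is free
GTP-Rho (most of it is buffered in the effector and GDI complexes). The
GDI-integrated model divides that decay rate by $1 + [\mathrm{GDI}]_\mathrm{free}/K_i$:
at the baseline free GDI of 0.7 μM and $K_i = 0.1$ μM the factor is 8;
at $K_i = 0.01$ μM it is 71. A decay that completes well inside a 600-min
window in the canonical model therefore stretches to a plateau lasting
thousands of minutes — activation outlives the stimulus by orders of
magnitude without any positive feedback loop. The same inhibition acting
on the GEF only scales the activation *level* (the pulse is over before
slow decay matters), which is why removing the GDI/GEF interaction changes
the amplitude (~2-fold up) but not the shape, while removing the GDI/GAP
interaction abolishes the sustainment.

## Parameters

Units are μM and min throughout. Concentration values with stated
provenance: resting free GDI 0.7 μM (estimated cellular free RhoGDIα, and
the default `GDI_free_excess`), inhibition constants scanned over
{0.01, 0.1, 1.0} μM with baseline 0.1 μM, GEF/GAP pools scanned over
{0.1, 0.3, 0.9} μM with baseline 0.3 μM, free-GDI scans on [0, 2.4] μM
(9 evenly spaced points by default), horizons 600, 1,800 and 12,000 min.

The remaining constants are calibrated defaults, chosen once against the
six qualitative behaviours in `check_behaviors()` and then frozen
(provenance: `tools/calibrate-defaults.R` in the source tree):

* `kon_re1/koff_re1 = 10/0.1` (Kd 0.01 μM): GDI binds GDP-Rho tightly, so
  >98% of Rho rests in the GDI·GDP-Rho complex.
* `kon_re2/koff_re2 = 10/1` (Kd 0.1 μM): GDI binds GTP-Rho two decades
  more weakly — the controversial interaction is present but modest.
* `kon_re3/koff_re3 = 10/1` (Kd 0.1 μM): sub-μM effector binding makes
  the readout an ~linear reporter of free GTP-Rho.
* `kcat_GEF = 100`/min, `Km_GEF = 0.5` μM: exchange is fast enough that
  activation is limited by the supply of free GDP-Rho (`koff_re1`), the
  regime in which removing GEF inhibition doubles rather than ×8 the peak.
* `kcat_GAP = 0.3`/min, `Km_GAP = 1` μM: sets the post-pulse decay scale —
  canonical half-decay ≈ 260 min (transient inside 600 min), ×8 inhibition
  → sustained past 600 min, ×71 → past 12,000 min.
* `k_stim_act = 10`/(μM·min), `k_gef_deact = 0.05`/min,
  `k_stim_decay = 0.1`/min, `Stimulus_0 = 0.1` μM: a GEF pulse that peaks
  within ~20 min and is gone by ~150 min.
* Pools: `Rho_total = 1`, `Effector_total = 1` μM.

`GDI_total` is not a parameter: the model is parameterised by the free-GDI
excess, and the total is derived. Because the resting state contains no
GTP-Rho, only the re1 equilibrium partitions GDI, giving the closed form
`GDI_total = g + Rho_total·g/(Kd1 + g)` for target free GDI `g`; the
resting state is then relaxed numerically to `max |d/dt| < 1e-10` μM/min
and the realised free GDI verified within 1% of the target. A target of 0
(the "no free GDI" scan point) implies no GDI in the system, since a
binding equilibrium with zero free ligand and non-zero complex does not
exist at finite Kd.

## Numerical choices

* Integration: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10` μM.
  The binding reactions are fast relative to the 12,000-min horizons, so a
  stiff-capable solver is required; halving the tolerances changes the
  activation series by <0.1% (tested).
* Conservation: each of the five totals must stay within 1e-6 μM of its
  initial value along every reported trajectory; a breach aborts rather
  than warns. Solver undershoot below −1e-8 μM also aborts; smaller
  negative excursions are clipped to 0 in reported states only.
* Steady state: relaxation in doubling windows until
  `max |d/dt| < 1e-10` μM/min, within a 10,000-min budget; used for the
  pre-stimulus resting state, and idempotent by construction.
* Metrics: the half-decay time is the first post-peak crossing of 50% of
  peak, linearly interpolated between grid points ("not reached" → `NA`);
  AUC by trapezoid; the *sustained ratio* is the readout at the 600-min
  reference divided by the peak, and "sustained" means ratio ≥ 0.5
  (`SUSTAINED_RATIO_THRESHOLD`, the single shared definition). Peak, not
  AUC, operationalises the "overall level"; AUC is reported alongside.
* Default grids: 1-min output steps up to 2,400 min, 5-min steps beyond;
  metric values change <0.5% under grid doubling (tested).

## The perturbation generator

The unprinted constants being calibrated rather than measured, the
robustness machinery re-draws them log-uniformly within ±`spread` decades
(default 0.5; the robustness report uses 0.25) around the baseline,
holding the stated-provenance values fixed, and re-evaluates the six
qualitative behaviours per draw. This emulates parameter uncertainty
only: it does not emulate structural error (membrane/cytosol shuttling,
intrinsic exchange/hydrolysis, multi-GTPase competition are all absent),
so passing fractions speak to the robustness of the *model comparison*,
not to the fidelity of any one rate constant in real cells. Draws are
deterministic under a single integer seed and the caller's RNG state is
restored.

## Problem sizes used by the tests

The test suite runs the four-variant comparison at 1-min resolution over
600 min, the free-GDI scan at 9 (acceptance) or 3 (unit) grid points over
600/1,800 min, both 3×3 grids, the Ki×free-GDI grid at 3×3–5 points over
600/12,000 min, the fixed-step RK4 oracle at dt = 1e-3 min over 10 min,
and a 2-draw zero-spread robustness report; the acceptance script adds an
8-draw report at spread 0.25. These sizes reproduce every qualitative
regime of the full figures while keeping a complete run in tens of
seconds.

## Known limitations

* No membrane–cytosol shuttling, prenylation or extraction kinetics: the
  cycle is treated as a well-mixed basal signalling module.
* No intrinsic (uncatalysed) exchange or hydrolysis; with the stimulus
  gone and GEF inactive, activation ultimately decays to zero — "sustained"
  is a very slow decay, not a bistable state.
* Deterministic ODEs only; no stochastic simulation.
* SBML import interprets core SBML elements only (CellDesigner annotation
  namespaces are ignored); species are mapped by a user-extensible alias
  table and reactions by reactant/product signature, so models with a
  different topology import only partially, with warnings.

## A minimal session

```{r example, eval = FALSE}
p <- default_parameters()
out <- fig_variant_timecourses(p)
out$summaries

net <- build_variant("gdi_integrated",
                     set_parameters(p, Ki_GAP_GDI = 0.01))
traj <- simulate_trajectory(net, t_end = 12000, n_points = 2401)
summarize_activation(traj, reference_times = c(600, 12000))
plot_activation(out$trajectories)
```
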