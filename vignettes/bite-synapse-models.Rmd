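---
title: "Modelling BiTE-induced immunological synapse formation with bitesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling BiTE-induced immunological synapse formation with bitesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bispecific T cell engagers (BiTEs) such as blinatumomab redirect CD3+
effector T cells against CD19+ B-lineage target cells. Cytolysis requires a
stable immunological synapse (IS), and at the cell-population level IS
formation is the product of three distinct processes operating on different
scales:

1. **Soluble-phase ("3D") binding.** The BiTE binds CD3 (arm A) and CD19
   (arm B) as two competing ligands, producing binary complexes AY and YB.
2. **Cell–cell encounter.** A freely diffusing effector must physically meet
   a target cell; this is a density- and motility-limited process.
3. **Cell–cell adhesion ("2D" binding).** During a brief contact
   (0.1–5 s), membrane-confined ternary complexes (CD3–BiTE–CD19, the
   "bonds") must form in sufficient numbers to stabilise the contact into a
   synapse.

`bitesim` implements this three-step picture as stochastic agent-based
simulators at three nested horizons: a **base model** (≤1 h, engagement
only), an **in vitro model** (≤72 h, serial engagement, killing and CD19
antigen-escape evolution) and an **in vivo model** (organ compartments,
trafficking, turnover and dosing regimens).

## Step 1: competing-ligand equilibrium

At total molar concentrations `A_tot` (CD3), `B_tot` (CD19) and `Y_tot`
(BiTE), rapid equilibrium with dissociation constants `KD_A`, `KD_B` gives

```
Y + A_tot*Y/(KD_A + Y) + B_tot*Y/(KD_B + Y) = Y_tot
```

for the free ligand `Y`. The left side is strictly increasing in `Y`, so the
unique physical root on `[0, Y_tot]` is found by bracketing plus a Newton
polish (`solve_equilibrium()`); conservation holds to 1e-9 relative and a
fixed-point iteration is used as an independent oracle in the tests.
Membrane receptors enter this solution-phase step as well-mixed solutes in
the co-incubation volume (`counts_to_molar()`); the reverse convention — per
ng/mL dosing — uses a 54 kDa molar mass.

Ternary complexes do **not** form in solution; `occupancy_curve()` exposes
the crosslinking potential `occA*(1-occB) + occB*(1-occA)`, which is
bell-shaped in `Y_tot`: at high BiTE both antigens are saturated by separate
BiTE molecules and crosslinking collapses. This is the molecular origin of
the bell-shaped dose–response.

Default rate constants are `kon = 1e5 /M/s` for both arms with
`KD_CD3 = 2.6e-7 M` and `KD_CD19 = 1.49e-9 M` (literature values for
blinatumomab); all four rates are configurable and the CD3 affinity sweep in
the acceptance suite varies `koff_A` over three decades.

## Heterogeneous populations

Per-cell receptor numbers are drawn log-normally (`generate_population()`),
the standard flow-cytometry convention, with the arithmetic mean matching
the configured expression level and a log-space SD of 0.3 for sorted
subpopulations (0.5 for unsorted patient B cells). Defaults: CD19
L/M/H = 3e4/1.45e5/3e5 per cell (M is the measured Raji medium-expression
value; H sits at the level beyond which additional CD19 no longer improves
lysis), CD3 L/M/H = 5e4/1e5/2e5 per cell for the sorted Jurkat gates. Bulk
binary complexes are distributed to cells in proportion to each cell's
antigen total (a binomial sampling option exists behind
`sim_params(allocation = "binomial")`), so the summed per-cell complexes
close against the bulk equilibrium exactly.

Two receptor programmes run during incubation:

* **CD3 downregulation** — the loss rate is driven by the per-cell
  CD3–BiTE complex level through a saturable drive
  `occ = AY'/(K + AY')` with `K = 500` complexes/cell; the cumulative loss
  approaches `fmax * occ * baseline` (`fmax = 0.7`) with first-order rate
  `0.06/min`, which places the plateau at roughly one hour. The incremental
  update is exact for a constant drive, so 60-s and 1-s stepping agree.
* **CD19 internalization** — first-order decay of the bound pool at
  `0.002/min`, applied in the base model only; the longer-horizon models
  drop it and instead re-solve the bulk equilibrium hourly.

## Step 2: encounter probability

Effectors perform Brownian motion among immotile targets. The per-round
(60 s) probability that a free effector meets at least one target at density
`C` is

```
P_e = 1 - exp(-s * kbar * C * dt),
kbar = 4*pi*D*R * (1 + 2R/sqrt(pi*D*dt)),   R = r_E + r_T
```

i.e. the Smoluchowski diffusion-limited rate including its transient term,
time-averaged over the round. The transient term matters here: each round
re-randomises positions (cells that fail to adhere diffuse away), which is
exactly the uniform-start condition under which the transient form is the
correct mean encounter count. The tests verify the formula against a
brute-force random-walk simulation among absorbing spheres.

The default diffusion coefficient, 0.03 um^2/s, is the Stokes–Einstein
thermal diffusivity of an 11–13 um suspension cell in culture medium at
37 °C; cell radii default to 5.5 um (effector) and 6.0 um (target).

Engaged entities move as single units. Their encounter rate carries a
spatial coefficient per size class (`spatial_coefficients`): 1 for a free
effector by convention, 1.35 for two-cell and 1.5 for three-cell entities,
encoding the larger encounter radius of a multi-cell cluster. A separate
mobility weighting applies to what an entity can recruit: meeting a mobile
free effector is a two-mobile-party encounter and runs at roughly twice the
rate (relative diffusion ~2D) of meeting an immotile target, and the
recruitment partner choice is weighted accordingly. Both knobs are
deliberately config-loaded, not fitted.

## Step 3: adhesion probability

On encounter, a contact patch of 3 um^2 (a small spherical-cap apposition)
is held for a uniformly drawn 0.1–5 s. 2D rate constants come from the
single-step confinement model: `kon2D = kon3D/(N_A * h)` with confinement
length `h = 10 nm`, and `koff2D = koff3D`. Bond formation on the patch is
mean-field mass-action over five species (free CD3, CD3–BiTE, free CD19,
CD19–BiTE, and the ternary bond) with two production channels
(`A + YB`, `AY + B`), dissociation of either arm returning its
constituents, and explicit reactant depletion — so the bond count can never
exceed the lesser side's available partners. The system is integrated by a
step-adapted RK4 and checked against a Gillespie stochastic simulation of
the same scheme.

Adhesion then follows the small-system adhesion-frequency law

```
P_a = 1 - exp(-alpha * N)
```

strictly increasing in the bond count `N`. `alpha` is **the** calibrated
parameter of the whole model family: `calibrate_alpha()` grid-searches it
against observed engagement fractions (the shipped calibration set is the
four printed engagement values at 1 and 8 million cells/mL under 20 and
100 ng/mL), minimising squared log-ratios. The package default
`alpha = 0.00316` is the output of that calibration at the default grid.
Because adhesion depends on each target's own CD19 through `N`, low-CD19
cells adhere less — the mechanism that later drives antigen escape.

## The round loop (base model)

Each 60-s round: (1) encounter probabilities are recomputed from current
free-cell densities; (2) every free effector gets one encounter chance, and
encountering effectors claim distinct free targets in shuffled order (ties
resolved first-come); each claimed pair draws a contact and adheres with
`P_a`, otherwise both stay free; (3) entities existing at the round start
(sizes 2–3) may recruit one free cell, chosen effector vs target in
proportion to the mobility-weighted free pools, tested by the same adhesion
machinery against
a random exposed member of the opposite role; entities never exceed four
cells; (4) receptor updates run. Synapses are unbreakable within the hour
and the binding equilibrium is frozen. Compositions are labelled
ET, ETE, ETT, ETET, ETEE, ETTT.

The simulated subvolume defaults to 0.1 uL, so 1e6–8e6 cells/mL becomes
100–800 agents; probabilities are driven by densities, never agent counts,
so the subvolume only sets Monte-Carlo resolution. A 10-replicate, 60-min,
800-agent run takes a few seconds.

## Serial engagement and antigen escape (in vitro model)

Beyond one hour, synapses dissolve 150 min after formation: all target
members are lysed (their CD19 at death is recorded) and all effector
members return to the free pool — serial killing. The bulk equilibrium is
re-solved hourly from surviving antigen totals, CD3 downregulation is
frozen after the first hour, CD19 internalization is off, and the BiTE
concentration is constant. Because adhesion increases with CD19, killing
preferentially removes high-expressing targets and the survivor CD19
distribution drifts downward — faster at higher BiTE concentrations and
densities. `evolution_summary()` reconstructs survivor distributions at any
snapshot time from the kill records, and `organ_grid_lysis()` maps 72-h
lysis over effector/target density grids.

A design point left open by the round rules: an entity may keep recruiting
up to four cells during its 150-min lifetime; we keep the base-model rule
unchanged.

## Organ compartments, trafficking and dosing (in vivo model)

Seven compartments (blood, bone marrow, lymph nodes, spleen, lung, gut,
remainder) carry fixed volumes, B- and T-cell partition fractions and
exposure scalings. The blood is a trafficking route only — the constructor
rejects any configuration in which blood forms synapses. The default
partition repertoire and volumes are package defaults assembled from
standard human lymphocyte distribution data (2% of lymphocytes in blood;
lymph nodes and spleen T-cell-rich and dense; bone marrow effector-poor);
they are deliberately editable because organ-level censuses vary widely.

The hourly loop per organ: the infusion schedule sets the concentration
(steady state = rate/clearance, default clearance 1.8 L/h so the 28 ug/day
step of the approved schedule gives ~0.65 ng/mL); the equilibrium is
re-solved from organ antigen totals; each free B-cell agent then runs its
hour of 60 encounter rounds in closed form — per-round encounter
probability from the organ's free T-cell density times its own
CD19-dependent adhesion probability — and engaged B cells are lysed 150 min
later, releasing their T cells. Engagements are capped by the free T-cell
pool. B cells then traffic (4.17%/h released through the blood and
multinomially reassigned by the partition repertoire, which conserves cell
number exactly) and grow exponentially. Growth scales a global per-agent
weight, so turnover is exact and daughters inherit CD19 — evolution is pure
selection. T-cell dynamics are exogenous: a baseline T:B ratio plus an
optional time-varying multiplier; T-cell death and trafficking are not
modelled. IS variants are not tracked in vivo since killing does not
distinguish them; this closed-form treatment of the inner rounds is what
keeps 22-week courses tractable (minutes, not hours).

Dosing presets follow the approved step-up pattern (high: 9 ug/day in week
1 of cycle 1, then 28 ug/day; medium: 9 then 15; low: 5), with scheme 1
infusing weeks 1–4 and scheme 2 weeks 1–3 of each 6-week cycle. The
numeric preset values are editable package presets. `rank_regimens()`
orders completed courses lexicographically: killing efficacy (log10 burden
reduction, tolerance 0.3), then CD19 evolution (final survivor-mean CD19
relative to baseline, tolerance 5%), then total dose.

## What the synthetic generator does and does not emulate

The population generator reproduces log-normal surface-expression
heterogeneity, E:T composition, densities and dosing — the inputs the model
is sensitive to. It does not emulate: adhesion-molecule variation (CD2,
integrins — assumed constant), intracellular activation signalling,
chemokine-directed motility, killing-efficiency differences between variant
types, or transcriptional CD19 regulation (escape here is selection on a
static per-cell expression). Passing tests therefore demonstrate internal
consistency of the three-step mechanism and reproduction of the reported
population-level outputs, not molecular completeness.

## Numerical choices and degenerate inputs

* Equilibrium: bracketed root + Newton polish; validation raises on any
  conservation or mass-action residual above 1e-9 relative; `Y_tot = 0` and
  `A_tot = B_tot = 0` short-circuit analytically.
* Bond ODE: RK4 with step size adapted to the fastest production channel,
  nonnegativity clamping, and a hard cap at the lesser side's partner count.
* Encounter probability clamps to [0, 1]; zero density gives exactly 0.
* Deterministic replication: every replicate derives its seed from the run
  seed (kept below 2^31); identical config + seed reproduces outputs
  bit-for-bit.
* Empty populations, zero-kill evolution summaries and zero-entity variant
  summaries return typed empty/NA sentinels rather than erroring.

## Problem sizes used by the test and acceptance suites

Replicated runs use the 0.1 uL subvolume (100–800 agents), 5–40 replicates
per condition, 2-week in vivo horizons with 2000 B-cell agents, and
oracle sizes of 10^3–10^4 (Gillespie runs, random walkers, random
equilibrium draws). These sizes were chosen so the full suite exercises
every mechanism at Monte-Carlo resolutions that clearly separate the tested
effects.

## Known limitations

Mean-field bond kinetics on small patches ignores fluctuation corrections
(verified small against Gillespie at the tested sizes); the in vivo model
treats each organ as well mixed; T-cell exhaustion and proliferation are
exogenous; partition repertoires, organ volumes and dosing presets are
editable defaults rather than fitted quantities; and the clinical B-cell
trajectories that motivated the model are not shipped — the acceptance
surfaces are the reported simulation outputs and the model's internal
properties.
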