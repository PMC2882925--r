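---
title: "The colony automaton: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The colony automaton: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonysim)
```

## The model

`colonysim` implements a one-dimensional continuous cellular automaton for
the cross-section of a bacterial colony growing on solid substrate. A row
of `L` sites represents the projection of the colony onto the substrate
surface. Each site holds a discrete bacterial layer thickness (0 to `N`
bacteria), a cell state, and — only while in early stationary phase — an
integer age. Two continuous variables close the loop between sites: the
per-site concentration of a substrate-diffusible *quorum* signal, and a
single *odor* level shared by the whole dish (the volatile signal is
emitted to the gas phase and re-absorbed everywhere, so spatial structure
in it is ignored by construction).

Cells pass through four states. Exponentially growing cells (state 1)
double each generation, spread into adjacent empty sites, and produce
quorum at rate `P` per bacterium. When the local quorum reaches `Qlim`, or
the site reaches the thickness ceiling `N` (a proxy for nutrient
limitation), the site enters early stationary phase (state 2), producing
quorum at the elevated rate `S * P` per bacterium for `A` generations
before maturing. Mature stationary cells (state 3) are absorbing: they
stop producing quorum and emit odor at rate `O` per bacterium into the
global pool. Growing and early-stationary cells that experience odor at or
above `Olim1` switch to a refractory growing state (state 4): they divide
(resuming division, if they had stopped), ignore the quorum signal, and
produce no signals, until either the thickness ceiling or the second odor
threshold `Olim2` sends them to state 3. When every occupied site is
mature the colony can never change again, which is the natural termination
point of a run.

Each generation applies four steps in a fixed order: state evaluation,
division and daughter migration, signal production, and quorum diffusion.
Diffusion is an explicit nested scheme: `G` iterations per generation, each
moving a fraction `D` of the concentration difference of every adjacent
site pair down the gradient, all fluxes computed from the iteration's
starting values. The model is fully deterministic — there is no random
number anywhere in the dynamics.

## Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `N` | maximum layer thickness | bacteria/site | 140 |
| `P` | quorum production, growing cells | quorum/bacterium/generation | 1 |
| `S` | stationary/exponential production ratio | — | 10 |
| `A` | early-stationary window | generations | 5 |
| `O` | odor production, mature cells | odor/bacterium/generation | 0.01 |
| `D` | diffused fraction per iteration | — | 0.495 |
| `G` | diffusion iterations per generation | — | 5 |
| `Qlim` | quorum limit for growth inhibition | quorum | 1000 (tuned) |
| `Olim1` | odor limit for reactivation | odor | 100 (tuned) |
| `Olim2` | odor limit for growth arrest | odor | 1000 (tuned) |
| `L` | lattice length | sites | 201 |

The first seven rows are the reference rates of the rimmed clone. The
three sensitivity thresholds are *not* fixed by the rates: they are
reported only graphically in the source material, so this package treats
them as tunable and ships a triple found by the documented grid search
(`tune_thresholds()`), with provenance recorded as "tuned, not printed" in
the shipped configuration files.

`D` must lie in `[0, 0.5]`: the explicit pairwise exchange overshoots and
oscillates for larger fractions. At `D = 0.495`, close to the stability
edge, a pair nearly equalizes each iteration, which is the intended
fast-but-local spreading of the substrate signal.

## Threshold tuning and the shipped defaults

`tune_thresholds()` runs every `(Qlim, Olim1, Olim2)` combination of a
logarithmic grid (spanning roughly 0.1-2 times the scales implied by the
production rates: quorum accrues at up to `S*P*N` per site per generation,
odor at `O*N` per mature site per generation) from a single planted site,
and keeps the triples whose run terminates and classifies RIMMED. The full
phase table is returned for audit. Many triples are feasible; the shipped
default (`Qlim = 1000, Olim1 = 100, Olim2 = 1000`) was selected from the
feasible set as the member with the most balanced navel / interstitial /
rim anatomy, and it also reproduces the planting-geometry phenomenology
(confluence of close pairs, macula onset at the control colony's
interstitial outer diameter). The shipped rimless triple differs only in
an effectively infinite `Qlim` — a quorum-insensitive clone — which
matches the interpretation that rimless clones perceive the same signals
differently rather than producing different ones.

## Design choices where the dynamics were underdetermined

* **Synchronous update.** All state evaluations and all diffusion fluxes
  within a step are computed from the step's starting snapshot and applied
  at once. A sequential sweep would break left-right symmetry.
* **Transition precedence.** The odor trigger (states 1-2 to 4) is checked
  before the quorum/thickness trigger (1 to 2), because refractory cells no
  longer respond to quorum: when both triggers co-occur, reactivation wins
  and the cell keeps growing.
* **Age bookkeeping.** Age is set to 0 on entering state 2 and incremented
  during each subsequent evaluation; maturation fires when `age >= A`, so
  a site spends its entry generation plus `A` further full generations in
  early stationary phase.
* **Division quantum.** Growing sites double (`t -> min(2t, N)`); the
  migrating daughter is one bacterium. Donors lose one bacterium per
  exported daughter (floored at thickness 1). Whether the daughter should
  instead be created without debiting the donor is genuinely open; the
  `decrement_donor` parameter toggles it.
* **Colonization rules.** An empty site adjacent to a growing site gains
  exactly one bacterium and the colonizer's state. A quorum-sensitive
  (state 1) colonizer is blocked when the *target's* quorum is at or above
  `Qlim`; a refractory colonizer ignores quorum but is blocked at odor
  `>= Olim2`, mirroring each state's sensitivities. When both neighbors
  could colonize, the left one donates. This deterministic tie-break is
  the one place the dynamics are not mirror-symmetric: a single shared
  empty site between two growing fronts is colonized from the left. No
  single-clone scenario in the package produces that configuration (ring
  gaps shrink by two sites per generation), so symmetric inocula develop
  symmetrically in practice, and the symmetry tests use such inocula.
* **Boundaries.** Zero-flux walls for diffusion, no colonization off the
  lattice: a dish wall neither absorbs nor supplies signal.
* **No signal decay.** Neither signal decays or is consumed; conditioned
  substrate keeps its activity on the timescale of a run.
* **Odor bookkeeping.** The per-generation odor reported in traces is the
  end-of-generation value (after production). Odor is cumulative; an
  instantaneous reading would also be consistent with the source
  figures, but cumulative pooling is the simpler mechanism that yields
  the observed sigmoid rise.
* **Termination.** The all-mature test runs after each full generation and
  once on the initial lattice, so an all-mature inoculum terminates at
  generation 0.

## Phenotype classification

The classifier works on the final thickness profile of a terminated run.
Occupied sites are TALL when `thickness >= tall_fraction * N` (default
0.5) and THIN otherwise; maximal runs become zones. Within a connected
colony the tall runs are read outward from the center: a single tall run
is a navel; of two, the more central is the navel and the other the rim;
of three or more, the outermost pair is the rim and every interior tall
run a navel — two or more navels under one rim pair mark a confluent
body. Thin runs between navel and rim are the interstitial ring; thin
colonization fringes outside the outermost rim fold into it, so zone
diameters always add up to the colony diameter. The `tall_fraction` knob
is the honest encoding of the fact that no quantitative navel/rim
thickness criterion exists in the source material; any mid-range cut
separates the near-maximal navel and rim from the flat ring.

Classification then maps anatomy to phenotype: navel + ring + rim is
RIMMED; a single tall zone with monotonically decaying flanks (plateaus
allowed — discrete thickness makes strict monotonicity brittle) is
RIMLESS, or MACULA when the plateau is wider than the reference diameter
supplied by the caller (the sweep driver passes the rimmed control's
interstitial outer diameter); a sub-cut peripheral rebound is reported as
RIMMED with an `imperfect_rim` flag rather than a separate class; bodies
below five occupied sites are UNDEVELOPED. Colonies are separated by even
a single empty site.

## Numerical behavior

Total quorum is conserved by construction (pairwise antisymmetric fluxes);
the tests bound the relative error at `1e-9` and observe it at zero. The
net-flux formulation (`q + (inflow - outflow)`) makes mirrored fields
diffuse bit-identically, so symmetric inocula yield bit-identical mirrored
traces. Runs are bit-reproducible across repetitions. Shifting an
inoculum shifts thickness and state profiles exactly; the quorum field
agrees to the field scale (about nine significant digits) rather than
bitwise, because the far tails of the diffusion field reach the
differently-placed walls at trace amounts.

## Problem sizes

The shipped configurations use `L = 201` (single colonies) or `L = 301`
(encounters and sweeps), where the reference colony spans 81 sites and
matures in 41 generations, leaving ample wall clearance. The tuning grid
is 4 x 4 x 4 threshold triples. The oracle cross-check runs the optimized
generation step against a scalar-loop transcription on 1000 randomized
lattices of up to 30 sites. These sizes were chosen so that any scenario
in the package runs in seconds on a laptop while still being an order of
magnitude larger than the structures being measured.

## What the simulations do and do not show

The automaton reproduces, from one mechanism, the qualitative repertoire
of colony forms: finite growth with three-zone anatomy, rimless domes from
altered sensitivities alone, mutual inhibition and confluence of
neighboring colonies, and the loss of ring and rim with increasing
planting size. It does not model chemical identity of either signal,
nutrient fields, swarming, two-dimensional geometry (ring plantings enter
only as their two-block cross-sections), multi-clone encounters, or any
stochastic variability — so quantitative agreement with measured colony
dimensions, and any phenomenon resting on the excluded mechanisms (e.g.
azimuthal patterning), is outside what passing tests can demonstrate about
real plates.
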