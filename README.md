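# colonysim

Simulation of bacterial colony cross-section morphogenesis as a
one-dimensional continuous cellular automaton, for microbiologists and
modelers studying how a colony of a single clone can build a finite,
internally patterned multicellular body — a central *navel*, a flat
*interstitial ring* and a massive peripheral *rim* — and why the same
machinery can instead produce rimless colonies, fused (confluent) bodies, or
structureless *maculae* when plantings are large or dense.

## The model

The dish is a row of `L` lattice sites. Each site carries a bacterial layer
thickness `t` (0 to `N` bacteria), a cell state, and — while in early
stationary phase — an age. Two signals couple the sites:

* a **quorum** signal diffusing slowly through the substrate
  (concentration `q_i` per site), and
* a volatile **odor** signal, pooled instantly across the whole dish
  (a single level `w`).

Cells move through four states:

1. **Exponential growth** — thickness doubles each generation (capped at
   `N`), one daughter migrates into an adjacent empty site; produces quorum
   at rate `P·t`.
2. **Early stationary** — entered when `q_i ≥ Qlim` or `t = N`; produces
   quorum at the elevated rate `S·P·t` for `A` generations.
3. **Mature stationary** — absorbing; stops producing quorum and emits odor,
   `w ← w + O·Σt` over all mature sites.
4. **Refractory growth** — entered from states 1-2 when `w ≥ Olim1`;
   divides while ignoring quorum and producing nothing, until `w ≥ Olim2`
   or `t = N` sends it to state 3.

Each generation applies, in order: state evaluation, division and
migration, signal production, and `G` iterations of pairwise quorum
diffusion (`D` = fraction of each concentration difference exchanged;
zero-flux dish walls). Everything is deterministic.

The interplay produces rimmed colonies from a single planted site: early
growth builds the navel, quorum accumulation flattens the spreading margin
into the interstitial ring, and the odor released by the maturing center
reactivates the margin into the thick rim before the second odor threshold
arrests everything. Changing only the three sensitivity limits
(`Qlim`, `Olim1`, `Olim2`) yields rimless domes; paired plantings pool
their odor and arrest each other early; over-wide plantings skip the ring
and grow to maculae.

## Worked example

```r
library(colonysim)

cfg <- load_config(default_config_path())   # reference rimmed clone
tr  <- run_simulation(build_inoculum(cfg$inoculum, cfg$params), cfg$params)
tr
#> Colony automaton trace: 41 generations on 201 sites
#>   terminated at generation 41 (all occupied sites mature)
#>   final extent 81 sites, biomass 8700, odor 1088.32

rep <- classify_phenotype(segment_zones(final_profile(tr), cfg$params), tr)
rep
#> Colony phenotype report
#>   classification: RIMMED
#>   colonies: 1; generations to maturity: 41
#>   zone diameters (sites):
#>         navel interstitial rim total
#> colony1    13            8  60    81
```

The colony stops growing on its own at generation 41 (every occupied site
mature), spanning 81 sites: a 13-site navel, 8 interstitial sites (the flat
ring — both flanks together), and 60 rim sites. `plot(tr)` draws the
thickness and quorum profiles and the size/odor time series.

Scenario drivers reproduce the planting-geometry experiments:

```r
scenario_rimmed_vs_rimless()   # rimless clone differs only in thresholds
scenario_encounters()          # paired colonies: smaller, sooner, confluent
scenario_inoculum_sweep()      # widening drops: navel grows, ring shrinks,
                               # rim lost -> macula
tune_thresholds()              # grid search behind the shipped thresholds
```

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/colonysim.R simulate --config inst/extdata/rimmed_point.yaml --trace run.tsv
Rscript inst/cli/colonysim.R classify --trace run.tsv --report report.yaml
```

## Scope

One clone per dish, 1-D cross-sections only, no stochasticity, no explicit
nutrient field, and no swarming motility. Ring plantings are represented by
their cross-sections (two blocks); multi-clone encounters are out of scope.
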