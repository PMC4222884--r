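# acetoflux

Constraint-based modeling of acetogenic metabolism in *Clostridium
ljungdahlii*: a flux balance analysis engine plus a curated, executable
core reconstruction of the Wood-Ljungdahl pathway and its energy
conservation machinery.

## Who this is for

Researchers studying acetogens (syngas fermentation, CO2 fixation,
metabolic engineering of *C. ljungdahlii* and relatives) who want a small,
fully auditable model of the organism's energy economy, and developers who
need a self-contained R implementation of the standard constraint-based
toolbox (FBA, FVA, parsimonious FBA, gene deletions, gap-filling) with an
exhaustively tested LP core.

## The model in brief

Flux balance analysis maximizes an objective flux over the steady-state
polytope

    max c'v   s.t.   S v = 0,   lb <= v <= ub

where S is the stoichiometric matrix (metabolites x reactions). The core
reconstruction encodes, exactly mass- and charge-balanced:

- the Wood-Ljungdahl pathway — FDH7, FTHFLi, MTHFC, MTHFD (NADP),
  electron-bifurcating MTHFR5, METR, net CODH/ACS — fixing 2 CO2 into
  acetyl-CoA at a cost of 1 NADPH + 1 reduced ferredoxin + 2 NADH + 1 ATP;
- energy conservation: the proton-translocating Rnf complex (2 H+ per
  ferredoxin), ATP synthase (4 H+ per ATP), the electron-bifurcating
  hydrogenase (NADP- or NAD-specific) and the Nfn transhydrogenase
  (2 NADPH <-> NADH + reduced ferredoxin);
- fermentation branches to acetate (with substrate-level ATP at acetate
  kinase), ethanol, lactate and 2,3-butanediol;
- the nitrate reduction pathway NO3 -> NO2 -> NH2OH -> NH4 (4 NADH per N);
- media presets for fructose, fructose + nitrate (ammonium-free), H2/CO2
  and CO.

Scenario functions reproduce the headline analyses: reducing-equivalent
audits per product, ATP yields at the Rnf/ATP-synthase couple, the
acetate-kinase knockout feasibility panel, the nitrate electron-sink
scenario, and substrate growth screens.

## Worked example

```r
library(acetoflux)

model <- buildCoreModel()                      # NADP hydrogenase default
sol <- fba(applyMedium(model, mediumPreset("h2_co2")))
sol
#> FluxSolution: optimal, objective = 0.0594059

reducingEquivalentAudit(model, "ethanol")
#> EquivalentLedger (demand view) per mol ethanol:
#>   NADH 4 | NADPH 1 | Fd 1 | total 6 equivalents; substrate-level ATP 1

energyGapAnalysis(model, mediumPreset("h2_co2"), "ethanol", "ackA")
#> EnergyReport:
#>   Rnf flux 3 -> 6 translocated H+ -> 1.5 ATP at the synthase
#>   ATP deficit 0 | surplus 0.5 | feasible for growth: TRUE

nad <- buildCoreModel(coreModelConfig(hydrogenase = "NAD"))
energyGapAnalysis(nad, mediumPreset("h2_co2", coreConfig(nad)),
                  "ethanol", "ackA")
#> EnergyReport:
#>   Rnf flux 1.5 -> 3 translocated H+ -> 0.75 ATP at the synthase
#>   ATP deficit 0.25 | surplus 0 | feasible for growth: FALSE
```

Reading: autotrophic growth on H2/CO2 is feasible (0.059 h^-1 with the
default lumped biomass). Producing one ethanol from CO2 demands six
two-electron reducing equivalents and one ATP. With acetate kinase deleted
the only ATP source is the proton gradient: the NADP-specific hydrogenase
routes 3 ferredoxin through Rnf, worth 1.5 ATP — enough (0.5 surplus) —
while the NAD-specific variant routes only 1.5, worth 0.75 ATP, leaving a
0.25 deficit: ethanol production without acetate kinase is infeasible on
H2 in that configuration, and feasible on CO either way (2.25 ATP).

Other entry points: `ackaPanel()` (the 2 x 3 feasibility matrix),
`nitrateScenario()` (nitrogen balance and acetate suppression under
nitrate), `substrateGrowthScreen()`, `singleGeneDeletion()`, `fva()`,
`gapfill()`, `randomFeasibleNetwork()` / `bruteForceLPOracle()` (engine
validation), `readModel()` / `writeModel()` (bundled JSON schema; the
shipped core model is at `coreModelFile()`), and `loadPublishedModel()`
for user-supplied genome-scale models (COBRA JSON or SBML-FBC). A thin
command-line front end lives at `inst/scripts/acetoflux-cli.R`.

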