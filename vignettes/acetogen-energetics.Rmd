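---
title: "Modeling acetogenic energy conservation with acetoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling acetogenic energy conservation with acetoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoflux)
```

## The modeling problem

*Clostridium ljungdahlii* is an acetogen: it fixes CO2 (or CO) into
acetyl-CoA through the Wood-Ljungdahl pathway (WLP) and conserves energy
while doing so, despite the pathway itself consuming one ATP at the
formate-THF ligase step. The organism lacks cytochromes and a sodium
gradient; its energy economy instead rests on flavin-based electron
bifurcation (the Nfn transhydrogenase, an electron-bifurcating hydrogenase,
and a bifurcating methylene-THF reductase) and on proton translocation by
the Rnf complex, whose proton-motive force drives the ATP synthase.

`acetoflux` provides (i) a general constraint-based modeling engine — flux
balance analysis (FBA) over the steady-state polytope
$\{v : S v = 0,\ lb \le v \le ub\}$, flux variability analysis (FVA),
parsimonious FBA, single-gene deletion screens and SMILEY-style
gap-filling — and (ii) a curated, executable core reconstruction of
*C. ljungdahlii* central metabolism on which the package's scenario
analyses run.

## The core reconstruction

The core model has 52 metabolites (cytosol `c` and extracellular `e`; no
periplasm) and 57 reactions: lumped glycolysis, pyruvate:ferredoxin
oxidoreductase, the complete WLP (ferredoxin-dependent formate
dehydrogenase `FDH7`, `FTHFLi`, `MTHFC`, NADP-dependent `MTHFD`,
bifurcating `MTHFR5`, `METR`, and the net `CODH_ACS` reaction), CO
oxidation (`CODH`), acetate, ethanol, lactate and 2,3-butanediol branches,
`RNF`, `ATPS`, the bifurcating hydrogenase `HYD` (NADP- or NAD-specific
per configuration), the Nfn transhydrogenase `NFN`, the nitrate reduction
pathway (`NTRARf`, `NTRIR5`, `HAMR` with proton-symport transporters), a
lumped biomass drain, a maintenance ATPase and exchange reactions.

Every non-exchange, non-biomass reaction is exactly elementally and charge
balanced over C/H/O/N/P/S/Fe using standard biochemistry formulas for the
THF-bound C1 carriers. Two conventions make the balance audit total rather
than partial:

* ferredoxin is a two-electron carrier pair with pseudo-formula `Fe2S2`
  (`fdxo` charge 0, `fdxr` charge −2), so one `fdxr` is one NAD(P)H-
  equivalent;
* the corrinoid iron-sulfur protein carries pseudo-formula `Fe4S4`
  (`mecfesp` adds CH3, charge +1), so the methyl transfer steps balance.

Cytosolic protons are a mass-balanced species with no free membrane leak;
extracellular protons, water and phosphate are freely exchanged. This is
what gives the Rnf/ATP-synthase couple its meaning: the only way to turn
reduced ferredoxin into proton-motive force is the explicit `RNF`
stoichiometry, and the only chemiosmotic ATP source is `ATPS`.

### Tunable parameters (`coreModelConfig()`)

| parameter | default | meaning |
|---|---|---|
| `hydrogenase` | `"NADP"` | cofactor of the bifurcating hydrogenase; the genome evidence favors the NADP-specific enzyme, so it is the default, with `"NAD"` as the alternative hypothesis |
| `rnfProtonsPerFd` | 2 | H+ translocated per ferredoxin oxidized at Rnf |
| `atpsProtonsPerAtp` | 4 | H+ per ATP at the synthase |
| `biomassAccoa`, `biomassAtp`, `biomassNadph` | 20, 40, 10 mmol/gDW | lumped biomass drain coefficients |
| `biomassNh4` | 4.91 mmol/gDW | nitrogen demand, derived from a 43% protein fraction at 16% N by mass |
| `ngam` | 0 mmol ATP/gDW/h | non-growth maintenance (lower bound of `ATPM`) |
| `fructoseUptake` | 1.88 mmol/gDW/h | fructose bound of the fructose media |

The absolute Rnf and ATP synthase proton numbers are not experimentally
pinned; what the published yield accounting fixes is their *ratio*
(0.5 ATP per ferredoxin), and the scenario results are invariant under
doubling both integers (a property the test suite checks). The validity
rule `rnfProtonsPerFd < 2 * atpsProtonsPerAtp` excludes configurations in
which the Rnf/ATPS loop could mint free energy from carrier cycling.

The biomass drain is deliberately coarse — four precursors (acetyl-CoA,
ATP, NADPH, ammonium) with defaults in the range typical of bacterial
biomass equations (about 40 mmol ATP and 10 mmol NADPH per gDW, about
40 mmol C in 20 mmol acetyl units). Absolute growth rates of the core model
are therefore indicative only; all headline analyses are yield ratios at
fixed product flux, which do not depend on the biomass coefficients.

### A note on the heterotrophic NADPH source

With the WLP reductases irreversible, a model containing only the classic
EMP lump would have no NADPH source on sugars once the Nfn transhydrogenase
is deleted — making Nfn universally essential, which contradicts its
specifically autotrophic essentiality. Clostridia possess a
non-phosphorylating NADP-dependent glyceraldehyde-3-phosphate dehydrogenase
(GAPN); the core model therefore carries a second lumped glycolytic route
(`GLYCn`: fructose + 2 NADP+ → 2 pyruvate + 2 NADPH, no net ATP) as the
heterotrophic NADPH supply. Because GAPN requires sugar flux, Nfn remains
essential for autotrophic growth, where NADPH can otherwise only come from
the hydrogenase (whose fixed 1:1 coupling of NADPH to ferredoxin cannot
match the pathway demand on its own).

## Scenario analyses

### Reducing-equivalent audits

`reducingEquivalentAudit()` has two views. The *demand* view disables the
interconverters (Rnf, Nfn, hydrogenase, ATP synthase) and the
substrate-level routes, feeds each carrier from a dedicated pseudo-supply
(plus a free cytosolic proton valve, needed because the bookkeeping
construct deliberately cuts the proton-closing machinery), fixes the
product at flux 1 and minimizes total supply. The result is the intrinsic
stoichiometric demand of the pathway: 1 NADPH (`MTHFD`), 1 ferredoxin (net
of `FDH7`, `MTHFR5` and `CODH_ACS`), 2 NADH (`MTHFR5`) and 1 ATP
(`FTHFLi`) per acetyl-CoA from 2 CO2; ethanol adds 2 NADH
(acetaldehyde/alcohol dehydrogenase), for 6 two-electron equivalents — the
12 electrons of the 2 CO2 → ethanol half reaction.

The *supply* view runs the intact model on a donor medium (CO, or H2/CO2)
with the product fixed at 1 and tallies carrier production by the
donor-oxidizing reactions in the parsimonious solution: on CO all six
equivalents arrive as reduced ferredoxin from `CODH`; on H2 they arrive
split 3 + 3 between ferredoxin and NADPH (NADP hydrogenase) or ferredoxin
and NADH (NAD hydrogenase).

### ATP accounting and the acetate-kinase knockout

`energyGapAnalysis()` reproduces the chemiosmotic bookkeeping: medium and
knockouts applied, biomass and all competing products blocked (including
H2 evolution, which would otherwise act as an electron outlet and
de-pin the Rnf flux), product fixed at 1, a diagnostic cytosolic ATP
source added, and its flux minimized. The minimized diagnostic flux is the
scenario's ATP deficit; with the diagnostic pinned there, a parsimonious
solve gives the canonical flux map from which Rnf proton translocation and
`atpFromPmf = translocated / atpsProtonsPerAtp` are read. Blocking the
side outlets makes the Rnf flux unique across alternate optima (its FVA
range is a point; tested), so the reported yields are stoichiometric
facts, not solver accidents. When the deficit is zero the surplus is the
maximal maintenance flux with the diagnostic removed.

For ethanol from H2/CO2 without acetate kinase this yields 1.5 ATP (NADP
hydrogenase: 3 ferredoxin through Rnf) against a 1 ATP pathway cost —
feasible with 0.5 surplus — versus 0.75 ATP (NAD hydrogenase: only 1.5
ferredoxin reach Rnf) — a 0.25 deficit, hence the knockout's
infeasibility on H2 with the NAD-specific enzyme. On CO, 4.5 ferredoxin
pass through Rnf (2.25 ATP) and the knockout is comfortably feasible. The
`ackaPanel()` feasibility matrix follows.

### Nitrate as an electron sink

With nitrate as sole nitrogen source, NO3 → NO2 → NH2OH → NH4 consumes
4 NADH per nitrogen. Nitrogen conservation makes the balance close
stoichiometrically (nitrate consumed = ammonium secreted + biomass N), and
at equal fructose uptake the acetate flux drops relative to the ammonium
medium because electrons that would refix CO2 into acetate are diverted
onto nitrate. The comparison basis (equal substrate uptake, growth
maximized, parsimonious fluxes reported) is a package choice; the
published magnitude of the drop belongs to the full genome-scale model,
so the core asserts the direction, not the percentage.

## Numerical choices

* The LP engine is a dense bounded-variable two-phase primal simplex with
  Dantzig pricing, a largest-pivot tie-break, a Bland fallback after 2000
  iterations, and re-factorization of the basis every iteration. At the
  package's scale (tens of variables; low hundreds for split-variable
  parsimonious solves) this is fast, deterministic and keeps steady-state
  residuals at machine precision (feasibility tolerance 1e-9; growth below
  1e-9 is "no growth").
* Infinite user bounds are clamped to ±1e6 internally; a solution resting
  on a clamped bound is reported as unbounded. Default bounds are ±1000
  (reversible) and [0, 1000] (irreversible) mmol/gDW/h.
* Parsimonious FBA fixes the objective at its optimum (with a 1e-9 band)
  and minimizes the total absolute flux via variable splitting. Ties among
  parsimonious optima are resolved deterministically by the fixed pivoting
  order; every quantity the package reports from a parsimonious solution
  is additionally unique by stoichiometry in its scenario.
* Gap-filling minimizes the number of activated pool reactions by
  branch-and-bound on the LP relaxation with big-M activation rows; the
  integrality tolerance sits strictly below `minObjective / M` so the
  relaxation cannot fake activation, and alternate minimal sets are
  enumerated through integer cuts. Returned sets are verified by re-running
  FBA, and minimality (remove-one infeasibility) holds by cardinality
  minimality.
* The brute-force oracle enumerates all 3^n lower/upper/basic patterns,
  solving each free subsystem by QR; it is the independent ground truth
  for the engine on networks of up to 10 reactions.

## What the synthetic generator does and does not emulate

`randomFeasibleNetwork()` builds parallel source-to-sink chains with
random uptake caps, so the LP optimum (the sum of the caps) is known
analytically and independently of any solver. This validates the engine's
optimality, determinism and monotonicity, but the networks are loop-free
and carry no cofactor coupling; passing these tests says nothing about the
biological fidelity of a reconstruction, which is why the core model has
its own balance, feasibility, knockout and yield tests, and why its
problem sizes (57 reactions; oracle networks of at most 8 reactions, 100
seeds) are chosen so the entire suite solves in seconds.

## Known limitations

* The core model is a ~60-reaction abstraction: no amino-acid or
  nucleotide biosynthesis, no PPP/TCA detail, no GS/GOGAT or nitrogenase
  alternatives to ammonium assimilation, and heterotrophic substrates
  beyond fructose/pyruvate/formate are out of scope. Absolute growth
  rates and the published substrate table are reachable only through the
  published genome-scale model via `loadPublishedModel()` (COBRA JSON or
  SBML-FBC; MATLAB files must be converted first).
* PTS versus kinase sugar-uptake energetics are folded into the glycolytic
  lumps.
* Membrane potential is not modeled; transport energetics enter only
  through explicit proton symport stoichiometries.
* No thermodynamic (free-energy) constraints; reversibilities are fixed by
  curation.
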