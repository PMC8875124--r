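# mcpk — mechanistically coupled pharmacokinetics of dabrafenib

`mcpk` simulates and calibrates a mechanistic pharmacokinetic model that
couples the BRAF inhibitor dabrafenib and its metabolites through an
explicit CYP3A4 reaction network. It is written for PK modellers and
systems pharmacologists who need to ask questions that phenomenological
clearance terms cannot answer: how much do carboxy- and
desmethyl-dabrafenib accumulate under chronic twice-daily dosing, when is
steady state reached, how long is washout, and how does a competing CYP3A4
substrate (ketoconazole) reshape exposure?

## The model

The metabolite cascade

```
D0 (dabrafenib) --CYP3A4--> DH (hydroxy) --CYP3A4--> DC (carboxy)
      DC --low pH--> DD (desmethyl) --CYP3A4, CYP2C19+--> M (sink)
```

is coupled through a finite enzyme pool. Each substrate S binds free
CYP3A4 in a mass-action cycle `S + Ef ⇌ ES → Ef + P` (rates `kon`, `koff`,
`kcat`); the pH-dependent step `DC → DD` and the CYP2C19+ elimination of
`DD` are Michaelis–Menten terms `Vmax·C/(Km + C)`. CYP3A4 additionally
serves baseline processes through a reversible complex `Ef ⇌ EB`, and when
drug load depresses `EB` below a threshold `TE`, mRNA is released at rate
`kr·max(0, TE − EB)`, translated into new enzyme (`kt`) and degraded
(`kdeg`) — a threshold-triggered induction motif. Ketoconazole competes for
the same free enzyme (`K + Ef ⇌ EK`), so the drug–drug interaction emerges
from occupancy without any inhibition rate law. Dabrafenib species have
central/peripheral compartments (`Vc`, `Vp`); oral dosing enters
formulation-specific depots (solution vs HPMC capsule differ in `ka` and
`F`). The state is molar (nM/nmol) internally, ng/mL at the interfaces,
and the dabrafenib moiety is conserved exactly — audited to 1e-6 by
`massBalanceResidual()`.

Simulation uses a compiled right-hand side under `deSolve::lsoda` with
hard restarts at dose events. Calibration follows a staged workflow:
constant-enzyme global fit (seeded differential evolution + polish),
per-interval enzyme-level profiling against troughs, induction-motif fit,
joint refinement, and local sensitivity analysis — which is also how the
package demonstrates that a 50-fold-weakened CYP2C8 route is prunable. A
synthetic-study generator reproduces the structure of the four clinical
designs the model is built for, so the whole pipeline is testable without
external data.

## Worked example

Three weeks of 75 mg b.d. dabrafenib with 400 mg o.d. ketoconazole on the
last four days — the DDI design:

```r
library(mcpk)
p   <- groundTruthParameters()
reg <- combineRegimens(
  bdRegimen(75, endDay = 22, horizon = 22 * 24 + 12),
  odRegimen(400, startDay = 19, endDay = 22, horizon = 22 * 24 + 12))
tr  <- simulateRegimen(reg, p)

m <- pkMetrics(tr, "DC")
sprintf("carboxy-dabrafenib: Cmax %.0f ng/mL (%.2f uM), accumulation ratio %.2f",
        m$Cmax, m$Cmax_nM / 1000, m$accumulation_ratio)
#> "carboxy-dabrafenib: Cmax 685 ng/mL (1.25 uM), accumulation ratio 3.69"

occ <- reportOccupancy(p, reg)
i <- which.min(abs(occ$time_h - (20 * 24 + 2)))  # 2 h after a keto dose
round(100 * occ[i, c("f_Ef", "f_EB", "f_EK", "f_EDH")])
#>   f_Ef f_EB f_EK f_EDH
#>     15   19   51     5
```

Two hours after a ketoconazole dose, half the CYP3A4 pool is sequestered
by ketoconazole — the mechanistic face of the DDI. The headline
accumulation prediction (6 weeks on, 4 weeks off, b.d. HPMC):

```r
reportAccumulation(p, doses = c(50, 150))
#>   dose_mg analyte fold_change tss_h washout_h flag
#> 1      50      DC        2.32   144       274
#> 2      50      DD        2.57   156       376
#> 3     150      DC       10.08   696       308
#> 4     150      DD        7.28   576       581
```

At 150 mg b.d. the carboxy and desmethyl metabolites accumulate roughly
eight- to ten-fold relative to the first dose, reaching steady state after
about four weeks (696 h) and washing out within two to four weeks of
discontinuation — at 50 mg b.d. accumulation is only ~2.5-fold. Doses are
mg, times hours, concentrations ng/mL.

A thin CLI over the same functions ships in `inst/scripts/mcpk.R`
(`synth`, `simulate`, `fit`, `sensitivity`, `report`).

## Package layout

* `R/` — S4 classes (`ParameterSet`, `DoseRegimen`, `Trajectory`,
  `PKDataset`, `EnzymeProfile`, `FitResult`, `StudyDesign`), the reference
  RHS, simulator, metrics, staged calibration, synthetic-data generator,
  reporting; `src/mcpk.c` — compiled RHS.
* `vignettes/mcpk-methods.Rmd` — the model, its assumptions, parameter
  meanings and defaults, identifiability guards, numerical choices and
  limitations.
* `tests/testthat/` — unit, property and acceptance suites (closed-form
  oracles, conservation/occupancy invariants, recovery studies).
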