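---
title: "The MCPK model of dabrafenib metabolism: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MCPK model of dabrafenib metabolism: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcpk)
```

## The modelling problem

Dabrafenib, a mutant-BRAF inhibitor used in metastatic melanoma, is cleared
almost entirely by CYP3A4-mediated metabolism. Its metabolites are not inert:
hydroxy-dabrafenib and desmethyl-dabrafenib are pharmacologically active, and
carboxy-dabrafenib — the most abundant circulating species under repeated
dosing — is slowly converted back into active desmethyl-dabrafenib in acidic
environments. Standard compartmental PK models treat metabolism as a
phenomenological clearance and cannot answer two questions that matter
clinically: how much do the downstream metabolites accumulate under chronic
twice-daily dosing, and how do enzyme induction and competing CYP3A4
substrates (such as ketoconazole) reshape that accumulation?

`mcpk` implements a mechanistically coupled PK (MCPK) model that answers
these questions by replacing the clearance terms with an explicit CYP3A4
reaction network. Parent drug and each metabolite bind the free enzyme
`Ef` in mass-action cycles (`S + Ef <-> ES -> Ef + P`), so the
metabolite cascade

dabrafenib `D0` → hydroxy `DH` → carboxy `DC` → desmethyl `DD` → sink `M`

is coupled through a shared, finite enzyme pool. Two steps are *not*
enzyme-limited and use Michaelis–Menten forms: the pH-dependent conversion
`DC -> DD` (`Vmax_pH·DC/(Km_pH+DC)`) and the elimination of `DD` by the
CYP2C19-dominated pool (`Vmax_2C19·DD/(Km_2C19+DD)`), both treated as pools
with a steady total amount. A CYP2C8-mediated `D0 -> DH` route can be
enabled as a Michaelis–Menten term, but the package's sensitivity analysis
(below) ranks it as negligible and the default model omits it.

Three mechanisms make the network more than a chain of compartments:

* **Baseline occupancy.** CYP3A4 also serves other substrates, modelled as a
  reversible baseline complex `Ef <-> EB` (`kBon`, `kBoff`). The split of
  enzyme between free, baseline-bound and drug-bound forms is the model's
  occupancy read-out.
* **Threshold-triggered induction.** When drug load depresses the
  baseline-bound pool below a threshold `TE`, mRNA is released at rate
  `kr·max(0, TE − EB)`, translated into new enzyme at rate `kt`, and
  degraded at `kdeg`. This closes a negative-feedback loop: more drug →
  less baseline capacity → more enzyme.
* **Competitive-occupancy DDI.** Ketoconazole binds the same free enzyme
  (`K + Ef <-> EK`, cleared at `kcat_K`). No inhibitory rate law is needed:
  the interaction emerges from occupancy alone.

## States, units and conservation

The state vector (21 species, `stateNames()`) carries oral depots in nmol
(split by formulation: solution and HPMC capsule have separate absorption
rate and bioavailability), plasma species in nM with a central (`Vc`) and a
peripheral (`Vp`) compartment per dabrafenib species, enzyme forms and mRNA
in nM, and two absorbing pools in nmol: `M` (downstream metabolites) and
`U` (cumulative excretion, fed by first-order `ke` routes; carboxy-dabrafenib
dominates excretion in the defaults, matching the radiolabel mass-balance
picture). Molar units internally, mass units (ng/mL) at every I/O boundary,
converted via molar masses in `speciesTable()` — enzyme binding is
stoichiometric, so molar state is not optional.

The network is built so that the dabrafenib moiety is conserved *exactly*:
every reaction moves drug between tracked pools, complex degradation (see
below) returns the substrate moiety to plasma, and
`massBalanceResidual()` audits |total − absorbed dose|/dose on every
simulation (the suite requires ≤ 1e-6). Ketoconazole is intentionally not
conserved: its catalytic step models clearance out of the tracked system.

Two turnover choices deserve a note. Translation does not consume mRNA —
mRNA is lost only by degradation, which is how the motif is described.
Enzyme protein turnover is included as first-order `kEdeg` on all enzyme
forms with a matching zero-order synthesis `kEdeg·E0`, so the drug-free
steady state is exactly `E0` and the enzyme returns to baseline after
treatment stops; the default half-life is ~72 h, typical of hepatic CYP3A4.
When a drug-bound complex is degraded its substrate moiety is released back
to the central compartment rather than destroyed — a choice made to keep
drug-moiety conservation exact; with the default `kEdeg` the flux through
this route is negligible.

The induction hinge `max(0, TE − EB)` is optionally smoothed by a softplus
of width `eps_hinge` (default `TE/100`; 0 restores the exact hinge). This
exists purely for stiff-solver robustness and changes rates only within
~1% of `TE` around the threshold.

## Simulation

`simulateRegimen()` integrates the network with `deSolve` (lsoda,
variable-step variable-order, stiff-capable) through a compiled C
right-hand side; an R reference implementation (`mcpkRHS()`) is exported
and the two are cross-checked in the test suite. Dose events are handled as
hard integrator restarts with exact depot increments `F·dose/MW`, so event
times are hit exactly rather than approximated by impulse forcing. Default
tolerances are rtol 1e-8, atol 1e-10 nM (the source analyses do not state
solver settings; these are the package's own, audited by a
tolerance-halving test that requires metric stability to 0.1%). Output
grids carry at least 20 points per dosing interval, fixed post-dose offsets
(0.05–3 h) so that peaks are sampled at a common phase across intervals,
and a pre-dose sample at each dose time − 1e-6 h used as the deterministic
trough.

`pkMetrics()` computes Cmax/Tmax from the grid maximum, AUC by the
trapezoid rule, troughs at the pre-dose samples, and the accumulation ratio
as Cmax in the last dosing interval over Cmax in the first.
`timeToSteadyState()` reports the earliest dose whose trough is within 5%
(default) of the final trough; `washoutTime()` the time after the last dose
at which a species falls below 1% (default) of its global peak and stays
there.

## The synthetic study suite

No machine-readable clinical data ship with the problem, so the
`synthetic_data` module generates datasets with the structure of the four
study designs the model is meant to fit, from known ground-truth
parameters (`designTemplates()`, `generate()`, `groundTruthBundle()`):

1. a single 95 mg oral solution dose with rich 0.5–96 h profiles of all
   four analytes plus cumulative relative excretion;
2. HPMC b.d. dose escalation (50/75/100/150 mg, 18 days) with first-dose
   and steady-state profiles and daily troughs;
3. single-dose ketoconazole escalation (100/200/400 mg);
4. a DDI study: 75 mg b.d. dabrafenib for 22 days with 400 mg o.d.
   ketoconazole on the last four days, profiled at day 18 and day 22.

Noise is proportional lognormal, `exp(N(0, sigma))` with
`sigma = sqrt(log(1+CV^2))` and CV 15% by default — the residual-error
model is the package's own choice (lognormal keeps concentrations
positive); arm-level data are geometric means over replicates (6 by
default). The excretion observable gets noise on its increments and is
re-accumulated so every replicate remains non-decreasing. Sampling
schedules (0.5, 1, 2, 4, 6, 8, 10, 24 h on profile days; one trough per
day otherwise) are structural stand-ins; the exact times of the source
studies are not reproduced.

The ground-truth parameter set (`groundTruthParameters()`) was chosen once
so that the qualitative clinical picture holds, and then frozen: parent
Cmax ≈ 2–3 µM at 150 mg b.d.; hydroxy-dabrafenib the dominant CYP3A4
occupant; carboxy/desmethyl accumulation strongly dose-dependent (about
2.4/2.6-fold at 50 mg rising to about 10/8-fold at 150 mg for DC/DD),
driven by saturation of the pH and CYP2C19 routes plus induction; troughs
reaching steady state in roughly four weeks at 150 mg with washout in
two to four weeks; induction barely triggered at 50 mg b.d. and sustained
at 150 mg; and ketoconazole raising parent exposure by ~40% through
occupancy alone. These are emergent behaviours of the frozen set, not
fitted quantities; what passing tests show is that the *pipeline* recovers
known truths under this realistic structure, not that the truth equals any
patient population.

## Staged calibration

Fitting all mechanisms at once is poorly conditioned, so calibration is
staged:

1. **`fitStage1()`** fits the constant-enzyme model (induction forced off)
   to the single-dose, ketoconazole and DDI designs by seeded differential
   evolution (rand/1/bin, in-package, population 50 × 200 generations by
   default) followed by an `nlminb` polish. All parameters are fitted on
   log10 scale inside box bounds — positivity and scale-invariance for
   rates spanning decades.
2. **`fitStage2EnzymeProfile()`** freezes those kinetics and, for each dose
   interval (daily by default), adjusts the total CYP3A4 level by 1-D
   bounded scalar search (`stats::optimize`, the `fminbnd` analog) until
   the simulated pre-dose trough matches the observation; the state is
   carried across intervals and data gaps inherit the previous level,
   flagged.
3. **`fitStage3Induction()`** fits the induction motif so that, driven by
   the simulated baseline-occupancy series EB(t), it reproduces the stage-2
   piecewise-constant enzyme profile. The motif is linear given the hinge
   forcing, so it is integrated by an exact-decay exponential-Euler
   recursion (dt = 0.05 h) rather than a generic ODE call. Two
   identifiability guards: `kt` is fixed by default because the profile
   constrains only the product `kr·kt`; and the threshold `TE` is searched
   within the observed EB range — outside it the release term is constantly
   off (or on) and the threshold is undefined, which the fit reports as a
   boundary flag. A flat profile short-circuits to `kr = 0` with an
   "induction unidentifiable" flag.
4. **`fitStage4Joint()`** re-enables induction and refines all free
   parameters from the stage-1+3 warm start, with a monotone-improvement
   contract: if refinement cannot beat the warm start, the warm start is
   returned flagged.

The objective (`rss()`) is a residual sum of squares on
`log(value + delta)` with `delta` = 0.1 ng/mL (1e-3 for excretion
fractions): concentrations span more than two decades and the weighting of
the original fits is not documented, so log scale with a small floor is the
package's choice. Binding constants `kon` are fixed by default to a
diffusion-plausible 0.01 /(nM·h): plasma PK constrains only the composites
`(koff+kcat)/kon` and `kcat`, and a configuration switch frees `kon` for
users who disagree.

**Registry and the 28 extension parameters.** Every parameter carries a
role annotation: `base` (the reproduced two-compartment dabrafenib model:
`ka_cap`, `F_cap`, `Vc`, `Vp`, `q_D0`), `extension` (the mechanistic
coupling), `structural` (units, smoothing width, switches) or `pruned`
(the CYP2C8 route). The free extension set — solution absorption (2),
metabolite distribution (3), four enzyme cycles (8), baseline exchange
(2), the two MM routes (4), excretion (2), the induction motif (4),
ketoconazole PK (2) and the enzyme level `E0` — counts exactly 28
(`countExtensionParameters()`), the model's cost over the base PK model.

## Sensitivity analysis and pruning

`localSensitivity()` computes central finite differences on log-parameters
(`S_i = ∂f/∂log θ_i`, step 1%) for any scalar functional; parameters at
zero are reported as exactly zero, and non-finite functional values flag
the parameter as undefined rather than failing. The package reproduces the
structural pruning decision on synthetic data: with a CYP2C8 route whose
Vmax is 50-fold below the CYP3A4 route capacity, the CYP2C8 parameters rank
in the bottom quartile of |S| across the full study suite (the functional
is the RSS at a generic displaced parameter point — at the optimum itself
every gradient vanishes and ranking is meaningless), and the route is
dropped from the default model.

## Numerical choices and degenerate inputs

* Dose events: integrator restarts, never impulse approximations;
  simultaneous doses at one time are summed into their depots.
* Troughs: sampled at dose time − 1e-6 h, deterministically on the grid.
* Negative concentrations: the RHS rejects negative states with a
  diagnostic naming the species; the solver's tiny round-off negatives are
  clamped to zero only at segment handoffs.
* Zero-dose regimens: mass-balance residual defined as 0; excretion
  fraction is an error (undefined denominator).
* Zero enzyme: occupancy fractions error rather than return NaN.
* Optimizer determinism: all stochastic stages take an explicit seed and
  restore the caller's RNG state; identical seeds give bit-identical
  results.

## Problem sizes used by the tests and the acceptance script

The shipped checks favour small, information-dense problems: stage-1
demonstrations fit 5–8 free parameters with DE populations of 20–24 over
25–30 generations on the single-dose, ketoconazole and DDI designs;
the noise-recovery report uses CV 5% with three seeds and arm-averaged
replicates; induction recovery uses a 14-day 150 mg b.d. profile. These
sizes were chosen as the smallest that exercise every mechanism; the
full-size defaults (population 50 × 200 generations, all four designs,
all 28 free parameters) are available through the same interfaces.

## Known limitations

* The synthetic generator emulates design structure, not source data:
  real profiles carry inter-individual variability, irregular sampling,
  and assay error structure that proportional lognormal noise does not
  capture. Passing recovery tests demonstrates pipeline correctness, not
  clinical parameter values.
* No population (mixed-effects) layer and no PBPK tissue detail: pH is a
  single lumped term, not a spatially varying quantity, so tumour-local
  metabolite conversion is out of scope.
* The PXR induction mechanism is deliberately not modelled; induction is
  driven by baseline occupancy only.
* With plasma data alone, `kon`/`koff` are not separately identifiable
  (hence fixed `kon`), and `kr`/`kt` only through their product (hence
  fixed `kt` in stage 3).
* The full 28-parameter joint fit is practically identifiable only in
  part; the recovery report, not a pass/fail point estimate, is the honest
  acceptance surface for it.
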