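---
title: "Modelling nitrate treatment of reservoir souring: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrate treatment of reservoir souring: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soursim)
```

Reservoir souring is the biogenic production of hydrogen sulfide by
sulfate-reducing bacteria (SRB) in water-flooded oil reservoirs. A common
countermeasure is nitrate treatment: adding nitrate to the injection water
stimulates nitrate-reducing communities that suppress SRB through several
candidate mechanisms — competition for the shared electron donor
(biocompetition), re-oxidation of sulfide back to sulfate or elemental
sulfur (sulfur cycling), and inhibition of SRB by the nitrite that nitrate
reduction produces. `soursim` implements a reaction-network modelling
pipeline for weighing these mechanisms against batch and flow-column
data: bioenergetic construction of community reactions, Monod kinetics
with nitrite product inhibition, genetic-algorithm parameter estimation
with SSE-based scenario screening, a 1D finite-volume reactive transport
model, and design metrics (MINC, RINC, the R ratio) for nitrate dosing.

## Community reactions from half-reactions

Each microbial community is represented by one overall growth reaction
built from three electron-equivalent half-reactions: an electron donor
oxidation, an electron acceptor reduction, and cell synthesis to the
conventional biomass formula C5H7O2N with ammonium as the nitrogen
source. Electrons from the donor are split between energy generation
(fraction $f_e$) and synthesis ($f_s = 1 - f_e$):

$$ R = R_{donor} + f_e \, R_{acceptor} + f_s \, R_{synthesis}, \qquad
   f_e + f_s = 1 . $$

The inventory covers lactate full oxidation (12 electron equivalents per
mole), sulfate reduction to sulfide (8), nitrate to nitrite (2), nitrite
to ammonium (6, the DNRA arm) or to dinitrogen (3, the lumped
denitrification arm), sulfide oxidation to sulfate (8) or to elemental
sulfur (2), elemental sulfur oxidation to sulfate (6), and synthesis (20
e-eq per mole biomass). Every half-reaction and every combined reaction
is balanced in C, H, O, N, S and charge to $10^{-8}$ by construction;
`check_balance()` exposes the residuals.

Eleven community reactions arise from this inventory: one SRB reaction
(lactate + sulfate) and ten nitrate/nitrite-reduction reactions spanning
heterotrophic (lactate-driven, "NRB") and autotrophic
(sulfide/sulfur-driven, "NRSOB") metabolism. They are organized into six
groups A–F, each pairing a nitrate step with a nitrite step that share a
donor; A–D follow DNRA, E–F denitrification. Admissible community
scenarios are the non-empty same-pathway subsets with the constraint
that group D (elemental-sulfur oxidation) requires group C (the pair
that produces the elemental sulfur): 11 DNRA plus 3 denitrification
combinations.

```{r}
length(enumerate_scenarios())
cs <- community_set()
stoich_yield(cs$SRB, "sulfate", "lactate")     # 1.27 mol/mol
stoich_yield(cs$NRSOB1, "sulfide", "nitrate")  # 0.29 direct
stoich_yield(cs$NRSOB2, "sulfide", "nitrite")  # 0.86 via nitrite
```

The energy fractions are pinned to reproduce this yield chain exactly
($f_e$ = 0.8499 for SRB, 0.8623 and 0.8656 for the two
sulfide-to-sulfate NRSOB steps; 0.86 for all other communities) and are
overridable per community. Since ammonium, not nitrate, is the nitrogen
source for synthesis, the nitrate step produces exactly one nitrite per
nitrate — the bookkeeping needed for the "indirect" oxidation yield.

## Batch kinetics

Each community grows by a dual-Monod rate law with optional product
inhibition:

$$ r = \mu_{max} X \frac{C_d}{C_d + K_d} \frac{C_a}{C_a + K_a}
       \frac{I}{C_{NO_2^-} + I} - bX , $$

with $\mu_{max}$ (1/s) the maximum specific growth rate, $K_d$ and $K_a$
(mol/l) the donor and acceptor half-saturation constants, $I$ (mol/l)
the nitrite inhibition coefficient, and $b$ (1/s) endogenous decay. The
inhibition factor applies to SRB only; `I = Inf` removes it, which is
exactly the "inhibition off" model variant. Species turnover is the
stoichiometric coefficient per mole of biomass times the growth term;
the decay term removes biomass only (the fate of decayed biomass is not
modelled). CO2, water and protons are balanced in the stoichiometry but
treated as buffered and are not part of the ODE state.

Two conventions follow from the heavy-inoculum, short-horizon batch
design (8000 mg/l biomass, 4.5–12 h): batch simulations default to
frozen biomass (`dX/dt = 0`, substrates still turn over), with growth
switchable on; the column model always grows biomass. Because synthesis
consumes ammonium, a growth medium must supply an ammonium pool — the
default batch design includes 5 mM, a typical anaerobic-medium level;
with no ammonium at all, every community stalls at zero rate.

Numerical choices: the ODEs are integrated with `deSolve::lsoda`
(defaults `rtol = 1e-8`, `atol = 1e-12` for simulation; relaxed to
`1e-7`/`1e-10` inside fitting loops), and every consumed species
multiplies the rate by a smooth cutoff $C/(C + \epsilon)$ with
$\epsilon = 10^{-12}$ mol/l, which keeps the system Lipschitz instead of
hard-clipping at zero. The right-hand side is evaluated in C for all
cells of a column at once; a pure-R reference implementation of the same
rates is kept and the two are cross-checked in the test suite. Closed-
batch sulfur is conserved to $10^{-9}$ mol/l and nitrogen (including
biomass N) to solver tolerance when growth is on.

## Fitting and scenario screening

Parameter estimation follows a two-stage global-plus-local procedure.
Stage one fits the SRB kinetics (KPSR) to the nitrate-free part of the
data; stage two fixes KPSR and fits each scenario's nitrate-reducer
kinetics (KPNR), including the SRB inhibition coefficient $I$, which has
no signal until nitrite appears. The global stage is a real-coded
genetic algorithm (default population 60, elite fraction 0.1, up to 200
generations, early stop when the best fitness improves by less than
1e-8 over 20 generations, plus a 10% random-immigrant fraction per
generation to keep diversity); the local stage is a bounded `nlminb`
polish from the GA optimum. Parameters with positive bounds are searched
in log10 space. The linear constraint that community biomass sums to at
most 8000 mg/l is enforced by proportional repair of candidates, so
every evaluated candidate is feasible and fitness values are comparable
across scenarios. The random seed is a first-class input recorded in
every result.

The objective is the sum of squared errors between model trajectories
(linearly interpolated onto observation times) and the data, with
residuals normalized per species by that species' observed range so
that mixed mg/l scales contribute comparably. Lactate is excluded from
the default score because fermentation — a visible lactate sink in real
data — is deliberately outside the model. Scenario screening reports
$RSSE_i = (SSE_i - \min SSE)/\min SSE \times 100$, ranked ascending
with ties broken by the canonical scenario order.

Two identifiability facts shape the default free-parameter set. With
frozen biomass, $\mu_{max}$ and $X_0$ enter the rate only as a product,
so $X_0$ is fixed by the design (the known inoculum split) unless
explicitly freed. And with lactate supplied in large excess (28 mM
against sub-mM $K_d$), the donor Monod term saturates and $K_d$ carries
no signal — it only trades off against $\mu_{max}$. The default free
set is therefore $(\mu_{max}, K_a)$ per community, which the recovery
tests show is estimated essentially exactly from noiseless synthetic
data. Similarly, the DNRA and denitrification arms differ only in
whether nitrite becomes ammonium or N2, so screening that must separate
them has to score ammonium; the acceptance suite does.

## The column model

The packed-bed bioreactor (4.5 cm × 64 cm sand column, five ports at
14 cm spacing) is modelled as a 1D reactive transport equation

$$ \frac{\partial (\varphi C_i)}{\partial t} =
   \nabla \cdot (\varphi D_i \nabla C_i) - \nabla \cdot (q C_i)
   - \sum_j \nu_{ij} R_j , $$

discretized cell-centred into 64 finite-volume cells of 1 cm (cells are
1-indexed; the first port averages cells 6 and 7, the last cells 62 and
63). Advection is explicit upwind, dispersion explicit central, with
automatic sub-cycling to the CFL limits; the inlet is an advective flux
boundary carrying the influent concentration and the outlet is advective
with zero dispersive gradient, which makes the discrete mass balance
close to machine precision (the tests check elemental sulfur balance to
1e-6 relative through reactive runs). Biomass neither advects nor
disperses. Reaction and transport are composed by operator splitting
with a global step of 0.01 d by default — sequential
transport-then-reaction, with a Strang option; halving the step moves
port series by well under 0.5% in the convergence tests.

The experiment's protocol is reproduced in two phases: a no-flow startup
in which the uniformly inoculated column acts as a batch until sulfate
falls to 0.1 mM (≈99% reduction), then scheduled flow and influent
steps. Porosity defaults to 0.375, a typical random packing of 225 µm
sand, which reproduces the 1.55-day advective travel time between the
first and last ports at 9 ml/h; dispersion defaults to
$D = D_m + \alpha v$ with $D_m = 10^{-9}$ m²/s and $\alpha$ = 0.1 cm.
Neither porosity nor dispersion is reported for the original column, so
both are config-exposed. `reconstructed_flow_schedule()` ships an
editable reconstruction of the operating narrative (flow ramp 0.5 to
9 ml/h at 0.5 ml/h per day, nitrate steps 2.5 to 20 mM); it is labelled
a synthetic reconstruction, and all tests run on programmatic fixtures
instead. The influent sulfate of a real experiment can be back-estimated
from port data by averaging sulfate + sulfide over a window
(`estimate_influent_sulfate()`), which is exact under sulfur
conservation.

## Mechanism dissection and design metrics

`sim_variant()` builds the toggled models used to apportion the
treatment effect: inhibition off (the SRB rate with the nitrite factor
removed — implemented exactly as $I \to \infty$), and community
removal (dropping the nitrate reducers removes biocompetition; dropping
the sulfide oxidizers removes sulfur cycling). On the packaged batch
fixture the inhibition-free and SRB-only variants misfit the data almost
identically and far worse than the full model — the signature that
nitrite inhibition, not biocompetition, carries the treatment.

The minimum inhibitory nitrate concentration (MINC) is pure
stoichiometry: the donor supply times the sulfate reduced per donor,
divided by the total (direct + indirect) sulfide oxidized per nitrate.
With the default yields, 25 mM lactate gives a 31.87 mM sulfate demand
and a 27.56 mM nitrate demand; `minc()` is exactly linear in the donor
concentration. The required inhibitory nitrate concentration (RINC) is
found by bisection over the injected nitrate for the lowest dose that
keeps quasi-steady sulfide below a threshold at an observation distance.
Neither a numeric "souring inhibited" criterion nor a steadiness
criterion is inherited from the experiments, so the package defines
both explicitly and exposes them: sulfide below 0.1 mM, and quasi-steady
meaning less than 1% relative change over a trailing 5-day window (the
short-column fixtures in the tests use a 3-day window). In the
inhibition-free limit with kinetics fast enough for complete conversion
within the residence time, the bisection lands on the stoichiometric
MINC — the test suite demonstrates this equivalence on a fixture column
(27.5 mM found against 27.56 mM predicted).

The nitrite-to-nitrate reduction rate ratio R is defined at substrate
saturation with the initial biomass,
$R = (\mu_{max,2} X_2 \nu_2) / (\mu_{max,1} X_1 \nu_1)$ over the two
steps' acceptor coefficients, and `set_r_ratio()` rescales the
nitrite-step $\mu_{max}$ to reach a target — matching the convention of
manipulating the nitrite step's maximum growth rate only. Low R lets
nitrite accumulate and is the favourable regime for treatment; on the
batch fixture the time to half-maximal sulfide shortens monotonically
as R grows through {0.25, 0.75, 1.5, 2.75}.

## Synthetic data

`make_batch_set()` emulates the five-flask anaerobic batch design
(sulfate 1000 mg/l, lactate 2500 mg/l, nitrate 0/200/500/700/1000 mg/l,
8000 mg/l inoculum, 0–12 h observations) and `make_column_set()` the
port series of the flow design, both from known ground-truth parameters.
Observation noise is multiplicative Gaussian (default 5% relative) with
an absolute floor of 0.5 mg/l, truncated at zero — a realistic error
model for ion-chromatography-scale measurements; noise is applied to
observations only and the noiseless trajectories are retained, so every
data set is regenerable bit-identically from its truth and seed. The
generator does not emulate instrument drift, lag phases, fermentation,
or pH/speciation effects, so passing recovery tests demonstrate the
estimator's correctness under the model's own assumptions, not
robustness to real-data misspecification.

## Problem sizes and limitations

The test and acceptance runs use deliberately small configurations
chosen to exercise every code path at desk scale: 13-point observation
grids, 16–50-cell fixture columns of 1 cm diameter (so residence times
are hours, not days), GA budgets of 16–24 individuals over 12–40
generations with a bounded polish, and 8–10 simulated days per column
run. The full-geometry 64-cell column and the default GA budget
(population 60, up to 200 generations) are the package defaults for
real analyses.

Known limitations, all deliberate: no fermentation (lactate declines in
real data even without electron acceptors), no pH/speciation or
thermodynamic $f_e$ estimation, no NO/N2O intermediates in
denitrification, no permeability change by biofilm growth, 1D transport
only, and decay that removes biomass without returning substrate. Mixed
DNRA-plus-denitrification scenarios are excluded by construction to
match the 11 + 3 scenario algebra.
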