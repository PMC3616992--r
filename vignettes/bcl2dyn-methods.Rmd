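---
title: "Modelling Src control of mitochondrial apoptosis with bcl2dyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Src control of mitochondrial apoptosis with bcl2dyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The biological system

`bcl2dyn` models how constitutive Src kinase activity makes fibroblasts
resistant to the mitochondrial (intrinsic) pathway of apoptosis, and what
that implies for drug combinations.  The system is a pair of NIH-3T3-like
cell populations — parental ("healthy") and v-Src-transformed ("cancer") —
whose Bcl-2 family composition differs in two decisive ways: transformed
cells carry roughly five-fold less of the BH3-only sensitizer Bik (because
Src-activated Erk1/2 phosphorylates Bik and accelerates its ubiquitylation
and proteasomal destruction), and roughly two-fold more of the effector
Bax.  Everything in the package follows from the dynamical consequences of
those two differences.

Two coupled models are implemented:

1. **Bik turnover** — a two-variable ODE for Bik and polyubiquitylated Bik,
   with closed-form steady states.
2. **The apoptosis network** — an eleven-species mass-action ODE for the
   Bcl-2 family response to a death stimulus, coupled to a survival law for
   the cell population.

## Bik turnover

With `Bik` the free protein and `BikUb` its polyubiquitylated form (both
nM), the turnover model is

$$\frac{d[\mathrm{Bik}]}{dt} = k_S - k_{ubi}[\mathrm{Bik}]
  - \frac{V_{max}[\mathrm{Bik}]}{K_m + [\mathrm{Bik}]},\qquad
\frac{d[\mathrm{BikUb}]}{dt} = k_{ubi}[\mathrm{Bik}]
  + \frac{V_{max}[\mathrm{Bik}]}{K_m + [\mathrm{Bik}]}
  - k_{deg}[\mathrm{BikUb}].$$

Synthesis is constant (`kS`, justified by equal Bik mRNA levels in both
lines); spontaneous ubiquitylation is first order (`kubi`); the
Src/Erk-dependent route is Michaelis–Menten (`Vmax`, `Km`), active only in
transformed cells; `kdeg` is fixed to 1 because it does not act back on
Bik.  The steady state solves a quadratic with a unique non-negative root
(`bik_steady_state()`), reducing to `kS/kubi` when `Vmax = 0`.

**Default parameterization.**  The decay measurements for this cell system are reported as curves, not
as fitted rate values, so the shipped defaults are fixed by the reported
quantitative anchors instead: `kubi = 1/360` per
min, chosen so that switching degradation off exactly doubles Bik in six
hours (the argument that rules out an accumulation-based death trigger,
`accumulation_profile()`); `kS = 50·kubi`, anchoring the parental steady
state at 50 nM; and `(Vmax, Km)` for the transformed line solving the
steady-state balance at 9.2 nM, giving a steady-state ratio of 0.184
against the measured 0.2.  Only the lumped ratio `Vmax/(Km + Bik_ss)` is
identified by steady-state information; `Km = 20` nM is a convention.
These defaults are the package's own calibration, not experimentally
fitted values.

**Fitting decay data.**  `fit_bik()` fits chase-style relative decay
courses (synthesis blocked, level normalized to 1 at the chase start) by
least squares under CMA-ES.  Two numerical choices matter:

* The optimizer does not search `(Vmax, Km)` directly.  That pair has a
  broad compensation valley — a slightly smaller `kubi` plus a
  near-zeroth-order Michaelis–Menten term reproduces an exponential decay
  to within half a percent — and both CMA-ES and quasi-Newton descent stall
  there.  The search runs in the coordinates `kubi`, `lump =
  Vmax/(Km + B0)` (the Michaelis–Menten contribution to the initial decay
  rate) and `Km`, with the starting level `B0 = kS/(kubi + lump)` the
  self-consistent steady state and `Vmax = lump·(Km + B0)` derived.  In
  these coordinates the only weak direction is `Km`, and noise-free
  parameters are recovered to numerical precision.
* A quasi-Newton (L-BFGS-B) polish follows the evolution-strategy run.

Herbimycin-labelled courses are fitted with `Vmax` scaled by 0.02 — Src
inhibition by herbimycin was measured as a 98% drop in Y416
phosphorylation, and the package models it as a 98% reduction of `Vmax`
throughout (`apply_herbimycin()`).

## The apoptosis network

Eleven species (nM): inactive and active Bik, the Bcl2:Bik complex, Bid,
tBid, the Bcl2:tBid complex, closed Bax, open (membrane-inserted) Bax,
oligomerized Bax, the free anti-apoptotic pool ("Bcl2", lumping Bcl-2 +
Bcl-xL + Mcl-1), and the Bcl2:BaxO complex.  Spontaneous reactions follow
mass action; Bax activation by tBid is catalytic ("kiss and run") and
follows Michaelis–Menten kinetics in closed Bax.  The ten reactions are
listed with their rate laws at the top of `R/apoptosis-model.R`; the
right-hand side is assembled as stoichiometry × flux so that the four
conservation laws (total Bik, Bid, Bax, anti-apoptotic pool) hold
identically.

Design choices worth making explicit:

* **Monomer accounting for oligomer.**  `BaxOligo` is tracked in monomer
  equivalents; the dimeric nucleation step converts two monomers per event
  (flux `2·k_dim·BaxO²`), so the Bax conservation law stays linear.
* **Autocatalysis dominates.**  The membrane recruitment step
  (`k_auto·BaxO·BaxOligo`) is the engine of oligomer growth; the shipped
  sets satisfy `k_auto/k_dim > 10` and the test suite checks that removing
  the dimeric route barely changes the outcome once a trace of oligomer
  exists, while removing autocatalysis abolishes threshold crossing.
* **Complexes do not dissociate**, except that active Bik displaces tBid
  from Bcl2:tBid, and BH3-mimetic pre-incubation dissolves complexes at
  time zero.  Association-only kinetics is a deliberate simplification;
  the association rates absorb the anchoring of the Bcl-xL dissociation
  constants used when the two fixed association rates were set.

The cell population obeys a Hill-gated survival law,

$$\frac{dn}{dt} = -a\,n\,
  \frac{[\mathrm{BaxOligo}]^{\gamma}}{[\mathrm{BaxOligo}]^{\gamma}
  + {B^\ast}^{\gamma}},$$

with `n` the surviving percentage, threshold `bax_star` = 13 nM (13% of
the 100 nM Bax total of the transformed reference line — the product of
the measured 33% mitochondrial share and 38% activated share — applied as
the same absolute threshold to both populations; applying 13% of the
parental total instead is available as a configuration), steepness `γ` and
maximal rate `a`.  The reference parameter row lists the pair (4.15,
0.0205); the assignment `γ = 4.15`, `a = 0.0205`/min is forced by
dimensional sanity — a death *rate* of 4.15/min would empty the population
in about two minutes, contradicting the 6–8 h threshold-crossing window.
Only the S-shape of the death law is reported, not its exact functional
form; the Hill form is this package's choice, and one consequence is documented under
*Limitations*.

**Initial conditions** (`build_initial_state()`): all Bik inactive at its
steady state, all Bax closed, all pre-existing tBid (1 nM) complexed, no
Bcl2:BaxO complexes, free Bid and Bcl2 from the conservation laws.  This
state is an exact fixed point until staurosporine switches on Bik
activation (`kact`) and Bid truncation (`ktrunc`) at `t = 0`.  The
activation rate is estimated from the measured mitochondrial relocation:
45% of Bik at the mitochondria within 2 h gives
`estimate_kact(0.45, 120) ≈ 0.005`/min.

## Treatments

`treatment_spec()` declares a combination; `apply_treatment()` maps it
onto parameters and initial conditions, identically for both cell lines:

| agent | model action |
|---|---|
| staurosporine | `kact`, `ktrunc` on at `t = 0` |
| Src inhibitor (herbimycin) | `Vmax` × (1 − inhibition); Bik steady state re-equilibrates before `t = 0` |
| BH3 mimetic (ABT-737) | removes nM from the anti-apoptotic pool; complexes that no longer fit dissociate, the remainder of tBid starts free |
| Bax down-regulator | removes nM from total Bax (floored at 0) |
| tBid up-regulator | adds nM to the resting tBid pool (capped at total Bid) |

Pre-incubated agents act before the stimulus, so the resting state is
re-derived after applying them; the mapping is a pure function of
`(cell, bik, net, rx)`.

## Calibration

The network inherits its structure from the wiring above, but the
reference rate set does not reproduce the endpoint data under this
reconstruction — integrated tBid production at the reference truncation rate
is an order of magnitude too small to drive the oligomer anywhere near the
threshold.  The package therefore treats endpoint matching as a
calibration problem rather than relying on rate-value reuse:

* **Data**: the three reported endpoint percentages (parental staurosporine
  80%, parental staurosporine + herbimycin 80%, transformed staurosporine +
  herbimycin 99%).
* **Cost**: sum of squared endpoint residuals plus 1000 per unsatisfied
  constraint (`calibration_cost()`).
* **Constraints** (`constraint_suite()`): threshold crossing in parental
  cells between 6 and 8 h; activated Bax below 20% of total during the
  first 6 h in transformed cells (the record is ambiguous about which
  population this cap was stated for; transformed cells are consistent
  with the adjoining resistance statement, and the suite is configurable);
  `k_auto/k_dim > 10`; association rates within the diffusion-limited
  window `[1e-6, 1]` /(nM·min); transformed-cell resistance (≤ 20%
  apoptosis under staurosporine alone); and no death without the stimulus
  even under full depletion of the anti-apoptotic pool (the experimentally
  demonstrated "not primed for death" behaviour).  The last predicate is
  load-bearing: without it the optimizer finds a spurious basin in which
  the 1 nM of pre-existing tBid, amplified by a large catalytic rate,
  reproduces the three endpoints while predicting death from BH3-mimetic
  exposure alone.
* **Free parameters**: ten rates (`ktrunc`, `k_disp`, `kcat_bax`,
  `Km_bax`, `k_dim`, `k_auto`, `k_bax_bcl2`, `k_back`, `γ`, `a`); the two
  Bcl2 association rates for Bik and tBid and `kact` stay fixed, and
  `bax_star` is fixed by its own derivation.
* **Optimizer**: log10-space CMA-ES with a multi-start schedule dispersed
  along the truncation axis (endpoint data leave it unconstrained a
  priori), early-stopped once the cost falls below 0.5.  Deterministic
  given the seed.

With three datapoints and ten free parameters the fit is deliberately
under-determined; per-parameter spread across seeds is wide and expected.
What is reproducible is the *behaviour*: the endpoint percentages, the
resistance ordering, the BH3-mimetic arm and the therapy-design structure.
`calibrated_apoptosis_params()` ships the seed-42 result of this procedure
(regenerable with `data-raw/calibrate-defaults.R`), and the calibrated
model then *predicts* — without having been fitted to it — that a 182 nM
depletion of the anti-apoptotic pool plus staurosporine kills ~99% of
parental cells, mirroring the validation experiment.

## Therapy optimization

A design is a setting of up to four knobs (Src inhibition fraction, pool
depletion, Bax removal, tBid addition) on top of staurosporine, applied to
both populations.  Its cost is the surviving percentage of transformed
cells plus 1000 if parental apoptosis exceeds 1%.  `optimize_therapy()`
seeds CMA-ES with a coarse pre-scan (full grid for up to two knobs, Latin
hypercube above) to escape the flat penalty plateau;
`rank_combinations()` runs the same inner optimization for every subset of
at most two knobs.

The structural result the package reproduces: staurosporine alone kills
~80% of parental cells, so *every* feasible design must first shelter the
parental population, and the only knob that can is Bax removal — parental
cells (48 nM Bax) can be pushed below the apoptotic threshold while
transformed cells (100 nM) retain enough Bax to die.  Bax down-regulation
alone is tolerable but kills almost no cancer cells; paired with a second
agent (pool depletion, Src inhibition or tBid up-regulation) it reaches
≥99% efficacy at <1% toxicity.

## Synthetic data

Because the raw measurements are not deposited, `gen_bik_decay()`,
`gen_colocalization()` and `gen_apoptosis_endpoints()` generate every
fixture with known ground truth: chase decays on a 0–360 min grid at
30-min steps (a plausible chase design; the measurement grid is not
reported),
colocalization fractions from a normal distribution truncated to [0, 1]
(mean 0.45, sd 0.13, 30 cells), and endpoint percentages with binomial
counting noise at 300 cells per arm (~2.5-point standard error at 80%,
comparable to replicate bars in apoptosis assays).  Determinism given the
seed is part of the contract and is tested.  What these generators do
*not* emulate: densitometry saturation and background subtraction in
immunoblots, cell-to-cell parameter heterogeneity, and any correlation
structure between arms — so passing recovery tests demonstrates numerical
identifiability under the stated noise, not robustness to real-data
artefacts.

## Numerical choices

* Stiff integration (`deSolve::lsoda`), reporting runs at `rtol = 1e-8`,
  `atol = 1e-10` nM on a 1-min grid; conservation drift is audited on
  every simulation and stays near machine precision.
* Optimization-loop simulations use a coarser 4-min grid at `rtol = 1e-6`
  (8-min and `1e-5` inside the calibration unit tests); final reported
  quantities are always re-evaluated at the tight settings.
* Problem sizes: calibration is three endpoint arms over 480 min;
  parameter-recovery checks use 20 noise seeds; the combination ranking
  covers the 11 knob subsets of size ≤ 2.
* Degenerate inputs are contracts, not crashes: a flat decay course drives
  `kubi` to the optimizer floor with the residual reported; an empty knob
  set returns the staurosporine-alone arm; zero free parameters evaluate
  the cost once.

## Limitations

* The Hill survival law softens the threshold: sub-threshold oligomer
  still kills at a rate proportional to `(BaxOligo/bax_star)^γ`, so
  "below threshold" protects only with a margin (at `γ ≈ 8`, parental Bax
  at ~60% of the threshold can still lose a few percent of cells over 8 h
  under maximal co-treatment).  Feasible optimized designs sit inside that
  margin.
* Bak is absent (as in the modelled system), so conclusions about Bax
  down-regulation do not transfer to Bak-redundant cell types.
* No pharmacokinetics: drugs are parameter changes with instantaneous
  pre-incubation equilibria; staurosporine is a binary trigger.
* The downstream caspase cascade is not modelled; "apoptosis" here is
  threshold-gated commitment at the mitochondrial outer membrane.
* Calibrated rate values are not unique (three datapoints, ten
  parameters); only behaviour-level statements are reproducible.
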