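# bcl2dyn

Dynamics of Src-controlled mitochondrial apoptosis in the Bcl-2 network,
for systems biologists studying how oncogenic kinase activity reshapes the
intrinsic death pathway and what that implies for combination therapy.

Src-transformed fibroblasts resist staurosporine-induced apoptosis because
active Src (via Erk1/2) accelerates degradation of the BH3-only sensitizer
Bik, while simultaneously over-expressing the effector Bax.  `bcl2dyn`
implements the two ODE models that formalize this:

**Bik turnover** — synthesis at rate $k_S$, spontaneous ubiquitylation at
$k_{ubi}$, and a Src-dependent Michaelis–Menten ubiquitylation branch:

$$\frac{d[\mathrm{Bik}]}{dt} = k_S - k_{ubi}\,[\mathrm{Bik}]
  - \frac{V_{max}\,[\mathrm{Bik}]}{K_m + [\mathrm{Bik}]}$$

with a closed-form steady state (`bik_steady_state()`), chase-decay
simulation and CMA-ES fitting (`fit_bik()`).

**The apoptosis network** — eleven Bcl-2 family species (Bik activation and
sequestration, Bid truncation to tBid, tBid-catalysed Bax activation,
dimeric + autocatalytic Bax oligomerization, a lumped anti-apoptotic pool)
under mass action, with four exact conservation laws, coupled to a
Hill-gated population survival law

$$\frac{dn}{dt} = -a\,n\,\frac{[\mathrm{BaxOligo}]^{\gamma}}
  {[\mathrm{BaxOligo}]^{\gamma} + {B^\ast}^{\gamma}}$$

where $B^\ast$ is the apoptotic threshold on oligomerized Bax.  On top of
the simulator (`simulate_apoptosis()`) sit a declarative treatment layer
(`treatment_spec()`: staurosporine, Src inhibition, BH3-mimetic pool
depletion, Bax down-regulation, tBid up-regulation), constrained CMA-ES
calibration (`calibrate_apoptosis()`), in-silico therapy optimization
(`optimize_therapy()`, `rank_combinations()`), and synthetic-data
generators with ground truth (`gen_bik_decay()`, `gen_colocalization()`,
`gen_apoptosis_endpoints()`).

## Worked example

```r
library(bcl2dyn)

# Bik steady states: the transformed line sits at 18% of the parental level
bik_steady_state(parental_bik_params())[["Bik"]]   # 50
bik_steady_state(src_bik_params())[["Bik"]]        # 9.2

# calibrated network, 8 h staurosporine in parental cells
p <- calibrated_apoptosis_params()
simulate_apoptosis(parental_cell(), p, treatment_spec(staurosporine = TRUE))
#> Apoptosis simulation: parental, STS
#>   t_end = 480 min, apoptotic cells = 80.27%
#>   conservation drift = 2.81e-15

# herbimycin pre-incubation breaks the resistance of transformed cells
simulate_apoptosis(src_cell(), p,
                   treatment_spec(staurosporine = TRUE, src_inhibition = 0.98))
#> Apoptosis simulation: src, STS + Src-inh 98%
#>   t_end = 480 min, apoptotic cells = 98.63%

# a BH3 mimetic is the wrong drug here: brutal on healthy cells...
simulate_apoptosis(parental_cell(), p,
                   treatment_spec(staurosporine = TRUE, bcl2_depletion = 182))
#>   ... apoptotic cells = 99.05%
# ...and harmless without the stimulus (not a primed-for-death system)
max(abt_alone_scan(parental_cell(), p, seq(0, 600, by = 100)))
#> 0.037

# the selective strategy exploits Bax over-expression in cancer cells
evaluate_design(c(src_inhibition = 1, bcl2_depletion = 550, bax_delta = 42), p)
#> Therapy design: STS + Src-inh 100% + Bcl2 -550 nM + Bax -42 nM
#>   efficacy 99.86% (Src), toxicity 0.18% (parental), feasible
#>   cost = 0.1442
```

The first simulation reports that 80% of parental cells die within 8 h of
staurosporine; the herbimycin arm shows Src inhibition restoring apoptosis
(99%) in transformed cells; the depletion arms show why inhibitors of
anti-apoptotic proteins fail in this system; and the final design shows
the counter-intuitive optimum — down-regulating pro-apoptotic Bax — which
pushes parental cells below the death threshold while transformed cells,
with twice the Bax, remain killable.

The methods vignette (`vignettes/bcl2dyn-methods.Rmd`) documents the model
assumptions, the calibration constraints, the identifiability caveats and
the numerical choices.

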