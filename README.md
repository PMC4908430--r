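# ribopinch

Kinetic and thermodynamic analysis of peripheral-domain activation in
HDV-like self-cleaving ribozymes.

## The problem

HDV-like ribozymes adopt a nested double-pseudoknot fold and cleave
themselves at the 5' end of their P1 helix. In some variants a peripheral
helix (P1.2) in the J1/2 joining region acts as a molecular "pinch": when it
forms, it juxtaposes the P1 and P2 helices and accelerates the rate-limiting
conformational change that precedes chemistry. Given a series of constructs
whose peripheral helix varies in length and composition, the quantitative
questions are:

* what is each construct's observed self-scission rate constant
  k<sub>obs</sub> (the faster component of a biexponential fit)?
* how does k<sub>obs</sub> depend on Mg²⁺ (Hill coefficient, estimated
  honestly in the sub-saturation regime)?
* expressed as an apparent activation energy
  E<sub>a</sub> = −RT·ln(k<sub>obs</sub>/k<sub>uncat</sub>) against the
  uncatalyzed phosphodiester-cleavage baseline, what fraction *c* of the
  helix folding free energy ΔG°₃₇ is transduced into barrier lowering, and
  where does the benefit plateau?

The package answers these with: mono-/biexponential time-course fitting with
AICc model selection (`fit_kinetics`), log-log and identifiability-guarded
nonlinear Hill fits (`fit_loglog_slope`, `fit_hill_nonlinear`), an
activation-energy ledger with explicit constants (`energy_ledger`),
nearest-neighbor helix thermodynamics and information content
(`helix_dG37`, `info_bits`), linear and segmented coupling regressions
(`linear_coupling_fit`, `hinge_fit`, `info_activity_fit`), and a forward
"pinch" kinetic model

k<sub>conf</sub> = A·exp(−(E<sub>a0</sub> − c·min(E<sub>P1.2</sub>, E<sub>cap</sub>))/RT),  1/k<sub>obs</sub> = 1/k<sub>conf</sub> + 1/k<sub>chem</sub>

that doubles as a synthetic-data generator (`simulate_panel`,
`gen_timecourse`, `gen_titration`, `gen_construct_ladder`), so every
estimator is validated by parameter recovery without any experimental
download. See the vignette in `vignettes/` for the model details and design
rationale.

## Worked example

Simulate a ladder of constructs whose peripheral helix grows from 0 to 7 bp,
convert rates to activation energies, and recover the coupling:

```r
library(ribopinch)

ns     <- noise_spec("lognormal_multiplicative", sd = 0, seed = 1)
ladder <- gen_construct_ladder(0:7, mean_stack_dG = 0.81,
                               pinch = pinch_params(k_chem = 1e9), noise = ns)

ledger <- energy_ledger(ladder$construct_id, ladder$k_obs,
                        uncat_model("constant", k_ref = 1.7e-10))
ladder$E_a_apparent <- ledger$E_a_apparent

linear_coupling_fit(ladder)
#> <coupling_fit> [pooled, linear] slope = 0.290 (dE_a/dDeltaG), r^2 = 0.933, n = 8
hinge_fit(ladder)
#> <coupling_fit> [pooled, hinge] slope = 0.380 (dE_a/dDeltaG), r^2 = 1.000, n = 8
#>   plateau beyond 4.00 kcal/mol of helix stabilization
info_activity_fit(ladder[ladder$p12_bp <= 4, ])$fold_per_10bits
#> [1] 12.14647
```

Reading the output: the ladder crosses the 4 kcal/mol cap, so a straight
line through all points is shallower (0.29) than the true coupling; the
hinge fit recovers both the generating coupling fraction (0.38 — about one
third of the helix free energy is used to lower the barrier) and the plateau
at 4 kcal/mol of helix stabilization. Below the cap, every 10 bits of helix
information (5 bp) buys a ~12-fold rate increase.

The Hill analysis on a synthetic sub-saturation titration
(K<sub>1/2</sub> = 100 mM, measured at 0.1–3 mM):

```r
tit <- gen_titration(1.06, 100, 1, exp(seq(log(0.1), log(3), length.out = 8)), ns)
fit_hill_nonlinear(tit)
#> <hill_fit> method = nonlinear: n = 1.054  [saturation not observed]
```

With a Hill coefficient of unity and no saturation, rates extrapolate
linearly in [Mg²⁺]: `extrapolate_kobs(0.2, 1, 10)` gives 2 s⁻¹.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "ribopinch.R", package = "ribopinch")` with subcommands
`fit-kinetics`, `fit-hill`, `energy-ledger`, `helix-energy`, `coupling-fit`,
`simulate-panel`, `synth` and `run-all`; `run_pipeline()` is the
programmatic equivalent of `run-all`.

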