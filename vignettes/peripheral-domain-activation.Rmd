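---
title: "Quantifying peripheral-domain activation of self-cleaving ribozymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripheral-domain activation of self-cleaving ribozymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopinch)
```

## The scientific problem

HDV-like self-cleaving ribozymes fold into a nested double-pseudoknot whose
catalytic core cleaves the RNA at the 5' end of the P1 helix. In some family
members a peripheral helix (P1.2) inside the J1/2 joining region acts as a
"pinch": by forming, it pulls the distal ends of P1 and P2 together and
promotes the conformational change that produces the catalytically competent
state. The experimental signature is a family of constructs differing only in
the length and composition of that peripheral helix, each yielding a
self-scission time course, from which one asks: how much of the helix's
folding free energy is converted into activation-barrier lowering, and where
does the benefit saturate?

This package implements the full quantitative chain for that question:
time-course fitting, Mg²⁺ dependence, activation-energy bookkeeping, helix
thermodynamics, the coupling regressions, and a forward kinetic model that
doubles as a synthetic-data generator so the whole chain can be validated
without any experimental input.

## Kinetic fitting

Fraction-intact data $f(t)$ are fit to

$$f(t) = f_\infty + \sum_{i=1}^{m} A_i e^{-k_i t}, \qquad m \in \{1, 2\},$$

with rates bounded in $[10^{-7}, 10^{3}]\,\mathrm{s^{-1}}$ and amplitudes and
the plateau in $[0,1]$. The plateau $f_\infty$ is a free parameter because a
persistent uncleaved fraction is the norm in gel-based self-cleavage assays;
`fix_plateau = TRUE` pins it to zero for the classical two- and
three-parameter models. The biexponential least-squares surface is
multimodal, so both fitters use multi-start initialization with rate seeds
log-spaced across the observed time window (and asymmetric amplitude seeds:
symmetric starts sit on a ridge where the Jacobian is singular). The observed
rate constant $k_{\mathrm{obs}}$ is always the *faster* rate of a
biexponential fit — the slow component is interpreted as a misfolded or
slowly committing subpopulation.

Model choice between $m = 1$ and $m = 2$ uses the corrected Akaike criterion
$\mathrm{AICc} = n\log(\mathrm{rss}/n) + 2p + 2p(p+1)/(n-p-1)$ with ties
going to the simpler model. Two deliberate choices here:

* $p$ counts mean-function parameters only. At $n \le p + 1$ the correction
  diverges; we define AICc as $+\infty$ there, so a five-parameter
  biexponential can never be selected from six points. This is the behavior
  one wants at gel-kinetics sample sizes (8–12 time points).
* An extra-sum-of-squares F-test is available (`criterion = "ftest"`) for
  users who prefer a significance-based rule; both agree on well-separated
  rate pairs.

## Mg²⁺ Hill analysis

The titration model is $k_{\mathrm{obs}} = k_{\max}[\mathrm{Mg}]^n /
(K_{1/2}^n + [\mathrm{Mg}]^n)$. The regime matters: these titrations are
typically *sub-saturating* ($[\mathrm{Mg}] \ll K_{1/2}$), where $k_{\max}$
and $K_{1/2}$ enter the likelihood only through the lumped scale
$k_{\max}/K_{1/2}^n$. Fitting all three parameters there is an
identifiability trap. `fit_hill_nonlinear()` therefore attempts the full
fit, checks whether the fitted $K_{1/2}$ falls inside the measured range,
and if it does not (or if the full fit refuses to converge, which is the
same symptom) refits the identifiable power law $\log k = \log s + n \log
[\mathrm{Mg}]$, reporting $k_{\max}$ and $K_{1/2}$ as `NA` with
`saturation_flag = FALSE`. The log-log slope estimator
(`fit_loglog_slope()`) is exact in the $[\mathrm{Mg}] \ll K_{1/2}$ limit;
the two estimators agree within 0.05 on sub-saturation data, and the
package warns when visible curvature means the slope underestimates $n$.

Least squares is computed on log rates by default, matching the log-log
design; linear-space weighting is available via `weighting = "linear"`.
Concentrations are fixed to mM at the interface. The synthetic emulation of
a sub-saturation titration uses a 0.1–3 mM grid with $K_{1/2} = 100$ mM —
an assumption chosen to keep the working range two decades or more below
half-saturation, not a measured value.

## Activation energies

Rates are placed on an energy scale via
$E_a^{\mathrm{app}} = -RT\,\ln(k_{\mathrm{obs}}/k_{\mathrm{uncat}})$ with
$R = 1.98720\times10^{-3}$ kcal mol⁻¹ K⁻¹ (carried in kcal throughout;
$RT = 0.61633$ kcal/mol at 310.15 K) and the thermochemical calorie
(4.184 J) for kJ conversion. The baseline $k_{\mathrm{uncat}}$ is the rate
of spontaneous phosphodiester transesterification under matched conditions.
Two modes are provided:

* **constant** — a declared `k_ref` used at every condition;
* **parameterized** — a log-linear empirical law around a reference
  condition (one decade per pH unit in the base-catalyzed regime above a
  configurable floor, Arrhenius temperature scaling, a linear divalent-ion
  term), with coefficients in `inst/extdata/uncat_baseline.yaml`.

A point documented prominently because it removes a whole class of worry:
every regression downstream depends only on *differences* of
$E_a^{\mathrm{app}}$ across constructs at a fixed condition, so the absolute
baseline cancels. The bundled coefficient values are approximate
transcriptions of published background-cleavage behavior and shift only the
common offset of the ledger; both the mode and the constants used are
recorded in every ledger row.

## Helix thermodynamics

Peripheral-helix stability is scored with a table-driven nearest-neighbor
model at 37 °C: duplex initiation + stacking term per dinucleotide step +
a terminal penalty per A-U/G-U helix end + an optional hairpin-loop penalty.
The bundled table is the Turner 2004 set as distributed with ViennaRNA
(stacks over all Watson–Crick and G·U steps, in kcal/mol), checked for
strand-flip symmetry on load; any same-schema CSV can be swapped in.
Internal loops and bulges are rejected rather than approximated, because the
variant series this package targets are contiguous helices.

Absolute minimum-free-energy values for whole pseudoknotted ribozymes are
*not* reproducible with any nearest-neighbor helix model (pseudoknot
prediction handles P1.1/P3 register shifts differently); only relative
stability trends across a construct series are in scope, and
`construct_records()` accepts externally computed MFE values per construct
for users who have them. Information content is the simple field convention
of 2 bits per base pair.

## Coupling regressions

With records assembled, three fits quantify the energy coupling:

* `linear_coupling_fit()` — OLS of $E_a^{\mathrm{app}}$ on helix free
  energy. On the signed axis (more negative = more stable) the expected
  slope is positive; the object reports both sign conventions
  (`slope`, `slope_magnitude`). Per-linker-class fits are available because
  linearity holds within an architecture, and groups must be
  condition-matched. The wild-type row is excluded by default (toggleable).
* `hinge_fit()` — continuous two-segment model $E_a = a + b\min(m,\theta)$
  in the stabilization magnitude $m$, with $\theta$ profiled on a 0.1
  kcal/mol grid across the observed range. The hinge is adopted only when
  it materially lowers the rss (ties go to the line — relevant for
  noiseless data where both fits are at numerical zero) *and* wins on AICc.
* `info_activity_fit()` — OLS of $\log_{10} k_{\mathrm{obs}}$ on bits,
  summarized as the fold-change per 10 bits, $10^{10\,\mathrm{slope}}$.

## The forward pinch model

The two-step scheme is: conformational change (rate $k_{\mathrm{conf}}$),
then chemistry (rate $k_{\mathrm{chem}}$). The peripheral helix pays a
fraction $c$ of its formation energy $E_{P1.2}$ against the conformational
barrier, up to a cap:

$$k_{\mathrm{conf}} = A\,\exp\!\left(-\frac{E_{a0} - c\,\min(E_{P1.2},
E_{\mathrm{cap}})}{RT}\right), \qquad
\frac{1}{k_{\mathrm{obs}}} = \frac{1}{k_{\mathrm{conf}}} +
\frac{1}{k_{\mathrm{chem}}}.$$

The harmonic combination is the steady-state rule for sequential
irreversible first-order steps and reproduces both limits smoothly
(conformational-change-limited when the helix is weak, chemistry-limited
when it is strong); a hard `min()` alternative is available. The cap is
placed inside `conf_rate()` as a hard saturation — putting the leveling-off
solely in the chemistry plateau is the configurable alternative, and both
produce the same observable shape. Defaults: $c = 0.38$,
$E_{\mathrm{cap}} = 4$ kcal/mol, $k_{\mathrm{chem}} = 1$ s⁻¹, and
$(A, E_{a0}) = (10^{13}\,\mathrm{s^{-1}}, 24.1\,\mathrm{kcal/mol})$ so that
the zero-stability construct cleaves on the hours scale
($k_{\mathrm{conf}}(0) \approx 10^{-4}$ s⁻¹) — the last pair is a declared
model default, not a measurement.

Two numbers worth keeping straight: at the defaults the conformational step
is accelerated at most $\exp(0.38 \times 4 / RT) \approx 11.8$-fold, while
*full* transduction of the 4 kcal/mol barrier lowering corresponds to
$\exp(4/RT) \approx 658$, i.e. $\log_{10} \approx 2.82$ — almost, but not
quite, three orders of magnitude. Whether a reported total acceleration
refers to the former compounded across a construct series or the latter
closed form is ambiguous in general; the package exposes both
(`enhancement_factor()` with the package defaults vs. `c = 1`) and treats
the closed form as the upper bound.

## Synthetic data: what it emulates and what it does not

The generators produce noisy time courses (additive Gaussian on fractions,
clipped to $[0,1]$ with clipping counted — truncated sampling was rejected
as needless complexity at sd ≤ 0.05), sub-saturation titrations and
construct ladders (log-normal multiplicative noise on rates, the
between-replicate error structure; replicate counts default to 2 where
replication is meaningful). Every generator is a pure function of
(parameters, seed) and restores the caller's RNG stream.

The ladder default of 0.81 kcal/mol mean stability per base pair is the
value at which, with $c = 0.38$, each 5-bp extension below the cap
multiplies the rate ~12-fold; real helices have stronger and
sequence-dependent stacks, which is why `gen_construct_ladder()` also
accepts explicit duplexes scored by the nearest-neighbor model.

What passing the recovery tests does **not** show about real data: the
generators draw independent homoscedastic noise, contain no gel-quantification
bias, no temperature or pipetting drift, no misfolded subpopulations beyond
the explicit biexponential mixture, and no secondary-structure heterogeneity
of the rest of the ribozyme. They validate the estimators under the model's
own assumptions, nothing more.

## Numerical choices and problem sizes

* Rate bounds $[10^{-7}, 10^3]$ s⁻¹; multi-start counts of 5 rate seeds
  (mono) and all their pairs (bi).
* Breakpoint grid 0.1 kcal/mol; hinge tie tolerance
  $10^{-10}(1 + \mathrm{rss})$.
* AICc rss floor $10^{-300}$ to keep noiseless fits finite.
* Validation problem sizes: recovery suites use 200 synthetic
  monoexponential fits at noise sd 0.02, 10-point time courses; 50–200
  replicate panels of 12 constructs for coupling-slope recovery. These sizes
  give stable medians and means while keeping the default test run fast.

## Known limitations

Only two exponential components; no mechanistic two-metal-ion binding
models; no partition-function or pseudoknot structure prediction; no
reverse (ligation) pathway — the chemistry is treated as unidirectional; the
hypothesized partially stable folding intermediate is not modeled, since
the two-state scheme already reproduces the observable kinetics.
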