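---
title: "Zinc speciation with citrate and DFOB: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zinc speciation with citrate and DFOB: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znspec)
```

## The problem

In the rhizosphere — the millimetre-scale soil zone around roots — zinc is
shuttled between chemically very different organic ligands. Citrate, a
tricarboxylate exuded in large amounts, binds Zn(II) weakly; desferrioxamine B
(DFOB), a bacterial trihydroxamate siderophore, binds it strongly but is
scarce. Whether these two ligand classes can act *synergistically* (the weak
ligand leaching metal off soil aggregates, the strong one carrying it to the
cell surface) hinges on whether the pH and ionic-strength gradients around the
root are steep enough that each ligand's complexes dominate in different
places. The quantitative object of interest is the **ligand-exchange point
(LEP)**: the pH (at fixed ionic strength) or ionic strength (at fixed pH) at
which the Zn fraction complexed by DFOB equals the fraction complexed by
citrate, each evaluated in its own binary system at the standard
ligand-efficiency test concentrations [Zn] = 10⁻⁶, [L] = 10⁻⁵ mol dm⁻³.

`znspec` implements the full chain from measured, medium-dependent stability
constants to LEPs and stability windows:

1. a chemical model container with the Zn/Cit/DFOB scheme built in
   (`zn_cit_dfob_model()`);
2. ionic-strength machinery — the Davies equation and a parametrised extended
   Debye–Hückel (EDH) model with least-squares fitting and Monte-Carlo
   confidence intervals;
3. a general Newton speciation solver on the component mass balances;
4. the LEP / dominance-window / sensitivity pipeline;
5. a potentiometric-titration toolkit (forward simulation, electrode
   calibration, joint refinement of constants) with a synthetic study-design
   generator in place of raw laboratory data.

## Stability constants and the EDH model

All equilibria are written as overall association reactions over the
components Zn²⁺, Cit³⁻, DFOB³⁻ and H⁺. Hydrolysed species carry negative
proton coefficients with water implicit, e.g.

$$2\,\mathrm{Zn}^{2+} + 2\,\mathrm{Cit}^{3-} + 2\,\mathrm{H_2O}
  \rightleftharpoons [\mathrm{Zn_2(OH)_2(Cit)_2}]^{4-} + 2\,\mathrm{H}^+ .$$

A conditional constant $\log\beta(I)$ measured in NaCl at ionic strength $I$
is linked to the intrinsic constant $\log\beta^0$ at $I = 0$ by

$$\log\beta(I) \;=\; \log\beta^0 \;-\; \frac{0.51\, z^* \sqrt{I}}{1 + 1.5\sqrt I}
  \;+\; C\,I ,$$

with $z^*$ a fixed charge factor and $C$ the single adjustable ionic-pairing
coefficient per species. Because the expression is linear in
$(\log\beta^0, C)$ once $z^*$ is fixed, `fit_edh()` is a closed-form weighted
regression — deterministic and exactly reproducible, and checked in the test
suite against a brute-force 2-D grid search.

**Sign convention.** The package fixes the sign of the Debye–Hückel term by a
single requirement: unweighted least-squares refits of the shipped
conditional series must reproduce the shipped $(\log\beta^0, C)$ values. With
$z^*$ defined as reactants-minus-products of $\nu z^2$ (so $z^* = 12$ for
Zn²⁺ + Cit³⁻ ⇌ ZnCit⁻) the convention above does so to ≤ 0.02 log units for
11 of the 15 equilibria, which also settles the question of how $z^*$ is to
be computed (it is not derivable from the constants alone).

**Known inconsistencies in the shipped constants.** Three entries of the
published constant set cannot be made self-consistent and are handled
explicitly rather than silently:

* *HDFOB²⁻*: the conditional series (11.07 → 10.14 over $I$ = 0.05–1.0)
  refits to $C = -0.170$ with $\log\beta^0 = 11.491$ exactly as published,
  while the published $C$ is $+0.169$. No choice of $z^*$ reconciles the
  positive sign with the series; the built-in model stores the
  sign-corrected $C = -0.169$.
* *[Zn(Cit)₂]⁴⁻*: the published $(\log\beta^0, C) = (7.400, 0.284)$ is not
  reproducible from its own four-point series under any integer $z^*$ or
  weighting (best fit: 7.647, 0.316). The published values are stored as-is;
  the species is negligible at the 10⁻⁶/10⁻⁵ study concentrations.
* *The two hydroxo citrate complexes*: the standard charge factors (8 for
  the binuclear species from the balanced reaction, −6 for
  [Zn(OH)₃Cit]⁴⁻) do not reproduce the published parameters, but effective
  values $z^* = 12$ and $z^* = 6$ do so to ≤ 0.002. The built-in model ships
  these effective factors (flagged in the source) so that conditional
  constants evaluated at any $I$ stay on the same curve the published
  parameters describe; `z_star()` itself always implements the standard
  rule.

**Weighting.** Point estimates use unweighted least squares — inverse-variance
weighting moves every fit far from the published parameters (the 0.05
mol dm⁻³ points have ~10–20× the uncertainty of the rest, and weighting lets
the remaining four points dictate a very different slope). Error propagation
is the opposite: `monte_carlo_ci()` perturbs the *fitted* curve with the
per-point σ's (inverse-CDF normal draws) and refits each replicate with
1/σ² weights. This combination reproduces the published uncertainties almost
exactly (ZnCit⁻: ±0.0088 vs ±0.009 on $\log\beta^0$, ±0.015 vs ±0.015 on $C$;
ZnDFOB⁻: ±0.043 vs ±0.039), and is internally consistent because a refit of
the unperturbed fitted curve returns the point estimate under any weighting.

## The speciation solver

`solve_equilibrium()` iterates damped Newton steps on the component mass
balances in log-free-concentration space (positivity is automatic). Details
that matter:

* **Tolerance** 10⁻¹⁰ on the largest relative mass-balance residual; maximum
  200 iterations with step-halving line search and a small multistart ladder
  over initial proton guesses before declaring failure.
* **pH convention**: conditional constants are concentration products, so
  internally pH ≡ −log₁₀[H⁺]. Fixed-pH mode drops the proton balance;
  total-proton mode treats H as an unknown and includes autoprotolysis
  through a conditional ion product of water (pKw = 13.997 at $I=0$,
  Davies-adjusted — 13.78 in 0.1 mol dm⁻³ NaCl).
* **Background electrolyte** (Na⁺, Cl⁻) is not a component; it enters only
  through the $I$-dependence of the constants. Zn–Cl ion pairing is outside
  the model scope.
* **Constant source**: the solver evaluates every species' conditional
  constant through the EDH parametrisation (`prefer = "edh"`), falling back
  to tabulated values only when no intrinsic form exists. Speciation curves
  therefore follow the smooth ionic-strength model rather than the
  measurement scatter; `zn_cit_dfob_model("conditional", I = ...)` gives
  direct access to the tabulated values where they exist.
* **Zn hydrolysis**: Zn(OH)⁺ … Zn(OH)₄²⁻ with NIST-compilation intrinsic
  constants (−8.96, −16.90, −28.40, −41.20) are included as a clearly
  flagged, removable block. Below pH 8 with ligand excess they are minor;
  they shave ≲ 0.3 % off the plateau fractions near pH 9.

`fraction_complexed()` counts ν_Zn-weighted mixed Zn–ligand species over
total Zn; free Zn²⁺ and hydroxo-only species are excluded, and the partition
free + hydroxo + per-ligand fractions sums to 1 to 10⁻⁹ in every converged
result.

## Ligand-exchange analysis

`find_lep()` solves the two binary systems independently on a scan grid,
brackets sign changes of $f_\mathrm{DFOB} - f_\mathrm{Cit}$ and refines each
bracket by bisection to 10⁻⁴. Multiple crossings are returned with an
ambiguity flag; when the curves never cross, the scan point of closest
approach is reported instead of a root. The default reproduction pipeline
(`reproduce_study()`) scans pH 3–10: both ligands complex Zn inside this
window, while above pH ≈ 10.5 hydroxide chemistry produces a second,
chemically distinct crossing of the two curves that is not a ligand-exchange
point in the intended sense.

A ternary mode (both ligands in one solution) is available through
`solve_equilibrium()` directly, but the exchange point itself is defined on
the binary systems: at trace metal the two definitions coincide (equality of
the two binding strengths), and the binary form matches how fraction curves
are measured and plotted in this field.

`davies_vs_edh_experiment()` quantifies the inconsistency introduced by
single-ionic-strength Davies corrections: intrinsic constants derived from
one conditional data point via the Davies equation differ from the
full-series EDH fit, and the resulting infinite-dilution models disagree on
the complexed fraction — at pH 5.5 the 1 mol dm⁻³-derived citrate model
underpredicts the complexed fraction by about 40 % relative to the EDH
model, while the 0.05 mol dm⁻³-derived model overpredicts it. The relative
difference uses the EDH fraction as the denominator.

`sensitivity_lep()` recomputes the LEP with every constant at +σ and −σ
(`perturb_constants()` shifts the intrinsic value and the conditional series
coherently); the hydrolysis block carries σ = 0 so that only the measured
equilibria move.

## What reproduces and what does not

Running `reproduce_study()` recomputes the pipeline's headline numbers from
the conditional series alone. On the citrate side the agreement with the
published speciation benchmarks is close: the fraction of Zn complexed by
citrate at pH 6 falls from 0.93 at infinite dilution to 0.096 at 1 mol dm⁻³
(published: 0.81 at 0.01 and 0.07 at 1 mol dm⁻³; we compute 0.846 at 0.01),
a decrease of 0.83 (published 0.84) and a relative binding-efficiency loss
of ~90 % (published 92 %); the Davies-vs-EDH discrepancy at pH 5.5 computes
to 43 % (published ≈ 38 %); the ±σ sensitivity of the pH-LEP is ≈ 0.0015 pH
(published < 0.01).

On the DFOB side a genuine inconsistency surfaces, and the package reports
it rather than papering over it. With the shipped constants — published or
refit, conditional or EDH-evaluated — the Zn/DFOB complexed fraction at pH 6
is only ~0.002–0.004 at any ionic strength: the exchange
Zn²⁺ + H₄DFOB⁺ ⇌ [Zn(H₂DFOB)]⁺ + 2H⁺ has log K ≈ −9.4 at $I=0$, which at
[L] = 10⁻⁵ leaves essentially no bound zinc at pH 6. Published
benchmarks that require a pH-6 DFOB fraction of ~0.1–0.2 (an
ionic-strength LEP of 0.7 mol dm⁻³ at pH 6, a fraction decrease of 0.09
between $I$ = 0 and 1) therefore cannot follow from the same constant set;
they would need ~1.8 log units more effective DFOB binding. The same offset
pushes the computed pH-LEPs (7.66 / 7.37 / 6.87 at $I$ = 0.01 / 0.1 / 1) about
0.3 pH units above the published 7.4 / 7.1 / 6.5, while reproducing their
monotone decrease with ionic strength exactly. The reported ±σ uncertainties
move the LEP by only ±0.0015 pH, so measurement error in the constants
cannot bridge the gap. The corresponding acceptance checks in
`tests/testthat/test-acceptance.R` are deliberately left failing.

## Synthetic titration data

No raw titration data ship with the package; `generate_study_dataset()`
emulates the study design instead: 30 mL initial solutions, ligand-only runs
at [L] = 5 mmol dm⁻³ and metal runs at Zn:L ratios 1:1–1:10 (Zn 0.5–1.5,
L 1–5 mmol dm⁻³), backgrounds $I$ = 0.05–1.0 mol dm⁻³, NaOH titrant, 90
points per curve (the mid-range of the 80–100 collected experimentally), and
Gaussian read-out noise of 0.2 mV / 0.003 mL. Ligands enter as their
protonated forms (citric acid, H₄DFOB⁺ mesylate) plus a 3 mmol dm⁻³ HCl
preload, which starts the curves near pH 2.4 with the ligands fully
protonated; the schedule spans 1.05× the total titratable protons so each
run crosses its equivalence region and ends near pH 11. Each curve draws its
noise from a sub-seed derived from the master seed, so a fixed seed
reproduces the data set byte for byte, and the manifest records the full
design and generating constants.

What the generator does *not* emulate: electrode drift and junction
potentials, CO₂ ingress, carbonate contamination of the titrant, per-point
ionic-strength feedback on the constants, and real chemical interferences.
Passing recovery tests on these data therefore demonstrate that the
estimation machinery is correct and well-calibrated under the stated noise
model — not that any particular laboratory data set would refine as cleanly.

One design tension is worth recording: at low background ionic strength the
fixed-$I$ idealisation is mathematically strained. A 5 mmol dm⁻³
triply-charged ligand contributes up to ~0.02–0.03 mol dm⁻³ of solute ionic
strength once deprotonated, which at $I$ = 0.05 is a > 10 % excursion no
matter how the background is pre-adjusted (at $I \ge 0.3$ the drift stays
below 10 %, consistent with how such experiments are usually reported). The
`ionic_strength_drift()` diagnostic makes the excursion visible instead of
assuming it away; refinement nevertheless treats $I$ as fixed per curve,
which is the standard practice the constants themselves were derived under.

## Refinement

`refine_constants()` minimises the weighted emf residuals jointly over all
curves of one ionic strength (Levenberg–Marquardt via `minpack.lm`), with
per-point weights $w = 1/(\sigma_E^2 + (dE/dV)^2 \sigma_V^2)$ propagating
the volume error through the observed curve slope. The misfit statistic
$\sigma = \sqrt{\sum w r^2/(n-p)}$ is ≈ 1 when the weights match the actual
noise (the test suite verifies a 0.8–1.2 band over 50 replicates);
refinements with σ > 5 are flagged as rejected, and parameters with
standard deviations above 1 log unit (or a near-singular normal matrix)
raise an identifiability warning naming the species — attempting to refine
[Zn(Cit)₂]⁴⁻ from a 1:1 curve triggers it, matching the experimental
observation that this species needs ligand excess to be determinable.
Electrode calibration (`calibrate_electrode()`) fits E vs log₁₀[H⁺] on the
strong-acid side with the same volume-error weighting; E₀ is recovered to
well under 1 mV at the instrument noise level.

## Problem sizes and determinism

The default pipeline is desk-scale: EDH fits are closed-form; one
speciation solve takes a few milliseconds; an LEP (101-point scan plus
bisection) about a second; the full `reproduce_study()` under five seconds;
the test suite, including 50 seeded refinement replicates, a few minutes.
Every stochastic component (Monte-Carlo CIs, synthetic noise, random-mode
perturbations) requires an explicit seed and is reproducible from it; RNG
state is restored after use so library calls do not perturb user sessions.
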