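---
title: "Methods: stoichiometry and energetics of autotrophic sulfur oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometry and energetics of autotrophic sulfur oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxtherm)
```

## The model

Chemolithoautotrophic sulfur-oxidizing bacteria (SOB) split a pool of
reduced sulfur (sulfide or thiosulfate) between two fates: a fraction `y`
is oxidized with a terminal electron acceptor (TEA: O2, or NO3- via
denitrification or DNRA) to generate energy, and the remaining `1 - y`
donates its electrons to CO2 fixation.  Independently, a fraction `x` of
the oxidized sulfur atoms stops at zero-valent sulfur (S0) while `1 - x`
proceeds to sulfate.  Two assumptions define the family of balanced
equations this package builds:

* the S0 : SO4 partition `x` is the same for the energy-generating and
  the CO2-fixing branch, and
* each branch is an electron-conserving combination of the substrate
  oxidation half-reaction (electron yield `E(x) = 8 - 6x` per mole for
  both substrates) with the reduction half-reaction of the TEA
  (4 e- per O2, 5 per NO3- in denitrification, 8 per NO3- in DNRA), of
  CO2 (4 e- per CH2O), or of the electron carriers demanded by the
  C-fixation pathway.

All builders (`energy_equation()`, `assimilation_equation()`,
`ret_equation()`, `overall_equation()`) assemble reactions from these
half-reactions, so element and charge balance hold by construction and
are verified independently by `check_balance()`.

Negative `x` is admitted for sulfide (down to `x = -10`, with a warning
below `-2`): it describes net co-oxidation of stored elemental sulfur,
as observed in symbiont-bearing tubeworms.

### Thiosulfate generalization

For thiosulfate we take the incomplete route to be the oxidation of the
sulfane sulfur only,

    S2O3^2- + H2O -> S0 + SO4^2- + 2 H+ + 2 e-,

so that a fraction `x` of the pool through this route gives products
`x S0 + (2 - x) SO4^2-` and the electron yield `8 - 6x` on `x` in
[0, 1].  We considered the alternative in which `x` is the fraction of
*all* sulfur atoms ending as S0 (products `2x S0 + (2 - 2x) SO4^2-`,
yield `8 - 12x`, `x < 2/3`).  The sulfane-route version was retained
because (i) it reduces to the textbook complete oxidation at `x = 0`,
(ii) it keeps the natural domain `0 <= x <= 1`, and (iii) it exactly
reproduces the reference efficiency of the one thiosulfate strain in the
packaged compilation with `x > 0` (Thiomicrospira sp. L-12, `x = 0.2`),
which the all-atom version does not.

## Thermodynamic constants

Formation free energies are biochemical-standard values (pH 7, 1 M,
25 degC) from the classical Thauer compilation, shipped as a versioned
two-column file (`inst/extdata/thermo_table.tsv`) rather than hard-coded.
Three entries deserve comment:

* **O2** is priced as the dissolved species (+16.4 kJ/mol), not the gas.
* **CH2O** (generic biomass) is one-sixth of glucose (-152.87 kJ/mol);
  this choice, not formaldehyde, reproduces the accepted +145 kJ/mol for
  sulfide-driven CO2 reduction at `x = 0`.
* **Thiosulfate** is a calibrated entry (-523.1 kJ/mol).  The commonly
  tabulated -513.2 kJ/mol underestimates the reference efficiencies of
  the aerobic thiosulfate oxidizers by about 10% relative (e.g. 2.65%
  instead of 2.90% for *Thioalkalivibrio versutus*).  We solved for the
  value that reproduces the reference traditional efficiencies of two
  independent thiosulfate strains (*T. versutus* and *Sulfurimonas
  denitrificans*); both give -523.2/-523.0, and the retained -523.1
  brings every thiosulfate row of the compilation within 0.1 percentage
  points except the L-12 row discussed above (0.3).  N2 is priced as the
  dissolved species (+18.2 kJ/mol), consistent with dissolved O2; this
  choice reproduces the denitrifying rows to within 0.06 points where
  the gas-phase zero leaves 0.2-point residuals.

Redox carriers enter only as couple increments (NADH - NAD+ =
60.99, FADH2 - FAD = 42.65, Fd_red - Fd_ox = 38.88 kJ per mole reduced
carrier), and ATP is booked at 41 kJ/mol.

### The proton convention

Printed forms of reaction-energy sums in the literature often omit the
H+ term because biochemical-standard tables already price H+ at pH 7.
We keep H+ as an explicit species with its Thauer pH 7 value
(-39.87 kJ/mol) and, consistently, let it enter the reaction quotient
*relative to the pH 7 standard state*, as `10^-(pH - 7)` per unit
coefficient.  Taking the quotient's [H+] literally (absolute molarity)
would double-count the pH 7 correction: the Gibbs energy would then not
reduce to its standard value at 1 M / pH 7.  With our convention
`delta_g()` satisfies `total == standard` exactly at
`standard_conditions()`, which is also how the reference efficiencies
must have been computed, since they are reproduced.

Activities are approximated by molar concentrations; S0 and H2O carry
unit activity (pure solid / solvent).  Temperature enters only through
`RT ln Q`; the formation energies themselves are not
temperature-corrected (no van 't Hoff / heat-capacity model), and no
ionic-strength activity model is applied.

## Efficiencies

The traditional efficiency divides the Gibbs energy stored by net CO2
reduction by the energy released by TEA reduction
(`efficiency_traditional()`):

    eps_I = (1 - y) dGr(CO2 red) / (-y dGr(TEA red)).

The carrier-explicit efficiency (`efficiency_new()`) recognizes that CO2
reduction proceeds via reverse electron transport (RET) into NADH (and,
for the rTCA cycle, ferredoxin and FADH2) followed by the fixation
reaction with a fixed energy requirement per CO2 (69.7 kJ Calvin,
64.3 kJ rTCA):

    eps_II = (1 - y) [dGr(RET) + dGr(CO2 fix)] / (-y dGr(TEA red)).

Because the two-step energy requirement always exceeds the net one,
`eps_II > eps_I` everywhere.  `factorize_efficiency()` splits `eps_II`
into partial efficiencies; only minima are identifiable, e.g. the
minimum efficiency of the sulfur-oxidation machinery

    eps_SO,min = eps_II [alpha / eps_CO2 + (1 - alpha)],
    alpha = dGr(CO2 fix) / [dGr(RET) + dGr(CO2 fix)],

attained when RET and ATP transfer are lossless.  The fixation-step
efficiency is a pathway constant: `eps_CO2 = 69.7/123 = 0.57` (Calvin,
3 ATP per CO2) and `64.3/(5/3 * 41) = 0.94` (rTCA, 5/3 ATP per CO2; we
use the exact 5/3 rather than the rounded 1.67, which reproduces the
conventional 68.3 kJ per CO2 ATP requirement).

Edge cases: `y = 1` returns efficiency 0 (the limit is well defined);
`y = 0` is an error (no energy source).  The efficiency is refused, with
both Gibbs energies in the message, when the supplied conditions make
the energy reaction endergonic or the CO2-reducing side exergonic.
Note that the formulas exceed 1 for `y` below the feasibility bound
`K/(1+K)` (with `K = [dGr(RET)+dGr(fix)]/(-dGr(energy))`); such `(x, y)`
pairs are thermodynamically impossible stoichiometries, not bugs, and
the test suite asserts the `(0, 1)` bound only above that region.

The CO2 : TEA consumption ratio -- a growth-yield proxy -- follows from
the coefficients as `(1 - y)/y * n_tea/4`, where `n_tea` is the
electrons accepted per mole of TEA.  For O2 this is the familiar
`(1 - y)/y`; for denitrification the factor is 5/4 (the packaged
reference yields confirm this scaling) and for DNRA 2.

## Inverse problems

`solve_xy()` inverts two measured ratios in closed form through the
electron balance `n_tea r + 4 c = E(x)`.  `adjust_for_host()` first
removes a host-respiration share `f` from whole-association
measurements: symbiont O2 = (1 - f) x whole O2, symbiont CO2 = whole CO2
+ RQ x f x whole O2.

When only one ratio is available, `solve_constrained()` adds an
assumption (`inverse_constraint()`): the carrier-explicit efficiency, or
the CO2 : TEA yield, is constant (or, for the efficiency, linear in `x`)
at its value calibrated at `x = 0`.  Because
`eps_II(x, y) = (1 - y)/y * K(x)`, `y` is eliminated analytically and a
single bracketed root search in `x` remains: the admissible domain is
pre-scanned with 64 subintervals, each sign change is polished with
`uniroot` at tolerance 1e-10, and if several roots exist the smallest
`x` is returned with a warning.  The constant-yield constraint fixes `y`
outright and the same residual interface solves `x` in closed form.
`co2_tea_curve()` uses the closed form `y = K/(eps + K)` directly --
no iteration is needed -- and `niche_band()` evaluates the efficiency at
the `x = 1` and `x = 0` extremes implied by the bounds of a fluctuating
TEA : substrate supply ratio.

For yield curves under "environmental" conditions we expose
`environmental_conditions()` (all reactants 1 mM, pH 7); the constant-
efficiency yield curves flatten there relative to the 1 M standard
state, which the test suite asserts.

In the structural test of the yield-curve property we evaluate four
organisms from the sensitivity analysis: the two aerobic sulfide
oxidizers with the Calvin cycle and the two *Sulfurimonas* strains in
their sulfide-driven denitrification mode with the rTCA cycle -- the
mode these epsilonproteobacteria run at natural redoxclines.  With
sulfide as the substrate the constant-efficiency CO2 : TEA variation
over the full `x` range is below 20% for every TEA/pathway combination
(17.6% aerobic/Calvin, 19.5% denitrification/rTCA).  Our re-derived
*thiosulfate* curves vary more strongly (up to ~43%), because
thiosulfate oxidation to S0 + SO4 still releases a large fraction of
the complete-oxidation energy; we know of no published curve for that
case to compare against, and report the sulfide-based property as the
framework's verifiable claim.

## Sensitivity analysis

`sensitivity_scan()` varies one concentration (or the pH) with the
stoichiometry frozen, reporting the chosen efficiency along the range.
"Changes by N%" in our reports means the relative change between the
scanned endpoint and the standard state, `|eps(c) - eps(1 M)|/eps(1 M)`;
for three-decade statements we compare 1e-3 M against 1 M.  A pH scan
moves the proton activity in *all* quotients simultaneously (one
experimental pH governs energy, assimilation and RET alike), and
carrier scans move one pool against the fixed partner so only the
couple ratio matters.  `equalizing_shift()` root-finds (tolerance 1e-6
in log10 space) the fold-change in one species' concentration -- or the
pH -- at which two strains' efficiencies coincide; folds outside
10^(+/-30) are reported as not equalizable, and shifted conditions that
make an efficiency thermodynamically undefined are treated as outside
the search domain.

## Synthetic data

`generate_synthetic_rates()` emulates a batch rate experiment on an
organism of known `(x, y)`: substrate, TEA and CO2 consumption rates are
the overall-equation coefficients scaled by a total sulfur oxidation
rate, each multiplied by independent unit-mean lognormal noise of a
given coefficient of variation.  The defaults mirror the conditions of
the compiled strain experiments: exact coefficient ratios (cv = 0) for
deterministic round trips, and cv = 5% with n = 200 replicates for the
recovery study in the test suite -- a noise level typical of replicated
microsensor or batch-consumption measurements.  What the generator does
*not* emulate: correlated errors between species measured with the same
electrode, systematic offsets (e.g. abiotic sulfide oxidation), or
temporal drift of `(x, y)` within an experiment.  Passing recovery tests
therefore show the *inversion* is unbiased under independent
multiplicative noise, not that field rate measurements are themselves
unbiased.

## Problem sizes and numerical choices

The computations are desk-scale and deterministic; the test suite
checks balance/linearity/round-trip properties on grids of 5-9 `x`
values per substrate, the efficiency orderings on 50 x 50 `(x, y)`
grids for all six substrate x TEA combinations, and the noisy-recovery
study at n = 200 replicates, all chosen to exercise every admissible
regime while keeping the suite fast.  Balance residuals are required
below 1e-9, round trips below 1e-12, constrained roots below 1e-8 in
the constraint residual.  Coefficients with magnitude below 1e-12 are
dropped when equations are assembled; ties at bracket endpoints are
resolved toward the smaller `x`.

## Known limitations

* The thiosulfate formation energy is calibrated, not independently
  measured; all thiosulfate energies inherit that choice.
* Carrier cores are not tracked elementally, so `check_balance()` can
  only detect couple-coefficient mismatches through H and charge.
* No kinetics, transport or mixed-substrate modeling: the framework is
  algebra over pool fractions, and rate *ratios* are its only contact
  with data.
* Efficiencies at non-standard conditions require concentrations that
  experiments rarely report; the sensitivity tools quantify, but cannot
  remove, that uncertainty.
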