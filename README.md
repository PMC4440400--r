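# soxtherm

Stoichiometry and energy-conservation efficiency of chemolithoautotrophic
sulfur oxidation.

## The problem

Sulfur-oxidizing bacteria (SOB) couple the oxidation of reduced sulfur
compounds (ΣH₂S, S₂O₃²⁻) to the reduction of a terminal electron acceptor
(O₂, or NO₃⁻ via denitrification or DNRA) *and* to CO₂ fixation.  Whoever
wants to quantify their role in sulfur, carbon, oxygen and nitrogen
cycling — microbial ecologists working on mats, symbioses and redoxclines,
and engineers running biodesulfurization reactors — faces two coupled
unknowns: how much of the sulfur pool is burned for energy versus spent on
CO₂ reduction, and whether oxidation stops at zero-valent sulfur (S⁰) or
runs through to sulfate.

`soxtherm` implements a generic algebraic framework for this problem.  The
whole reaction family is parameterized by two numbers,

* **x** — fraction of the oxidized sulfur pool ending as S⁰ rather than
  SO₄²⁻ (negative x = co-oxidation of stored S⁰), and
* **y** — fraction of the reduced sulfur pool used for energy generation;
  1 − y donates its electrons to CO₂ fixation,

so that, e.g., aerobic sulfide oxidation obeys

```
H2S + y(2 − 1.5x) O2 + (1 − y)(2 − 1.5x) CO2 + ... ->
      x S0 + (1 − x) SO4^2− + (1 − y)(2 − 1.5x) CH2O + ...
```

On top of the balanced-equation builders the package computes, from a
versioned table of biochemical-standard formation energies (ΔG⁰f′, with
ΔGr = ΔG⁰r + RT ln Q at user conditions):

* the **traditional efficiency** ε_I = (1 − y) ΔGr(CO₂ red) / (−y ΔGr(TEA
  red));
* the **carrier-explicit efficiency** ε_II, which splits CO₂ reduction
  into reverse electron transport (RET) into NADH/Fd/FADH₂ plus the
  fixation pathway's fixed requirement (Calvin: 69.7 kJ and 3 ATP per CO₂;
  rTCA: 64.3 kJ and 5/3 ATP per CO₂), with ε_II > ε_I always;
* the **factorization** of ε_II into partial efficiencies and their
  identifiable minima (ε_SO,min etc.);
* **inverse solvers**: (x, y) from two rate ratios in closed form, or from
  a single ratio plus a constant-efficiency / constant-yield constraint
  (bracketed root search), including host-respiration correction for
  symbioses;
* **sensitivity tools**: efficiency scans over concentrations and pH, and
  the concentration shift that would equalize two strains' efficiencies;
* a packaged **strain compilation** whose published efficiencies the
  package re-derives from (x, y) alone.

## Worked example

A marine *Beggiatoa* strain consumes O₂ : ΣH₂S = 1.65 and CO₂ : ΣH₂S =
0.35.  What is its full stoichiometry and how efficient is it?

```r
library(soxtherm)

s <- solve_xy(c(tea = 1.65, co2 = 0.35))
s$stoichiometry
#> <overall> H2S + 1.65 O2 + 0.35 H2O + 0.35 CO2 -> SO4^2- + 2 H+ + 0.35 CH2O
#> substrate = sulfide, x = 0, y = 0.825, tea = aerobic
```

Sulfate is the exclusive product (x = 0) and 82.5% of the sulfide pool is
burned for energy.  The energetics at standard biochemical conditions:

```r
factorize_efficiency(s$x, s$y)
#> eps_I = 0.0369, eps_II = 0.0962 (x = 0, y = 0.825, sulfide/aerobic/calvin)
#>   dGr: energy -829.30, CO2 red 144.14, RET 236.66, fix 139.40 kJ/mol
#>   alpha = 0.3707, eps_CO2 = 0.57, minima: SO 0.1235, t 0.1235, RET 0.0646
```

Read: the energy reaction releases 829 kJ per mol H₂S; the traditional
efficiency is 3.7%, but once the RET and fixation steps are priced
separately the organism conserves 9.6% of the released energy, and its
sulfur-oxidation machinery must be at least 12.3% efficient.

If a later experiment found O₂ : ΣH₂S = 0.5, assuming the organism holds
ε_II constant the solver predicts it has switched to S⁰ production:

```r
con <- inverse_constraint("constant_efficiency", 0.0962)
sol <- solve_constrained(0.5, con)
sol$stoichiometry
#> <overall> H2S + 0.5 O2 + 0.12 CO2 -> 0.92 S0 + 0.0797 SO4^2- + 0.801 H2O
#>           + 0.159 H+ + 0.12 CH2O
#> substrate = sulfide, x = 0.92031, y = 0.807056, tea = aerobic
```

And an SOB tracking an O₂ : ΣH₂S supply fluctuating between 0.45 and 1.7
must span efficiencies from 4.3% (all S⁰) to 8.0% (all sulfate):

```r
niche_band(0.45, 1.7)
#>          end x ratio    y epsilon_II
#> 1 incomplete 1  0.45 0.90 0.04283014
#> 2   complete 0  1.70 0.85 0.08002355
```

A thin command-line wrapper exposes the same operations
(`soxtool solve-xy --tea-ratio 1.65 --co2-ratio 0.35`,
`soxtool efficiency --x 0 --y 0.825 --json`, `soxtool table`, ...); see
the header of `exec/soxtool`.

## Further reading

The methods vignette (`vignettes/soxtherm-methods.Rmd`) documents the
half-reaction construction, the proton and activity conventions, the
calibrated thiosulfate entry of the thermodynamic table, the closed forms
behind the inverse solvers, and the package's known limitations.
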