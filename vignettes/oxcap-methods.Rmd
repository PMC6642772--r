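---
title: "Predicting intermediate accumulation in N/S bioprocesses from bulk-liquid chemistry"
author: "oxcap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intermediate accumulation in N/S bioprocesses from bulk-liquid chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxcap)
```

## The problem

Nitrification and sulfur-driven autotrophic denitrification remove ammonia
and sulphide from wastewater cheaply, but under some operating conditions
they accumulate noxious intermediates: nitrous oxide (a potent greenhouse
gas) during ammonia oxidation, and nitrite and elemental sulfur during
sulphide-driven nitrate reduction. `oxcap` implements two purely chemical
predictors of that accumulation, computable from routine bulk-liquid
measurements:

1. **Reaction energetics.** The Gibbs free energy of each candidate redox
   reaction under the actual concentrations, normalized per mole of
   electrons transferred, on the hypothesis that microorganisms favor the
   most energetic electron route.
2. **Oxidative capacity (OXC).** A single conservative parameter — the
   electron-equivalent balance of oxidants minus reductants in the bulk
   liquid, relative to a chosen electron reference level — regressed against
   biomass-specific intermediate production rates.

The embedded bench-scale data set (12 nitrification stages from a biofilm
airlift reactor probed at dissolved-oxygen levels 0.5–5 mg/L; 9 stages of a
sulphide/nitrate sequencing batch reactor, of which 7 reached stable
operation) lets every stage of the pipeline be reproduced end to end. On
those data the energetic ranking fails to predict which intermediates
accumulate, while OXC regressions are significant for all three
intermediates — the package exists to make both computations reusable.

## Reaction energetics

Each of the eight candidate reactions (two ammonia-oxidation routes, six
sulfur/nitrogen routes) carries a standard free energy $\Delta G^0$ (kJ per
reaction as written) and a reaction-quotient specification. Under a
bulk-liquid state with temperature $T$ and quotient $Q$,

$$\Delta G = \Delta G^0 + R T \ln Q, \qquad
  \Delta G/e^- = \Delta G / n_e,$$

with $R = 8.314\times10^{-3}$ kJ/(mol K) and $n_e$ the electrons
transferred. Conventions, chosen once:

* **Activities are concentrations** (ideal solution): element-basis mass
  concentrations (mg N/L, mg S/L; mg O~2~/L for DO) are divided by the basis
  molar mass (14000, 32000, 32000 mg/mol). No ionic-strength or speciation
  corrections; sulphide reported as S^2−^–S supplies the bisulphide activity
  one-to-one on the sulfur basis, since HS^−^ dominates at the relevant pH.
* **Solids (S^0^) and water** take unit activity and are absent from $Q$.
* **Unmeasured dissolved gases** (N~2~, N~2~O) default to unit activity;
  explicit activity overrides are available, because absolute
  $\Delta G/e^-$ values shift with that choice even though the qualitative
  rankings reported here do not.
* **Zero concentrations** are floored at $10^{-12}$ M inside logarithms,
  with a warning, so a single non-detect cannot silently produce an
  infinite quotient. The floor is configurable (`conc_floor`).
* $\Delta G^0$ is used as tabulated; no van 't Hoff temperature correction
  beyond the explicit $RT\ln Q$ term.

`rank_reactions()` sorts by $\Delta G/e^-$ ascending with ties broken by
input order (no ties occur for the shipped reactions). Two qualitative
properties hold across the whole embedded data set and are asserted in the
test suite: ammonia oxidation to N~2~O yields more energy per electron than
oxidation to nitrite at every nitrification stage, and the
sulfur-*consuming* denitrification reactions outrank the sulfur-*producing*
ones at every stable stage — which is precisely why energetics alone cannot
explain the observed sulfur accumulation.

## Redox ladders and the potential table

Half-reactions are written as reductions with a standard potential $E^0$
(volts at pH 0 and unit oxidized/reduced ratio) and a protons-per-electron
coefficient $m$:

$$E_H = E^0 - \frac{2.303\,R\,T}{F}\, m\, \mathrm{pH}.$$

`build_ladder()` orders couples by $E_H$ descending and annotates the
electron reference level (NH~4~^+^ for nitrification, HS^−^ for
denitrification). The Faraday constant defaults to 96485 C/mol with a
96500 C/mol option; at two-decimal precision in volts they are
indistinguishable.

**Temperature policy.** `reproduce_table4()` recomputes the per-stage
potential table under three policies. The default `"study"` policy applies
the conventional handbook Nernst slope of 0.059 V per pH unit — the
two-significant-figure value of $2.303RT/F$ near 25 °C that
electrochemistry tables traditionally quote — under which every cell of the
study's potential table is recovered to two-decimal precision (maximum
deviation 0.0049 V). Computing the slope exactly from the constants
(`"standard"`, 298.15 K) reproduces almost all cells but misses four
denitrification cells by 0.0051–0.0064 V, and the recorded 30 °C
operational temperature (`"stage"`) fits the tabulated denitrification
values even less well (NO~3~^−^/N~2~ at pH 7.7 gives 0.69 V against the
tabulated 0.70 V). The tabulated values are therefore best understood as
computed with the rounded 0.059 V slope, and that is the documented
reproduction mode; the physically exact formula remains the default for
`half_potential()` itself.

```{r table4}
t4 <- reproduce_table4()
round(t4$denitrification[, c("no3_n2", "no2_n2", "so4_hs", "s_hs")], 2)
```

## Oxidative capacity

For a chosen electron reference level, the OXC condenses the bulk liquid
into one number,

$$\mathrm{OXC} \;(\mathrm{eq/L}) = \sum_i n_i\,[\mathrm{Ox}]_i
  - \sum_i n_i\,[\mathrm{Red}]_i,$$

with molar concentrations and $n_i$ the electron equivalents each species
can accept or donate relative to the reference. Two presets transcribe the
process-specific forms used with the study data:

* nitrification (reference NH~4~^+^):
  $4\cdot\mathrm{DO}/16000 + 6\cdot\mathrm{NO_2^-\!-\!N}/14000$;
* denitrification (reference HS^−^):
  $5\cdot\mathrm{NO_3^-\!-\!N}/14000 + 3\cdot\mathrm{NO_2^-\!-\!N}/14000 +
  8\cdot\mathrm{SO_4^{2-}\!-\!S}/32000$.

The nitrification DO divisor 16000 is kept verbatim even though a strict
4 e^−^ per mol O~2~ accounting would use 32000 (mg O~2~/mol); a documented
`"nitrification_consistent"` preset provides the alternative. For the
study's conditions the DO term never exceeds ~2% of the OXC, so the choice
cannot change any conclusion. Residual effluent sulphide is omitted from
the denitrification preset — it sits at the electron reference level, so
its formal contribution is zero — but the generic `oxc_spec()` engine
accepts reductant terms for custom systems. Effluent (steady-state bulk
liquid) concentrations are used throughout; for the nitrification
quick-change assays, the tested DO is paired with the effluent nitrite of
the parent composition block, which is what yields twelve distinct
regression points.

## The regression model

`oxc_lm()` fits ordinary least squares with intercept,
$y = a + b\,\mathrm{OXC} + \varepsilon$, $\varepsilon \sim N(0,\sigma^2)$,
where $y$ is a biomass-specific production rate (per g VSS per day,
normalized via `normalize_by_biomass()`). Inference is the classical
simple-regression ANOVA: $R^2 = 1 - SSE/SST$,
$F = R^2 (n-2)/(1-R^2)$ on $(1, n-2)$ degrees of freedom, two-sided
$p$-value from that $F$ (equivalently a two-sided $t$ on the slope).
Confidence and prediction bands are the standard $t$-based forms with the
prediction band carrying the extra unit variance term; standardized
residuals are the internally studentized variant,
$e_i / (s\sqrt{1-h_{ii}})$ — the common default among the several
"standardized residual" conventions. No multiple-testing correction is
applied across the three study regressions. Degenerate inputs error
explicitly: fewer than 3 complete observations, or a constant predictor. An
exact fit (residual scatter at floating-point noise) returns zero
standardized residuals with a warning and zero-width bands.

```{r regressions}
reg <- reproduce_regressions()
reg$n2o
reg$s0
reg$no2
```

All three regressions are significant at the 5% level with the expected
directions: nitrous-oxide production rises with OXC, sulfur accumulation
falls (net consumption in the most oxidative stages), nitrite rises. The
$R^2$ values computed here (`r paste(sprintf("%.3f",
vapply(reg, function(f) f$r_squared, 0)), collapse = ", ")`) come from the
embedded records and a brute-force normal-equations oracle agrees with them
to 10 significant figures; they are the package's own recomputation, not
imported summary statistics.

## Synthetic data and what it shows

`generate_stages()` draws stage records with a *known* linear
OXC–production relationship: concentrations uniform within per-species
ranges (defaulting to the ranges observed in the embedded data, so
synthetic OXC spans realistic values), OXC computed by the process preset,
and production `true_slope * OXC + true_intercept` plus Gaussian noise on
the production — the same error model the regression assumes. Everything is
seeded; a fixed configuration reproduces identical records.

`recovery_experiment()` repeatedly generates and refits, reporting slope
bias, RMSE and the empirical coverage of the t-based confidence interval.
With 50 stages, noise SD 1 and true slope 100, coverage sits at the nominal
95% (200 replicates are used in the shipped checks; at that size the
Monte-Carlo standard error of a 95% coverage estimate is about 1.5%).

The generator emulates the *statistical* structure of reactor stage data,
not its mechanism: no reactor kinetics, no microbial growth, no correlation
between concentrations, no measurement error on the concentrations
themselves (noise enters only through the response, matching the OLS error
model). Passing recovery tests therefore validate the estimation machinery,
not the chemistry; the claim that real systems follow a linear OXC–
production law rests on the embedded experimental records alone, with
n = 12 and n = 7 — small samples from two specific bench-scale systems.

## Problem sizes and numerical choices

The shipped tests and reproduction scripts run the full embedded data set
(21 stages), 200-replicate recovery experiments at 50 stages each, and
randomized property checks of a few dozen cases — all complete in seconds.
Key numerical defaults: concentration floor $10^{-12}$ M inside logarithms;
Faraday constant 96485 C/mol (96500 optional); decadic Nernst factor 2.303;
exact-fit detection at $\sqrt{\epsilon}$ relative to the response scale;
band level 0.95.

## Known limitations

* No aqueous speciation (H~2~S/HS^−^/S^2−^, NH~3~/NH~4~^+^) or
  activity-coefficient corrections; at pH well above 9 the one-to-one
  sulphide-to-bisulphide mapping overstates HS^−^.
* $\Delta G/e^-$ values for reactions involving N~2~/N~2~O depend on the
  unit-activity convention for unmeasured gases; only rankings robust to
  that convention should be interpreted.
* The OXC–production relationships are correlative, fitted on few points
  from two systems; the prediction bands quantify that uncertainty and
  should be reported alongside any use of the fitted lines.
* The nitrous-oxide production unit is stored exactly as recorded
  (g N~2~O–N/g VSS d); its magnitude suggests mg, but unit choice cannot
  affect $R^2$ or $p$.
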