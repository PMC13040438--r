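---
title: "Modelling acetogenic bioenergetics: ledgers, thermodynamics and the expression screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling acetogenic bioenergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoledger)
```

## The scientific problem

*Moorella thermoacetica* is a thermophilic acetogen that fixes CO2 through
the Wood-Ljungdahl pathway (WLP) and, unusually for an acetogen, carries
menaquinone and cytochromes but neither an Rnf nor a classical
ferredoxin-driven Ech respiratory complex. How such an organism conserves
energy during autotrophic growth on H2 + CO2 or on CO is a bookkeeping
problem as much as a biochemical one: every electron pair entering from H2
or CO must pass through a small set of soluble carriers (NADPH, NADH,
reduced ferredoxin written Fd2-, menaquinol MQH2) and leave in acetate,
and every vectorial proton crossing the membrane must be paid for by an
exergonic redox step. This package encodes that model quantitatively, in
three layers:

1. **thermodynamics** of the individual electron transfers (`delta_g_standard`,
   `delta_g_prime`, `h2_potential`, `feasibility_sweep`);
2. **stoichiometric ledgers** of whole growth modes (`scenario`,
   `validate_scenario`, `net_reaction`, `atp_yield`) with three built-in
   scenarios (`build_high_h2`, `build_low_h2`, `build_co`);
3. the **transcriptome arithmetic** used to support the model: a
   two-condition differential-expression stage (`nb_wald_test`,
   `bh_adjust`, `classify_and_summarize`), enzyme-assay and growth-curve
   calculations (`specific_activity`, `fold_change`, `fit_growth`), and
   seeded generators for all inputs (`generate_counts`,
   `generate_growth`, `generate_trace`).

## Redox thermodynamics

For transfer of $n$ electrons from a donor couple to an acceptor couple
with midpoint potentials $E'_0$ (mV),

$$\Delta G'_0 = -\,n\,F\,(E'_{0,\mathrm{acc}} - E'_{0,\mathrm{don}}),$$

with $F = 96.485$ kJ V$^{-1}$ mol$^{-1}$; negative values mean the
transfer is exergonic. Concentrations enter through
$\Delta G' = \Delta G'_0 + RT\ln Q$, and the H+/H2 couple gains
$RT\ln 10/2F = 29.58$ mV per decade of falling H2 partial pressure at
298.15 K.

The shipped couple registry (`redox_couples()`) mixes two kinds of
constants, tagged in its `source` column. The potentials printed in the
study behind this model — CO2/formate $-432$ mV, NAD $-320$ mV (cellular
$-270$), NADP cellular $-370$ mV, ferredoxin $-450$ mV, menaquinone
$-74$ mV — are tagged `PAPER`. Two couples the model needs but whose
potentials are standard textbook values, H+/H2 at $-414$ mV and
CH2=THF/CH3-THF at $-200$ mV, are tagged `LITERATURE`; both are forced by
back-calculation from the model's quoted free energies ($-3$ and
$+24.3$ kJ/mol with the printed $-432$ and $-74$ mV).

Two anchor reactions tie the registry together:

```{r anchors}
params <- thermo_params()
delta_g_standard(get_couple("co2_formate"), get_couple("h2"), 2, params)
delta_g_standard(get_couple("mq"), get_couple("methylene_thf"), 2, params)
```

The first ($-3.5$, printed as $-3$ kJ/mol) is formate oxidation to
H2 + CO2 at the proposed Fdh-Ech complex — close enough to equilibrium
that metabolite levels decide its direction. The second ($+24.3$ kJ/mol)
is the endergonic menaquinol-to-methylene-THF leg that the confurcating
Type IV MTHFR must drive with NADH.

**Temperature convention.** The default temperature is 298.15 K because
the quoted standard free energies are 25 °C standard-state values; the
organism's growth temperature (328.15 K) is available through
`thermo_params(temperature = 328.15)` and changes only the $RT\ln Q$ and
Nernst terms, not $\Delta G'_0$.

**The "10-fold shift" convention.** The model's prose states that a
10-fold difference in educts and products raises the formate-oxidation
$\Delta G'_0$ to about 8.7 kJ/mol, without fixing which species shift or
at which temperature. Plausible conventions give 7.9-9.1 kJ/mol. Rather
than guess, the package computes `delta_g_prime(dg0, Q)` under an explicit
quotient: the documented default, $Q = 100$ (one decade for the educt and
one for the product pool) at 298.15 K, gives $-3.47 + RT\ln 100 = +7.95$
kJ/mol — endergonic, and within 1 kJ/mol of the quoted value. The tests
check exactly that sign flip and band, not the unreproducible 8.7.

**Feasibility sweep.** `feasibility_sweep()` asks at which H2 pressure
NADPH-dependent CO2 reduction stops being viable. Two reductant modes are
exposed because they answer different questions. With
`reductant = "h2_equilibrated"` the NADPH pool is assumed equilibrated
with gaseous H2 through the NADP+-reducing hydrogenase, so its potential
*is* `h2_potential(p)`; the reported dG' crossover is then the pressure at
which the pool potential passes the CO2/formate midpoint ($-432$ mV, at
about 4 atm). With `reductant = "fixed"` the couple keeps its tabulated
(cellular, if recorded) potential at every pressure, isolating the
couple-vs-couple comparison. Independently of the mode, the sweep reports
the *equilibration pressure* at which the H2 couple matches the
reductant's cellular potential — for NADPH at $-370$ mV this is
$10^{-1.49} \approx 0.033$ atm, the pressure below which H2 can no longer
hold NADPH at its usual cellular reduction state. The crossover is located
by bisection on $\log_{10} p$ to $10^{-6}$ decades and is cross-checked in
the tests against a dense-grid sign change.

## The scenario ledgers

A `scenario` is an ordered list of enzyme-level `reaction_step`s with
exact rational flux multipliers, normalised to one acetate produced. Three
conservation laws are enforced by `validate_scenario`, all in exact
rational arithmetic (`rational()`), so balances close to *identically*
zero rather than to within a tolerance:

* every carrier (NADPH, NADH, Fd2-, MQH2) nets to zero;
* every species not declared external nets to zero;
* each step passes an electron-pair audit: pairs released by its
  metabolite redox changes plus pairs from oxidised carriers equal pairs
  captured in reduced carriers.

Ferredoxin is counted as a **two-electron (one-pair) carrier**: that is
the only convention under which the CO ledger's coefficients
(0.75 MQH2 + 0.75 Fd2- confurcated to 1.5 NADH) balance. Water is tracked
only where the chemistry demands it (CO oxidation consumes it, the
cyclohydrolase releases it) and scalar, non-vectorial protons are not
balanced — the same loose convention as the figures such ledgers are drawn
in.

Vectorial proton stoichiometries are constants of the model, exposed as
options: the ferredoxin-dependent NADH-dehydrogenase-like complex
translocates 4 H+ per MQ reduced (forced by "1.25 MQ, five protons" in
the CO ledger); the menaquinone redox loop at the MTHFR yields 1 H+ per
0.5 MQH2 oxidised; and the Fdh-Ech complex translocates an *unknown*
number $x$ of protons per formate, deliberately defaulted to $x = 0$ and
never silently nonzero — it enters with positive sign when Fdh-Ech runs
forward (high-H2, CO) and as a cost when it runs in reverse (low H2).
Chemiosmotic ATP is protons divided by the H+/ATP quotient, default 4.

The three built-in scenarios then reproduce, exactly:

| scenario | net reaction | vectorial H+ | ATP (chemiosmotic) |
|---|---|---|---|
| high H2 | 4 H2 + 2 CO2 → acetate + 2 H2O | 2 + x | 0.5 at x = 0 |
| low H2 | 4 H2 + 2 CO2 → acetate + 2 H2O | 2 − x | 0.5 at x = 0 |
| CO | 4 CO + 2 H2O → acetate + 2 CO2 | 6 + x | 1.5 at x = 0 |

```{r ledgers}
atp_yield(build_high_h2())
atp_yield(build_co())
```

Substrate-level ATP nets to zero in all three (formyl-THF synthetase
spends the ATP that acetate kinase recovers), which is why autotrophic
growth hinges entirely on the chemiosmotic terms. Every ledger also turns
over exactly four electron pairs (8 electrons) per acetate
(`electron_pair_total`), entering as 4 H2 or as 3 oxidised CO plus the
carbonyl-bound CO.

**Step granularity** follows the named-enzyme level of the model's
narrative — one step per enzyme or complex, with formyl-THF synthetase and
the cyclohydrolase kept separate for ATP and water bookkeeping. Reversible
enzymes (Nfn, Fdh-Ech, EtfABCX) are encoded as explicit directional
variants rather than signed fluxes, keeping the invariant that flux
multipliers are non-negative rationals. The monofunctional CODH and the
CODH/ACS are pooled into single oxidation/reduction steps: the ledger is
enzyme-agnostic for balance purposes, and their differential regulation is
outside its scope.

**The formate cycle.** The model proposes, without quantifying its proton
yield, a periplasmic cycle: FocA exports formate, a periplasmic cytochrome
*b*-dependent Fdh oxidises it feeding menaquinone, and the CO2 is
re-reduced inside the cell. `apply_formate_cycle()` renders this as a
carbon-closed loop whose electrons return through the quinone pool, so the
carrier ledger stays closed and only the configurable vectorial proton
count (`loop_protons_per_formate`, default 0) changes the ATP yield. The
real cycle would interleave with the NADPH-Fdh and displace part of the
Etf/NADH-dehydrogenase quinol supply; the model gives no revised
coefficient set for that, so the package deliberately keeps the closure
electron-neutral instead of inventing one. Applying the cycle to the
low-H2 scenario is an error, mirroring the model's statement that it is
inactive there.

## The differential-expression stage

The transcriptome side of the model rests on one rule: a gene is
differentially expressed iff $|\log_2 \mathrm{FC}| \ge 2$ and BH-adjusted
$p < 0.05$; on the 2594-gene universe, 489 DEGs give 18.85% and 517 give
19.93%. The rule's surroundings (normalisation, test, adjustment) are not
pinned by the model, so the package defines them explicitly and
reproducibly:

* **median-of-ratios size factors**, rescaled to geometric mean 1;
* a **negative-binomial Wald test**: $\log_2$ fold change of
  pseudocounted (0.5) normalised means, delta-method standard error under
  $\mathrm{var} = \mu + \alpha\mu^2$, two-sided normal p-value;
* **step-up Benjamini-Hochberg** adjustment (verified identical to
  `p.adjust(..., "BH")`), with all-zero genes reported at
  $p = p_{adj} = 1$ and excluded from the BH multiplicity while the
  percentage stays anchored to the full universe.

**Dispersion.** The per-gene method-of-moments estimate
$(\hat s^2 - \bar\mu)/\bar\mu^2$ is far too noisy at 2-3 replicates: by
chance roughly 40% of null genes appear underdispersed, hit the floor, and
inflate the Wald statistic (measured null false-positive rate ≈ 0.12 at
nominal 0.05). The default therefore pools the per-gene moment values
into a mean-dispersion trend $\alpha(\mu) = a/\mu + b$ fitted across
genes, which restores calibration (measured ≈ 0.053) while remaining a
pure moment method with no distributional fitting; `dispersion =
"per-gene"` retains the raw floored estimates for users who want them.
The trended test agrees closely with an established NB Wald engine on
synthetic data (fold-change correlation > 0.99, p-value rank correlation
> 0.95 against DESeq2 in the test suite), and its p-values rank-match an
exhaustive label-permutation oracle.

## Assays and growth curves

One enzyme unit is the transfer of 2 µmol electrons per minute. From an
absorbance trace, `specific_activity()` chains: least-squares slope
(A/min) → Beer-Lambert concentration rate (slope/(ε·path), mM/min) →
µmol/min via the assay volume → µmol electrons/min via the electrons per
chromophore (2 for NAD(P)H at 340 nm, ε = 6.3 mM⁻¹cm⁻¹; configurable for
ferredoxin at 430 nm, ε = 13.1, default 2 per Fd2- to match the ledger
convention) → U → U/mg. A falling trace yields a signed negative activity
with a direction flag rather than an error, and `fold_change(a, b,
rounded = TRUE)` uses round-half-away-from-zero to mirror prose-style
"15-fold" statements (1.06/0.07 → 15, 0.20/0.04 → 5, 2.25/0.39 → 6).

`fit_growth()` fits $\ln \mathrm{OD}$ against time by ordinary least
squares over a user window, reporting $\mu$, $t_d = \ln 2/\mu$, and $R^2$;
`window = "auto"` selects the longest window whose log-linear $R^2$
clears a threshold (default 0.99), since the underlying protocol does not
define window selection. One internal inconsistency is handled openly:
$\mu = 0.055$ h⁻¹ implies $t_d = 12.6$ h, not the 12.4 h quoted alongside
it (whereas 0.075 h⁻¹ ↔ 9.2 h is consistent); the package reports the
derived value and leaves the discrepancy visible rather than matching one
number silently.

## Synthetic data: what it does and does not show

`generate_counts()` emulates the *statistical shape* of the study's
two-condition transcriptome: 2594 genes, 3 + 3 replicates, ~19% planted
DEGs (`round(0.19 × 2594)` = 493) with $|\log_2\mathrm{FC}|$ uniform on
[2, 8] and random sign, log-normal base means (log-mean 5, log-sd 1.2 —
typical means near 150 counts spanning a few orders of magnitude),
dispersion trend $\alpha = 1/\mu + 0.05$, and log-normal library-size
factors (log-sd 0.1). Planted genes are stratified across the expression
range so power can be read by expression level. These distributional
choices are the generator's own, stated here because the real deposit's
library sizes and dispersions are unknown; passing tests therefore
demonstrate that the *pipeline arithmetic* is correct and calibrated
under a realistic NB model, not that the study's 489/517 gene lists would
be reproduced from raw reads — reproducing those identities is explicitly
out of scope.

`generate_growth()` and `generate_trace()` invert the fitting chains
exactly at zero noise (round-trip recovery to machine precision), giving
the assay and growth modules end-to-end oracles. Every generator runs on
an isolated RNG stream: the same seed gives byte-identical output and the
caller's `.Random.seed` is untouched.

## Numerical choices and degenerate inputs

* Rational arithmetic stores numerators/denominators as whole doubles
  (exact far beyond any ledger's magnitudes) and reduces by GCD; ledger
  "zero" is exact.
* Regression slopes and $R^2$ use closed-form least squares, so constant
  input gives an exactly zero slope (flagged, not `NaN`).
* Degenerate DE genes (all counts zero) get $p = 1$ and a flag; BH input
  is validated to [0, 1]; quotients and pressures must be positive.
* Reported energies round to one decimal; comparisons to quoted integers
  use round-half-away-from-zero (`round_half_away`).
* Test problem sizes (2594 × 6 count matrices, 10-seed null batteries,
  dense 0.01-decade sweep grids) keep the whole suite under half a
  minute while leaving Monte-Carlo margins comfortable.

## Known limitations

* No activity-coefficient, ionic-strength or pH corrections; pH 7 is
  baked into the primed potentials.
* Scenarios are fixed ledgers — no kinetics, no flux optimisation, no
  growth-yield prediction from ATP, no membrane-potential magnitude.
* The Fdh-Ech proton number $x$ and the formate-cycle proton yield are
  free parameters by design; every ATP figure should be read as a
  function of them.
* The DE stage defines its own normalisation/test/adjustment; it honours
  the threshold rule exactly but is not a reimplementation of any
  specific published engine.
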