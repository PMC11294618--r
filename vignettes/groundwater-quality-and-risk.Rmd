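---
title: "Groundwater quality indices and health-risk assessment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Groundwater quality indices and health-risk assessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## Scope and data model

`aquarisk` assesses brackish groundwater from a deep desert aquifer on
three fronts: suitability for drinking (a multi-criteria water quality
index), heavy-metal pollution load and ecological risk (HPI, HMI,
Hakanson RI), and human health risk from the potentially toxic elements
Fe, Mn, Cr and Pb (USEPA chronic-daily-intake framework, deterministic
and Monte Carlo). The universal input is a per-sample table of analyte
concentrations in mg/L (pH unitless, EC in µS/cm), validated by
`read_samples()` / `validate_samples()`.

The field survey the package was built around (45 production wells
sampled once, TDS 1.7–2.8 g/L) is not publicly deposited. All
development, testing and the workflow under `analysis/` therefore run on
a synthetic stand-in produced by `generate_samples()`; what that
generator does and does not emulate is discussed at the end.

## Charge-balance quality control

Major-ion analyses are screened with the charge balance error
$\mathrm{CBE} = 100\,(\Sigma \mathrm{cat} - \Sigma \mathrm{an}) /
(\Sigma \mathrm{cat} + \Sigma \mathrm{an})$ on meq/L, with the
conventional ±5 % acceptance band. Conversion to meq/L uses IUPAC 2021
equivalent weights shipped in `equivalent_weights()`. All measured ions
enter the balance (including K⁺ and NO₃⁻); CO₃²⁻ is taken as zero when
not reported, which is the common situation at near-neutral pH. Failing
samples are flagged, never silently dropped.

## Hydrochemical classification

* **Chloro-alkaline indices.** `cai_indices()` implements the standard
  Schoeller forms, CAI-I = (Cl − (Na + K))/Cl and CAI-II with the
  weak-acid + sulfate + nitrate denominator, on meq/L. Positive values
  mean reverse ion exchange (aquifer Ca/Mg replaced by water Na/K). Some
  presentations of these indices print the numerator as "Na − Ca"; that
  variant is inconsistent with the sign interpretation and is not used.
* **Piper facies.** `piper_facies()` classifies from milliequivalent
  percentages with explicit, documented diamond thresholds (50 %
  dominance rules, see the function's help page). The exact subfield
  boundaries used in published diagrams of comparable surveys are not
  stated anywhere, so ours are a declared convention rather than a
  reproduction.
* **Gibbs ratios.** Weight-based ratios Na/(Na+Ca) and Cl/(Cl+HCO₃)
  against TDS; the published envelope boundaries are approximated by a
  rectangular rule (evaporation zone: ratio ≥ 0.5 and TDS ≥ 300 mg/L)
  because the original boomerang polygons were drawn, not tabulated.
* **Sulin genetic classification.** Quadrants on Cl − (Na+K) and its
  ratio to Mg (meq/L): chloride excess with ratio < 1 is recent-marine
  (MgCl₂ type), ratio ≥ 1 old-marine (CaCl₂); alkali excess goes to the
  meteoric branch, split on (Na+K−Cl)/SO₄ at 1. The exact tie
  Cl = Na + K breaks to the meteoric branch — an arbitrary but frozen
  convention exercised by a test.

### Mineral saturation indices

`saturation_index()` computes SI = log₁₀(IAP/Ksp) at 25 °C for calcite,
dolomite, gypsum and halite with a deliberately simplified speciation:
total analysed concentrations are treated as free-ion molarities,
activity coefficients come from the Davies equation (A = 0.5092,
adequate to ionic strength ≈ 0.5 mol/L; the target waters sit near
0.06), and carbonate activity is derived from bicarbonate and pH via
log K₂ = −10.329. log Ksp values follow the common speciation-code
compilation (calcite −8.48, dolomite −17.09, gypsum −4.58, halite
+1.570). Ion pairing and temperature corrections are omitted; against a
full speciation code this biases SI slightly high for the carbonates,
which does not affect the sign conclusions the package draws (carbonates
supersaturated, evaporites undersaturated at mean survey chemistry —
checked in the test suite and by `scripts/acceptance.R`).

## The integrated-weight water quality index

For m samples and n parameters the raw matrix X is min-max normalised
(`normalize_matrix()`); constant columns map to 0.5 with a warning and
end up with zero entropy weight.

**Entropy weights.** With $P_{ij} = Y_{ij}/\sum_i Y_{ij}$,
$e_j = -\tfrac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}$ and
$w^{(1)}_j = (1-e_j)/\sum_j(1-e_j)$. Two numerical conventions matter
and are configurable: 0·ln 0 := 0, and a floor of 1e-4 added to Y
before forming P (every normalised column contains an exact zero; the
floor keeps those samples in the entropy sum, matching common
entropy-WQI practice). The printed lineage of this formula sometimes
omits the minus sign; it is implemented so that $e_j \in [0,1]$.

**CRITIC weights.** $S_j = \delta_j \sum_k (1 - r_{jk})$ and
$w^{(2)}_j = S_j/\sum S_j$, with r the Pearson correlation matrix.
δ is the standard deviation of the *normalised* column (the original
CRITIC convention): on raw mg/L the EC and TDS columns would dominate
for purely dimensional reasons, which contradicts the published
integrated weights for this kind of survey (Mn and NO₃ highest). The
raw-σ variant remains available via `normalize = FALSE`. Whether the
population or sample σ is used cancels in the normalisation.

**Integration.** The default combination is the normalised product
$W_j = w^{(1)}_j w^{(2)}_j / \sum_j w^{(1)}_j w^{(2)}_j$; a linear
blend $p\,w^{(1)} + (1-p)\,w^{(2)}$ is available as a mode. The two
published forms of this step are mutually inconsistent; the product
form is the default because the published weight table for the
reference survey carries no preference coefficient. Note the product
form is *not* idempotent: identical inputs renormalise the squared
weights. `preference_coefficient()` reproduces the printed companion
expression verbatim, with its unclear derivation flagged in the help.

**Scoring.** $Q_j = 100\,(C_j - C_{jp})/(S_j - C_{jp})$ with ideal
values $C_{jp} = 0$ except pH (ideal 7, WHO standard 7.5), and
$\mathrm{IWQI} = \sum_j W_j Q_j$. Classes use left-closed intervals
[0,50) excellent, [50,100) good, [100,150) medium, [150,200) poor,
[200,∞) extremely poor, so a sample exactly at every standard
(IWQI = 100) falls in "medium" — the conservative side of the boundary.

## Pollution and ecological indices

HPI uses unit weights 1/Sᵢ and sub-indices 100·Cᵢ/Sᵢ (the nested
summation sometimes printed inside the sub-index belongs to the outer
weighted mean). Its published class scale overlaps; we resolve it to
the monotone partition [0,15), [15,30), [30,76), [76,100), [100,∞).
HMI is the plain sum of Cᵢ/HALᵢ with the six-level scale. The Hakanson
index multiplies enrichment over background by toxic-response factors
(Tr = 1, 1, 2, 5 for Fe, Mn, Cr, Pb). No site background survey exists
for the emulated aquifer, so the packaged `c_bg` defaults fall back to
the drinking-water limits — a documented synthetic stand-in, overridable
through `toxicology_table()`, and the reason RI magnitudes (not signs or
class fractions) should be read with care.

## Deterministic exposure risk

Oral and dermal chronic daily intakes follow the USEPA formulas with
the packaged receptor profiles (adult: IR 2.2 L/day, ED 70 y, EF 350
d/y, ET 0.58 h/day, SA 18 000 cm², BW 70 kg; child: 1.8, 6, 350, 1,
6600, 15; CF 1e-3 L/cm³). The averaging time is never printed alongside
these parameters in the survey lineage; we adopt the USEPA convention
AT = ED·365 for non-carcinogenic and 70·365 for carcinogenic horizons.
Back-calculation against all sixteen reported oral HQ endpoints with
RfD_oral = {Fe 0.7, Mn 0.024, Cr 0.003, Pb 0.0014} mg/kg/day confirms
this choice: fourteen endpoints agree at printed precision and the two
Fe maxima agree within 0.4 % (consistent with rounding of an
intermediate CDI in the source spreadsheet); the comparison is frozen
in `tests/testthat/test-acceptance.R`.

HQ = CDI/RfD with RfD_dermal = RfD_oral·ABS; HI sums HQ over metals
within a route by default (the form in which the reference results are
reported), with an opt-in combined oral+dermal mode. CR = CDI·CSF for
Cr and Pb on the lifetime horizon. Dermal Kp and ABS and the CSFs come
from RAGS-lineage tables; reported dermal HQ and CR values in the
survey lineage cannot be reconciled with any standard parameter set
(they sit orders of magnitude below every recomputation we tried), so
dermal and carcinogenic outputs are treated as configuration-dependent:
the package tests only their linearity, additivity and
order-of-magnitude behaviour, never printed endpoint values.

## Monte Carlo propagation

`simulate_risk()` draws all variables independently: concentrations
from lognormal fits to the sample table (moment matching — the fitted
analytic mean equals the sample mean exactly), behavioural factors
(IR, ED, ET, SA, BW) from truncated normals centred on the point values
with CV 0.2, truncated at ±3σ and at zero; EF and CF stay fixed. The
reference methodology states normal exposure factors and 10,000
iterations but neither CVs nor truncation nor the concentration family;
lognormal concentrations are the natural choice for right-skewed data
(the survey's Fe mean of 0.713 mg/L against a max of 3.61 demands a
skewed, nonnegative family), and every choice is exposed through
`dist_spec()`. Unbounded normal specs reject and redraw negative
values, erroring above a 50 % rejection rate. Percentiles use the
linear-interpolation (type 7) rule, stated explicitly because p95
values are compared across implementations. The generator is seeded;
the seed is stored in every result object, and identical seeds
reproduce results bit for bit.

## The synthetic-sample generator

`generate_samples()` draws each analyte from a beta distribution scaled
to the target [min, max] with its shape chosen so the mean matches the
target mean (concentration parameter κ = 4, giving the broad spread the
wide survey ranges imply), couples analytes through a Gaussian copula
(salinity block TDS–Ca–Cl–SO₄–NO₃ at r = 0.6, TDS–EC at 0.9, an
anthropogenic Fe–Cr–Pb block at 0.4 — signs follow the principal
component structure reported for such surveys; magnitudes are invented
defaults), and finally repairs each sample's charge balance by moving
Na and Cl symmetrically (preserving total ionic content) to the nearest
point with |CBE| ≤ 5 %, resampling the row if its ranges make that
infeasible.

What it emulates: marginal ranges and means, approximate electroneutrality,
the sign structure of the major correlations, and the
right-skewed PTE distributions. What it does not: the true joint
distribution (unknowable from summary statistics), spatial structure,
and any min–mean–max pattern beyond the beta family. Consequently,
passing tests demonstrate that the *methods* behave correctly on data
with this structure; dataset-dependent headline numbers (exact IWQI
range, HPI mean, RI mean) are reproduced only in magnitude and in their
qualitative statements (e.g. "most samples above HPI 100", "child oral
Mn and Pb exceed HQ = 1 at the 95th percentile"), which is exactly what
`scripts/acceptance.R` recomputes.

## Problem sizes and numerical conventions

The shipped workflow and tests use the survey-sized n = 45 for
pipeline runs, n = 1000 for generator-convergence checks (means within
5 % of targets), and 10⁴–10⁵ Monte Carlo iterations (10⁴ matches the
reference methodology; 10⁵ is used where a closed-form lognormal
quantile is compared at 1 % tolerance). Degenerate inputs are handled
loudly: all-zero ion vectors, constant columns, zero denominators in
the classification ratios and Sj = Cjp misconfigurations all raise
errors or warnings rather than returning silent numbers.

## Known limitations

* SI values are simplified-speciation estimates (no ion pairs, no
  temperature correction of log K).
* The Hakanson background values and all dermal/carcinogenic
  toxicological constants are packaged defaults, not survey-confirmed;
  override them via `toxicology_table()` when the site values are known.
* Generator correlation magnitudes are plausible inventions; only their
  signs are data-backed.
* The Gibbs and Piper class boundaries are declared conventions, so
  facies *counts* are not comparable across implementations using
  different boundaries.
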