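---
title: "Tracing PM2.5 mortality to household consumption: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing PM2.5 mortality to household consumption: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conshealth)
```

## The accounting chain

`conshealth` connects five models that are usually run separately, so that a
premature death caused by ambient PM2.5 can be assigned to the household
consumption that ultimately caused the underlying emissions.

**Input–output accounting.** A multi-regional input–output (MRIO) table with
regions $r,s$ and sectors $l$ satisfies $\mathbf{x} = \mathbf{A x} +
\mathbf{y}$, where $\mathbf{A}$ holds direct-requirement coefficients and
$\mathbf{y}_t^{r,s}$ is final demand of category $t$ (rural households, urban
households, government, capital formation, exports) produced in $r$ and
consumed in $s$. Emissions embodied in a demand slice are
$\mathbf{e}_t^s = \hat{\mathbf{f}}\,(\mathbf{I}-\mathbf{A})^{-1}\mathbf{y}_t^s$
with $\hat{\mathbf{f}}$ the diagonal matrix of emissions per unit output.
Total household emissions add locally emitted direct emissions:
$\mathrm{ce}_t^s = \sum_{r,l} e^{r,s}_{l,t} + \mathrm{de}_t^s$. The key
assumption is the standard Leontief one: production is linear in demand, so
attribution is additive and conserves every region's production emissions
exactly — a property the test suite checks at $10^{-8}$ relative tolerance.

**Income groups.** Survey data report, per province and setting, the average
per-capita income, household fraction and household size of each original
income group (seven urban groups at 10/10/20/20/20/10/10 % of households,
five rural at 20 % each), and per-capita expenditure by sector. Resident
numbers follow $\mathrm{rn} = P/\mathrm{pph}\cdot\mathrm{frac}\cdot
\mathrm{pph}_j$; because the province-average household size need not equal
the fraction-weighted group mean, the package renormalizes resident numbers
to the provincial population (the inconsistency is bounded at 2 % in the
generator and flagged by a warning beyond that). Province groups are pooled
nationally by ranking all (province, group) units on per-capita income and
cutting the cumulative resident count at the prescribed fractions; a unit
straddling a cutoff is split proportionally by population, which makes the
regrouping a transport plan with exact row and column marginals. Ties are
broken by (province, group) order, deterministically.

Household demand is split across national groups per sector in proportion to
expenditure volume (assigned population × per-capita expenditure), so
group demand sums exactly to category demand. Direct emissions are allocated
by source: rural biomass by the fitted power law
$t_{\mathrm{bio}} = 0.7072\,\alpha^{-0.18}$ evaluated at *original*
provincial-group incomes (the shallow negative exponent encodes that poorer
households burn more solid biomass per person); fossil fuel by
residential-energy expenditure; private cars by transport expenditure. Urban
households have no biomass source. The expenditure-to-sector concordance is
configuration, not code: `proxy_sectors` names which MRIO sectors serve as
the two proxies.

**Missing survey data.** Not every province reports group detail. A missing
province inherits the income-ratio pattern of a proxy — the national average
over reporting provinces (default) or a named neighbouring province — scaled
to its own average income and renormalized so the resident-weighted mean of
the imputed incomes reproduces the province average exactly. Expenditure
patterns scale linearly with average income from the same proxy. The
`cv_sensitivity_scenarios()` helper quantifies how much the proxy choice
matters by recomputing group emissions under every available proxy and
reporting the coefficient of variation per group.

**Mortality.** The integrated exposure-response (IER) curve gives relative
risk $RR(C) = 1 + \alpha(1 - e^{-\gamma (C - C_0)^\delta})$ above the
counterfactual concentration $C_0$ and 1 below it, per endpoint (IHD,
stroke, COPD, lung cancer). Attributable deaths per cell are
$M = \frac{RR-1}{RR} B P$ with all-age baseline incidence $B$ and population
$P$; anthropogenic deaths scale by the concentration ratio
$(C_{\mathrm{all}} - C_{\mathrm{no\_anth}})/C_{\mathrm{all}}$ (the direct
proportion assumption, which linearizes an otherwise nonlinear
source-apportionment problem). Because the IER saturates, mortality computed
on spatially aggregated exposure is *not* the sum of per-cell mortality;
a test documents this nonlinearity rather than assuming it away.

**Attribution.** Receptor-region deaths are distributed over emitting cells
and species by the normalized semi-normalized sensitivity
$P_{m,n,k} = SS_{m,n,k} / \sum SS \times 100\,\%$ with
$SS = \partial M/\partial E \cdot E$, then mapped to consuming
(region, setting, group) classes through per-cell attribution ratios
$\beta$ — the share of the cell's emissions embodied in each class's
consumption, laid out within the producing province by the sector-specific
spatial distribution of the gridded inventory (indirect) or population
(direct household fuel). Cells are assigned wholly to the province of their
center; emissions in unmapped cells fall into a reserved "external"
category instead of being dropped, so the decomposition always sums to
100 % of each receptor's deaths.

**Inequality.** Household groups are ranked by per-capita income — always,
also for death-Lorenz curves, so the curves are comparable — and the
trapezoid Gini $G = 1 - |\sum_h (H_{h+1}-H_h)(I_h+I_{h+1})|$ is computed on
cumulative population/quantity shares. Groups are internally homogeneous by
construction, so the group-level Gini is a lower bound on the
individual-level one. When the quantity is *inversely* related to income
(direct-emission deaths), the income-ranked index is a concentration index
and can legitimately be negative; the package reports it as computed.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid steps `dlon`, `dlat` | 2/3, 0.5 | degrees | resolution of nested regional transport simulations |
| IER $\alpha, \gamma, \delta$ | per endpoint, see `ier_parameters()` | — | packaged central values of GBD-2010-era magnitude; override via config |
| counterfactual `C0` | 7.5 | µg/m³ | midpoint of the commonly used 5.8–8.8 counterfactual interval; an assumption, flagged as such |
| baseline incidence `B` | `baseline_incidence()` | deaths/person/yr | plausible national all-age magnitudes; override via config |
| `mc_draws`, `cv` | 1000, 0.2 | —, CV | lognormal spread of $\alpha,\gamma$ multipliers; `C0` drawn uniform on ±20 % |
| biomass law | 0.7072, −0.18 | — | the fitted income–biomass relation; taken as given, not re-fitted |
| imputation `proxy` | `"national"` | — | national-average ratio pattern; any reporting province may be used instead |

Units are fixed package-wide: emissions Gg/yr, concentrations µg/m³,
population persons, money in the MRIO table's own currency; file headers
carry unit labels.

## What the synthetic generator emulates

`synth_scenario()` builds a complete input set with known ground truth. The
default desk scenario — 6 provinces × 8 sectors, a 30 × 24 cell grid at the
standard steps, 3 receptor regions — runs in a few seconds while exercising
every index structure; those sizes were chosen so the full test suite and
acceptance script complete quickly at desk scale.

* **MRIO**: nonnegative random coefficient blocks with intra-regional
  dominance, rescaled to spectral radius 0.45 (safely productive); five
  demand categories with home-consumption bias and households present in
  every region; output solves the accounting identity exactly.
* **Survey**: lognormal province mean incomes (urban ≈ 3× rural); group
  income ratios from mid-quantiles of a lognormal with sdlog 0.8, matching
  yearbook-like within-province richest/poorest ratios around 7–8×;
  household sizes mildly decreasing with income within 1–6 persons;
  Engel-type expenditure shares shifting toward late-listed (service)
  sectors as income rises, with the first sector (residential energy) and
  last sector (transport) serving as the direct-emission proxies. Default
  missing-data flags mirror yearbook reporting: 40 % of provinces lack rural
  group detail and 10 % lack urban detail. Flagged provinces are generated
  *by* the national-average scale-factor construction, so the imputation
  recovers the ground truth exactly and the noise-free end-to-end recovery
  target is well defined with imputation active.
* **Direct emissions**: 30 % of production emissions per species, split
  75/25 rural/urban; rural sources 85 % biomass, 10 % fossil, 5 % car;
  urban 65 % fossil, 35 % car. Provincial rural biomass totals follow the
  same income power law used for group allocation (population ×
  $0.7072\,\bar\alpha^{-0.18}$), so the inverse income gradient of the
  direct burden — the structural pattern the inequality analysis is about —
  is present at both the province and the group level.
* **Fields**: provinces are Voronoi cells around random centroids; sectoral
  emissions are Gaussian bumps masked to the province and normalized so
  gridded totals conserve the inventory exactly; population is a bump field
  scaled to provincial totals. Transport is a single Gaussian kernel
  (σ = 2°, an annual-mean footprint breadth) with a 1° eastward drift;
  concentrations respond linearly to emissions through it, and per-receptor
  sensitivities are the same kernel weighted by receptor population. Using
  one kernel for both concentration and sensitivity makes the surrogate
  *exactly* linear, so the pipeline's attribution has an analytic ground
  truth (`truth$share_house`, computed by an independent plain-loop
  implementation with a Neumann-series Leontief inverse) and conservation
  holds to numerical precision.

What the generator does **not** emulate: real geography or inventory
magnitudes, chemical nonlinearity (real secondary PM2.5 formation is
nonlinear in precursors; the linearization is the method's own assumption,
made explicit here), seasonality (real sensitivities average a few monthly
adjoint runs; the package accepts any number of snapshots and averages with
configurable weights), within-group heterogeneity, and indoor air
pollution. Passing tests on synthetic data therefore demonstrate the
*accounting machinery* — conservation, normalization, ordering, recovery of
generating parameters — not the realism of any particular national estimate.

## Numerical choices

* Spectral radius by power iteration (50 iterations, tolerance 1e-9) as a
  pre-check; the Leontief inverse by dense `solve()` against the identity,
  not an explicit inversion formula. The independent test oracle is the
  truncated Neumann series with tail below 1e-12.
* Sectors with zero output get zero emission intensity (0/0 → 0) with a
  warning; a zero-output sector with nonzero emissions is an error.
* Demand splitting falls back to population shares for sectors with zero
  total expenditure but nonzero demand, with a warning.
* Zero-emission cells receive attribution ratio 0; the per-cell ratio sum is
  validated against 1 at 1e-9.
* National-ranking ties break by (province, group) lexicographic order.
* Grid definitions serialize as extents plus cell counts (not steps), so a
  step of 2/3° survives YAML round trips exactly; gridded CSV readers check
  the file grid against the expected grid at 1e-6°.
* The Gini's absolute value is defensive; ascending income order is
  enforced and unsorted input is an error.

## Design decisions on open questions

* Exports are a terminal demand category; no tracing to foreign consumers.
* The imputation proxy for the headline run is the national average; the
  neighbour-province alternative is exposed and exercised by the CV
  scenarios.
* Resident numbers are renormalized to provincial populations (the raw
  identity cannot hold when the average household size is inconsistent with
  the group values); the adjustment is logged via a warning beyond 2 %.
* Monte-Carlo parameter sampling (lognormal multipliers on $\alpha,\gamma$
  with 20 % CV, uniform $C_0$) is a package choice; the sampling scheme of
  uncertainty analyses in this literature is rarely documented, and ours is
  configuration-replaceable.
* Spatial disaggregation of provincial emissions is taken as given gridded
  input; the package never constructs inventories.

## Limitations

Group-level Ginis bound individual inequality from below. The IER parameters
and baseline incidences shipped are representative defaults, not a specific
published fit — any quantitative application must supply its own table. The
linear surrogate makes attribution exactly conservative by construction;
with real adjoint sensitivities the normalization step hides whatever
nonlinearity the adjoint linearized around its base state. Updated
exposure-response curves (post-2010 IER revisions and GEMM) are known to
yield substantially higher mortality and are out of scope for this version,
as are years-of-life-lost and indoor exposure.
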