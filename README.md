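# conshealth

Consumption-based accounting of ambient PM2.5-related premature mortality.

Outdoor PM2.5 kills through emissions that someone, somewhere, caused — and a
large share of those emissions exist only because households consume goods and
services whose supply chains pollute. `conshealth` implements the full
accounting chain that turns this idea into numbers, for researchers in
environmental health, energy economics and air-quality policy:

1. **Embodied emissions** (multi-regional input–output accounting). With
   direct-requirement blocks **A**, final demand **y** and sectoral emission
   intensities **f̂**, emissions attributable to a demand slice are
   `e = f̂ (I − A)⁻¹ y`, summed with household direct fuel-burning emissions
   `ce = Σ e + de`.
2. **Income-group tracing.** Yearbook-style surveys (7 urban + 5 rural income
   groups per province, household fractions 10/10/20/20/20/10/10 % and 5×20 %)
   are completed by scale-factor imputation for provinces without group
   detail, pooled into national income groups by resident-count cutoffs,
   and used to split household demand by group expenditure volumes.
   Rural biomass burning is allocated by the fitted power law
   `t_bio = 0.7072 · income^−0.18`; fossil-fuel and private-car emissions by
   residential-energy and transport expenditure proxies.
3. **IER mortality.** Per grid cell and endpoint (IHD, stroke, COPD, lung
   cancer): `RR(C) = 1 + α(1 − e^{−γ(C−C0)^δ})` above the counterfactual
   `C0`, deaths `M = (RR−1)/RR · B · P`, scaled to anthropogenic sources by
   the concentration ratio `(C_all − C_no_anth)/C_all`. Monte-Carlo parameter
   resampling gives 95 % intervals.
4. **Source–receptor attribution.** Adjoint-style sensitivity fields times
   gridded emissions give semi-normalized sensitivities
   `SS = ∂M/∂E · E`, normalized to percentage contributions per receptor
   region and combined with per-cell attribution ratios `β = ce ./ e` to
   assign each receptor's deaths to the consuming region, setting and income
   group that caused them — including the cross-region matrix of where
   consumption-driven deaths actually occur.
5. **Inequality.** Lorenz curves and the trapezoid Gini
   `G = 1 − |Σ (H_{h+1} − H_h)(I_h + I_{h+1})|` over income-ranked household
   groups, for income and for attributed deaths (total, direct, indirect).

Real applications of this method need proprietary or heavyweight inputs
(national emission inventories, MRIO tables, satellite PM2.5, chemical
transport adjoints). The package therefore ships a first-class synthetic
scenario generator (`synth_scenario()`) that produces internally consistent
inputs on a desk-scale grid with a linear transport surrogate and an
analytically computed ground truth, so every stage is testable end to end.

## Worked example

```r
library(conshealth)

scen <- synth_scenario(seed = 1)   # 6 provinces x 8 sectors, 30 x 24 grid
run  <- run_pipeline(scen)
run
#> Consumption-attributed PM2.5 mortality run
#>   anthropogenic PM2.5 deaths: 55975 across 3 receptor regions
#>   household direct: 13103 (23%)  household indirect: 23831 (43%)
#>   other final demand: 19042 (34%)  external/residual: 0 (0%)
#>   Gini: income 0.490, attributed deaths 0.155
```

The print method summarizes the attribution: of ~56,000 synthetic
anthropogenic PM2.5 deaths, 23 % trace to household fuel burning (direct),
43 % to emissions embodied in household consumption (indirect), and the rest
to government consumption, capital formation and exports. Deaths are far more
equally distributed than income (Gini 0.155 vs 0.490): poor rural groups bear
a burden out of proportion to their income because they burn solid biomass,
while the indirect burden rises steeply with income.

```r
summary(run)          # per-receptor deaths and cross-region shares
#> Cross-region share of indirect household deaths: 61%

run$inequality$deciles[c(1, 10), ]
#>    decile income_share deaths_share
#> 1       1         1.26         6.97
#> 10     10        35.89        18.62

plot(run, which = "groups")   # per-capita burden by income group (Fig-2 style)
plot(run, which = "lorenz")   # four Lorenz panels
```

Scenario bundles round-trip through plain-text formats (`write_scenario()` /
`read_scenario()`), and a thin CLI wraps the same functions:

```sh
inst/exec/conshealth synth  --seed 3 --out bundle/
inst/exec/conshealth run    --in bundle/ --out report/
inst/exec/conshealth report --in report/
```

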