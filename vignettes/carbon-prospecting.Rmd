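---
title: "Carbon prospecting: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carbon prospecting: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonprospect)
```

## The problem

Avoided-deforestation ("REDD+") projects sell carbon credits for emissions
that would have occurred had a threatened forest been cleared. Under the
Voluntary Carbon Standard (VCS), only carbon that is *additional* — at
demonstrable risk of loss — can be certified, a share of gross credits must
be withheld as a non-permanence buffer, and various land types are
ineligible. Whether a certified site is worth developing then depends on a
discounted cash-flow comparison of credit revenue against establishment and
maintenance costs.

`carbonprospect` implements this chain as a raster pipeline: per-cell carbon
stocks are converted to certifiable annual CO~2~ flux ("investible carbon"),
priced over a 30-year project, and summarized as viability maps, break-even
prices, price-sensitivity curves, scenario analyses, and validation
statistics against issued verified carbon units (VCUs). All stages run on
synthetic worlds with known ground truth, so every claim the package makes
is checkable without external datasets.

## Carbon pools

Three pools are mapped, each in tCO~2~/ha:

* **Aboveground (AGC)** — dry biomass $B$ (t/ha) times a stoichiometric
  carbon fraction $s$ times the C→CO~2~ mass ratio 3.67:
  $\mathrm{AGC} = 3.67\, s B$.
* **Belowground (BGC)** — root biomass predicted from shoot biomass by two
  global allometric models, $R_1 = 0.489\,B^{0.89}$ and $R_2 = 0.26\,B$,
  then converted as above. The central estimate uses the cell-wise mean of
  the two predictions, the bounds their min and max.
* **Soil (SOC)** — topsoil (0–30 cm) organic carbon density times 3.67,
  taken as given with no uncertainty model.

Uncertainty is carried as a deterministic low/central/high ensemble that
composes three sources in a worst/central/best direction: the stoichiometric
factor ($s = 0.45 / 0.475 / 0.50$), the allometric envelope (min / mean /
max), and the biomass map's per-cell standard deviation ($B - \sigma$
clipped at 0, $B$, $B + \sigma$). Reported uncertainties are the half-range
$(\mathrm{high} - \mathrm{low})/2$ — a proxy for a standard deviation, and
labelled as such, since the sources have no stated joint distribution.

## Certification

A cell's projected fraction of forest loss $d_{tot}$ over a 15-year horizon
is annualized by simple proration $d = d_{tot}/15$ (a compound option
$1-(1-d_{tot})^{1/15}$ is available; proration is the default because the
per-year rate is applied uniformly over the projection period). Eligibility
requires a certifiable (forest) land-cover class, no recent deforestation,
no settlements, and a cell center inside the tropical band
$[-23.44°, 23.44°]$ (closed interval: boundary centers are retained).

Certified flux per track splits into a *fast* component (AGC + SOC, credited
in the year of avoided loss) and a *slow* component (BGC), both scaled by
$(1-\text{buffer})\,d$ with a 20% baseline buffer, multiplied by true cell
area and the 0/1 eligibility mask. The belowground pool's conservative
10-year decay is interpreted as *credit timing, not reduction*: each year's
avoided belowground emission is issued in 10 equal annual tranches, so the
year-$t$ belowground credit is $f_{slow}\min(t,10)/10$. This conserves total
carbon while keeping early-year revenue conservative; crediting the soil
pool in full (rather than discounting it) follows the pool-sum formulation
and may overstate soil credits. Ineligible cells produce zero flux but stay
on the grid so that area accounting is consistent.

## Finance

Defaults: establishment \$25/ha at $t=0$ (undiscounted), maintenance
\$10/ha/yr, starting price \$5.8/tCO~2~ flat for 5 years then appreciating
5%/yr, horizon 30 years, risk-adjusted discount rate 10%/yr. Maintenance and
revenue are booked at end-of-year, the standard convention where cash-flow
timing is otherwise unspecified; moving establishment to $t=1$ changes NPV
by under 10% of the establishment line and is immaterial to the results.

$$\mathrm{NPV} = -25A + \sum_{t=1}^{30}
\frac{p(t)\,[f_{fast} + f_{slow}\min(t,10)/10] - 10A}{1.1^{t}}$$

Viability is *strictly* positive NPV (an NPV of exactly 0 is non-viable).
"NPV per year" in summary tables is total NPV divided by the 30-year
horizon — a documented convention; the total is always emitted alongside.
Because revenue is proportional to the starting price, the break-even price
has the closed form $\mathrm{PV(costs)}/\mathrm{PV(revenue\ at\ price}=1)$,
and the viability mask is identical to
$\{\text{break-even} < \text{price}_0\}$; the price sweep keeps the 5-year
flat period and the 5% appreciation at every starting price. Accumulation
curves carry a year-0 row holding the establishment outlay so that row
differences equal each year's discounted net cash flow *and* the final row
equals the aggregate NPV of viable cells; per-track curves use each track's
own viability so every band is self-consistent.

## Scenarios

Leakage removes a fraction $L$ of every flux component; an extra buffer
$\delta$ raises the withheld share to $0.2+\delta$ and re-runs
certification; cost inflation scales both cost lines; the opportunity-cost
filter keeps a cell only when carbon NPV strictly exceeds the land rent
capitalized as a constant-rent annuity over the same 30-year/10% frame (the
same-frame NPV-vs-NPV comparison is the only internally consistent one when
the rent capitalization is otherwise unspecified). Scenario reports
recompute viability from scratch — no reuse of the baseline mask — so cells
that cross the profitability threshold are captured, and percentages are
quoted against the *baseline* profitable volume (the natural fixed
denominator; a scenario-specific denominator would make the percentages
incommensurable across scenarios).

## Validation

One modeled estimate per project (buffered investible flux summed over cells
whose centers fall in the project polygon; an unbuffered switch exists) is
paired with *each* issued vintage, reproducing registry-style bookkeeping in
which a project with $k$ vintages contributes $k$ data points. The three
statistics are Pearson's correlation, RMSE, and a two-sided paired t-test
(sample SD, $n-1$ df). Perfect agreement (all differences zero) is defined
as $t = 0$, $p = 1$ rather than an error.

## The synthetic-world generator

The generator emulates the *structure* of the real inputs, not tropical
geography: lognormal biomass and rent fields built on smoothed Gaussian
noise (separable moving-average smoothing with reflective padding — simple,
dependency-light, and deterministic, unlike spectral methods whose FFT
plans can vary across platforms); a soil field mixing a biomass-tracking
component with an independent residual; Beta-distributed projected loss,
smoothed and clipped to $[0,1]$; land-cover/recent-loss/settlement layers
whose ineligible fractions are planted *exactly* (rank-based selection), so
eligibility tests have exact expectations; and VCU series equal to the
generator's own ground-truth flux times multiplicative lognormal noise
(credits are positive, so noise is multiplicative; CV configurable, 0 gives
exact recovery).

Mock countries are a recursive rectangular partition of the grid with split
lines on cell edges: a true partition whose polygons have exact closed
forms and in which no cell center can sit on a border ambiguously.
(Nearest-seed regions were considered and rejected: their boundaries have
no closed polygon form without a computational-geometry dependency, and the
partition guarantee is what the conservation tests need.)

Ground truth is computed by `truth_oracle()`, a scalar single-cell
reimplementation of the certification and pricing arithmetic kept
deliberately separate from the raster code. The stored truth table samples
`n_truth_cells` cells (default 1000) — a seeded random sample is as
powerful a check as exhaustive evaluation and keeps large-world generation
fast; the oracle itself can be called at any cell. Certified flux matches
the pipeline bit-for-bit (the oracle mirrors the pipeline's operation
order); NPV, accumulated in a different order, matches to better than
$10^{-9}$ relative.

Default generator magnitudes (150 t/ha biomass with CV 0.5 and 20% per-cell
SD, 60 tC/ha topsoil carbon, Beta(1, 9) 15-year loss, 30% ineligible cover,
5% recent loss, 2% settlements, \$30/ha/yr rent with CV 1) are round
humid-tropics values chosen once for structural realism. What passing tests
show is that the *accounting and pricing machinery* is correct and
internally consistent; they do not show that real-world maps produced from
real inputs would be accurate — that depends entirely on the quality of the
input rasters.

```{r example}
world <- generate_world(synth_config(n_rows = 60, n_cols = 60, seed = 1))
run <- run_pipeline(world)
run
run$sweep[, c("price0", "carbon_frac_central")]
```

## Numerical and geometric conventions

* Grids are north-up, cell-center registered, in lon/lat degrees; two grids
  are compatible for arithmetic only if all fields match exactly. Masked
  cells are `NA` and propagate strictly.
* Cell areas use a spherical Earth, $R = 6{,}371$ km:
  $A = R^2\,\Delta\lambda\,(\sin\varphi_{top}-\sin\varphi_{bot})$ — under
  0.3% from ellipsoidal areas at tropical latitudes and fully reproducible.
  A constant-nominal-area switch exists since the latitude convention of
  published per-cell figures is often unstated.
* Bilinear resampling reproduces affine fields exactly; a source cell is in
  a target cell's support only if its weight is non-zero, so target centers
  coinciding with source centers return the source value unchanged and
  resampling onto the same grid is the identity. Only same-scale or
  coarsening resampling is supported.
* Zone membership uses the cell-center rule with even-odd ray casting;
  shared-border cells go to the first zone in file order, which makes zonal
  sums over a partition conserve the global sum exactly.
* Rasters are exchanged as single-band ESRI ASCII grids written at full
  double precision (`%.17g`), so write/read round-trips are bit-exact;
  vectors as GeoJSON. Summary-table rounding to the nearest 1000 is
  presentation-layer only.
* All randomness in the generator flows from one integer seed through
  Mersenne-Twister with pinned normal/sample kinds; identical seeds give
  byte-identical worlds and pipeline outputs.

## Problem sizes

The test-suite worlds are 50×50 (module tests), 200×200 (end-to-end
property checks, 1000 truth cells), and one 500×500 full-pipeline run;
the bundled analysis script uses a 200×200 world. These sizes give stable
statistics while keeping a full check cycle in well under a minute; all
operations are vectorized and scale linearly in cell count.

## Limitations

* The low/central/high ensemble is a bounding composition, not an error
  model; half-ranges are not standard deviations.
* Additionality is proxied entirely by the projected deforestation layer;
  no project-level baseline or land-cover dynamics are modelled.
* Leakage is a uniform scaling, not spatially displaced deforestation.
* Price paths are deterministic; no stochastic prices, taxes, transaction
  costs, or country-specific discounting.
* The generator aims at structural, not statistical, realism of pantropical
  patterns.
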