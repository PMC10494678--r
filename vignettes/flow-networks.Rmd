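---
title: "Displacement networks for neonatal hospital care: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Displacement networks for neonatal hospital care: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonet)
```

## The problem

When specialized neonatal care (NICU beds, high-risk obstetric services)
concentrates in regional pole cities, a newborn's hospitalization often
occurs outside the mother's municipality of residence. Each admission of a
child aged 0–27 days (the neonatal period) whose occurrence municipality
differs from the residence municipality is treated as one *displacement*
event. `neonet` quantifies these displacements along three axes:

1. **Network structure** — who serves whom: a directed graph per biennium
   whose nodes are municipal seats and whose edges are origin→destination
   flows;
2. **Distance** — how far the displaced travel, summarised per health
   region by a flow-weighted mean;
3. **Trends and associations** — how distances, displacement shares,
   service supply and the neonatal mortality rate (TMN) evolve over biennia,
   with the health region as the observational unit.

## Statistics

### Two-level flow-weighted distance

For origin municipality $O_i$ with destinations $D_k$ ($k = 1..K$) and
flows $f_k$ (admission counts of the pair in a biennium), the mean outgoing
edge is

$$d_i = \frac{\sum_k f_k \, d(O_i, D_k)}{\sum_k f_k},$$

and for health region $j$ containing origins $i = 1..n_j$ with outflows
$F_i = \sum_k f_k$,

$$m_j = \frac{\sum_i F_i \, d_i}{\sum_i F_i}.$$

Because both levels weight by flow, $m_j$ is algebraically identical to the
flow-weighted mean of $d(O,D)$ taken in a single pass over all the region's
displaced admission records. The test suite asserts this identity to a
relative tolerance of $10^{-9}$ on randomly generated OD tables — it is the
module's primary correctness oracle, since any aggregation or join mistake
breaks it.

$d(\cdot,\cdot)$ is the great-circle (haversine) distance between the two
municipal seat coordinates on a sphere of radius 6,371 km. Administrative
sources do not state whether published displacement distances are road or
straight-line distances; seat-to-seat great-circle distance was chosen
because it is reproducible without road-network data and is a lower bound
on travel distance. Travel time and cost are out of scope.

### Proportions and indicators

Per health region $\times$ biennium:

* **% displaced** = 100 × (displaced in-state admissions of the region's
  residents) / (all in-state neonatal admissions of the region's
  residents). Out-of-state admissions enter neither term; their share of
  all displaced admissions is reported separately (about 1% in the study
  population this emulates).
* **% same-region** = 100 × (displaced flow with destination in the same
  region) / (total displaced flow of the region's origins). The denominator
  is *displaced* admissions only — published same-region shares close to
  99.7% are only consistent with that denominator.
* **NICU beds / 1,000 live births**, with pooled type I–III bed counts
  averaged over the biennium's two year-end values (the sources do not say
  whether a single reference date was used; the two-year mean is the
  symmetric choice).
* Birth-outcome percentages (< 1,500 g; gestational age < 28 weeks;
  5-minute Apgar ≤ 7; maternal age ≥ 35 years) and **TMN** = 1,000 ×
  (deaths at age ≤ 27 days) / live births, all by residence municipality.

A region–biennium cell with zero displaced flow has an *undefined* (not
zero) weighted distance and same-region share: a weighted mean over an
empty set is reported as missing. Likewise all indicators are missing when
a cell has zero births. Percent variation between biennia is
$VP = 100\,(B - A)/A$; a zero baseline yields a missing value with a
warning rather than an infinity.

### Graphs

Graphs are directed and simple: parallel admissions collapse into one edge
weighted by flow, self-loops are rejected (an admission at home is not a
displacement). Node in-degree counts distinct origin municipalities served
by a destination; inflow sums incoming flows. Node colour encodes the
municipality's macroregion and edge colour the *origin's* macroregion, with
the fixed palette leste = red, noroeste = blue, norte = green,
oeste = yellow. Exports: GEXF 1.2 (written directly, with positions and
declared attributes, openable in Gephi), GraphML (via igraph) and a flat
edge-list CSV; numeric attributes are serialized with 17 significant digits
so re-imports reproduce them exactly.

The "frequent destinations" comparison table lists all region seats plus
any municipality whose inflow reaches a configurable threshold (default
100) in either biennium. The threshold is explicit because no objective
rule exists for which non-seat cities "count" as frequent destinations;
seats alone miss emerging poles.

### Mixed models

Trends are estimated with a random-intercept linear model per indicator,

$$y_{jt} = \beta_0 + \beta_1 t + u_j + \varepsilon_{jt}, \qquad
u_j \sim N(0, \tau^2),\ \varepsilon_{jt} \sim N(0, \sigma^2),$$

fitted by REML (lme4), with region $j$ as unit and biennium
$t = 1, \dots, 6$ as time. The biennium is coded as consecutive integers
starting at 1; the slope is invariant to that choice of origin, only the
intercept shifts. The adjusted TMN analysis uses three nested models:
biennium only; + flow-weighted distance; + displacement share, NICU bed
supply and the four birth indicators (all covariates raw, so estimates read
as change in TMN per unit of the covariate). Fixed effects get Wald 95%
CIs; the variance components ($\tau$, $\sigma$, reported as SDs) get
profile-likelihood CIs by default or parametric-bootstrap CIs on request —
the original CI method is not derivable from the published tables, so both
defensible options are exposed. Rows with missing response or covariates
are dropped listwise; non-convergence is flagged on the returned object
(`converged = FALSE`), and a design-matrix condition number above $10^3$
raises a recorded collinearity warning. No multiplicity adjustment is made
across indicators, mirroring the per-indicator presentation this analysis
follows. Degenerate zero-noise inputs produce boundary ("singular") fits
whose fixed effects are still exact; their Wald CIs may be reported missing
when the covariance matrix is not estimable.

Because the real coefficients depend on the confidential administrative
extracts, the acceptance surface for the models is *parameter recovery*,
not coefficient matching: `simulate_panel()` draws panels from the model
above and the test suite verifies, over 500 replicates at the study's panel
shape (22 regions × 6 biennia, slope −0.35, $\tau = 0.94$,
$\sigma = 1.34$ — the magnitudes of the mortality-trend estimates), that
the mean estimated slope is within Monte-Carlo error of the truth and that
Wald CI coverage lies in [90%, 98%].

## The synthetic generator

`synth_params()` / `generate_state()` produce a full synthetic state:

* **Geography** — a rectangular lattice: 4 macroregion quadrants, each
  tiled by its health regions, each region patch holding a jittered grid of
  municipalities with the region seat at the patch centre. Defaults: 22
  regions × 18 municipalities (396; the emulated state has 399) in a
  ~600 × 440 km bounding box, giving within-region distances of tens of km
  and cross-region distances of 100–300 km.
* **Admissions** — Poisson counts per municipality-year; ages put 80% of
  mass on days 0–27 and a tail up to day 364, so the neonatal filter always
  has records to remove. An admission is displaced with probability
  `displacement_prob` (default 0.39, between the two published biennial
  shares of 34.67% and 42.52%); given displacement it is out of state with
  probability `out_of_state_prob` (default 0.01, the published ~1% share —
  note the conditioning: the sentinel share is a fraction of *displaced*
  admissions). In-state destinations are drawn with gravity weights
  $a^{\mathrm{seat}} \cdot d^{-\gamma}$, defaults $a = 500$,
  $\gamma = 2.5$, chosen once so that the synthetic state's flow-weighted
  distance (~60 km), same-region share (~70%) and displaced volume
  (~12,000 per biennium) sit at the published order of magnitude.
* **Vital records** — births with independent Bernoulli indicators at the
  configured prevalences (defaults 1.25% < 1,500 g, 0.48% GA < 28 w, 2%
  Apgar ≤ 7, 12.9% mothers ≥ 35 y — mid-period values of the published
  trends) and continuous attributes drawn consistently with each
  indicator; neonatal deaths at 8.2/1,000 births (between the published
  biennial rates 8.98 and 7.44) with early-neonatal concentration, plus
  post-neonatal deaths at 2.5/1,000 so the day-27 cutoff in the TMN
  numerator is exercised.
* **Beds** — Poisson counts concentrated at seats (default mean 30 per
  seat, 0.2 elsewhere), constant across years.

All randomness flows from a single integer seed through fixed per-table
offsets, so identical parameters give byte-identical tables and different
tables are still mutually independent draws.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: temporal growth in admission volumes and
displacement shares (rates are constant over years, so synthetic trends are
flat by construction); real geography, road networks, population-size
heterogeneity beyond Poisson noise; correlation between birth-risk
indicators and mortality within municipalities; duplicate admissions of the
same newborn (each admission row is one event, as in AIH-style counting;
whether the original analysis deduplicated transfers is not stated). Tests
on synthetic data verify the *computations*, and the recovery study
verifies the *estimator* — neither certifies substantive conclusions about
any real state.

## Numerical and interface choices

* The neonatal window is the closed interval [0, 27] days; ages at exactly
  0 and 27 are included, 28 is not. Negative ages are a validation error,
  never silently dropped.
* Municipality codes are 6-digit; 7-digit codes are accepted with the
  trailing check digit dropped. The out-of-state sentinel is the reserved
  code 999999, never present in a registry.
* Biennium is derived from the admission year alone (2008–2009 is index 1
  through 2018–2019, index 6); years outside the configured range are a
  range error.
* Aggregations are exact integer counts; distance identities are asserted
  to $10^{-9}$ relative tolerance; graph exports serialize numerics to 17
  significant digits.
* Presentation rounding (two decimals in the worked examples) happens only
  at print time; all computations keep full precision.
* Problem sizes in the shipped tests were chosen to exercise the documented
  scales — ~100,000 admission records for the conservation suite, 50,000+
  births for prevalence calibration (asserted within 2–3 binomial standard
  errors), 1,000-edge graphs for round-trips, and 500 simulated panels for
  the recovery study.

The package's functions are the interface (`generate_state()` →
`build_region_summary()` → `build_graph()`/`rank_destinations()` →
`fit_trend()`/`fit_tmn_model()`), with CSV/GeoJSON/GEXF/GraphML readers and
writers for interoperability; `scripts/acceptance.R` chains them into the
full reproducible run.

## Limitations

Great-circle seat-to-seat distance understates door-to-door travel;
flow-weighted means hide within-region dispersion; the frequent-destination
threshold is a reporting choice, not an estimate; mixed-model CIs for
variance components near zero are unstable (profile CIs may fail on
boundary fits and are then reported missing); and all defaults describe a
stylised state — analyses of real extracts should set `synth_params()`
aside entirely and feed their own tables to the same pipeline.
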