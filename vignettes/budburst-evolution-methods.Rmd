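---
title: "Methods: simulating budburst-phenology evolution along an elevational gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating budburst-phenology evolution along an elevational gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenoevo` couples three submodels — physiology, demography and quantitative
genetics — into an individual-based simulation of budburst-timing evolution
in a tree population spread over a 700–1700 m elevational gradient. This
vignette documents the model equations, the parameters that matter, the
choices made where the design was genuinely open, and what the synthetic
study conditions can and cannot show about real populations.

## The trait and its genetics

The only genetically variable trait is the critical forcing requirement
`F_critBB` (°C): the temperature sum above a base temperature that a bud
must accumulate, from the rest-onset day onward, before it breaks. Ten
unlinked biallelic loci act purely additively. Locus $l$ contributes
$m_l + \alpha_l$, $m_l$, or $m_l - \alpha_l$ for genotypes A1A1, A1A2,
A2A2; all midpoints are equal, $m_l = \mu/10$ with $\mu = 190$ °C, so a
fully heterozygous genotype scores exactly $\mu$. Allelic effects are drawn
once per study from $\mathcal{N}(\mu/20, (\mu/80)^2)$ and redrawn until they
fall in $[0, \mu/10]$, which yields an L-shaped distribution of locus
contributions and keeps every genotypic value inside $[0, 2\mu]$. Every
replicate run of a scenario shares the same effects; only founder genotypes
and positions differ among repetitions.

Founder genotypes are in Hardy–Weinberg proportions at per-locus allele
frequencies drawn from Uniform(0, 1). The within-population additive
variance is the standard form for additive biallelic loci,

$$V_A = \sum_l 2 p_l (1 - p_l)\, \alpha_l^2,$$

which the test suite validates against the empirical variance of genotypic
values over $10^5$ Hardy–Weinberg genotypes. (The uniform founder
frequencies make the *expected* founder $V_A$ of order
$10 \times 2 \times \tfrac16 \times E[\alpha^2] \approx 320$ (°C)²; the
non-heritable control regime is nevertheless parameterised at
$V_P = 22$ (°C)², a deliberate, configurable convention rather than a
derived quantity.)

Three heritability regimes are supported. Fully heritable ($h^2 = 1$):
phenotype = genotypic value. Control ($h^2 = 0$): phenotypes are drawn from
$\mathcal{N}(190, V_P = 22)$ regardless of genotype, so selection acts
within a generation but cannot propagate across generations. Partial
($0 < h^2 < 1$, default 0.6): phenotype = genotypic value +
$\mathcal{N}(0, V_E)$ with $V_E = V_A^{\mathrm{conf}}(1 - h^2)/h^2$ and
$V_A^{\mathrm{conf}} = 22$. A tree's phenotype is fixed at creation for its
whole life; the environmental deviation is *not* redrawn each year. All
regimes consume exactly one random deviate per tree, so runs differing only
in heritability share identical randomness everywhere else — without
selection, genotype dynamics are bit-identical across $h^2$ settings
(common random numbers), which the engine tests exploit.

Mutation, linkage, dominance, epistasis and immigration are excluded by
design.

## Budburst and the surrogate carbon balance

Budburst follows the thermal-time model: daily forcing
$\max(T - T_2, 0)$ accumulates from day $N_{\text{START1}} = 78$ (that day
included; $T_2 = 0$ °C), and budburst occurs on the first day the sum
reaches the tree's `F_critBB`. Ties at exact equality count as budburst; a
non-positive requirement degenerates to budburst on day 78. Chilling and
dormancy release are held constant across years and elevations and are not
modelled.

The daily carbon/water balance is a surrogate with the same interface
quantities as a full process-based canopy model, not a reimplementation of
one. Its contract:

* **Before budburst** — no assimilation; maintenance respiration
  $(r_0 + r_m B_{\text{tree}})\,Q_{10}^{(T-15)/10}$ drains the reserve pool,
  then structural biomass if reserves run out (any still-unpayable remainder
  is recorded, keeping the carbon audit exact).
* **At budburst** — the canopy is set to `lai_max` and its construction cost
  (leaf carbon $ \text{LAI}_{\max}\times\text{LMA}\times 0.5$, plus a 50%
  growth-respiration overhead) is drawn from reserves. The shortfall, if
  any, is the *pre-budburst reserve deficit* used by the Type II mortality
  rule.
* **Leaf period** (budburst to the fixed senescence day 285) — assimilation
  $A = a_{\max}(1 - e^{-k\,\mathrm{LAI}})\,f(T)\,g(W)$ with a parabolic
  temperature response $f$ and a drought modifier
  $g = \min(1, w/0.4)$, $w$ the relative soil water content. The daily
  shortfall $1 - g$ accumulates into the water stress index (WSI), a
  dimensionless sum of fractional photosynthesis reductions. Positive net
  carbon is split 35% to wood (converted annually to a DBH increment) and
  65% to reserves.
* **Soil** — a single bucket per tree (SEW = 60 mm): precipitation in,
  LAI- and temperature-proportional evapotranspiration out, clipped to
  [0, SEW]. Trees do not compete for water or light.
* **Frost** — after budburst initiation, any day with minimum temperature
  below `T_minEffect` = 0 °C multiplies LAI by
  $\max(0,\, 1 - k_{\text{frost}}(T_{\text{minEffect}} - T_{\min}))$;
  $k_{\text{frost}}$ is 0, 0.1 or 0.2 depending on the scenario. The exact
  functional form of the frost response was an open choice; the per-degree
  multiplicative reduction was adopted because it is the form in which the
  frost scenarios are defined.

Calibration targets for the surrogate's free parameters
($a_{\max} = 14$ gC m⁻² d⁻¹, $k = 0.5$, $T_{\text{opt}} = 20$ °C,
$r_0 = 0.35$ gC m⁻² d⁻¹, $r_m = 2\times10^{-4}$ d⁻¹, $Q_{10} = 2$,
ET coefficient 0.02 mm LAI⁻¹ °C⁻¹, senescence day 285, LMA 93 g m⁻²) were
order-of-magnitude plausibility only: annual GPP near $10^3$ gC m⁻² at
mid-gradient, a WSI that declines by roughly a third from 1000 to 1700 m,
budburst spanning about four weeks across the gradient, and
carbon-starvation mortality concentrated in anomalous years and at the
gradient's hot, dry end. None of these is asserted as a quantitative
reproduction of any particular site.

Every simulated year satisfies an exact carbon audit (tested to $10^{-9}$
relative): change in structural + reserve pools = GPP − respiration −
litter + unmet respiration, with litter collecting frost-shed and senescent
leaf carbon and seed carbon debited from reserves at crop time.

## Demography

**Mortality.** Type I: end-of-year reserves below 45 gC m⁻². Type II:
pre-budburst reserve deficit above 160 gC m⁻². Scenario switches mask
either or both rules. Type I is evaluated first so every dead tree has
exactly one cause.

**Fecundity.** If end-of-year reserves $B_{\text{res}}$ exceed 100 gC m⁻²,
the primary seed crop is
$N_S = \lfloor 0.05\, B_{\text{res}}\, C_P / 0.45 \rfloor$ ($C_P$ the crown
projection in m²; 0.45 gC per seed) and the carbon $0.05\,B_{\text{res}}$
is debited; effective fecundity discounts empty seeds (0.33), seed survival
(0.15) and germination (0.485). The gating-and-rate form was reconstructed
from its dimensional structure (gC m⁻² × m² / gC seed⁻¹ → seeds). In the
no-differential-reproduction scenario all living adults are assigned the
year's mean fecundity, so realised fecundity varies only through the
Poisson recruitment draw.

**Dispersal.** Both pollen and seed kernels belong to the exponential-power
family $p(r) = \frac{b}{2\pi a^2 \Gamma(2/b)} e^{-(r/a)^b}$, parameterised
by the mean distance $\delta = a\,\Gamma(3/b)/\Gamma(2/b)$ and shape $b$;
$b = 1$ recovers the pure exponential with $\delta = 2a$. The family was
chosen because the configured shapes (pollen 0.97, seed 0.31) are not 1;
with $b_P = 0.97$ the pollen kernel is near-exponential. Distances are
sampled exactly via $(r/a)^b \sim \Gamma(2/b, 1)$. The domain has
reflecting borders, implemented as first-order mirror images of the source
across the four edges: densities of the direct and four mirrored paths are
summed. Corner (diagonal) images are omitted; for the default kernels the
missing mass is a few percent at worst, which the seed-rain conservation
test makes explicit.

**Mating.** A seed is selfed with probability 0.025; otherwise its father
is drawn with probability ∝ kernel density of the mother–candidate distance
× DBH^0.82. Pollen is never limiting.

**Recruitment.** Seed rain from mother $j$ on cell $i$ is
$\tau_{ij} = F_j\, p_S(r_{ij})$ at the cell centre. Recruits per
(cell, mother) are Poisson with mean $\tau_{ij} \times S \times
s_{\text{seedling}}$, where $S = 400$ m² and $s_{\text{seedling}}$
(default 0.005) is the probability that a germination-stage seedling
survives the 39-year seedling stage that the model does not simulate
individual-by-individual. Recruits are placed uniformly in their cell —
or from an isotropic Gaussian (SD 5 m, truncated to the domain) around the
mother when she occupies the same cell — and enter at age 40 with Gaussian
sizes (height 9 ± 0.34 m, DBH 13.8 ± 0.9 cm). Two genotype-independent
regulation steps follow: a per-cell ceiling (`k_cell`, default 12 stems per
400 m², i.e. ~300 stems ha⁻¹ at recruitment age) applied by uniform
subsampling, then crown-overlap thinning — crowns are discs of the crown
projection, and violating pairs (> 30% overlap of the *smaller* crown, a
convention fixed here) are visited in random order, removing one member of
each at random. Removals never create violations, so the survivor set
satisfies the constraint exactly, which the tests audit pair-exhaustively.
Both $s_{\text{seedling}}$ and `k_cell` are this package's own
density-regulation choices for the unmodelled seedling stage: without them,
germinant-scale fecundities (tens of effective seeds per tree per year)
would drive recruit numbers far beyond any plausible stand density. For
efficiency the engine applies thinning before drawing recruit sizes — and
fathers are assigned at seed creation, with that year's adult attributes —
which leaves all distributions unchanged because both regulation steps are
independent of genotype and size.

**Growth.** Annual wood carbon (per m² crown, scaled by crown projection)
is converted to stem volume through wood density (0.55 g cm⁻³ dry, carbon
fraction 0.5) and a cylindrical stem of form factor 0.5, inverted at the
current height for the DBH increment; height and crown projection follow
configurable power laws of DBH chosen so a 13.8-cm recruit stands ~9 m tall
with a ~12 m² crown.

## The engine and the synthetic climate

A scenario run: one allelic-effects draw; per repetition, 500 founders
(100 per 20-m band centred on 800–1600 m), five neutral pre-evolution
generations (everyone survives, equal fecundity, physiology bypassed;
mating and dispersal operate normally, so drift and restricted gene flow
build spatial genetic structure; recruits are thinned uniformly back to the
founder count), then six selected generations. Each selected generation is
a 30-year adult stage: daily physiology per tree under the lapse-adjusted
looped climate, annual growth and mortality, reproduction in adult years
21–30 only, all adults removed at year 30, dormant seeds recruited to found
the next cohort at age 40. A repetition whose seed pool empties terminates
gracefully and is flagged as collapsed.

The climate generator emulates the *shape* of a Mediterranean-mountain
daily series, not any particular station record: a sinusoidal seasonal
cycle (annual mean 8 °C, amplitude 9 °C at the 1000-m reference) with AR(1)
daily anomalies (SD 2.5 °C, autocorrelation 0.7), daily minima ~4 °C below
the mean, a few injected spring frost nights (days 90–150), mostly dry
summers (~500 mm yr⁻¹), a radiation proxy, and one hot (+4 °C summer), dry
(half summer rainfall) year per 5-year block, mimicking an extreme-drought
year. Years have 365 days; no leap days. Elevation enters only through a
linear lapse model, default −0.6 °C per 100 m for both mean and minimum
temperature (the standard environmental lapse rate; the true site-specific
coefficients are configurable), zero for precipitation, and radiation
deliberately unadjusted. Humidity and wind are not generated because the
surrogate physiology does not consume them. Consequences: passing tests
demonstrate the *mechanisms* — counter-gradient selection pressures,
mortality-driven responses, drift-only nulls — under controlled synthetic
conditions; they do not reproduce site-specific published values that
depend on a real weather series and a full canopy-physiology
parameterisation, which is why the package's checks are parameter-recovery
and property tests rather than comparisons to field tables.

Randomness: a master seed spawns named streams (effects, climate,
per-repetition founders, pre-evolution, generation dynamics) through a
31-bit mixing hash, so components are reproducible in isolation and a rerun
under one master seed is bit-identical.

## Analysis conventions

Bands Alt1–Alt5 partition 700–1700 m into five 200-m intervals, half-open
on the right with the top edge closed; membership is fixed at recruitment
(trees do not move). `Cb` (response to selection) is the mean over
repetitions of the change in band mean `F_critBB` between the first adult
year of the first and last selected generations; repetitions with an empty
band in either generation are excluded and the usable count reported (the
analysis always uses *all* available repetitions, however many were run).
The budburst-date response is additionally averaged over the five matched
climatic years. `Cw` (selection differential) compares survivors at the
final adult year to their cohort at the first adult year; it is exactly
zero without mortality. Band phenotypic variance is computed among
final-year survivors; under full heritability it equals the realized
additive variance computed from the band's allele frequencies, a
two-route identity the tests verify.

## Numerical choices and problem sizes

Degenerate inputs: a non-positive forcing requirement flushes on day 78; a
requirement met only on/after the senescence day develops no canopy that
year; trees whose reserves and biomass are both exhausted carry an explicit
unmet-respiration term so the audit stays exact; a band with fewer than two
survivors reports no variance. Ties in the forcing sum count as budburst.
Kernel scale parameters are solved in closed form from the mean-distance
identity rather than fitted.

The shipped tests run the full design's *components* at their study values
(10⁶ kernel samples, 10⁵ mating and phenotype draws, 200 founder
initializations) but scale the end-to-end simulations down — typically 80–150
founders, 1–3 repetitions, 10 adult years with reproduction from year 6, and
20 replicates for the drift-null check — sizes chosen so the whole suite
exercises every pathway, including collapse handling, at desk scale. The
default configuration (21 repetitions, 500 founders, 6 × 30-year
generations) runs unattended in well under an hour on a single core; the
worked example in the README (3 repetitions, 150 founders, 3 generations)
takes about a minute.

## Known limitations

No competition among adults for light or water; no pollen limitation; no
mutation or immigration; non-overlapping generations; a fixed senescence
date; a single repeated 5-year climate block (so between-generation climate
is perfectly stationary); first-order-only boundary reflections; and a
surrogate physiology whose parameters are plausible rather than fitted.
Within those bounds, the simulator is intended for mechanism exploration
and hypothesis generation, not site-specific prediction.
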