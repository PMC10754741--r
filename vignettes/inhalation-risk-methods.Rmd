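---
title: "Inhalation risk assessment for PM10-bound metals and PAHs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhalation risk assessment for PM10-bound metals and PAHs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm10risk)
```

## The problem

Communities around large opencast coal mines breathe PM₁₀ whose toxicity is
driven less by its mass than by what is bound to it: heavy metals (notably
hexavalent chromium and arsenic) and polycyclic aromatic hydrocarbons.
`pm10risk` turns daily speciated PM₁₀ concentrations, measured per monitoring
zone, into the standard suite of inhalation risk metrics, quantifies their
uncertainty, and maps where the risk comes from using air-mass trajectories.
The bundled example tables come from a February–May 2022 campaign at Latin
America's largest opencast coal mine (La Guajira, Colombia), with eight
sites grouped into North, South and Populated zones.

## Deterministic risk model

For each metal the chain is exposure concentration → hazard quotient →
hazard index, plus lifetime cancer risk where an inhalation unit risk
exists:

$$EC_i = \frac{C_i \cdot ET \cdot EF \cdot ED}{AT_n}, \qquad
HQ_i = \frac{EC_i}{RfC_i \cdot CF}, \qquad
HI = \sum_i HQ_i, \qquad
CR_i = EC_i \cdot IUR_i$$

with $C_i$ in µg m⁻³, $RfC_i$ in mg m⁻³ and $CF = 1000$ µg mg⁻¹. Because
$ET \cdot EF \cdot ED \le AT_n$ is enforced, $EC_i \le C_i$ always. The PAH
mixture is reduced to benzo[a]pyrene equivalents and converted to a dose:

$$TEQ_{total} = \sum_i C_i \cdot TEF_i, \qquad
ILCR = \frac{TEQ_{total} \cdot SF \cdot IR \cdot EF \cdot ED \cdot 10^{-6}}{BW \cdot AT}$$

where the $10^{-6}$ factor converts the ng m⁻³ TEQ to the mg-based dose the
slope factor expects. Cancer-risk classes use the conventional screening
thresholds $10^{-6}$ and $10^{-4}$; the sources defining them leave the
boundary points unassigned, so this package deliberately assigns both
boundaries to the closed middle ("acceptable") interval.

Hexavalent chromium is not measured directly by XRF; following the
convention for coal-mining atmospheres it is estimated as one-seventh of
total chromium (`chromium_vi()`).

### Parameters, units, defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| ET | h day⁻¹ | 24 | residential scenario, continuous presence |
| EF | days yr⁻¹ | 350 | EPA residential default |
| ED | yr | 30 | EPA residential default |
| AT_n | h | 70·365·24 | 70-year lifetime (hours) |
| AT | days | 70·365 | 70-year lifetime (days) |
| IR | m³ day⁻¹ | 20 | adult inhalation rate |
| BW | kg | 70 | adult body weight |
| CF | µg mg⁻¹ | 1000 | unit bridge in HQ |

Concentrations are stored in ng m⁻³ everywhere; unit conversion happens only
inside the risk equations, never in storage. The toxicity preset
(`toxicity_table()`) carries EPA IRIS / OEHHA RfC and IUR values, the BaP
slope factor 3.14 (mg kg⁻¹ day⁻¹)⁻¹, Nisbet & LaGoy TEFs, and Colombian-soil
background values; every entry is overridable from a YAML/JSON config, and
every risk output records the parameter set used. Triphenylene has no
canonical TEF; it ships at the chrysene-class value 0.01, overridable.

Exposure-parameter and toxicity values of this kind vary between assessments;
published HI/CR figures for the bundled campaign depend on a parameter
supplement we do not reproduce, so the shipped defaults are documented
conventions rather than a claim to re-derive any specific published total.
A known related discrepancy: with Nisbet–LaGoy TEFs applied to the bundled
zone means, IDP contributes ~22–25% of the TEQ, whereas values of 16–19%
circulate for this campaign; no TEF set recoverable from public sources
reproduces the latter, and we do not force agreement.

## Censoring, summaries, indices

Below-detection records (As and Pb have below-detection minima in the
campaign tables) carry a flag rather than a value. Summaries substitute
LOD/2 by default — the most common convention for left-censored
environmental data — with `zero` and `omit` as alternatives; the policy used
is recorded on the output, and per-species LODs must be user-supplied since
they are instrument-specific. The standard deviation is the sample (n−1)
estimator.

The geo-accumulation index $I_{geo} = \log_2(C / 1.5B)$ uses a direct ratio
of concentration to background, so both must arrive in the same declared
unit; the function refuses mixed units rather than guessing a conversion.
Backgrounds for Cr, As, Pb, Cu, Zn and Mn ship as plausible Colombian
surface-soil values (33, 15, 10, 35, 65, 500 mg kg⁻¹); Al has no regional
background and yields `NA` with a warning.

Diagnostic ratios are computed per day and then averaged (mean of daily
ratios). The alternative — the ratio of zone means — is not equivalent for
skewed daily data and is not what zone-level ratio reports in this field
describe, so it is not offered.

## Monte Carlo uncertainty and sensitivity

`mc_propagate()` evaluates a deterministic risk function on independent
joint draws. Default distribution families in `mc_zone_risk()`: lognormal
for concentrations and the inhalation rate (non-negative, right-skewed;
moment-matched to the target mean/sd via
$\sigma^2_{\log} = \ln(1 + sd^2/mean^2)$), truncated normal (±3σ and > 0)
for body weight, fixed values for ET/EF/ED. These choices are recorded in
the output and fully overridable. Percentiles use the type-7
linear-interpolation definition — tabulated 5th/95th percentiles depend on
this choice, so it is fixed and documented. Sensitivity is the Spearman rank
correlation of each varied parameter with the output, reported together
with a normalized contribution (squared coefficient over the sum of
squares). One global seed drives per-parameter substreams derived
deterministically from it, so draws are reproducible bit-for-bit and adding
a parameter does not perturb the others' streams.

## CPF spatial risk mapping

Daily receptor risk (HI, CR or ILCR computed per day) is combined with
trajectory endpoints on an axis-aligned grid of square cells (half-open on
east/north edges, so shared-edge points belong to exactly one cell). A day
is "high-risk" when its metric is at or above the 75th percentile of the
series — the convention of the CPF literature; the cutoff is configurable —
and each cell's CPF is the fraction of its endpoints belonging to high-risk
days. Cells visited by few trajectories are statistically unstable, so a
step weighting multiplies the CPF: 1 for $n_{ij} > 2\bar n$, 0.7 down to
$\bar n$, 0.42 down to $0.5\bar n$, 0.05 below, with $\bar n$ the mean count
over non-empty cells. Weighting never increases a value, and raising the
percentile threshold can only shrink the high-risk day set.

Trajectory clustering resamples each track to a common point count,
projects to planar km (longitude scaled by cos of the mean latitude —
adequate at sub-100 km domain scale, stated rather than hidden), and runs
Euclidean k-means; k is a user choice and the mean silhouette width is
reported to guide it. Forward and backward trajectories are pooled by
default and distinguishable by the `direction` field.

## The synthetic generator

`gen_concentrations()` draws censored-lognormal daily series moment-matched
to per-zone/species mean–sd targets — matching the right-skewed, max ≫ mean
structure of the campaign tables — with optional equicorrelation on the log
scale (common-factor Gaussian copula) for exercising correlation analyses.
`gen_trajectories()` produces correlated random walks under a prevailing
wind direction (default easterly, the dominant regime at the mine; 12-h
endpoint interval; 15 km h⁻¹ transport speed as a typical synoptic value),
with backward tracks extending upwind of the receptor. What the generator
does *not* emulate: serial autocorrelation of daily concentrations,
meteorology-driven covariance between species and transport, seasonal
trends, or dispersion physics. Tests passing on generated data therefore
validate the arithmetic and statistical machinery, not any claim about a
particular real atmosphere.

## Numerical and design notes

- Problem sizes in the test-suite: generator recovery uses n = 10⁴ days,
  uniform-quantile checks n = 10⁵ draws, CPF conservation 100 random small
  grids, spatial-direction checks 20 seeded runs of 30 trajectories — sizes
  at which the 3-standard-error bounds used are sharp while the whole suite
  stays fast.
- Episode-day selection: with the ≥-threshold convention and type-7
  quantiles, planted episodes are selected *exactly* when they form exactly
  the top quartile of days; with fewer episodes the selection is a superset.
  Tests plant 10 episodes in 40 days accordingly.
- Truncated draws use rejection sampling with a retry cap; a distribution
  whose mass lies essentially outside its bounds errors out naming the
  parameter instead of looping.
- All-censored groups under the `omit` policy, PAHs without TEFs, zero
  compositional totals, zero-area grids and non-monotone trajectory
  timestamps are hard errors; missing RfC/IUR/background values yield `NA`
  with a warning and are excluded from totals — never silent zeros.
- `run_pipeline()` writes a JSON manifest (config hash, seed, input
  digests, package version) so that outputs are traceable to exactly one
  configuration; optional stages with missing inputs are skipped with a
  logged warning.

## Limitations

Inhalation only — no dermal or ingestion pathways, no mixture interactions
beyond additive TEQ, no receptor modelling (PMF/CMB) or PSCF/CWT variants,
and no meteorological simulation: trajectories are inputs. Risk classes are
screening conventions, not dose–response epidemiology.
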