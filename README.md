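# pm10risk

Inhalation health-risk assessment for PM₁₀-bound heavy metals and polycyclic
aromatic hydrocarbons (PAHs), built for speciated filter-sampling campaigns
around strong particulate sources such as opencast coal mines. The package is
aimed at exposure scientists and environmental epidemiologists who have daily
speciated PM₁₀ concentrations (XRF metals, GC–MS PAHs) per monitoring zone
and want defensible risk numbers, uncertainty bounds and source/risk maps
from them.

## What it computes

**Deterministic risk.** For each metal *i* with zone concentration *C\_i*
(µg m⁻³):

    EC_i = C_i · ET · EF · ED / AT_n          (exposure concentration)
    HQ_i = EC_i / (RfC_i · CF)                (hazard quotient)
    HI   = Σ HQ_i                             (hazard index)
    CR_i = EC_i · IUR_i                       (lifetime excess cancer risk)

with the usual screening classes (CR < 10⁻⁶ negligible, 10⁻⁶–10⁻⁴
acceptable, > 10⁻⁴ likely harmful). For the PAH mixture, congeners are scaled
to benzo[a]pyrene potency with toxic equivalency factors (Nisbet & LaGoy
preset) and propagated to an incremental lifetime cancer risk:

    TEQ_total = Σ C_i · TEF_i
    ILCR = TEQ_total · SF · IR · EF · ED · 10⁻⁶ / (BW · AT)

**Pollution and source indicators.** Geo-accumulation index
`Igeo = log₂(C / 1.5·B)` with the seven Muller classes; compositional mass
fractions; regulatory exceedance factors; PAH diagnostic ratios
(Ant/(Ant+Phe), FR/(FR+Pyr), BbF/(BbF+BkF)) averaged over daily values;
Pearson correlation matrices.

**Uncertainty.** Monte Carlo propagation (default 10,000 iterations) with
per-parameter distributions (fixed / uniform / normal / lognormal /
triangular, truncated), type-7 percentiles, and Spearman rank-correlation
sensitivity with contribution-to-variance.

**Spatial risk.** Conditional probability function (CPF) mapping of daily
HI / CR / ILCR onto a geographic grid using forward/backward air-mass
trajectory endpoints, with step-function down-weighting of sparsely visited
cells and k-means trajectory clustering.

**Synthetic data.** A generator for censored-lognormal daily concentrations
(moment-matched to zone mean/sd targets) and directional trajectory bundles,
so the whole pipeline is testable without external downloads.

## Worked example

The package bundles the zone summary statistics of a 2022 field campaign at
Latin America's largest opencast coal mine (three zones, seven metals,
fourteen PAHs):

```r
library(pm10risk)

met <- campaign_zone_summary("metals")
pah <- campaign_zone_summary("pahs")

# Composition: Al dominates the metal mass
f <- composition_fractions(met)
subset(f, species == "Al")
#>   zone      species  mean fraction_pct
#>   North     Al      1423.         82.8
#>   South     Al      1421.         88.6
#>   Populated Al      1659.         88.8

# Cr(VI) exceeds the 12 ng/m3 US-EPA limit 8.7-fold in the North Zone
exceedance_factor(met$mean[met$zone == "North" & met$species == "Cr(VI)"], 12)
#> [1] 8.68

# Deterministic cancer risk for the metals
risk <- metals_risk(met)
subset(risk, species == "Cr(VI)")
#>   zone      species c_ng_m3 EC_ug_m3    HQ       CR cr_class
#>   North     Cr(VI)    104.    0.0428 0.428 0.000514 likely_harmful
#>   South     Cr(VI)     64.1   0.0263 0.263 0.000316 likely_harmful
#>   Populated Cr(VI)     66.0   0.0271 0.271 0.000326 likely_harmful

# PAH mixture: TEQ ~0.91 ng/m3 in the North Zone, ~54% of it from BaP,
# and an acceptable ILCR in all three zones
res <- pah_risk(pah)
res$ilcr
#>   zone      TEQ_total        ILCR risk_class
#>   North         0.909 0.000000335 acceptable
#>   South         1.14  0.000000421 acceptable
#>   Populated     0.794 0.000000293 acceptable
```

`CR = 5.14e-4` means an estimated five excess cancers per ten thousand
lifetime-exposed residents from Cr(VI) inhalation alone; the PAH ILCR values
sit one to two orders of magnitude below the 10⁻⁶ concern threshold.

Uncertainty and spatial mapping follow the same grammar:

```r
mc <- mc_zone_risk(subset(met, zone == "North"), subset(pah, zone == "North"),
                   n_iterations = 10000, seed = 1)
tr <- gen_trajectories(30, prevailing_deg = 90, seed = 1)   # easterly regime
g  <- grid_spec(origin_lat = 8.2, origin_lon = -75.6, cell_km = 20)
map <- cpf(assign_endpoints(tr, g),
           risk = data.frame(date = as.Date("2022-02-01") + 0:29,
                             value = rlnorm(30)))
```

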