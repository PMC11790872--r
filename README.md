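# coastrisk

Environmental and human-health risk assessment for coastal seawater
contaminant surveys: polycyclic aromatic hydrocarbons (PAHs), potentially
toxic elements (heavy metals) and total organic carbon.

Coastal waters near shipping lanes, refineries and desalination intakes
accumulate dissolved PAHs and metals whose levels must be screened both for
ecological harm and for human exposure (the water is drunk after
desalination and contacted directly). `coastrisk` is for the environmental
chemists and risk assessors doing that screening. It takes per-sample
analyte tables (with non-detect flags) and computes:

* **PAH metrics** — per-site totals, carcinogenic/LPAH/HPAH group totals,
  diagnostic source ratios (LMW/HMW, Phe/Ant, Flu/Pyr, Flu/(Flu+Pyr),
  BaA/(BaA+Chry)) with petrogenic/pyrogenic classification, and risk
  quotients against negligible (NC) and maximum-permissible (MPC) quality
  values, RQ_NC = 1000·C/NC, with four-level risk grading.
* **Metal pollution indices** — the heavy-metal pollution index
  HPI = ΣWᵢQᵢ / ΣWᵢ with Qᵢ = 100·Cᵢ/Sᵢ and Wᵢ = 1/Sᵢ; the metal index
  MI = Σ Cᵢ/UALᵢ; and the potential ecological risk index
  RI = Σ Tᵢ·Cᵢ/C_bg,ᵢ — each with its classification scale.
* **The USEPA health-risk chain** — chronic daily intake for oral
  (C·IR·EF·ED/(BW·AT)) and dermal (C·ET·EF·Kp·SA·CF·ED/(BW·AT)) routes,
  hazard quotients HQ = CDI/RfD (with RfD_dermal = RfD_oral·ABS), hazard
  index HI = ΣHQ, and carcinogenic risk CR = CDI·CSF, for adult and child
  receptors, with survey-level exceedance fractions.
* **A seeded Monte Carlo engine** propagating distributions over
  concentrations and exposure parameters through the same chain, with
  5th/95th percentiles and exceedance probabilities.
* **Source identification** — Ward (minimum-variance, Euclidean)
  hierarchical clustering in R- or Q-mode, correlation-matrix PCA with
  Kaiser retention, KMO sampling adequacy and Bartlett's sphericity test.
* **A synthetic survey generator** (correlated lognormal analytes via a
  Gaussian copula, hotspot samples, detection-limit censoring) so every
  stage is testable against planted ground truth.

The per-sample measurements of a published Gulf-of-Suez coastal survey ship
as plain-CSV fixtures (`inst/extdata/`), together with the NC/MPC quality
values used for risk quotients.

## Worked example

```r
library(coastrisk)
registry <- load_reference_registry()

pahs <- read_survey(system.file("extdata", "table2_pahs.csv",
                                package = "coastrisk"), "pahs")
pahs <- substitute_nondetects(pahs, "zero")
pah_site_report(pahs, registry)[, c("site_name", "total_pahs", "car_total",
                                    "rq_nc_total", "rq_grade")]
#>       site_name total_pahs car_total rq_nc_total rq_grade
#> 1          Suez     479.02     29.62     17611.0     high
#> 2    Ain Sukhna      19.66     16.42       723.0 moderate
#> 3  Zaafarana N.      26.72     21.60       982.4     high
#> 4  Zaafarana S.      15.08     10.44       554.4 moderate
#> 5    Ras Gharib      11.12      8.66       409.0 moderate
#> 6   Ras Shokier      20.45     18.09       751.7 moderate
#> 7 Gabal El Zeit      14.77     11.95       542.9 moderate
#> 8        Qusier      22.53     17.15       828.3     high
```

The most polluted site carries 479 µg/L of total PAHs (29.6 µg/L of them
carcinogenic) and a site-total risk quotient of 17 611 against the
negligible concentration — far into the `high` ecological-risk grade
(RQ_NC ≥ 800 with RQ_MPC ≥ 1).

```r
metals <- read_survey(system.file("extdata", "table1_metals.csv",
                                  package = "coastrisk"), "metals")
idx <- metal_index_report(metals, registry)
head(idx$per_sample, 3)
#>   sample_id     hpi  hpi_class      mi          mi_class
#> 1       S01   58.77     medium   1.408   partly affected
#> 2       S02 2143.03 unsuitable 101.166 severely affected
#> 3       S03   37.14        low   1.614   partly affected
```

Sample 2 is the Pb-dominated hotspot (0.999 mg/L against an upper allowable
limit of 0.01 mg/L): its Pb term alone contributes 99.9 of its metal index
of 101.2. Over the survey, 55.6% of samples are severely affected (MI > 6).

```r
risk <- survey_risk(metals, registry)
subset(risk$exceedance$hq, metal %in% c("Cd", "Cr", "Pb") & route == "oral")
#>    metal receptor route frac_hq_gt_1
#> 17    Cd    adult  oral        0.222
#> 18    Cr    adult  oral        0.222
#> 23    Pb    adult  oral        0.222
#> 25    Cd    child  oral        0.500
#> 26    Cr    child  oral        0.500
#> 31    Pb    child  oral        0.222
```

Cd, Cr and Pb are the non-carcinogenic drivers, and children exceed the
HQ = 1 threshold in more samples than adults. The Monte Carlo engine puts
uncertainty bands on the same quantities:

```r
tmpl <- default_mc_template(metals, registry)
mc_survey_risk(tmpl$concentration["Pb"], tmpl$exposure, registry,
               n = 10000, seed = 1)[, c("metal", "receptor", "route",
                                        "hq_mean", "cr_p5", "cr_p95")]
#>   metal receptor  route hq_mean    cr_p5   cr_p95
#> 1    Pb    adult   oral 2.31403 2.40e-07 1.05e-04
#> 2    Pb    adult dermal 0.00110 1.17e-10 4.88e-08
#> 3    Pb    child   oral 4.99635 4.84e-07 2.12e-04
#> 4    Pb    child dermal 0.00325 3.19e-10 1.38e-07
```

A shell-style entry point wrapping the same functions is installed at
`inst/scripts/coastrisk` (subcommands `pah`, `metals`, `health`, `mc`,
`stats`, `simulate`, `report`).

See `vignettes/coastrisk-methods.Rmd` for the models, the default parameter
tables and their provenance, the numerical conventions (half-open class
boundaries, quantile rule, seeding scheme), and known limitations —
including which published summary figures are reproducible from the shipped
data and which are not.

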