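# irpipe

Quantifying **immune resilience (IR)** — the capacity to maintain
immunocompetence and control inflammation under immunological stress — from
bulk transcriptomes and T-cell counts, and estimating its association with
survival.

`irpipe` is aimed at computational immunologists and epidemiologists working
with cohort expression data. It implements, as a tested reusable pipeline:

- **Signature scoring** — oriented gene-set composites on gene-wise
  z-scored expression: `score(s) = mean_g o_g · z_gs` with orientations
  `o_g ∈ {+1, −1}`, median-split **H/L strata** (H iff score > cohort
  median), and the four **SAS-1/MAS-1 IR profiles** `H-L, H-H, L-L, L-H`
  (`H-L` = optimal IR, `L-H` = extreme IR degradation), plus single-gene
  TCF7 strata.
- **Immune health grades (IHG I–IVc)** from absolute CD4⁺/CD8⁺ counts:
  the CD4:CD8 ratio crossed with absolute CD4 bands, with IIc/IVc flagged
  as extreme IR-degraders.
- **Pathogenic-triad burden** — a composite over six salutogenesis
  readouts: `burden = mean(neg readouts) − mean(pos readouts)` (weighted
  and 0–6 count variants available), with linear-model group contrasts.
- **Trajectory classification** of longitudinal profile sequences into
  IR-**preservers** / **reconstituters** / **degraders**, anchored on an
  optimal baseline.
- **Survival modelling** — Cox proportional hazards (Efron ties) plus the
  **hazard-equivalence age**: with log-hazard
  `β_age · age + β_group · I(degraded)`, the age at which an optimal-profile
  subject matches the hazard of a degraded-profile subject at a reference
  age is `ref_age + β_group/β_age`; the **survival gap** is `β_group/β_age`
  with a delta-method CI. Age-stratified HRs and Kaplan–Meier/log-rank
  utilities included.
- **FDR screens** — mass-univariate linear/logistic association screens
  with a hand-implemented Benjamini–Hochberg step-up, set-overlap
  utilities, octile dose–response, and 2×2 contingency summaries
  (odds ratio, Fisher exact, χ²).
- **A synthetic-cohort simulator** (`sim_config()`, `simulate_cohort()`,
  `gen_*()`) planting all of the above structures with known parameters, so
  every stage is verified by parameter recovery.

## Worked example

```r
library(irpipe)

cfg <- sim_config(n_subjects = 2000, seed = 42)   # stated-world defaults
coh <- simulate_cohort(cfg)
table(coh$profile)
#> H-L H-H L-L L-H
#> 685 315 315 685

## survival: degraded (L-H) vs optimal (H-L), sex- and age-adjusted
ph <- coh$phenotypes
d  <- data.frame(time = ph$time, event = ph$event, age = ph$age,
                 sex = ph$sex, degraded = as.integer(coh$profile == "L-H"))
d  <- d[coh$profile %in% c("H-L", "L-H"), ]
fit <- fit_ph(d, c("age", "sex", "degraded"))
hazard_ratio(fit, "degraded")
#> HR 8.61 [6.03, 12.29]
equivalence_age(fit, "degraded", "age", ref_age = 40)
#> equivalence age 54.4, gap 14.4 [11.7, 17.1]
```

The planted group effect is `exp(2.273) = 9.71`; at n = 2000 a single
cohort recovers it within its CI, and averaging over 100 replicate cohorts
(`simulate_hazard_recovery()`) returns ≈ 9.7 with an equivalence age of
≈ 55.5 years at reference age 40 — i.e. a ≈ 15.5-year survival gap between
extreme IR degradation and optimal IR.

```r
g <- assign_ihg(ph$cd4, ph$cd8)
round(prop.table(table(g)), 3)
#>     I   IIa   IIb   IIc   III   IVa   IVb   IVc
#> 0.595 0.139 0.072 0.002 0.084 0.065 0.040 0.002
sum(is_extreme_degrader(g))
#> 10
```

## Command line

```sh
exec/irpipe simulate --n 500 --seed 1 --out-dir sim/
exec/irpipe ihg --input sim/phenotypes.csv --out-dir out/
exec/irpipe run --expression sim/expression.tsv --gmt sim/signatures.gmt \
                --phenotypes sim/phenotypes.csv --out-dir out/
```

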