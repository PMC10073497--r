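# fatiguekit

Stress-life fatigue assessment of load-bearing implant components — built
around the qualification problem of 3D-printed (SLM) Ti6Al4V osteosynthesis
plates, where a design must survive about 10^5 loading cycles and physical
fatigue testing of every patient-specific variant is impractical.

The package is for biomedical-device and fatigue engineers who want to

* synthesize a **Basquin stress-life (S-N) curve** from nothing more than a
  material standard's minimum static properties, with a fabrication
  knock-down factor *C_f* for as-built additive-manufactured surfaces;
* apply **Goodman / Gerber mean-stress corrections** to tension-dominated
  stress cycles and predict **capped fatigue lives** per load case;
* check validity with the **Coffin-Manson transition life** and correct
  over-yield elastic peak stresses with a **Neuber bilinear-hardening**
  surrogate;
* run or replay the **modified staircase test protocol** (an ISO 12107
  variant that sizes the force step by the observed life), fit **Basquin
  force-life regressions with runout-censoring policies**, and read off the
  **fatigue limit**;
* validate the whole chain on **virtual specimen populations** with known
  ground truth (normal static strength, lognormal life scatter, runout
  censoring).

## The model in brief

The S-N curve is the log-log line through two anchors derived from the
ultimate strength σ_u:

    S1 = 0.8 σu              at N = 10^3 cycles
    S2 = 0.307 Cf σu         at Nc1 = 10^6 cycles (endurance)
    b  = (log10 S2 − log10 S1) / (log10 Nc1 − 3)
    σa(N) = σf′ N^b,  σf′ = S1 · (10^3)^(−b)

A cycle (σ_a, σ_m) maps to an equivalent fully reversed amplitude σ_w via
Goodman, `σw = σa / (1 − σm/σu)`, or Gerber, `σw = σa / (1 − (σm/σu)²)`;
inverting the S-N line at σ_w gives the life, truncated at the campaign cap
N_max (default 10^5). The staircase protocol starts at 50% of the mean
static failure force, multiplies the force by 0.5 / 0.7 / 0.8 after a
failure (life < 10%, 10–50%, ≥ 50% of N_max), bisects toward the lowest
failing force after a runout, and stops after three runouts. See the
methods vignette (`vignettes/fatigue-life-methods.Rmd`) for the design
decisions behind each piece.

## Worked example

The package ships the plate study's published tables as plain-text
fixtures. Replaying the experimental campaign through the protocol engine
reconstructs the force sequence from the protocol rules alone:

```r
library(fatiguekit)

statics <- read.csv(fatiguekit_example("static_forces.csv"))$force_N
unlist(static_strength_summary(statics))
#>      mean        sd         n
#> 254.52000  29.78264   5.00000

campaign <- read_observations(fatiguekit_example("plate_campaign.csv"))
rec <- run_campaign(replay_oracle(campaign$life), statics, campaign_config())
rec
#> Staircase campaign (completed, 6 specimens)
#>  specimen force_exact force_reported outcome   life
#>       E01   127.26000          127.3 failure   1230
#>       E02    63.63000           63.6 failure  23262
#>       E03    44.54100           44.5 failure  78567
#>       E04    35.63280           35.6  runout 100000
#>       E05    40.08690           40.1  runout 100000
#>       E06    42.31395           42.3  runout 100000

sufficiency_test(rec)     # slope p-value of the campaign's force-life fit
#> [1] 0.0001737397          # < 0.05: six specimens were sufficient

fit <- fit_basquin(rec, "as_failure")
fatigue_limit(fit, 1e5)   # force sustained for 100,000 cycles
#> [1] 40.29181
```

The mean static strength is 254.5 N (population SD 29.8 N), so the campaign
starts at 127.3 N; the fitted fatigue limit says the plate sustains about
40.3 N for 100,000 cycles. Life prediction from the material minima and the
linear-elastic peak-stress table:

```r
material <- read_material(fatiguekit_example("material_ti64_eli.json"))
curve <- build_sn_curve(material, Cf = 1)
cases <- read_load_cases(fatiguekit_example("load_cases_elastic.csv"))
predict_life_table(cases, curve, "gerber")[, c("label", "sigma_w_MPa",
                                               "status", "reported_life")]
#>   label sigma_w_MPa     status reported_life
#> 1   E01          NA infeasible            NA
#> 2   E02    660.3604     finite      1344.107
#> 3   E03    296.6808     finite    100000.000
#> 4   E04    188.5468  endurance    100000.000
#> 5   E05    240.2713  endurance    100000.000
#> 6   E06    188.3269  endurance    100000.000
```

Every case from 44.5 N (E03) downward reports the 100,000-cycle cap: the
Gerber-corrected amplitudes either sit below the endurance stress
(264.02 MPa for this curve) or invert to lives beyond the cap. The highest
load case is flagged infeasible — its fictitious linear-elastic mean stress
exceeds the ultimate strength — which is what the elasto-plastic stress
table (`load_cases_elastoplastic.csv`) and `plastic_correction()` are for.
`run_pipeline(fatiguekit_example("plate_config.yaml"))` runs the whole
analysis (both corrections, fits, limits, provenance) in one call.

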