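---
title: "Stress-life fatigue assessment of implant plates: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-life fatigue assessment of implant plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguekit)
```

## The problem

Patient-specific osteosynthesis plates printed from Ti6Al4V by selective
laser melting must survive on the order of 10^5 masticatory loading cycles
while new bone takes over the load. Physical fatigue qualification of every
design is slow and expensive, so the workflow this package implements
couples three ingredients:

1. a **stress-life (S-N) model** synthesized from nothing more than the
   minimum static properties a material standard guarantees,
2. **mean-stress corrections** that map the plate's real, tension-dominated
   stress cycle onto the zero-mean S-N curve, and
3. a **modified staircase test protocol** (an ISO 12107 variant) that
   brackets the experimental fatigue limit with roughly half the specimens
   of the classical fixed-step staircase.

A virtual-specimen simulator closes the loop: it generates populations with
known ground truth so that the whole pipeline — protocol, regression,
limit estimation — can be validated end to end without a test rig.

## The stress-life model

`build_sn_curve()` constructs the Basquin law
\(\sigma_a(N) = \sigma_f' N^b\) from two anchors:

* \(S_1 = 0.8\,\sigma_u\) at \(N = 10^3\) cycles — a stress close to yield;
  below 1000 cycles plasticity dominates and the stress-life approach is
  invalid, so the curve is only evaluated above this bound unless
  extrapolation is explicitly requested;
* \(S_2 = 0.307\,C_f\,\sigma_u\) at the endurance life \(N_{c1} = 10^6\)
  cycles — survival past \(N_{c1}\) is treated as infinite life for
  titanium alloys.

The exponent is the log-log slope between the anchors,
\(b = (\log_{10} S_2 - \log_{10} S_1)/(\log_{10} N_{c1} - 3)\), and the
coefficient is defined as \(\sigma_f' = S_1 \cdot (10^3)^{-b}\) **so that the
curve passes exactly through both anchors**. A commonly printed alternative,
\(\sigma_f' = S_1 N_{c1}^{\,b}\), is inconsistent with the \((10^3, S_1)\)
anchor (for \(\sigma_u = 860\) MPa it would put the 1000-cycle stress near
101 MPa rather than 688 MPa); this package deliberately uses the two-anchor
form, which makes `stress_at_life()` and `life_at_stress()` exact inverses
and keeps every downstream life prediction on the same line. Working in
cycles \(N\) rather than reversals \(2N\) is likewise a convention choice
that the two-anchor construction makes immaterial: the line is pinned by
the anchors, not by the unit of its abscissa.

The **fabrication factor** \(C_f \in (0, 1]\) is a single scalar knock-down
on the endurance anchor that lumps together surface roughness, porosity and
process defects of additive manufacturing. No microstructural modelling is
attempted. \(C_f = 1\) (standard material, no knock-down) reproduces the
published plate analysis.

### Mean-stress corrections

The plate's cycle runs between a preconditioning stress and the peak stress
at the target force, so its mean stress is strongly tensile. Two classical
corrections map the cycle \((\sigma_a, \sigma_m)\) to the equivalent fully
reversed amplitude \(\sigma_w\):

* Goodman (linear): \(\sigma_w = \sigma_a / (1 - \sigma_m/\sigma_u)\) —
  conservative, tends to under-estimate life;
* Gerber (quadratic): \(\sigma_w = \sigma_a / (1 - (\sigma_m/\sigma_u)^2)\) —
  for \(0 < \sigma_m < \sigma_u\) always below Goodman, hence longer
  predicted lives.

Both degenerate when the mean stress reaches \(\sigma_u\): there is no
finite equivalent amplitude. `predict_life()` propagates this as an
`"infeasible"` flag rather than an error, because a highly loaded case in a
linear-elastic stress table can legitimately hit it (the fictitious elastic
peak stress exceeds anything the material can carry; the elasto-plastic
correction below is the remedy). Negative mean stress is admitted by the
squared Gerber term and flagged with a warning for Goodman — the package's
intended regime is tension-dominated.

### Flags and truncation

`life_at_stress()` returns one of three outcomes: a finite life on the line
(\(S_2 \le \sigma_w \le S_1\)), `"endurance"` below \(S_2\) (infinite
life), or `"low_cycle"` above \(S_1\) (outside the validity window;
extrapolation is available but off by default). `predict_life()` caps all
reported lives at the campaign target \(N_{max}\) (default \(10^5\)) —
survival past the cap is operationally indistinguishable from infinite
life, so endurance outcomes also report the cap. On the packaged plate
fixtures this reproduces the published truncation pattern: with Gerber, all
cases from 44.5 N downward report exactly 100,000 cycles.

## The strain-life transition

Whether the stress-life treatment applies at all is decided by the
transition life: the reversal count \(2N_t\) at which the elastic strain
amplitude (strain-form Basquin, \((\sigma_f'/E)(2N)^b\)) equals the plastic
one (Coffin-Manson, \(\varepsilon_f'(2N)^c\)):

\[ 2N_t = \left( \frac{\varepsilon_f' E}{\sigma_f'} \right)^{1/(b-c)} . \]

`build_strain_life()` uses the standard titanium estimates
\(\sigma_f' = 1.67\,\sigma_u\), \(b = -0.095\), \(\varepsilon_f' = 0.35\),
\(c = -0.69\). For \(\sigma_u = 860\) MPa and \(E = 110\) GPa the formula
gives \(2N_t \approx 251.5\) reversals — the same order as values reported
for SLM titanium (roughly 160–180). Note that published transition-life
figures for these exact inputs are not always reproducible from the formula
itself; this implementation follows the formula, and its tests verify the
closed form to \(10^{-10}\) relative, not any printed round number. Either
way the conclusion is unchanged: at \(10^5\) cycles the material is deep in
the elastic-dominated regime and the stress-life approach is valid.

## Plasticity surrogate

When a linear-elastic stress table reports peaks above yield, the material
actually yields and redistributes stress. The published plate study reran a
full elasto-plastic finite-element model; this package instead provides a
local, geometry-free surrogate, `plastic_correction()`: **Neuber's rule on a
bilinear hardening law**. The corrected stress \(\sigma\) solves

\[ \sigma\,\varepsilon(\sigma) = \sigma_e^2 / E , \qquad
   \varepsilon(\sigma) = \sigma_y/E + (\sigma - \sigma_y)/H
   \ \ (\sigma > \sigma_y), \]

by bisection to \(10^{-8}\) MPa; the default hardening modulus
\(H = (\sigma_u - \sigma_y)/(\text{elongation} - \sigma_y/E)\) makes the
bilinear law reach the ultimate strength at the elongation limit. The
solution is strictly between yield and the elastic input and monotone in
the input. Being geometry-free, it will not match a structural model's
redistributed stresses quantitatively — when elasto-plastic peak stresses
are available (as in the packaged `load_cases_elastoplastic.csv`), they are
consumed directly as inputs instead. The correction is defined on
fictitious linear-elastic stresses; its output lies on the material law and
is tagged as such, so re-applying the correction is a no-op.

Two yield strengths circulate for this alloy (795 MPa standard minimum,
765 MPa measured): the material record carries one value (795 by default)
and `plasticity_model()` takes yield as an explicit argument so either can
be used without touching the material record.

## The modified staircase protocol

The classical ISO 12107 staircase moves the force by a fixed step after
every specimen. The modified protocol implemented by `run_campaign()` uses
the *observed life* to size the step:

* start at 50% of the mean static failure force (`initial_force()`);
* after a **failure** at life \(N_i\), multiply the current force by 0.5,
  0.7, or 0.8 according to whether \(N_i/N_{max}\) fell below 10%, between
  10% and 50%, or at/above 50%;
* after a **runout**, bisect (arithmetic mean) between the current force
  and the lowest failing force observed so far;
* stop after three runouts.

The banded rule is a **reconstruction**: the source protocol is published
only as a flowchart, and this rule is the one that reproduces its printed
six-specimen force sequence (127.3, 63.6, 44.5, 35.6, 40.1, 42.3 N)
exactly. Alternative band edges could reproduce the same sequence; every
piece (thresholds, multipliers, stop rule, no-failure increase factor) is
therefore configurable in `campaign_config()`. Two numerical details are
load-bearing:

* forces are carried at **full precision** internally and only rounded for
  reporting — rounding before stepping breaks the published sequence;
* report rounding is **half away from zero** at 0.1 N (base R's `round()`
  is half-to-even and would report 127.25 as 127.2).

A runout before any failure has no failing force to bisect toward; the
protocol then *increases* the force by a configurable factor (default
1.25). Waveform metadata (13 Hz sinusoid, preconditioning at 10% of the
initial force) never enters any computation.

`sufficiency_test()` implements the campaign's sample-size rule: the
campaign is sufficient when the log-log Basquin regression on its points
(runouts kept at the cap) has a slope p-value below 0.05. On the packaged
campaign the p-value is about 1.7e-4.

## Censored Basquin regression and the fatigue limit

`fit_basquin()` is ordinary least squares of \(\log_{10}(\text{force})\) on
\(\log_{10}(\text{life})\) — deliberately not a maximum-likelihood censored
regression, matching the published treatment. Runouts are handled by
policy:

* `"as_failure"` (default) keeps them at the cap. This is the convention
  under which the packaged experimental campaign yields a fatigue limit of
  about 40.3 N at \(10^5\) cycles, within 5% of the published 40.92 N (the
  exact regression variant behind the published figure is unspecified, so
  only tolerance agreement is claimed).
* `"exclude"` drops them, which is unbiased when the failures alone trace
  the force-life line.

`fatigue_limit()` is simply the fitted line evaluated at \(N_{max}\).

The two policies trade bias differently, which is why
`recovery_experiment()` defaults to `"exclude"`: runouts recorded at the
cap sit *below* the true line by construction, and keeping them drags the
fitted limit down (about 7% low in the zero-scatter simulation, where
excluding them recovers the truth exactly — noiseless failures lie on the
line). For reproducing the published experimental limit, which mixes three
failures and three runouts in a six-point fit, `"as_failure"` is the policy
that lands within tolerance and is kept as `fit_basquin()`'s default.

## The virtual-specimen population

`virtual_population()` emulates exactly the statistical structure the
analysis assumes, and nothing more:

* static strength \(\sim \mathcal N(254.5, 29.8^2)\) N, truncated at zero
  (the published static series);
* a true Basquin force-life law \(F = A N^{\beta}\) with defaults
  \(A = 727.7\) N, \(\beta = -0.25\) — back-derived once so the true curve
  passes through the published experimental fatigue limit (about 40.9 N at
  \(10^5\) cycles) with the exponent of the failure-only fit;
* lognormal life scatter (normal in log-life; the standard fatigue scatter
  model — no noise model is stated for the source data), default standard
  deviation 0.2;
* runout censoring at \(N_{max} = 10^5\): no emitted life ever exceeds the
  cap, every runout sits exactly on it.

Seeding is hierarchical: a master seed spawns per-replicate and
per-specimen seeds, so inserting a specimen does not reshuffle later draws
and every level (population, specimen, campaign, experiment) is exactly
reproducible.

What the simulator does **not** emulate: stress fields and geometry,
manufacturing defects, frequency or waveform effects, or any dependence of
scatter on force level. Passing recovery tests therefore demonstrate that
the *protocol and regression* are sound under the assumed statistical
structure — not that real plates obey that structure.

### Recovery results the tests compute

With zero scatter, the full pipeline (generate → staircase → fit → limit,
excluding runouts) recovers the true limit to well within one 0.1 N
reporting step. With log-life scatter 0.2 and 200 seeded replicate
campaigns (about 6–9 specimens each), the median estimated limit falls
within 5% of the truth; with scatter 0.3, at least 90 of 100 campaigns
complete within a 12-specimen budget. These simulation sizes run in a few
seconds and are the ones the test suite executes.

## Numerical choices and degenerate inputs

* Stress is MPa and force is N everywhere; moduli entered in GPa are
  converted at the I/O boundary (`read_material()`), and units are encoded
  in CSV column names to prevent drift.
* Anchor exactness (\(10^{-12}\) relative) and round-trip inversion
  (\(10^{-9}\)) are tested properties, not accidents of the construction.
* The Neuber bisection tolerance is \(10^{-8}\) MPa.
* Ties in the staircase life bands: band edges belong to the upper band
  (a life of exactly 10% of the cap uses the 0.7 multiplier).
* A specimen life landing within \(10^{-12}\) relative of the cap is
  censored as a runout (knife-edge power-law round trips).
* Degenerate fits (no variance in life), too few failures, runouts with
  nothing to bisect toward, and invalid configuration blocks all fail fast
  with named errors — except mean-stress infeasibility, which is a flagged
  result because it is a legitimate analysis outcome.

## Known limitations

* The force-to-stress map (`stress_transfer_model()`) is piecewise linear
  in the supplied knots; it stands in for a structural model and inherits
  none of its nonlinearity (contact, large deflection). Published stress
  tables can be non-monotone in force (the packaged fixture contains
  525.9 MPa at 42.3 N but 526.2 MPa at 35.6 N); such values are consumed
  verbatim, not "fixed".
* Published finite (non-truncated) life predictions for this plate are
  mutually inconsistent under any monotone life model, so this package's
  finite lives agree with them only in ordering and order of magnitude;
  the truncated entries, the force sequence, and the summary statistics
  reproduce exactly.
* Single constant-amplitude cycle per case: no rainflow counting, no
  multiaxiality, no probabilistic (P-S-N) percentile curves.
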