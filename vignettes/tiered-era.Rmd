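---
title: "Methods: tiered environmental risk assessment with pharmera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered environmental risk assessment with pharmera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmera)
library(dplyr)
```

pharmera implements the tiered environmental risk assessment (ERA) workflow
used for active pharmaceutical ingredients in surface waters: predicted
environmental concentrations (PECs) from sales data, effect thresholds
(PNECs) from chronic ecotoxicity and from bacterial MIC distributions, risk
quotients, censored measured-concentration (MEC) statistics,
secondary-poisoning chains, a PBT screen, and a simplified river-network
simulator for distributional exposure. The bundled worked example is
mycophenolic acid (MPA) and its prodrug mycophenolate mofetil (MPM), an
immunosuppressant whose published assessment exercises every tier. This
vignette explains the models, their assumptions, the defaults and the
numerical conventions; the package tests and the acceptance script compute
every number referred to here.

## Exposure: from sales to surface-water PECs

The screening exposure model is a down-the-drain mass balance. Annual sold
masses of active substance and prodrug are converted to an active-moiety
per-capita daily use (the prodrug stoichiometrically, by the ratio of
molecular weights, assuming complete cleavage — the standard assumption for
an ester prodrug fully hydrolysed in vivo; year basis fixed at 365 d):

```{r}
use <- tibble(country = "EU", year = 2017L, mpa_kg = 0, mpm_kg = 1000,
              population = 1e7)
per_capita_daily_use(use, mw_active = 320.34, mw_prodrug = 433.5)
```

The STP influent PEC divides use (µg/person/d) by per-capita wastewater
volume `W` (L/person/d; regulatory screening default 200). The surface-water
PEC applies treatment and dilution:

$$\mathrm{PEC_{sw}} = \mathrm{PEC_{stp}} \cdot
  \frac{f_t (1 - R) + (1 - f_t)}{D}$$

with treated fraction `f_t` (default 1 for the initial tier; refined
assessments commonly assume 0.8, i.e. one fifth of wastewater reaches the
river untreated), STP removal `R`, and dilution factor `D` (default 10).
A useful consequence is that PECs under two removal scenarios differ only by
the ratio of "passage" factors $f_t(1-R)+1-f_t$, independent of dilution —
the identity the tests assert for the published removal-scenario triplets.

Cross-country summaries weight per-country PECs by population. The weighted
median is the *lower* weighted median (smallest value whose cumulative weight
reaches 50%); the convention matters for small country sets and is fixed
here because published summaries rarely state theirs. Country-specific water
use and dilution factors are scenario inputs (per-row columns in
`derive_pec()`); the package does not ship a country dataset, and the
synthetic generator's values are explicitly non-published stand-ins.

## Fate: first-order kinetics and an approximate STP-removal estimator

Biodegradation and photolysis are treated as first-order. `rate_constant()`
carries explicit time units, `convert_rate()` is exact (factors of 60 and
24), and `dt50_from_rate()` is $\ln 2 / k$. `fit_first_order()` extracts a
rate from a cumulative mineralization curve by least squares on

$$C(t) = \text{plateau} \cdot (1 - e^{-kt}),$$

with the plateau free because activated-sludge simulation tests typically
mineralize only part of the applied radiocarbon (the MPA test plateaus at
82.2%). Fitting uses Levenberg–Marquardt (`minpack.lm::nlsLM`) with the
plateau initialised at the curve maximum and `k` from the earliest non-zero
point; both parameters are bounded below by zero. An all-zero curve or fewer
than four points is a refused fit, not a silent zero. The functional form is
an assumption: sources rarely state how a rate was extracted from a CO₂
curve, and first-order-to-plateau is the conventional reading.

`estimate_stp_removal()` is a deliberately simple one-tank
continuously-stirred estimator, `k·τ/(1+k·τ)` plus an optional sorbed
fraction. It is *not* a multi-compartment STP model; removal fractions from
such models should be supplied as scenario inputs where available. The
default hydraulic residence time of 7.7 h is a calibration: with it, the
estimator reproduces the three published multi-compartment removal
predictions for MPA (12%, 43.6%, 73.1% at k = 0.0174 h⁻¹, 0.0017 min⁻¹ and
0.006 min⁻¹) within two percentage points, which is the accuracy claimed for
it in the tests. Sorption is negligible for MPA (highest Koc 37 L/kg), so
`sorbed_fraction` defaults to 0.

## Effects: PNEC variants

All assessment-factor PNECs are "lowest relevant endpoint ÷ AF" with AF = 10
by default (the convention when chronic endpoints from three trophic levels
exist). `pnec_aquatic()` selects the minimum NOEC or EC10 among fish,
daphnids, green algae and cyanobacteria; for MPA both are fish-driven
(1.32 → 0.132 and 5.8 → 0.58 µg/L). `pnec_stp()` divides the sludge
respiration-inhibition EC10 (69 mg/L → 6900 µg/L).

Two provisional antibiotic-resistance PNECs are implemented. The fixed-factor
method divides the lowest bacterial MIC by 100 (31.25 mg/L → 312.5 µg/L).
The distribution-based method keeps only species with ≥ 10 MIC observations
(to avoid conclusions from sparse data), takes one value — the lowest MIC —
per eligible species, and applies a size-dependent uncertainty factor and a
general factor of 10:

$$\mathrm{PNEC_{ABR,raw}} = \mathrm{MIC_{lowest}} \cdot
  \frac{n_\text{species}}{41} \cdot \frac{1}{10},$$

where 41 is the species count of the reference MIC compilation the method
was calibrated on. The raw value is rounded *down* to the nearest
concentration of the standard two-fold antimicrobial dilution series
(…, 16, 32, 64, 128 µg/L, i.e. integer powers of two extended downward by
the 0.5/0.25/0.125 decade pattern), because the source method quotes PNECs at
MIC-test concentrations; for MPA this gives 76.2 → 64 µg/L. The formula as
circulated is ambiguous about operator precedence; the reading implemented
here is the one that reproduces the published 76 µg/L. The final resistance
PNEC is the lower of the two methods. Only the per-species minima and counts
of the bundled MIC table are published values; the within-range spread is a
synthetic stand-in and never enters a derivation.

The PBT screen is deliberately asymmetric. Persistence is an evidence *flag*
supplied by the caller, because regulatory persistence judgments weigh
simulation-test outcomes rather than a single numeric trigger.
Bioaccumulation uses the screening triggers max BCF ≥ 2000 or max
log D$_{OW}$ ≥ 4.5. Toxicity triggers on any chronic NOEC < 10 µg/L or a CMR
classification. Missing inputs give an explicit "undetermined", never a
default verdict.

## Censored MEC statistics

Monitoring datasets mix detects with "< LOQ" nondetects. Following common
practice the package uses substitution, not maximum-likelihood or
Kaplan–Meier estimation: `censored_mean()` replaces each nondetect by half
its LOQ (bounds via full-LOQ and zero substitution are available).
`percent_rank_mecs()` orders nondetects first (among themselves by LOQ),
detects ascending, and evaluates percentile *p* by the nearest-rank (ceiling)
convention: the value at rank ⌈p·n/100⌉, reported as censored ("< LOQ") when
that rank is a nondetect. With ten values of which five are nondetects, the
median (rank 5) is therefore "< LOQ" and the 51st percentile is the smallest
detect — the convention is fixed and documented because published compound
quantiles are typically quoted approximately ("~"), indicating no
interpolation. With zero nondetects every quantile equals the ordinary
empirical nearest-rank quantile. `fraction_above()` refuses to answer when a
nondetect's LOQ exceeds the threshold (the comparison is genuinely
indeterminate) rather than guessing a side. Trace detects reported below
their own LOQ are kept as detects. Pooling across datasets of unequal size is
unweighted.

## Risk characterisation and secondary poisoning

`risk_quotient()` is exposure/PNEC with the verdict boundary exactly at 1
(a quotient of 1 is *not* potential risk). `exceedance_summary()` gives the
fraction of a PEC or MEC distribution above a threshold.

The secondary-poisoning chain follows the standard consumer models. An
acceptable daily exposure (ADE) is a mammalian point of departure
(mg/kg bw/d) times a 60-kg default body weight divided by an ordered chain
of adjustment factors, each with a recorded rationale. Rounding policies are
explicit named strategies, because published derivations apply different
implicit conventions: two-decimal rounding and downward (protective)
truncation to one significant figure are both provided, and the unrounded
value is always retained. The selected ADE is the minimum of the candidates
(the lower is protective of the rest). For the MPA chains: systemic
NOAEL 2 mg/kg/d with factors {6.2, 10, 1, 5, 3} → 0.129 → 0.1 mg MPM/d;
teratology NOEL 2 mg/kg/d with factors {6.2, 10, 1, 10, 1} → 0.19355 →
0.19 mg MPM/d; selected 0.1 mg MPM/d → 0.0739 mg MPA/d, quoted to the
nearest 5 µg as 75 µg/d. Wildlife limits scale linearly with body weight
(`mtdi_scale()`: 75 µg/d for 60 kg → 12.5 µg/d for a 10-kg otter).

Intake combines fish and water: the otter default eats 1 kg fish and drinks
0.79 L/d; the human default consumes 115 g fish and 2 L/d with no removal
assumed in drinking-water production (a worst case; treatment data show
removal to below detection). Fish tissue concentration is water
concentration × BCF, with the BCF chosen as the geometric mean of modelled
values over pH 5–9 — the environmentally relevant window, endpoints
inclusive. The modelled BCF at pH 10 exists in the MPA profile but lies
outside the window; including it would change the geometric mean (4.59
instead of 6.22), and the published value corresponds to the pH ≤ 9
selection implemented here. The worked human scenario mixes a measured water
concentration (0.656 µg/L) with a PEC-derived fish burden (0.671 × 6.22);
`intake_scenario()` reproduces that mixture but accepts a single
concentration for a fully consistent mode.

## Catchment simulation

`propagate()` is a topological-order mass balance over a tree-shaped river
network: each segment's load is the attenuated sum of upstream loads
(optional first-order decay over travel time, default 0 because in-stream
fate is usually argued qualitatively) plus the local STP load
`population × per-capita use × (1 − removal)`; PEC = load/flow. Effluent
volume is excluded from the denominator, consistent with the
dilution-factor convention of the screening tier (a documented divergence
from georeferenced models, which add effluent flow). Flow scenarios
(mean/low/high) are static per-segment fields, not hydrographs. With zero
decay the outlet load equals the total discharged load exactly — the
conservation law the acceptance tests assert. Segments with no STP upstream
carry exactly zero concentration, and `pec_percentiles()` includes those
zeros, flagging values below a reporting floor (default 0.0005 µg/L, half a
typical LOQ) instead of printing them. This simulator emulates the *shape*
of georeferenced PEC distributions for testing distributional risk
summaries; it makes no claim to reproduce any real catchment, which requires
GIS hydrology, real STP registers and human-metabolism modulation.

## Synthetic data and what passing tests show

Each generator (`gen_use_table()`, `gen_mec_dataset()`,
`gen_mineralization_curve()`, `gen_network()`) is seeded once per call,
restores the caller's RNG state, and is bit-reproducible per seed. Defaults
mirror the study conditions of the worked assessment: 24 countries × 14
years of sales; 110 MECs with LOQ 0.001 µg/L and a detection fraction of
0.55 (61/110 detects); mineralization sampled at days 1–28 with k =
0.0174 h⁻¹ and plateau 82.2%; networks of ~50 segments. The MEC generator
places the lognormal location so the expected detection fraction is exact;
per-capita use draws centre on ~300 µg/person/d (the order implied by
European sales of this drug class), spread σ(log) = 0.6 — a typical
between-country spread for prescription pharmaceuticals.

Synthetic data share none of the messiness of real inputs: no mixed LOQs
across laboratories, no spatial correlation, no seasonality, no reporting
bias. Passing tests therefore demonstrate that the *arithmetic and
conventions* are correct and stable, not that any real monitoring campaign
is well summarised. Problem sizes in the tests (networks of 30–200 segments,
MEC pools of 110, curve fits on 6 points) were chosen as the smallest sizes
at which each property is non-trivial; the full suite runs in a few seconds.

## Numerical choices and degenerate inputs

* Quantiles everywhere use nearest-rank (ceiling); no interpolation.
* The MIC round-down series is exact in log₂ space (`2^floor(log2(x))`).
* Duplicate pH keys in profiles are rejected (silent last-wins would be data
  loss); BCF window endpoints are inclusive.
* Empty endpoint/MIC/MEC/PEC sets raise typed no-data errors naming the
  filter; indeterminate censoring raises its own condition class.
* `fit_first_order()` failure carries diagnostics (start values) in the
  condition; zero rates give DT50 errors rather than `Inf`.
* ADE adjustment factors below 1 are rejected; unrounded values are invariant
  under factor reordering (multiplication is commutative, asserted anyway).
* The verdict boundary of every quotient is exact at 1.

## Limitations

The exposure tier is a steady-state, fully-mixed screening model; no
seasonality, no in-sewer transformation, no glucuronide back-conversion
modelling (for MPA, conjugates cleave in STPs, which the sales-based load
already covers conservatively). The STP estimator is a calibration, not a
process model. Censored statistics use substitution, which biases means for
low detection fractions. The catchment simulator is an emulation. The
published low-flow top-predator risk quotients for extreme scenarios are not
reproduced: they are mutually inconsistent with the mean-flow intake
arithmetic (they imply an effective intake two orders of magnitude above the
BCF-and-drinking-water model) and are excluded as reproduction targets.
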