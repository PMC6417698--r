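---
title: "Probabilistic ecological risk assessment of heavy metals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic ecological risk assessment of heavy metals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisk)
```

# The assessment problem

Coastal sediments act as both a sink and a secondary source for heavy
metals: what settles can be resuspended into the water column. A risk
assessment for a bay survey therefore runs on two tracks with different
logic and different units.

**Sediment track.** For each metal, the Hakanson potential ecological
risk factor is

$$E_r^i = T_r^i \cdot \frac{C^i}{C_r^i},$$

where $C^i$ is the measured sediment concentration (mg/kg dry weight),
$C_r^i$ a background reference concentration, and $T_r^i$ a
dimensionless toxic response factor (As 10, Cd 30, Cr 2, Cu 5, Hg 40,
Pb 5, Zn 1). The composite index is $RI = \sum_i E_r^i$. Both are graded
on half-open bands with inclusive lower bounds: $E_r^i$ at 40/80/160/320
(low, moderate, considerable, high, very high) and $RI$ at 150/300/600
(low, moderate, considerable, high).

A single-point $E_r^i$ from a mean concentration hides the uncertainty
in the station data. The Monte Carlo refinement ([`mc_eri()`],
[`mc_ri()`]) fits a parametric distribution to the station
concentrations, pushes a large number of draws (default 100,000)
through the index arithmetic, and reports the *probability of each
grade* rather than one grade. For $RI$, metals are sampled
independently — the survey data carry no usable dependence structure,
and independence is the simplest faithful choice; a rank-correlation
hook is deliberately out of scope.

**Aquatic track.** Effects are summarized by a species sensitivity
distribution (SSD): a cdf fitted to one chronic tolerance per species
(μg/L). Its 5th percentile, HC5, is the concentration hazardous to 5%
of species; PNEC = HC5 / SF with a safety factor SF = 5. Screening-level
risk is the hazard quotient HQ = EEC/PNEC, where the EEC is a summary of
the seawater concentrations (geometric mean by default); HQ ≤ 1 is
acceptable, with the boundary counted as acceptable. The refinement is
the joint probability curve: for each proportion $x$ of species
affected,

$$\mathrm{EXP}(x) = 1 - F_{\text{exposure}}\!\big(Q_{\text{SSD}}(x)\big),$$

and the overall risk probability is $\mathrm{ORP} = \int_0^1
\mathrm{EXP}(x)\,dx$, which equals $P(\text{exposure} >
\text{tolerance})$ for independent draws — the expected potentially
affected fraction of species. ORP ≤ 0.05 (inclusive) is deemed
acceptable.

# Distribution families and fitting

Four families are supported on the positive reals, with fixed,
documented parameterizations (the literature uses several conventions;
self-consistency matters more than any one of them):

* log-normal (`meanlog`, `sdlog`);
* log-logistic, $F(x) = 1/(1 + (x/\alpha)^{-\beta})$ — the median is
  $\alpha$;
* Weibull (`scale`, `shape`);
* Burr III, $F(x) = (1 + (x/b)^{-c})^{-k}$, which reduces to the
  log-logistic at $k = 1$.

Fitting is maximum likelihood on raw concentrations (`fit_mle()`): the
log-normal in closed form, the others by BFGS over log-parameters with
moment/quantile starting values and a Nelder–Mead retry. Optimizer
failure is an error, never a silent default. Burr III fits whose $\hat k$
runs outside $[10^{-2}, 10^{2}]$ are flagged as boundary ("limit
distribution") cases and excluded from model selection — with three
parameters on small samples the family readily degenerates, which is
exactly why it is distrusted for environmental monitoring data.

Model selection (`select_model()`) uses two criteria, mirroring how the
two tracks weigh evidence:

* **Exposure data**: largest Kolmogorov–Smirnov p-value. The p-value is
  the naive asymptotic one by default. With parameters estimated from
  the same data this is anti-conservative; a seeded parametric
  bootstrap (`p_method = "bootstrap"`) is available when calibrated
  p-values matter. The naive default reproduces the conventional
  workflow this package emulates.
* **SSDs**: largest Anderson–Darling p-value with AIC as tie-breaker.
  The AD statistic weights the tails, which is appropriate when the 5th
  percentile is the quantity of interest. No closed-form null covers
  all four families with estimated parameters, so the p-value is a
  seeded parametric bootstrap that refits the family on every resample
  (`ad_test()`, default B = 999; `select_model()` and `fit_ssd()`
  default to B = 199 because selection bootstraps every candidate
  family, and ranking stabilizes well before calibration-grade B).

A nesting caveat documented here because it shapes what AIC races can
show: Burr III nests the log-logistic, so on log-logistic data the AIC
gap between the two is $\chi^2_1$ likelihood-ratio noise against the
2-unit penalty — Burr III "wins" about 16% of replicates no matter how
good the implementation is. Identification claims are therefore stated
against the non-nested competitors (log-normal, Weibull).

# Reference values

Background concentrations $C_r^i$ default to the Grade I marine
sediment quality convention as applied in the bay assessment this
package reproduces: As 20, Cd 0.50, Cr 80, Cu 35, Pb 60, Zn 150, and
Hg 0.05 mg/kg. These were recovered by dividing each published average
risk factor into $T_r^i$ times the published mean concentration. The Hg
entry deserves a flag: the nominal Grade I value for Hg is 0.20 mg/kg,
which does *not* reproduce the published factors (0.05 does). The
default follows the published numbers; `default_reference(cri_overrides
= c(Hg = 0.20))` switches to the nominal standard. No claim is made
about which value the original assessment intended.

The per-metal HC5 values shipped in `laizhou_hc5()` (As 9.33, Cd 2.57,
Cr 1.16, Cu 0.87, Hg 1.08, Pb 9.53, Zn 29.09 μg/L) are reference
fixtures: the chronic toxicity extraction behind them is not
redistributable, so they serve as inputs to downstream arithmetic and
as calibration anchors for the synthetic toxicity generator — never as
fitting targets.

# Toxicity screening and SSD construction

Chronic endpoints NOEC (primary), MATC and LOEC (supplements) are
admitted; acute endpoints are rejected at parse time. Exposure duration
must reach 1 day for algae and invertebrates and 4 days for
crustaceans, fish, mollusks and worms (`default_screening_rules()`).
After screening, all admitted endpoints enter the SSD equally.

Multiple records per species are collapsed by geometric mean (standard
SSD practice; a `"minimum"` most-sensitive policy is available), and
the policy is recorded in the output metadata. Data adequacy is
enforced as at least 8 species spanning at least 3 functional groups —
a functional-group approximation of the usual "eight families in three
classes" rule, since the data model carries functional groups rather
than Linnaean ranks.

# Numerical choices

* **JPC quadrature**: `EXP` is evaluated on a uniform open grid
  (default 10,001 interior points) and integrated by the trapezoid
  rule with the endpoints extended by the limits `EXP(0+) = 1` and
  `EXP(1-) = 0`. `EXP` is bounded and monotone, so the trapezoid rule
  converges fast; doubling the grid moves smooth cases by under 1e-4.
  The endpoint extension implies an O(1/grid) floor on the computed
  ORP, visible only in no-risk limiting cases (a point-mass exposure far
  below the SSD reports ~5e-5 rather than ~0 at the default grid).
  The quadrature is cross-validated against an independent Monte Carlo
  oracle, `orp_oracle()`, which estimates the same quantity as
  $E[F_{\text{SSD}}(C)]$ over exposure draws.
* **Sampling** is inverse-transform from a seeded uniform stream for
  every family, so identical seeds give identical draws and point-mass
  distributions collapse Monte Carlo stages onto their deterministic
  counterparts (used as a test oracle).
* **Grade tabulation** counts draws into half-open bands; the reported
  percentages partition 100 exactly up to floating-point summation.
* **Ties and sorting** in the Anderson–Darling statistic use R's stable
  sort; probability transforms are clamped to $[10^{-12},
  1-10^{-12}]$ before logs.
* **Replicates**: three grabs per station are averaged into one station
  value by default (`combine_replicates()`, `"pooled"` available); how
  the original survey combined them is not recorded, so this is an
  explicit switch rather than an assumption buried in code.
* **Standard deviations** of summary tables use the $n-1$ denominator,
  matching how field surveys report SDs; a single observation reports
  SD 0 by convention.

# The synthetic survey generator

The generator (`laizhou_scenario()`, `gen_concentrations()`,
`gen_toxicity()`) encodes the survey design the package emulates: 20
seawater stations (10 with sediment grabs) sampled in two seasons with
three replicates, per-stratum concentration mean/SD/range for all seven
metals in both matrices, and per-metal functional-group record counts
for the toxicity side (336 records in total, e.g. 123 for Cu).

Station values are drawn from a normal law with the stratum's mean and
SD, rejection-truncated to the stratum's observed range; replicate
jitter is truncated-normal at 2% relative SD (the original survey never
uses replicate spread; the 2% is an invented, documented constant).
Species tolerances are drawn from a true log-logistic SSD per metal
whose 5th percentile equals the reference HC5, with shape $\beta = 1.5$
— a typical breadth for multi-taxon chronic SSDs; durations are drawn
uniformly above the screening floors so the default dataset is fully
screening-compliant.

Two fidelity limits are worth stating plainly. First, truncation to the
observed range shrinks the realized SD below the printed SD whenever
the printed range is narrow relative to it (for the autumn Hg sediment
stratum: realized ≈ 0.0033 vs printed 0.005 mg/kg); no unimodal law on
the printed range can reach some of the printed SDs, so this is a
limitation of *any* range-respecting generator, not a tuning choice.
The practical consequence is that generated Monte Carlo tail
probabilities run somewhat below those computed from the real station
data — the autumn Hg moderate-grade probability averages about 0.02%
across seeds against the published 0.03%, the same order of magnitude.
Second, the generator draws stations independently: it emulates summary
statistics, not spatial structure, so passing tests say nothing about
spatially correlated fields.

# Problem sizes used by the test suite

The suite exercises parameter recovery at n = 500 (20 seeds per
family), HC5 recovery at 30 species over 60 seeds, AIC identification
at n = 200 over 100 replicates, ORP oracle agreement over 20 random
distribution pairs at 1e5 draws, and the full sediment Monte Carlo at
the survey's 100,000 draws. These sizes were chosen to make median
recovery statements stable while keeping a complete run in the order of
a minute; they are the package's own test design, and larger runs only
sharpen the same estimates.

# Known limitations

* No censored-data likelihoods: detection limits are carried as
  metadata only, matching a survey whose reported values are all above
  them.
* No acute-to-chronic extrapolation, taxonomic lookups, or
  between-metal mixture logic in the aquatic track (metals are assessed
  singly there, as in the emulated workflow).
* KS selection with the naive asymptotic p-value is anti-conservative
  by construction; the bootstrap option exists where that matters.
* Seasonal campaigns are always analyzed separately; pooling across
  seasons is intentionally unsupported.
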