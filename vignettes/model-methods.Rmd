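---
title: "Model and methods: Markov cohort CEA of HAIC-FOLFOX plus sorafenib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: Markov cohort CEA of HAIC-FOLFOX plus sorafenib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haiccea)
```

## The decision problem

Advanced hepatocellular carcinoma (HCC) with portal vein invasion has a
dismal prognosis under first-line oral sorafenib (median progression-free
survival around 2.6 months). Adding hepatic arterial infusion chemotherapy
(HAIC) with FOLFOX — oxaliplatin, leucovorin and fluorouracil delivered
through a hepatic-artery catheter over a two-day admission every 21-day
cycle — roughly doubled survival in the source phase-III trial, at
substantial extra cost per cycle. This package implements the Markov cohort
model that weighs that trade-off from the Chinese health-system perspective:
discounted lifetime costs (2019 USD, converted at 6.77 CNY/USD), life-years
(LY), quality-adjusted life-years (QALY), and the incremental
cost-effectiveness ratio (ICER) of the combination (SoraHAIC) versus
sorafenib alone, judged against willingness-to-pay thresholds of three times
regional GDP per capita (China \$30,492; Beijing \$72,000; Fujian \$47,285;
Gansu \$14,595 per QALY).

## Model structure

Four mutually exclusive health states, evaluated on 21-day cycles
(0-based index $k$, time in months with one month $= 30.4375$ days,
$u = 21/30.4375$ months per cycle):

* **PFS** — progression-free on induction treatment (the initial state for
  the whole cohort);
* **RFS** — recurrence-free after down-staging hepatectomy;
* **PD** — progressive disease;
* **DEAD** — absorbing.

No transition returns to an earlier state. At the start of cycle 4 (the end
of four induction cycles) the configured hepatectomy fraction of the
patients still in PFS (12.8% in the combination arm, 0.82% under sorafenib)
moves to RFS, once.

### Survival curves and transition probabilities

Each arm carries Weibull fits to its digitized PFS and overall-survival (OS)
Kaplan-Meier curves, parameterised as
$$S(t) = \exp(-\lambda\, t^{\gamma}), \qquad t \text{ in months.}$$
Under this convention the bundled PFS parameters imply median PFS of about
7.5 (SoraHAIC) and 2.9 (sorafenib) months, matching the trial medians of
7.03 and 2.6 months; no other time unit comes close, which fixes the
convention. Per-cycle exit probabilities are the conditional
$$p_k = 1 - S\!\big((k+1)u\big)/S(ku),$$
so composing cycles telescopes back to the curve exactly (a property the
test suite asserts to $10^{-12}$).

Two corrections are applied to the bundled OS parameters, both reversible
through `default_parameters(os_shape =)` and
`settings$os_median_calibration`:

1. **Shape typo.** The combination arm's OS shape is published as
   `0.139235`, which implies a median OS of order $10^{10}$ months and
   leaves most of the cohort alive after decades — inconsistent with the
   trial's 13.37-month median OS, with the published ~8-year horizon, and
   with the published 1.68 discounted life-years. The default reads it as a
   decimal-point slip for `1.39235`.
2. **Median calibration.** Even then, both arms' OS fits undershoot the
   trial medians by a common factor of about 1.36 (9.88 vs 13.37 months;
   5.22 vs 7.13) while the PFS fits match their medians well — the signature
   of an axis-scale inconsistency in the digitization behind the OS fits.
   The default rescales each OS curve's $\lambda$ (holding $\gamma$, i.e.
   preserving the fitted hazard shape) so its median equals the trial
   median. Refitting $\gamma$ instead is available
   (`os_median_calibration: "shape"`) but produces heavier tails that move
   every reproduced quantity further from the published results; `"none"`
   uses the table verbatim.

### The death split

How progression and death share the PFS exits is not identifiable from
published material, so the engine implements three wirings
(`settings$pfs_death_rule`) and the default was selected by validating the
reproduced base case against the published cost/LY/QALY table:

* `os_competing` (default): PFS→PD at the PFS-curve exit probability and
  PFS→DEAD at the OS-curve conditional probability, as competing events
  (progression capped at the residual after death). This is the wiring that
  reproduces the published sorafenib arm (0.51 vs published 0.52 QALYs;
  \$15.3k vs \$14.3k).
* `os_excess`: PFS→PD is the excess of PFS exit over death, floored at
  zero — the textbook two-curve decomposition; it underestimates the
  published sorafenib QALYs by ~25% because it books a larger share of PFS
  exits as deaths.
* `background`: only background mortality acts in PFS.

In all cases PD→DEAD uses the same OS-derived conditional probability (one
OS curve per arm governs death before and after progression), floored by
background mortality; under the first two rules the pre-branch cohort's
overall survival tracks the OS curve exactly. RFS faces the recurrence
hazard plus background mortality only: a resected, recurrence-free patient's
excess disease mortality is taken as negligible, and no published quantity
constrains it otherwise.

Recurrence after hepatectomy uses a clinical risk score of 1 (initial
disease beyond the Milan criteria), i.e. a 33.5% five-year cumulative
incidence converted at constant rate to
$p = 1 - (1-0.335)^{u/60}$ per cycle (3- and 7-year values 31.3%/34.1%
bound the sensitivity analyses). Background mortality is a flat annual
all-cause probability of 0.00713 (the national crude death rate in the
statistics the reference analysis cites), converted by
$1-(1-q)^{u/12}$ and applied as a floor on disease mortality.

### Horizon

The published horizon is "approximately 8 years", described as the time for
99% of the cohort to die. With RFS patients facing only background
mortality, the literal 99% rule is not reached for decades (the RFS pool
drains at under 1% per cycle), so the two descriptions conflict; the
default follows the stated duration: `horizon_mode: fixed_cycles` with 139
cycles (= 8.0 years). The 99%-mortality rule (`mortality_fraction`) is
implemented, tested, and available for configurations where it terminates.

## Valuation

Utilities: 0.76 per year in PFS and RFS, 0.68 in PD. Severe (grade ≥ 3)
adverse events enter twice, incidence-weighted per arm: management costs and
utility decrements are charged **once in cycle 0** — except hand-foot
syndrome (HFS), whose cost and disutility persist **every alive cycle**
(`hfs_scope` restricts this to on-treatment cycles if desired). One-off
decrements are applied as one-cycle utility reductions. Elevated ALT/AST
carries management cost but zero disutility.

Per-cycle state costs (USD):

* **PFS**: sorafenib \$2,308.32 + examinations \$352.19; the combination arm
  adds FOLFOX drugs (\$811.70 at the reference body-surface area of 1.72 m²,
  scaled by `bsa_patient/bsa_reference` — only the per-m²-dosed drugs
  scale), the HAIC procedure \$1,817.03 and the two-day hospitalization
  \$376.92.
* **RFS**: surveillance examinations only; the hepatectomy lump sum
  (\$8,862.63) is charged to the branching fraction at the branch cycle.
* **PD**: best supportive care (\$357) by default. The published
  subsequent-treatment mix (sorafenib / HAIC / BSC per arm) is implemented
  as `pd_cost_mode: "mix"`, applied every PD cycle; but with no published
  second-line duration that rule books \$21k–28k for the sorafenib arm
  against a published \$14.3k total, whereas the published total leaves
  almost exactly the BSC cost per PD cycle. The BSC-only default is
  therefore the convention that the published totals themselves imply.
* **DEAD**: nothing.

Costs, QALYs and LYs are all discounted at 3% per year, evaluated at each
cycle's start time (consistent with no half-cycle correction, the default;
`half_cycle_correction` instead values each cycle at the mean of its start
and end occupancy). Totals are occupancy-weighted sums over cycles; the
cost breakdown by component always reconciles with the total.

The published sorafenib-arm proportions of subsequent treatment
(0.35/0.33/0.33) sum to 1.01 as printed and are renormalised in the
defaults.

## Sensitivity analyses

**One-way (tornado).** Every parameter in the published table with a range
(and base ± 20% where none exists) is set to each bound in turn with all
else at base, the full two-strategy pipeline re-run, and the ICER span
recorded; the discount rate sweeps 0–5% and the recurrence rate its
3-/7-year bounds. Sweeping one component of a subsequent-treatment mix
rescales its complement to keep the mix summing to 1. Under the defaults
the PFS utility has the widest span, with the HAIC and sorafenib per-cycle
costs in the leading group — the published ordering.

**Probabilistic (PSA).** Utilities, probabilities and proportions draw from
beta distributions, costs from gamma, body-surface area from normal, each
matched by method of moments to mean = base and SD = (max − min)/3.92 (the
published ranges read as 95% intervals; the reference analysis names the
families but no variance rule, so this is the package's convention,
falling back to (max − min)/6 when beta moments are infeasible). The
Weibull scale/shape parameters are **not** varied: the published table
assigns them no distribution or range. Draw $i$ seeds its own substream as
`seed + i`, so extending a run never changes earlier draws and any draw can
be reproduced in isolation. Each draw re-runs both arms end to end; the
acceptability at threshold $w$ is the fraction of draws with positive net
monetary benefit $w\,\Delta E - \Delta C$.

A caution on reading the acceptability curve at Beijing's threshold: the
published base ICER (\$77.1k/QALY) sits just *above* \$72,000, so its
acceptability there (≈ 39%) is a knife-edge quantity. The reproduced ICER
under this package's defaults is \$65.7k — inside the ±15% band that the
unresolvable wiring choices impose, but on the *other side* of the
threshold — which flips that single CEAC point to ≈ 80% while leaving the
China/Fujian/Gansu conclusions unchanged (all ≈ 0%). Any reconstruction
whose ICER lands a few percent below the published value behaves this way.

## Synthetic data

The digitized Kaplan-Meier coordinates behind the published fits were never
deposited, so `generate_curve_points()` fabricates them from known Weibull
truths: evenly spaced times, Gaussian jitter on the survival scale (the
shape of digitization error), clamped to (0, 1] and forced non-increasing
by a running minimum. `fit_weibull()` recovers parameters by least squares
on the linearised relation $\ln(-\ln S) = \ln\lambda + \gamma\ln t$ —
appropriate for curve coordinates, where maximum likelihood (which needs
event times) is not available — and reports the $R^2$ of that linear fit.
Exact round-trips hold to $10^{-6}$ on noiseless curves; with 30 points,
noise SD 0.02 and a time span reaching S ≈ 0.05, the median parameter
recovery error is about 7%. What these tests do **not** show: performance
on real digitized figures with censoring marks, plateaus, or non-Weibull
shapes — the generator emulates jitter, not model misspecification.

`random_valid_bundle()` fuzzes whole parameter bundles (valid by
construction) for property tests: occupancy conservation to $10^{-10}$ and
death monotonicity hold across 500 random bundles and all three death
rules, and a 100,000-patient microsimulation through the identical
per-cycle probabilities matches the cohort trace within three Monte-Carlo
standard errors.

## Numerical choices

* Survival underflow ($S(ku) = 0$) yields transition probability 1 with a
  warning rather than NaN.
* Probabilities are clipped to $[0,1]$ only against floating-point spill
  ($\pm 10^{-12}$); genuinely out-of-range constructions raise errors
  naming the cycle.
* Beta/gamma method-of-moments degeneracies (base at a support boundary,
  zero SD) fall back to the base value.
* Normal BSA draws are floored at a negligible positive value so the
  BSA-scaling factor stays defined.
* Digitized points with survival exactly 0 or 1 carry no log-log
  information and are excluded from fits with a warning; generated curves
  clamp to $10^{-12}$ above zero.
* Fit $R^2$ is computed directly from residuals (exact fits are routine
  with synthetic curves and `summary.lm` warns on them).

## Problem sizes

The bundled configuration runs 139 cycles in well under a second per arm;
the tornado (45 parameters × 2 bounds) takes ~2 s; the full 10,000-draw PSA
about a minute. The test suite uses 1,000 PSA draws for the acceptability
checks, 100,000 individuals for the microsimulation cross-check, 500 fuzzed
bundles for the conservation properties and 200 replicates for
parameter-recovery — all chosen so the whole suite runs in about half a
minute.

## Known limitations

* Only Weibull (and its exponential special case) survival shapes; no
  log-logistic/log-normal/spline alternatives.
* No tunnel states: the recurrence hazard after hepatectomy is constant,
  and PD costing cannot depend on time since progression (the root of the
  second-line duration ambiguity above).
* Background mortality is a flat annual probability, not an age schedule.
* Second-line effectiveness is not modelled separately: one OS curve per
  arm absorbs all post-progression treatment effects.
* The two-strategy comparison is hard-wired; there is no efficiency
  frontier for three or more strategies.
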