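---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teecea)
library(dplyr)
```

`teecea` evaluates a screening question: does detecting ascending-aorta
atherosclerosis *before* sternotomy with modified transesophageal
echocardiography (TEE), rather than by manual palpation after sternotomy,
buy enough averted embolic strokes to justify its cost? The package
couples a diagnostic decision tree to a three-state Markov cohort model
and propagates parameter uncertainty by Monte-Carlo simulation. This
vignette records the model's structure, the assumptions behind it, and
the numerical and design choices an analyst auditing or extending the
package will want to know.

## Part 1: the diagnostic decision tree

A patient subgroup is defined by sex, age at surgery and atherosclerosis
prevalence $\pi$. A strategy is a test with sensitivity $se$ and
specificity $sp$ (defaults: palpation 31%/98%, modified TEE 97%/80%,
both against epiaortic ultrasound as reference standard). The tree has
three stages.

**Classification.** `classify_test()` returns the four joint
probabilities $\pi se$, $\pi(1-se)$, $(1-\pi)(1-sp)$, $(1-\pi)sp$.

**Adaptation.** Detected atherosclerosis (a true positive) leads to a
major surgical adaptation — ascending-aorta replacement, raising surgery
cost from €15,628 to €23,886 — with probability 2.7%, and otherwise to a
cost-free minor adaptation (relocated cannulation/clamp sites). A false
positive can only yield a minor adaptation: a major one would immediately
reveal the absent disease and be aborted. Reported adaptation chances
therefore cover patients with atherosclerosis; false-positive minor
adaptations are tracked separately and carry neither cost nor risk
change (no embolic source is present).

**Stroke and early death.** Early (30-day) mortality $m$ is a subgroup
input (a calibrated logistic EuroSCORE prediction; the package also
ships the calculator `euroscore_logistic()` plus `calibrate_mortality()`
for the 71% contemporary-practice reduction, with coefficients supplied
via config rather than hard-coded). Because atherosclerosis is treated
as equivalent to the extra-cardiac-arteriopathy risk factor,
`stratify_mortality()` splits $m$ into strata $m_0 < m_1$ that
reproduce $m$ exactly under prevalence weighting and have a configured
odds ratio (default $e^{0.6559} \approx 1.93$, the published logistic
EuroSCORE coefficient for that factor).

Stroke risk is then anchored to early mortality. Fatal strokes are taken
to be the fraction $p_{ds} = 13.2\%$ of early deaths, and the fatal
share of all strokes is $1 - p_{nf} = 19.2\%$, so the per-stratum total
stroke risk is

$$T_i = \frac{m_i \, p_{ds}}{1 - p_{nf}}.$$

In adapted patients (true positives) the embolic portion — 71% of
strokes — is multiplied by the adaptation relative risk $RR = 0.46$;
false negatives get no reduction, and patients without atherosclerosis
are unaffected. Cohort totals are prevalence-weighted; other early
deaths absorb $m - $ (fatal strokes), floored at zero with a warning
flag, so total early death is strategy-invariant. This linkage is a
*reconstruction*: published model descriptions of this design rarely
print their stroke equations, and the exact equation behind them is not
recoverable from rounded report tables. The module therefore exposes the
linkage as a pluggable policy: `"proportional"` (the default above) and
`"concentrated"`, in which all embolic strokes arise in the
atherosclerosis stratum, the limiting case that maximizes what detection
can prevent. A consequence of the strategy-invariant early mortality is
that the two strategies differ in *how* patients survive (post-stroke
vs. uncomplicated), so the TEE benefit appears almost entirely in QALYs
and costs; life-years are equal up to round-off.

## Part 2: the Markov cohort model

States: 'post-surgery, no complications' (utility 1), 'post-surgery,
post stroke' (utility 0.439), 'dead'. Starting occupancy comes from the
tree: fatal strokes and other early deaths start dead, non-fatal stroke
survivors start post stroke. Both alive states face the same annual
death probability: during the post-surgery excess window the band risk
replaces background mortality (age < 61 at surgery: 1.18% in years 1–2;
61–70: 2.33% in years 1–5; > 70: 4.35% in years 1–5; the band is fixed
at surgery and the window lengths are as published, including the
2-year window of the youngest band), and the sex- and age-matched life
table applies thereafter. There is no recovery from the post-stroke
state and no recurrent-stroke modelling.

Numerical conventions:

* **No half-cycle correction.** Transitions and rewards are applied at
  end of cycle, matching the default behaviour of the commercial
  decision-tree software this class of model is usually built in.
  Cycle $t$ uses the life-table row for attained age (age at surgery
  $+ t - 1$); the final cycle starts at the terminal age (110), where
  the death probability is forced to 1, so absorption is guaranteed.
* **Discounting.** Costs at 4.0%/yr, effects at 1.5%/yr (Dutch
  guideline rates), factor $(1+r)^{-t}$.
* **Utilities are age-invariant** (the ageing-related decline in
  quality of life is assumed identical for stroke survivors and others,
  so it cancels from incremental results).
* Because the two alive states share one mortality and never exchange
  members, the whole trace reduces to a survival product; the engine is
  a vectorised `cumprod`, which is what makes a 5,000-draw PSA cheap.

Costs: one-time decision-stage costs (surgery base + major-adaptation
increment weighted by the major-adaptation probability, the €212 device
for the TEE arm, and event costs for death €2,736, fatal stroke €2,736
and acute non-fatal stroke) plus the discounted annual post-stroke care
cost accrued in the trace.

## Parameters and distributions

`default_parameters()` holds every input with its point value and PSA
distribution; the identical YAML ships at `default_config_path()`.
Choices worth recording:

* **Beta** distributions for probabilities, with the published shape
  pairs; every beta mean agrees with its printed point value to under
  half a percent (tested).
* **LogNormal(−0.864, 0.392)** (natural-log scale) for the adaptation
  relative risk. The printed log-scale parameters are themselves
  rounded: back-solving the printed CI 0.196–0.910 gives (−0.86198,
  0.39167), and with the rounded parameters the 2.5% quantile computes
  to 0.1955. Tests therefore assert agreement to one unit in the last
  printed digit.
* **Triangular(0.186, 0.439, 0.653)** for the post-stroke utility,
  reading the reported 0.439 as the mode; the analytic mean is then
  0.426, a known ambiguity of range-only utility reports.
* **Gamma** for the device cost, moment-matched so the mean is 212 and
  the central 95% interval is ≈ [184, 243]
  ($\sigma = (243-184)/3.92$, shape $=(212/\sigma)^2$, scale
  $=\sigma^2/212$): the printed range is narrow and symmetric and no
  parameterization was published.
* **Uniform** for range-only rows (excess mortality, death/fatal-stroke
  costs), using the printed range as support.
* Alternative published stroke fractions (38% fatal instead of 19.2%;
  "roughly 15%" instead of 13.2% of deaths) exist in the source
  literature; the table values are the defaults, and a user can switch
  by editing two lines of the YAML config.
* **Stroke care costs are synthetic stand-ins.** The acute non-fatal
  stroke cost (€16,000) and annual post-stroke care cost (€10,000) have
  no published value in the model's parameter table (they lived in an
  unavailable supplementary costing file). The defaults were chosen
  once from the range reported by Dutch stroke costing studies of the
  same era and are deliberately plain config values. Without *some*
  long-term stroke cost the cost model would be structurally blind to
  averted strokes — the incremental cost of TEE would reduce to the
  device plus extra surgery cost and could never fall with age, which
  contradicts the qualitative behaviour this model class is known for.
  Absolute cost totals should not be compared against published tables
  until real costing data replaces these two values.

PSA draws sample every uncertain parameter once per simulation (common
random parameters across the two strategies, since prevalence and the
stroke fractions are strategy-independent), in a fixed order, so a
seeded run is bit-reproducible. A joint draw failing validation is
rejected and redrawn with a logged count; with the default families
this is essentially impossible (every family's support already
satisfies the constraints), but the guard protects user-configured
distributions.

## Synthetic life tables

`make_lifetable()` builds two-sex tables from Gompertz–Makeham hazards,
$q(a) = 1 - \exp(-(c + \alpha e^{\beta a}))$, the minimal law that
reproduces the structure the model needs: adult mortality monotonically
increasing in age, sex-differentiated (female below male at every age),
terminal age 110. The default parameters (male $c=5\cdot10^{-4}$,
$\alpha=2.7\cdot10^{-5}$, $\beta=0.093$; female $c=3\cdot10^{-4}$,
$\alpha=1.35\cdot10^{-5}$, same slope) give a male annual death
probability near 1.2% at 65 and residual life expectancies in a
plausible Dutch adult range. They are fixture constants, **not**
official national statistics: passing tests show the engine treats any
valid table correctly, not that life-year totals match analyses run on
real tables. Users supply real tables through the `sex, age, qx` CSV
interface (`read_lifetable()`).

The 12 default subgroups cross sex, ages 55/65/75 and a low/high
prevalence track (10/20/40% and 15/30/50%), each with its published
subgroup-average calibrated early-mortality prediction, accepted as a
direct input because the underlying risk-factor prevalences were never
printed.

## What the tests do and do not show

The suite verifies: exact distribution summaries against the published
parameter table; the decision tree against closed-form arithmetic and a
brute-force enumeration oracle over the classification cells and
mortality strata; the Markov engine against the geometric-series life
expectancy $\sum_{t\ge1}(1-q)^t = (1-q)/q$ for constant hazard and zero
discounting (to $10^{-8}$); cohort conservation and monotone absorption
every cycle; the CEAC against a brute-force net-monetary-benefit count;
ellipse coverage against simulation from a known bivariate normal
(94–96% at $n=10^5$); and bit-reproducibility of a full 5,000-draw PSA.
Under the baseline fixture the modified TEE strategy strictly lowers
total stroke risk in all 12 subgroups, gains QALYs in all 12, and its
incremental cost falls monotonically with age, crossing into dominance
(south-east quadrant) in the oldest subgroups.

Deliberately *not* claimed: numerical reproduction of published
life-year, cost and ICER tables — those depend on the real national
life table and the supplementary costing data, neither of which is
available to the package. Problem sizes in the suite (cohort traces to
age 110, $10^5$-draw distribution checks, one full-size and several
small PSAs) were chosen as the smallest that make the statistical
assertions sharp.

## Known limitations

* The stroke-risk linkage is a reconstruction (see above); both
  policies under-predict the stroke-risk gap between the strategies
  relative to published report tables, whose generating equations are
  not recoverable.
* No modelling of palpation itself dislodging plaques, of stroke-risk
  differences by surgical technique, of recurrent stroke, or of
  value-of-information quantities.
* The ICER quadrant of young subgroups is sensitive to the synthetic
  stroke-care costs; conclusions about *where* dominance begins require
  real costing data.

## Session info

```{r}
sessionInfo()
```
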