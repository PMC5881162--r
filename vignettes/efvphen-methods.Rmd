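---
title: "Identifying CYP2B6 poor metabolizers from a single efavirenz test-dose concentration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying CYP2B6 poor metabolizers from a single efavirenz test-dose concentration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efvphen)
```

## The problem

Efavirenz is cleared predominantly by the polymorphic enzyme CYP2B6.
Carriers of the 516 TT genotype — poor metabolizers (PM) — reach much
higher plasma concentrations on a standard 600 mg dose than extensive
(EM, 516 GG) or intermediate (IM, 516 GT) metabolizers, and are the
patients most at risk of neuropsychiatric adverse effects and treatment
discontinuation. Where genotyping is unaffordable, a cheap alternative is
attractive: give a single 600 mg test dose, draw one plasma sample, and
decide from that one concentration whether the patient is likely a PM who
should start on a reduced dose.

`efvphen` implements that workflow end to end: a calibrated population
pharmacokinetic (PK) simulator that generates virtual EM/IM/PM cohorts, an
empirical Bayesian classifier that turns one concentration into phenotype
probabilities, ROC-based selection of the best sampling time, and blinded
evaluation of the resulting decision rule.

## The population PK simulator

### Structural model

Each virtual subject follows a one-compartment model with first-order
absorption and elimination. With dose $D$ (mg), apparent clearance $CL$
(L/h), apparent volume $V$ (L), absorption rate constant $k_a$ (1/h) and
$k = CL/V$:

$$C(t) = \frac{D\,k_a}{V (k_a - k)}\left(e^{-kt} - e^{-k_a t}\right),$$

reported in ng/mL. This is a deliberately reduced description: the
classifier only ever sees the marginal distribution of concentrations at a
handful of sampling times, so the simulator's job is to get those
marginals' summary statistics right, not to resolve organ-level
disposition. The closed form is cross-checked in the test suite against an
independent ODE integration of the same two-state system (gut, central) to
within 0.1%. The degenerate case $k_a = k$ ("flip-flop" singularity) is
excluded by resampling during subject generation.

### Between-subject variability and calibration

$CL$, $V$ and $k_a$ are drawn independently lognormal per phenotype.
The calibration targets are the per-phenotype population means of CL/F,
AUC$_{0-\infty}$ and C$_{\max}$ after a single 600 mg dose
(`efv_pk_targets()`):

```{r}
efv_pk_targets()
```

The AUC unit is µg·h/mL (equivalently mg·h/L); dimensional analysis with a
600 mg dose and clearance in L/h forces this reading.

Three moments pin the three free location/shape choices per phenotype:

* **Clearance CV.** Per subject AUC $= D/CL$, so with lognormal $CL$,
  $E[\mathrm{AUC}] = D\,(1+\mathrm{cv}_{CL}^2)/E[CL]$. The printed mean AUC
  exceeds $D / \bar{CL}$ (Jensen's inequality), and the gap identifies
  $\mathrm{cv}_{CL} = \sqrt{\bar{\mathrm{AUC}}\cdot\bar{CL}/D - 1}$
  (0.652 for EM, 0.497 for IM, 0.447 for PM). This treats the apparent
  inconsistency between mean AUC and dose/mean-CL as information rather
  than error.
* **Volume.** $\bar V$ is tuned by a bounded scalar search (on
  $\log \bar V$) so that the expected population C$_{\max}$, evaluated over
  a fixed set of Monte Carlo draws from the joint lognormal population,
  hits the target (calibrated values land near 270–285 L). The fixed draws
  make calibration deterministic and independent of the user's seed.
* **Absorption.** $\bar k_a$ is held at 0.6 /h, a typical single-dose oral
  value. C$_{\max}$ alone cannot identify both $\bar V$ and $\bar k_a$,
  and we verified that the 24 h phenotype separation — the quantity that
  matters downstream — is insensitive to where on the
  ($\bar V$, $\bar k_a$) ridge the calibration lands.

Defaults $\mathrm{cv}_V = 0.25$ and $\mathrm{cv}_{k_a} = 0.30$ are typical
oral-PK between-subject values; both are arguments of
`calibrate_population()`. There is no lag time, no enterohepatic
recirculation and no assay quantification floor; sex is recorded as
metadata (50% female designs) but has no PK effect.

### Designs, seeds and NCA

Cohorts follow trial-replicate designs: 10 trials × 500 subjects per
phenotype for classifier development, 10 × 30 for PK verification
summaries, and one trial of 100 mixed subjects for blinded verification.
The verification mix uses the Caucasian phenotype frequencies 46/38/26
(EM/IM/PM); these are normalized to proportions (they are printed as
percentages summing to 110, and the intended triple is unknowable, so
normalization is the only defensible reading) and allocated by largest
remainder — 42/34/24 in a cohort of 100 — so the blinded cohort is
byte-reproducible. One master seed (default 2018) drives everything;
per-trial child streams are derived arithmetically from it, so enlarging a
design never reshuffles the trials already drawn.

`summarize_pk()` computes per-subject noncompartmental estimates on a
dense 0–72 h grid at 0.5 h: C$_{\max}$ as the profile maximum, AUC by
linear trapezoid plus terminal extrapolation $C_{last}/\lambda_z$ with
$\lambda_z$ from a log-linear fit over $t \ge 48$ h, and
$CL = D/\mathrm{AUC}_{0-\infty}$. For this structural model the procedure
recovers the exact per-subject $D/CL$ to within 2% (tested). Interval
summaries are 2.5–97.5 percentiles of the per-trial means — the printed
"CI" of trial-replicate simulators is not defined precisely enough to
reproduce any other way, so this choice is explicit and configurable
upstream of nothing else. Predicted:observed ratios within two-fold are
flagged acceptable.

## The Bayesian classifier

`efv_bayes()` fits, at one sampling time $t$, the empirical conditional
distribution of the *binned* concentration given each phenotype $e_j$:

$$P(C \mid e_j) = \frac{\#\{\text{subjects of } e_j \text{ with binned
concentration } C \text{ at } t\}}{\#\{\text{subjects of } e_j \text{ at }
t\}},$$

with concentrations rounded to the nearest 100 ng/mL (bin width
configurable; exact midpoints round up — the convention had to be fixed
somewhere and half-up is the common one). Bayes' theorem then gives

$$P(e_j \mid C) = \frac{P(e_j)\, P(C \mid e_j)}
{\sum_k P(e_k)\, P(C \mid e_k)},$$

and the call is the maximum a posteriori phenotype. Priors default to
uniform (1/3 each): the development cohorts are equal-sized by design, and
the same uniform prior is deliberately kept when classifying
mixed-frequency cohorts, mirroring the verification procedure; population
priors can be supplied instead.

Numerical and degenerate-input choices, all configurable or tested:

* **Smoothing.** A pseudo-count (default 0.5) is spread across the union
  bin range of the training data plus two guard bins at each end, so every
  phenotype has positive likelihood on every reachable bin and the
  posterior is defined everywhere. With smoothing 0 the fitted table is
  exactly the raw count ratio.
* **Unseen bins at smoothing 0.** The posterior is then undefined at zero
  evidence; a test-dose tool must still answer, so the call falls back to
  the nearest populated bin (distance in bins, ties toward the higher
  concentration).
* **Out-of-range concentrations** clamp to the guard bins: values above
  every trained bin are, in practice, called PM.
* **Ties.** Exactly tied posteriors break toward the slower metabolizer
  (PM over IM over EM) — the clinically conservative direction, since the
  costly error is missing a PM — and the tie is flagged in the output.

Fitted models serialize to plain JSON (`write_efv_bayes()`), carrying bin
centers, counts, probabilities, priors, smoothing and provenance, and a
restored model reproduces the original calls.

## Evaluation and sampling-time selection

For each phenotype, performance reduces to the per-phenotype sensitivity
$P(+|+)$ (fraction of that phenotype called correctly) and specificity
$P(-|-)$ (fraction of the other phenotypes not called as it), computed
exactly from the confusion-matrix counts; $P(+|-) = 1 - P(-|-)$ by
construction. Candidate sampling times {2, 4, 8, 12, 24} h each get their
own fitted classifier, and the per-time $(P(+|-), P(+|+))$ pairs form a
discrete ROC. The optimal time is selected by maximizing Youden's
$J = P(+|+) - P(+|-)$ for the target phenotype (PM): the published
procedure picks the point closest to the ideal corner by eye, and Youden's
J is the standard scalarization of exactly that criterion. Exact ties go
to the later time.

Development-time probabilities are computed in-sample on the 10 × 500
training cohorts (the scale at which the published probabilities were
produced); `eval_mode = "held_out"` scores an independent mixed cohort
instead. Blinded verification is structural, not procedural:
`evaluate_cohort()` drops any phenotype column before calling, and joins
the separately supplied truth table only to score, so the call table is
identical with or without labels present.

## What the generator does and does not emulate

The simulator reproduces: the per-phenotype means of CL/F, AUC and
C$_{\max}$ (recovered within 10% at the 10 × 500 scale, tested); their
trial-to-trial spread under lognormal between-subject variability; the
ordering of 24 h concentrations (PM > IM > EM in median, tested); and full
seeded reproducibility.

It does not reproduce the shape of a whole-body physiological model's
concentration decline. That limitation is consequential and worth being
precise about. Matching an EM subject's C$_{\max}$ of 1850 ng/mL and CL/F
of 12.8 L/h under a one-compartment model forces $V$ into roughly
190–324 L for *any* absorption rate, hence an elimination half-life of
10–16 h and a median EM 24 h concentration around 700–950 ng/mL. A
multi-compartment disposition with the same C$_{\max}$ and AUC can put far
more of the EM distribution below 500 ng/mL at 24 h. Consequently the
phenotype distributions at 24 h overlap more here than under the full
physiological engine: the posterior P(PM | C) climbs through 0.6 only near
1800 ng/mL rather than just above 1000, and the in-sample PM sensitivity
at 24 h sits near 0.7 rather than 0.82 (both numbers are computed by the
acceptance checks, not asserted). A further numerical consequence of the
histogram likelihood is that the IM/PM posterior crossing is nearly flat
across one or two bins, so the MAP boundary bin — and with it a few
percentage points of PM sensitivity — can shift between simulation seeds
even with 5000 subjects per phenotype. The *qualitative* conclusions are
robust across seeds: 24 h is always the best sampling time by PM Youden J,
EM is always the call below 500 ng/mL, and high concentrations always
call PM.

Passing tests therefore demonstrate correctness of the machinery
(counting, Bayes arithmetic, blinding, ROC selection, reproducibility) and
calibration-level fidelity of the simulator; they do not demonstrate that
the specific clinical decision threshold of ~1000 ng/mL transfers to real
patients, which requires the physiological model and clinical data this
package does not contain.

## Problem sizes

Default study conditions: 10 × 500 subjects per phenotype at five sampling
times for classifier development; 10 × 500 per phenotype on the 0.5 h
dense grid for PK recovery; 100 mixed subjects for blinded verification.
The whole pipeline at these sizes runs in seconds; tests use reduced
designs (2 × 200 and similar) where full scale adds nothing to the
property under test.
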