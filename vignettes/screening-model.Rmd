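---
title: "The pancscreen microsimulation model: natural history, screening and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pancscreen microsimulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancscreen)
```

## Purpose

`pancscreen` simulates individual life histories of people at high inherited
risk of pancreatic cancer (PC) — mutation carriers and relatives of familial
PC patients — and overlays image-based screening (a combined EUS/MRI-like
test) to estimate what screening can and cannot achieve: the reduction in PC
mortality, the number of screening tests (NNS), surveillance tests (NNSurv)
and resections (NNT) per cancer death prevented, life-years gained, and
interval-cancer rates. Because the natural course of pancreatic
carcinogenesis is largely unobservable, the package implements two
contrasting hypotheses as switchable pathway presets and a sensitivity grid
over risk level, test characteristics and surgical mortality.

## Natural-history model

Each simulated person carries:

* an **other-cause death age**, drawn from a life table by inverse-CDF with
  linear interpolation inside year-of-age bins (death ages are continuous, so
  life-year computations have no binning artifacts);
* possibly one **pancreatic lesion at a time**, with an onset age drawn from
  a Weibull cumulative hazard `Lambda(a) = rate * (a/100)^shape`;
* a **lesion fate**: progressive or (in the indolent-included pathway, with
  calibrated probability) indolent;
* **stage dwell times** through LGD → IGD → HGD → preclinical cancer stage I
  → II → III/IV. Dwell times are exponential. A single shared quantile per
  lesion is pushed through every stage's inverse CDF, so a lesion that is
  fast in one stage is fast in all of them (perfect rank correlation; a
  Gaussian-copula parameter `rho` can relax this, default 1 — the strongest
  reading of "correlated consecutive durations");
* possible **clinical diagnosis** while in a preclinical cancer stage, with
  per-stage probabilities 5.1% (I), 13.1% (II) and 100% (III/IV), at a
  uniform time within the stage dwell (the model gives only per-stage exit
  probabilities, so a uniform diagnosis time is the least-informative
  completion);
* **post-diagnosis survival**: with probability `1 - S5(stage)` (S5 = 29.1%,
  11.4%, 0% for stages I, II, III/IV) the person dies of PC at a uniform
  time within five years of diagnosis (linear mortality); otherwise the
  person is cured for life. PC death competes with other-cause death:
  whichever comes first determines the cause.

Progressive dwell means are 3.33/3.33/3.33 years for the preinvasive grades
and 2/2/1 years for the preclinical cancer stages (progressive-only
pathway), or 1.11/1.11/1.11 and 0.66/0.66/0.33 in the indolent-included
pathway, whose indolent lesions instead dwell 7.08/11.78/24.15 years in the
preinvasive grades and then stay in preclinical stage I until death from
other causes — an indolent lesion never causes a clinical cancer or a PC
death. With the detection probabilities above, the expected time from onset
to clinical diagnosis is 14.1 years (progressive-only) and 4.7 years
(indolent-included progressive lesions); the closed form is checked in the
test suite.

Disease timelines are generated in full and truncated at the other-cause
death age only when outcomes are read off. This keeps random-stream
consumption identical whatever the screening policy does to the person.

## Screening and management

Screening is offered at ages 50–75 (1- or 5-year interval) with complete
adherence; persons dead or already diagnosed before age 50 are never
screened. The test is positive for a lesion-free pancreas with probability
`1 - specificity` (default specificity 0.90) and for a true lesion with
stage-specific sensitivity 60/60/75/90/93/99% (LGD…preclinical III/IV).
A positive test leads to:

* **palliative care** for preclinical stage III/IV (no resection; the fatal
  5-year survival law applies from detection);
* **resection** with probability 0.9 for any other detected stage — the one
  anchor the model's description provides (90% sensitivity × 90% referral =
  81% of stage-I persons resected per round); resection carries a 3%
  surgical mortality. Resected preinvasive lesions are cured outright and
  the person returns to routine screening, *remaining at risk of a new
  lesion* (re-onset uses the same hazard conditioned on current age, with a
  fresh fate). Resected preclinical I/II cancers receive the stage-specific
  survival of clinically detected cancer — screen detection shifts the stage,
  not the stage-specific prognosis — and exit screening;
* **surveillance** otherwise: tests every 6 months with the same
  characteristics, while the disease keeps progressing; positives re-enter
  management. A lesion-free (false-positive) person returns to routine
  screening after one negative surveillance test (configurable).

Two design points deserve emphasis. First, stage-specific survival is
applied to every screen-detected invasive cancer regardless of lesion fate;
a resected *indolent* preclinical-I cancer therefore carries stage-I
prognosis even though it would never have killed untreated. This is the
conservative reading of "screen-detected survival equals clinically detected
survival", and it is the mechanism by which overdiagnosis can do harm in the
model. Second, surgical deaths count as PC-related deaths in mortality
outcomes: they are consequences of the screening program, and the treatment
mortality sensitivity analysis is only meaningful if they count.

## Random numbers and the paired design

Every person owns two counter-based Wichmann–Hill uniform streams derived
from `(seed, person, stream)`: one for natural history, one for screening.
The no-screening and screening arms of a scenario consume identical
natural-history draws — common random numbers — so between-arm differences
are the policy effect alone, which is what makes NNS stable at feasible
cohort sizes. Stream arithmetic uses only exact integer-valued double
operations, so the compiled engine (C++) and the interpreted per-person
reference engine (pure R) reproduce the same histories draw for draw; the
test suite asserts event-by-event agreement on 10,000 persons. Bernoulli
decisions that carry a time (clinical detection within a stage, death within
the 5-year window) reuse the same uniform for both: conditional on `u < p`,
`u/p` is again uniform, which halves stream consumption without changing
the law.

## Life table

The reference publication for this class of models does not include its life
table. The shipped default is a Gompertz–Makeham-style table
(`mu(a) = A + B exp(theta a)`, small fixed background `A`) fitted to the two
anchors that the model's printed cohort implies: survival to age 50 of 0.925
(the fraction of simulated persons ever screened) and 69.7 life-years per
person (person-years implied by the printed incidence rate and case count).
Any user table can be supplied as a two-column CSV (`age,
cumulative_survival`).

## Calibration

The free parameters are the onset-hazard scale (both pathways) and the
indolent fraction (indolent-included). Calibration is monotone bisection
with common random numbers across iterates and a verification run on an
independent seed (`calibrate_onset_scale()`).

**Choice of target.** The reference cohort's printed inputs and outputs are
mutually inconsistent: a 7.5% lifetime risk of *clinical* PC caps clinical
cases at 750 per 10,000, yet the printed no-screening column shows 921 cases
and 751 deaths. Given the printed detection probabilities and stage
survival, deaths per case are pinned near 0.82–0.87, so no onset scale can
deliver 7.5% clinical risk and 751 deaths simultaneously; the printed cohort
itself realizes a 9.2% clinical risk. The shipped presets therefore
calibrate to the **death burden** (751/753 PC deaths per 10,000 without
screening), the quantity that anchors every effectiveness measure
(mortality reduction, NNS, NNSurv, NNT all divide by deaths prevented). The
realized lifetime clinical risk, about 9.2%, is reported rather than forced;
risk-targeted calibration remains available (`metric = "risk"`) and is
exercised by the tests. Doubled and halved risk scenarios recalibrate the
onset scale to a doubled or halved death-burden target — never a scaling of
counts.

**Onset shape.** The Weibull shape of the onset hazard is not identified by
any single printed number; it controls how steeply onset — and hence stage
prevalence and diagnosis age — rises with age. The default (shape 5) was
chosen once so that the unscreened cohort is clinically coherent: median
clinical diagnosis in the mid-to-late 60s, as observed in familial
pancreatic cancer, prevalence rising into the 70s, and a realized case
fatality (deaths/cases ≈ 0.82) matching the reference cohort's own
arithmetic (751/921).

**Indolent fraction.** Without screening, indolent lesions are invisible —
they never reach clinical diagnosis — so the unscreened burden cannot
identify their share; any fraction can be offset by the onset scale. The
fraction is therefore identified against the overtreatment volume that
indolent disease exists to represent: total resections under annual
screening (1,278 per 10,000 in the reference cohort), via a nested
bisection (outer: fraction against resections; inner: onset scale against
deaths). The shipped preset fixes the fraction at 0.361. A parameter-recovery
test plants a known (scale, fraction) pair and recovers it.

## Problem sizes and runtime choices

The compiled engine simulates a paired 10^6-person annual-screening scenario
in about one second on one core. The test suite uses 10^6 persons for the
headline reproduction checks, 2×10^5 per calibration iterate, and
10^3–10^5 persons for property checks; `scripts/acceptance.R` recomputes
everything from scratch (calibrations at 2×10^5, scenarios at 10^6) in well
under a minute. Counters are accumulated in doubles; counts are exact
integers well below the 2^53 limit.

## What the simulated cohorts do and do not capture

The generator reproduces the study conditions of the reference analysis:
complete adherence, a single merged precursor type, one lesion at a time,
detection without stage misclassification, no systematic false negatives,
and survival independent of lead time beyond the stage shift. Real screening
programs violate most of these in some degree: attendance is partial,
multifocal disease exists, lesions can be systematically missed (size,
parenchymal changes), and screen-detected survival may be inflated by
lead-time and length biases that the stage-shift mechanism only partly
captures. Passing reproduction tests therefore demonstrates fidelity to the
modeled conditions, not a forecast for any particular clinical program.
Quality-of-life losses, surgical morbidity short of death, costs, and
biomarker-based testing are out of scope.

## Known limitations

* The onset-age distribution and the indolent fraction are identified only
  through the aggregate choices documented above; other (shape, fraction)
  pairs could reproduce the same aggregates with different age patterns.
* The lifetime clinical risk realized under the death-burden calibration
  (~9.2%) exceeds the nominal 7.5% input of the reference analysis; the two
  cannot be reconciled under the printed stage parameters (see
  *Calibration*).
* With the single published referral anchor (90% resection given a positive
  test), true-lesion surveillance episodes are short; at perfect
  specificity the surveillance burden per death prevented falls well below
  the reference model's value of 5, which evidently reflects unpublished
  stage-specific referral probabilities.
* Relative survival is implemented as cause-specific mortality competing
  with other-cause death; with five-year cure this is a close but not exact
  equivalent of registry relative survival.

## A worked example

```{r example, eval = FALSE}
library(pancscreen)
spec <- scenario_spec("progressive_only", "annual", n_persons = 1e6,
                      seed = 1)
res <- run_paired_scenario(spec)
print(res)
```

See the README for the numbers this prints and how to regenerate the full
set of headline quantities with `scripts/acceptance.R`.
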