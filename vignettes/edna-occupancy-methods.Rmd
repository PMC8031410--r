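---
title: "Methods: occupancy inference and qPCR calibration for vernal pool eDNA surveys"
author: "ednaOccu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occupancy inference and qPCR calibration for vernal pool eDNA surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaOccu)
```

## Scope and data flow

`ednaOccu` covers the inference chain of a qPCR-based eDNA monitoring survey
for vernal pool branchiopods, from instrument output to survey-design
recommendations:

1. **qPCR calling** — well amplification flags, the 2-of-4/re-run sample
   rule, plate QC (NTC, positive control, extraction blank, field negative).
2. **Calibration** — log-linear standard curves; Low95, LOD, LOQ.
3. **Detection histories** — per-event replicate outcomes coded 0/1/2 with
   covariates, built from sample sheets, calls and dip-net results.
4. **Occupancy models** — the single-season model with imperfect detection,
   AIC enumeration over detection covariates, MacKenzie–Bailey GOF, and the
   false-positive model for certain/uncertain data.
5. **Design** — k-of-n binomial tails, minimum replicate counts, interval
   propagation.

Each sampling event (one pool visit: typically three 1 L water replicates
followed immediately by a dip-net sweep) is one "site".  Repeat visits to
the same pool are deliberately treated as independent events — occupancy
here means "occupied at the time of the visit", appropriate for organisms
whose detectability and presence vary within a wet season; `poolId` is kept
for reporting only.

## The likelihoods

With replicate outcomes $y_{ij}\in\{0,1\}$ at site $i$, detection
probability $p_{ij}=\mathrm{logit}^{-1}(x_{ij}^\top\beta)$ and occupancy
$\psi_i=\mathrm{logit}^{-1}(w_i^\top\alpha)$, the site likelihood is

$$L_i=\psi_i\prod_j p_{ij}^{y_{ij}}(1-p_{ij})^{1-y_{ij}}
      +(1-\psi_i)\,\mathbb{I}[\textstyle\sum_j y_{ij}=0].$$

Missing replicates (`NA`, including QC-discarded ones) contribute no
factor.  Sites with a positive dip-net capture are *known occupied*: the
$(1-\psi_i)$ branch is dropped but the $\psi_i$ factor is retained, so
$\psi$ stays estimable from the full likelihood rather than being pinned to
1 at those sites.  A caveat follows from treating the flags as exogenous:
the likelihood does not model the dip-net outcome itself, so the fact that
a site *lacks* a flag is not used as evidence about occupancy.  This is the
standard known-occupancy convention, and it is exactly how the false-positive
model receives its "certain" codes.

The false-positive model takes codes $y_{ij}\in\{0,1,2\}$ (0 none, 1
uncertain, 2 certain) and replaces the two branch kernels by
$f_1=(1-p_{11},\,p_{11}(1-b),\,p_{11}b)$ at occupied sites and
$f_0=(1-p_{10},\,p_{10},\,0)$ at unoccupied ones.  $p_{10}$ is a scalar by
design: an assay should produce false positives at a rate indifferent to
pool area or filtration method, so no covariates are allowed on it.  $b$
(the probability a true detection is recorded certain) is estimated by
default; `bFixed` fixes it instead, since a survey protocol might pin
certainty administratively.  Setting $p_{10}=0$ collapses the model onto
the binary likelihood exactly (up to the separable certainty factor
$b^{n_2}(1-b)^{n_1}$), which the test suite asserts.

## Estimation and numerics

- **Optimization**: BFGS on the logit scale, 5 starts by default — the
  first from data-driven naive estimates (observed occupancy and detection
  fractions), the rest jittered N(0, 0.5²) under a derived seed; best
  log-likelihood wins, ties to the first found.
- **Standardization**: non-binary covariates are z-scored before
  optimization for conditioning; binary covariates (protocol: field = 0,
  lab = 1) are left as coded.  `naturalCoefs()` maps back to the data
  scale.
- **Uncertainty**: covariance is the inverse numerical Hessian at the
  optimum.  Prediction intervals use the delta method on the linear
  predictor, back-transformed through the logistic, so they are always
  inside [0, 1].  Profile intervals were the main alternative; the delta
  choice is simple, matches common practice, and is flagged as a source of
  small CI differences near boundaries.
- **Boundaries**: |logit| > 10 flags a boundary estimate (e.g. $\hat p_{10}$
  with no uncertain detections, $\hat\psi$ with all sites known occupied);
  Wald inference is unreliable there and the flag is surfaced rather than
  "fixed".
- **Stability**: all likelihoods are computed in log space
  (`plogis(log.p=)`, pairwise log-sum-exp), and the 0·(−∞) conventions for
  empty counts are handled explicitly.

**AIC enumeration** fits all $2^m$ subsets of the detection-covariate pool
(16 models for the standard four).  Among models within 2 AIC units of the
minimum, the fewest-parameter model is selected — the usual parsimony
convention; the full ranked table is always returned so that choice is
transparent.  Occupancy covariates are supported but default to none,
matching surveys that vary only detection conditions.

**Goodness of fit** uses the MacKenzie–Bailey chi-square
$T=\sum(O-E)^2/E$ over per-site detection-history cells; with continuous
covariates every site is its own cohort, expected probabilities condition
on occupancy at known-occupied sites, and cells with $E<10^{-10}$ are
skipped.  The reference distribution is a parametric bootstrap (simulate
from the fit, respecting known-occupied flags and the missingness pattern;
refit from the data-fit estimates; recompute $T^*$), giving
$p=(1+\#\{T^*\ge T\})/(B+1)$ and $\hat c=T/\bar T^*$.  Calibration of
$\hat c$ holds when the generating process and the fitted model coincide;
with dip-net-derived known-occupied flags the generator embodies a dip-net
selection effect the model deliberately ignores (flags exogenous), and
$\hat c$ sits modestly below 1.  The package's calibration tests therefore
run on surveys without known-occupancy conditioning; users comparing
$\hat c$ on flagged data should expect that mild downward shift.

## Calibration metrics

The standard curve is OLS of Cq on $\log_{10}$(copies/reaction) over
amplifying wells only; non-amplifying wells are excluded from the
regression but counted in detection fractions (standard qPCR practice —
a dropout is information about detection, not about the line).  Metrics:

- **Low95** — lowest *tested* concentration with ≥ 95% of replicates
  amplifying; `Inf` encodes "above the highest standard".
- **LOD** — `discrete` applies the Low95 rule; `curvefit` (default) fits a
  two-parameter logistic of detection vs $\log_{10}$(copies) and solves the
  95% crossing, clamped at the lowest tested concentration.  A
  non-increasing dose-response falls back to `discrete` with a warning.
  The optional `nReplicates` output solves $1-(1-d)^r\ge0.95$ for surveys
  pooling $r$ replicates.
- **LOQ** — back-calculate copies for each amplifying well through the
  fitted line; the `discrete` LOQ is the lowest concentration (≥ 3
  amplifying replicates) with CV ≤ 0.35, the `curvefit` variant solves the
  threshold crossing of a decreasing linear CV-vs-$\log_{10}$(copies)
  model.  The 0.35 CV threshold is the convention of the widely used
  qPCR LOD/LOQ calculator scripts and is configurable; published tables
  report outcomes only, not the threshold.

Tissue-identification calls are separate from eDNA calling: specimens
classify as target when the median quadruplicate Cq (non-amplifying wells
counted at the 50-cycle run length; median for robustness to one aberrant
well) is at or below the assay's target cutoff (20 cycles, 30 for BRLY),
non-target when nothing amplifies before the off-target floor (30 cycles,
42 for BRLY), indeterminate between.  eDNA wells, by contrast, count as
amplified at any reported Cq within the 50-cycle protocol — published
calling rules count amplified replicates without a Cq ceiling — with the
ceiling exposed as `maxCycle` for labs that want one.

## The synthetic-study generator

`simulateStudy()` emulates the study design end to end: occupancy
Bernoulli($\psi$); per-replicate detections Bernoulli($p_{11}(x)$) at
occupied and Bernoulli($p_{10}$) at unoccupied sites; dip-net detection
Bernoulli(sensitivity) at occupied sites; quadruplicate qPCR wells per
replicate with both re-run branches of the 2-of-4 rule exercised; per-event
plates with NTC, duplicate positive controls, and a field negative whose
contamination discards the event.  Defaults are fixed once to mirror the
study conditions: 98 sampling events (89 pools visited once plus 3 pools
visited three times), 3 replicates per event, $\psi=0.5$, per-replicate
detection 0.7564 (the published BRLY field estimate), $p_{10}=0.091$ (the
published LEPA estimate), dip-net sensitivity 0.85 (a free parameter — no
dip-net detection rate has ever been established, so a realistic
high-but-imperfect value was chosen once), curve truth slope −3.4 /
intercept 38.7 / Cq sd 0.3, and panels of five concentrations
(1, 2, 5, 10, 100 copies/reaction) × 8 replicates + 8 NTCs.

Replicate volumes are coupled to a site-level turbidity latent (turbid
pools clog filters early), capped at the 1000 mL protocol maximum, making
*average volume filtered* a meaningful site covariate exactly as in turbid
BRCO pools.  Certainty comes in two modes: event-level (all detections at a
dip-net-positive event are certain — how real data are coded) and
per-detection (`b =` argument; each true detection is independently certain
with probability $b$ — the process the false-positive model itself
assumes).  Parameter-recovery tests use the per-detection mode; with
event-level certainty, certainty status is perfectly predicted by the
site's flag and $\hat b$ legitimately drifts to its boundary.

What the generator does **not** emulate: within-season pond drying and
abundance dynamics, spatial correlation between neighbouring pools, PCR
inhibition gradients, or cross-contamination between samples on a plate.
Passing tests therefore demonstrate correctness of the inference machinery
under the stated model, not robustness of the field protocol to violations
of replicate independence.

## Problem sizes in the test suite

The suite exercises oracle equivalence on 100 randomized toy datasets (≤ 8
sites × ≤ 4 replicates) at $10^{-10}$ tolerance, a $10^{-3}$-resolution grid
search, parameter recovery at 500–1000 sites × 3 replicates, interval
coverage over 200 surveys of 200 sites, and GOF calibration over 50
surveys of 60 sites at $B=200$ bootstrap draws — sizes chosen to put
Monte-Carlo error well below the tolerances being asserted while keeping
the default test run in the low minutes.

## Known limitations and reproduced discrepancies

- Published per-species field estimates (detection 75.64%/97.44%,
  false-positive rates 0.091 and 4.25×10⁻⁵) are *scale anchors*, not
  regression targets: the underlying field detection histories are not
  public, so tests verify that the machinery recovers known truth on
  synthetic surveys of the same design instead.
- A published worked example quotes a 2-of-3 rule false-positive rate of
  0.0081 (also printed as "0.08%", internally inconsistent) at
  $p_{10}=0.091$; 0.0081 equals $p_{10}^2$, whereas the exact ≥2-of-3
  binomial tail is $3p^2(1-p)+p^3=0.0233$.  The package computes the exact
  tail and documents rather than reproduces the discrepancy.
- One published concordance panel sums to 44 events where the text says 45;
  concordance summaries report whatever counts they are given, reproducing
  the table as-is.
- A published LOQ of "24 cycles/reaction" conflicts in units with its own
  table (copies/reaction); copies are used throughout.
- Reported percentages follow the printed convention: round half-up to
  integers, except exact single-decimal values (62.5%) keep that decimal.
- No multi-season/dynamic occupancy, no spatial models, no Bayesian
  estimation, no fluorescence-curve processing, and no XLSX parsing (sample
  sheets are plain CSV).
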