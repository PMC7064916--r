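---
title: "CIBP allocation for phase I dose-escalation trials: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CIBP allocation for phase I dose-escalation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cibpcrm)
```

## The problem

A phase I dose-escalation trial seeks the maximum tolerated dose (MTD): the
dose whose probability of a dose-limiting toxicity (DLT) is closest to a
prespecified target $\gamma$ (conventionally below 0.5, often 0.25--0.33).
Model-based designs such as the continual reassessment method (CRM) update a
dose--toxicity model after every cohort and allocate the next cohort to the
dose whose estimated toxicity $\hat p_i$ minimizes the squared distance
$(\hat p_i - \gamma)^2$. That rule ignores two things: the uncertainty of
$\hat p_i$, and the ethical asymmetry between treating a patient at an overly
toxic versus an overly safe dose.

## The CIBP criterion

The convex infinite bounds penalization (CIBP) divergence replaces the
squared distance with

$$\delta(p, \gamma) \;=\; \frac{(p-\gamma)^2}{p^{a}\,(1-p)^{2-a}},
\qquad 0 < a < 2 .$$

Its properties drive everything in this package:

* $\delta \ge 0$ with a unique zero at $p = \gamma$; it is convex and
  unimodal in $p$.
* $\delta \to \infty$ as $p \to 0$ or $p \to 1$: boundary probabilities can
  never win an argmin, which is what "infinite bounds penalization" means.
* At $a = 1$ the denominator is the Bernoulli variance $p(1-p)$ and the
  divergence is symmetric on the logit scale: if
  $\mathrm{logit}\,\gamma - \mathrm{logit}\,p_1 =
  \mathrm{logit}\,p_2 - \mathrm{logit}\,\gamma$ then
  $\delta(p_1,\gamma) = \delta(p_2,\gamma)$ (tested to $10^{-10}$).
* $a$ tilts the penalty: $a < 1$ punishes overly toxic doses more than
  overly safe ones. The plug-in rule at $a = 2\gamma$ allocates like the
  squared distance almost always (the equivalence is approximate: the
  denominator peaks at $\gamma$ but is not symmetric about it, so near-ties
  and boundary-adjacent estimates can flip the argmin; a property test
  checks a $\ge 97\%$ agreement rate instead of exact equality).

### Choosing $a$ from an indifference interval

`asymmetry_from_interval(gamma, theta)` returns the $a$ for which
$\delta(\gamma-\theta,\gamma) = \delta(\gamma+\theta,\gamma)$:
inside $(\gamma-\theta, \gamma+\theta)$ the safer of two equidistant
estimates is preferred, outside it the more uncertain one. Closed form:
$a = 2/(1+A)$ with
$A = \log\frac{\gamma-\theta}{\gamma+\theta} \big/
\log\frac{1-\gamma-\theta}{1-\gamma+\theta}$.
As $\theta \to 0$, $a \to 2\gamma$ (the squared-distance-like regime);
widening $\theta$ drives $a$ down and the design toward conservatism.
For $\gamma = 0.25$ and the near-maximal $\theta = 0.245$ the closed form
gives $a \approx 0.257$.

```{r calibration}
asymmetry_from_interval(0.25, 1e-8)   # ~ 2 * gamma
asymmetry_from_interval(0.25, 0.245)
```

## The Bayesian design

The working model is the one-parameter power model
$\psi(d_i, \beta) = d_i^{\exp(\beta)}$ on standardized doses $d_i$ (the
skeleton values), with prior $\beta \sim N(0, 1.34)$ — the usual
operational prior for this model. After $j$ patients the posterior
$f_j(\beta)$ is the prior times the Bernoulli likelihood, and the design:

1. allocates cohort 1 to the lowest dose;
2. after each cohort, allocates the next cohort to the dose minimizing the
   posterior expectation
   $E\!\left[\delta(\psi(d_i,\beta), \gamma) \mid \text{data}\right]$
   (the CRM comparator minimizes $(\hat p_i - \gamma)^2$ with
   $\hat p_i = E[\psi(d_i,\beta)\mid\text{data}]$);
3. repeats until the sample size is reached, then selects the MTD by the
   squared distance — uncertainty and conservatism matter during
   allocation only, so the final selection is the plain argmin.

A skeleton can be built with `make_skeleton()`, which anchors the
anticipated MTD at $\gamma$ and extends it by the indifference-interval
recursion for the power model; each step is pinned by the closed form
$s_{k+1} = \exp\{\log(\gamma+h)\log s_k / \log(\gamma-h)\}$ (and its
mirror going down), and the tests cross-check it against an independent
root-finding implementation.

### Escalation constraints

Three restrictions, all optional flags in `escalation_constraint()`:

* `start_lowest`: cohort 1 at dose 1.
* `no_skip`: the candidate may not exceed the highest dose yet
  administered plus one. "Highest administered + 1" is the standard
  reading; de-escalation is never blocked.
* `coherent`: no escalation immediately after a cohort that contained at
  least one DLT (the candidate is clipped to the current dose). This is
  the cohort version of the classic coherence principle. It is on by
  default: a one-parameter model pools information across doses, and
  immediately after a toxic cohort the pooled estimate can still favor
  escalation, which clinicians would not accept. The individual-trial
  replay below requires it to reproduce its recommendation path.

CRM(M) additionally restricts the admissible set to doses with estimated
toxicity *strictly below* $\gamma$ (falling back to the lowest dose when
the set is empty — early in a toxic trial nothing qualifies). Strictness
means a dose estimated exactly at the target is stepped off; that is the
restriction's own definition, not an artifact.

Ties everywhere break to the lower dose index: safety-conservative and
deterministic.

## Numerics

**Grid posteriors.** The posterior is a deterministic quadrature grid:
2001 nodes over the prior mean $\pm 8$ standard deviations (1-D), or a
$201 \times 201$ product grid (2-D logistic model). All weight arithmetic
is in log space with max-subtraction. Determinism makes every allocation
decision exactly replayable, and the tests compare the default grid
against a brute-force $10^6$-node refinement (agreement to $10^{-6}$ after
the first cohort of the worked example; doubling the node count moves
posterior means by less than $10^{-8}$).

**Log-scale scoring.** The posterior expectation of the CIBP divergence is
heavy-tailed in a way that matters: under the power model,
$\delta(\psi(d,\beta),\gamma) \sim \gamma^2 \psi^{-a}$ grows
double-exponentially in $\beta$, so before the first DLT has been observed
the expectation diverges under an untruncated normal prior, and even on the
truncated grid its value overflows double precision. The package therefore
computes $\log E[\delta]$ by logsumexp over nodes; logs are finite,
ordering is preserved, and the argmin is well defined. Practically, in the
no-DLT regime the score ordering is dominated by the largest grid nodes and
always prefers the highest dose — which the no-skip constraint then clips.
This divergence is a real property of the criterion, not a numerical
nuisance, and it is why reported values of the CIBP score should be read on
the log scale.

**Boundary sentinels.** Pointwise, `cibp_divergence()` returns `Inf` at
$p \in \{0, 1\}$; comparisons treat it as larger than any finite value.

**Interval losses.** The BLRM loss table uses right-open intervals
$[l, h)$ with $p = 1$ assigned to the last interval — a measure-zero
convention fixed for determinism.

## The individual-trial replay

`everolimus_fixture()` ships the inputs of a three-regimen trial of
Everolimus given with Paclitaxel and Trastuzumab: $\gamma = 0.3$, skeleton
$(0.20, 0.30, 0.40)$, prior $N(0, 1.34)$, cohorts of three, and aggregated
outcomes of 6/17/10 patients with 3/6/7 DLTs at the three regimens. The
fixture's per-dose outcome streams fix one replayable order of those
outcomes; only cohort totals matter to the designs. The dose-2 stream's
cohort-level DLT counts (1, 0, 1, 2) are a reconstruction consistent with
the aggregated data, and the replayed totals are invariant to the split.
The safety rule stops the trial when a full cohort at the lowest dose all
experience DLTs; such a trial makes no MTD selection.

```{r replay}
replay_everolimus("CRM")
replay_everolimus("CIBP", a = 0.3)
```

The CRM path escalates after the clean first cohort (clipped to $d_2$ by
no-skip), holds at $d_2$ after one DLT (the coherence clip — the pooled
posterior means are $(0.165, 0.244, 0.329)$, whose unconstrained argmin is
$d_3$), escalates after a clean cohort, and unwinds after the all-DLT
cohort at $d_3$, ending with 21 patients and 10 DLTs.

For the CIBP design at $a = 0.3$ the posterior-expected divergence after
cohorts $\{d_1\!: 0/3,\ d_2\!: 1/3\}$ scores the three doses
$(0.112, 0.092, 0.136)$: it *holds* at $d_2$ rather than de-escalating.
De-escalation to $d_1$ at this state requires an effective asymmetry
parameter below about $0.15$; that threshold is robust to the prior scale,
to truncation and trimming of the posterior, to sampling-based evaluation,
and to the plug-in and absolute-distance variants. The replay above is the
faithful evaluation; readers comparing it with external accounts of this
illustration should be aware that de-escalation at $a = 0.3$ is not
reproducible from these inputs, and the package does not tune itself to
force it.

## The simulator

`simulate_oc()` crosses designs with scenarios, replays `n_reps` trials
per cell with per-replicate seeds derived deterministically from
`base_seed` (results are independent of execution order and of any worker
layout), and reports:

* per-dose selection probabilities $\pi_i$, with safety-stopped trials
  contributing *no selection* — this deflates the PCS and is reported
  separately as `prop_no_selection`;
* PCS, the fraction of replicates selecting the true MTD, with its
  binomial Monte-Carlo standard error;
* the accuracy index
  $\mathcal{A} = 1 - m \sum_i (p_i-\gamma)^2 \pi_i / \sum_i (p_i-\gamma)^2$,
  which weights wrong selections by how far their true toxicity sits from
  the target (1 for all mass at the target, 0 for uniform selection,
  negative when mass concentrates on the worst doses);
* mean DLT count and mean patients per dose, with standard errors.

Across scenarios, accuracy and PCS aggregate by geometric mean and DLT
counts by arithmetic mean; a negative accuracy index aborts geometric
aggregation with an explicit error rather than producing a complex number.

`generate_scenarios()` builds monotone dose--toxicity curves on the logit
scale with the designated MTD anchored exactly at $\gamma$ and jittered
logit steps between neighbors. It emulates the shape of realistic
single-agent toxicity curves (smooth, strictly increasing, one dose near
the target). It does not emulate plateaus, non-monotone curves,
patient-level covariates, or delayed/graded toxicities — so passing
simulation tests speak to allocation behavior under clean monotone
scenarios, not to robustness against model misspecification of those
kinds.

Package test runs use scaled-down problem sizes chosen to keep the whole
suite interactive while leaving Monte-Carlo error well below the effects
being tested: 500 replicates per cell for the safety-ordering and
CRM-equivalence properties (6 doses, 30 patients, $\gamma = 0.25$,
skeleton anchored at $d_2$ with half-width 0.05), and 60--240 replicates
for engine-level checks.

## Defaults that are package choices

Two comparator inputs are not pinned by published sources and are
explicit, documented package choices:

* the two-parameter logistic prior for the EWOC family and BLRM:
  bivariate normal with mean $(0, 1)$, covariance $\mathrm{diag}(4, 1)$,
  dose covariate the logit of the skeleton;
* the TDFB scale $S = 12$: the feasibility bound reaches its 0.50 cap
  after about twelve DLT-free patients, between the TR schedule's pace and
  a fixed bound. `S` has no reliable published value and is a required
  parameter of `tdfb_design()` in any serious comparison.

The TR and TDFB schedules are indexed by patient count: when a cohort is
allocated after $n$ patients, TR uses the bound of the incoming patient
$n + 1$ and TDFB uses its update computed from the $n$ patients observed.

## Limitations

* One-parameter pooling means early estimates move all doses together;
  the coherence constraint exists precisely because the pooled argmin can
  escalate at clinically awkward moments.
* Discrete doses only; no continuous-dose EWOC, no dose-combination or
  dose-schedule extensions, no time-to-event outcomes.
* The safety-stop convention (no selection) is one of two defensible
  accounting choices for stopped replicates; PCS values are not
  comparable across conventions, so the proportion of stopped trials is
  always reported alongside.
* Quadrature ranges are finite by construction; the divergence of the
  pre-DLT CIBP expectation means its absolute scale there is
  range-dependent even though the allocation ordering is stable.
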