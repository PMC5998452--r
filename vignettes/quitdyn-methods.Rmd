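---
title: "Methods: stage-of-change CTMC and compartmental ODE modelling"
author: "quitdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-of-change CTMC and compartmental ODE modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quitdyn)
```

`quitdyn` evaluates behaviour-change interventions from panel-observed
stage-of-readiness data in two modelling steps: a continuous-time Markov
chain (CTMC) for the observation window, and a linear compartmental ODE
parametrized from the CTMC curves for long-horizon analysis. This
vignette records the models, their assumptions, the parameter
conventions, and the numerical and design choices a maintainer would
want written down.

## Staging

Four stages are binned from two questionnaire items. A respondent who
reports no smoking in the past 7 days (not even part of a cigarette) is a
former smoker, stage 4, regardless of motivation. Otherwise a 0–10
motivation score maps 0–3 to unmotivated (1), 4–7 to indecisive (2), 8–10
to motivated (3). The cut points are arguments (`bins`), but the defaults
are the convention for this instrument. A missing motivation score is
acceptable only alongside a "no" smoking answer, because stage 4 does not
use it; a missing score for a current smoker is a hard error rather than
an imputation, since the pipeline deliberately has no imputation step —
subjects missing a wave are excluded in complete-case mode (the default)
and logged, or retained as partial sequences when `complete_case =
FALSE`, which the likelihood can use because it handles unequal
observation intervals.

Stage 4 is treated as absorbing. `censor_relapse()` truncates every
sequence at its first stage-4 observation: this removes the rare observed
relapses (reported via `relapses_removed`) and also the 4→4 pairs, which
carry probability 1 under the model and therefore contribute nothing to
the likelihood. A `drop_subject` mode removes relapsing subjects entirely
instead; truncation is the default because it keeps the subject's
informative pre-absorption transitions.

The 3-wave design observes at weeks 0, 12 and 26 — intervals of 12 and 14
weeks that the study convention treats as two nominal 13-week follow-ups.
`transition_counts()` therefore idealizes mixed wave spacing to the mean
grid spacing, flags the result (`nominal_interval`), and accepts an
explicit `interval` override. Fitting directly from a panel object
instead uses the exact per-pair intervals.

## The CTMC step

Stage occupancy is modelled as a time-homogeneous CTMC with generator
$Q = [q_{lk}]$: off-diagonal entries are nonnegative per-week rates, each
diagonal is minus its row sum, and the absorbing stage-4 row is zero. The
two structural assumptions — the Markov property and stationarity of the
transition process over the window — are not testable from 3 waves; the
package's operational check is that the simulator (`sample_ctmc_panel()`),
which generates data satisfying both by construction, is recovered by
`fit_ctmc()` within sampling error (the recovery and coverage tests).

Transition probabilities solve the Kolmogorov equations,
$P(t) = e^{tQ}$. The matrix exponential is a hand-rolled
scaling-and-squaring Padé (order 8) implementation, contract-tested to
1e-8 against a truncated power-series oracle; it handles the stiff
rate scales that appear later in the ODE step (order $10^3$–$10^4$ per
week) via the scaling step.

For equal-interval panels the sufficient statistic is the 4×4 interval
transition count matrix $n$, and the log-likelihood is
$\sum_{lk} n_{lk}\log P(\Delta)_{lk}$. The MLE is computed over
log-intensities (positivity for free, and matching the scale on which
confidence intervals are simulated), L-BFGS-B with gradient tolerance
1e-8, from a method-of-moments start plus log-normally perturbed
multi-starts (default 5, seeded). Rates are capped at $10^4$/week to keep
the surface bounded — the cap exceeds the largest published rate scale
(~3.7×10³) by a safe margin. Arrows with no supporting transitions are
driven to the lower boundary (≤1e-6); such parameters carry no curvature
in log space, so the covariance is computed from the inverse Hessian of
the *active* parameters only, with degenerate zero rows for the vanished
ones.

Sojourn times are $-1/q_{ll}$. Their standard errors and 95% bounds come
from the simulated multivariate-normal scheme — 1000 draws from
$N(\hat\theta, \hat\Sigma)$ on log-intensities, transformed to rates and
sojourns, percentile bounds — rather than the delta method, because the
percentile simulation is the convention this pipeline follows end to end.
A non-PSD covariance (possible after boundary handling) is repaired to
the nearest PSD matrix with a warning.

Model prevalence curves are $100\,\pi_0 P(t)$ for an initial stage mix
$\pi_0$ (by default each group's observed week-0 distribution), evaluated
weekly on $[0, 26]$.

## Efficacy and effectiveness

Efficacy is $\sigma_g(t) = F_g(t)/F_{max}$ with $F_{max}$ a single scalar
— the maximum former-smoker prevalence over all groups *and* grid times —
so the best group at its peak scores exactly 1. Effectiveness penalizes
adverse motivational shifts:
$$\rho_g(t) = \frac{\Delta F_g(t) - \alpha\,(\Delta U_g(t) - \Delta M_g(t))}{N_{max}},
\qquad \alpha = 0.20 \text{ by default.}$$

Two conventions here were genuinely open and are package decisions:

- **Δ is change from the week-0 baseline**, not week-over-week. All
  groups start with $F(0)=0$, so $\Delta F(t) = F(t)$ and the two metrics
  are directly comparable; week-over-week differencing would produce
  jagged, grid-dependent curves.
- **$N_{max}$ is global by default** (the maximum numerator across groups
  and times, one scalar), keeping each curve comparable along time. The
  alternative reading — renormalizing at every $t$ — is available as
  `normalization = "per-time"`.

$\rho$ may be negative (a group can be worse than its own baseline); an
all-groups-deteriorate configuration makes $N_{max} \le 0$ and is
reported as a degenerate-configuration error rather than silently
flipping signs.

## The ODE step

The compartmental model moves percentages among U, I, M with nine
nonnegative rates $d_{ij}$ (including flows $d_{i4}$ into the absorbing
former-smoker pool); $F$ takes the conservation remainder
$100 - U - I - M$. The system is linear, so the package simulates it
*exactly* as $x(t) = e^{tA}x_0$ — there is no integrator error and no
stiffness restriction, which matters because one published rate set has
rates of order $10^3$ per week (its fastest eigenvalue is about
−6353/week while its slowest is about −0.7/week, a 4-decade spread that
would force tiny steps in an explicit solver).

Rates are estimated by bounded least squares against target prevalence
curves (by default the CTMC's weekly curves on $[0,26]$, all four
compartments): lower bounds at zero, 20 seeded log-uniform multi-starts
because the 9-parameter surface is multi-modal, a coarse pass followed by
one tight polish of the best basin. The SSE is reported; large values
(the HE-like fixture fit has SSE in the hundreds) indicate curves the
linear model cannot track and are flagged with a warning, not hidden. A
caution on interpretation: exchange pairs such as $d_{23}/d_{32}$ are
only weakly identified from smooth curves — under added noise the
trajectory is recovered far more precisely than the individual rates (the
noisy-recovery test asserts rates to 20% but the trajectory to half a
percentage point RMS).

The 3×3 Jacobian $A$ has trace $-\sum_{ij} d_{ij}$ exactly (a test
invariant). Its eigenvalues classify the long run: all negative means the
trivial equilibrium $(0,0,0,100)$ is the unique, globally stable
equilibrium; a zero eigenvalue (within 1e-10 of the spectral scale) means
an under-determined system with a continuum of equilibria — the null
space of $A$ intersected with the nonnegative simplex, reported scaled to
percentages. The asymptotic state from a given start is the spectral
projection of $x_0$ onto the zero-eigenvalue subspace (with a
long-horizon propagation fallback if the eigenbasis is defective).
Averages over $[0,T]$ use the composite trapezoid on the simulation grid.
Time-to-absorption reports the first time the transient compartments stay
within $\epsilon$ of their asymptotic values; $\epsilon$ defaults to 0.5
percentage points — this convention is package-chosen (the published
year-scale figures do not state theirs, and are therefore not treated as
reproducible targets). A full-absorption query returns infinity whenever
the asymptotic former-smoker share is below $100 - \epsilon$.

One documented discrepancy: the published HE equilibrium
$(73.31, 0, 0, 26.68)$ is not derivable from the published HE rate triple
together with the week-0 initial condition — that rate set has no inflow
into M, and M(0)=0 at week 0, so the motivated-to-former flow never
activates and the trajectory's own limit puts no mass at 26.68. The
package computes the equilibrium *family* (which does contain such
states) and leaves the specific published point unreproduced rather than
tuning initial conditions toward it.

## Synthetic data

`sample_ctmc_panel()` generates exactly the world the estimators assume:
latent event-driven CTMC paths (exponential holding times, embedded jump
chain) observed only at grid weeks, per-group generators and initial
mixes, with optional injected missingness (a fixed fraction of subjects
lose one follow-up wave — mirroring the ~11–16% exclusion rates typical
of such trials) and optional relapse injection that exists solely to
exercise the censoring step. Seeds fully determine output. What a green
simulation test does *not* establish: robustness to non-Markov dynamics,
time-varying rates, or informative missingness — none of which the
generator emulates, by design, since the model itself assumes them away.

`study_fixtures()` bundles the published three-group margins, the three
resolved nine-rate sets, and a deterministic synthetic panel whose stage
margins match the printed counts at every wave via a block coupling
(individual transitions are synthetic; the true transition tables are not
in the public record). Two printed-table quirks are preserved rather than
smoothed over: the MI rows at the follow-up waves sum to 88 subjects
although n=87 is stated (the panel carries a documented 88th baseline
subject), and one MI percentage cell prints 7.9 where its count ratio is
7.95.

## Test and runtime conventions

Recovery-style checks use n = 2000 subjects and fixed seeds; the CI
coverage check runs 100 replicates with single-start fits (the recovery
design is well-conditioned, so multi-starts add runtime, not accuracy).
The acceptance-level eigenvalue checks are deterministic desk-scale
computations from the bundled rate tables.
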