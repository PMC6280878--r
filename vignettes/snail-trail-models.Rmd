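---
title: "Snail-trail models of corneal angiogenesis: automaton, continuum limit, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Snail-trail models of corneal angiogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snailtrail)
```

## The biological setting and the modelling idea

In the corneal assay, a source of tumor angiogenic factor (TAF) implanted in
the avascular cornea induces blood-vessel sprouting from the limbus, the
vessel-bearing rim of the eye. Migratory **tip cells (TCs)** lead each
sprout, moving by diffusion and chemotaxis up the TAF gradient; **stalk
(endothelial) cells, ECs** are laid down along the paths the tips have
traversed — the *snail-trail*. New tips appear by branching, which is
stimulated by TAF, and tips are lost when sprouts fuse: a tip meeting
another tip (*tip-to-tip anastomosis*) or a tip meeting an existing sprout
(*tip-to-sprout anastomosis*). Because cells have finite volume, a tip may
also simply be blocked by a cell in its way (*volume exclusion*).

`snailtrail` implements this process at two scales and connects them:

1. a stochastic lattice **cellular automaton** (CA) in which every cell
   occupies a site and every interaction is resolved agent by agent;
2. the one-dimensional **mean-field PDEs** for the column-averaged tip and
   stalk densities $N(x,t)$, $E(x,t)$ that follow from the automaton's
   transition probabilities when site occupancies are treated as
   independent;
3. an **RMSE calibration** layer that estimates the PDE parameters
   governing branching and anastomosis by fitting the PDEs to averaged CA
   ensembles — the route the mean-field derivation itself suggests whenever
   birth/death rates are large enough to build correlations between sites.

Two automaton variants are supported. In **Model 1** tips interact only
with tips (exclusion and tip-to-tip anastomosis); stalk-cell counts per
site are unbounded and never impede motion. In **Model 2** a site holds at
most one cell of either species, tips are excluded by stalk cells, and
tip-to-sprout anastomosis operates. Comparing the two isolates what
single-species versus two-species exclusion does to the macroscale
dynamics.

## The automaton

The lattice is $(R+1)\times(R+1)$ sites, $0 \le i, j \le R$, with spacing
$h = 1/R$; the limbus is the column $i=0$ and the TAF source sits beyond
$i=R$. Time advances in steps of $\tau$. All quantities are dimensionless
(space scaled by the limbus-to-source distance, time by the TAF diffusion
scale). The TAF field is prescribed, quasi-steady and linear, $c(x)=x$,
discretized $c_i = ih$; it is the simplest field consistent with a
diffusion-dominated source-to-limbus gradient and keeps the focus on cell
dynamics.

A tip at $(i,j)$ that is given a movement opportunity picks a von Neumann
neighbor with probabilities
$$P^{x\pm}_{i} = \tfrac14\left(1 \pm k\,(c_{i+1}-c_{i-1})\right), \qquad
  P^{y\pm} = \tfrac14,$$
so the walk is unbiased transversely and biased toward the source with
sensitivity $k$. At $i=0$ and $i=R$ the central difference uses the one
available neighbor; moves that would leave the lattice are aborted.

One discrete step is a **random sequential update** in two phases. With
$\bar N$ the tip count at the start of the step, phase 1 makes $\bar N$
movement selections: each selection draws a tip uniformly *with
replacement* from the currently-alive tips and offers it a move with
probability $P_m$. Phase 2 re-reads the tip count and makes that many
branching selections the same way. Selection with replacement is what makes
the per-capita event rates of the mean-field equations exact; tips killed
mid-phase leave the pool.

The movement outcome depends on the target:

* vacant — the tip relocates and deposits one EC at the origin (the
  snail-trail rule: an EC appears at every site a tip vacates);
* a tip — with probability $a_n$ both tips are removed and ECs appear at
  origin and target; otherwise the move is aborted (tip exclusion);
* an EC (Model 2) — if the EC belongs to the mover's own trail the move is
  aborted (self-loops are prohibited); otherwise with probability $a_e$ the
  mover is removed (tip-to-sprout anastomosis, EC at origin, target EC
  remains), else aborted (stalk exclusion).

Branching succeeds with probability $P_b = P_p c_i$ — linear in TAF, which
is what produces the *brush-border* rise of tip density near the source —
and requires **both** transverse neighbors $(i, j\pm1)$ vacant (no tip in
Model 1; no tip and no stalk cell in Model 2). The parent is replaced by
two daughters with fresh (empty) trails; no ECs are created. Requiring
both sites vacant, rather than placing a single daughter when one side is
blocked, is forced by the continuum limit: the branching source carries the
squared vacancy factor $(1-N-BE)^2$, i.e. two independent vacancy checks.
Daughters inheriting empty trails is the simplest reading of "an EC it has
left behind"; since a daughter starts where its parent stood, its first
moves are usually away from the parent trail and the choice is second
order.

Initial condition: tips at alternating sites $j = 1, 3, \dots, R-1$ of
column $i=0$ (so $R/2$ tips, forcing $R$ even), no ECs. Tips cannot cross
the lattice boundary.

Two engines implement these rules: a pure-R reference used by the
event-level tests, and a compiled engine used for production ensembles.
Both consume R's RNG stream in an identical documented order (selection,
movement gate, direction, at most one anastomosis draw; boundary aborts and
self-loop aborts consume no anastomosis draw), so their output is
bit-identical for the same seed — this equivalence is asserted in the test
suite. Realization $m$ of an ensemble is seeded `base_seed + m`.

## The continuum models

Averaging site occupancies over $M$ realizations and over the transverse
index (with the $1/(M(R+1))$ normalization), treating occupancies as
independent (the mean-field approximation), and Taylor-expanding to second
order in $h$ yields, with the model switch $B = 0$ (Model 1) or $1$
(Model 2):

$$\frac{\partial N}{\partial t}
 = D\,(1 - a_n N - B a_e E)\,N_{xx}
 - \chi\!\left[\big(N(1-N)c_x\big)_x + a_n N N_x c_x
   - B a_e E (N c_x)_x\right]
 - \mu\,(a_n N^2 + B a_e N E)
 + \lambda\, c\, N (1 - N - BE)^2,$$

$$\frac{\partial E}{\partial t}
 = \mu N (1 - N + 2 a_n N) - D (1 - 2a_n) N N_{xx}
 - \chi N \left[(1-a_n) c_x N_x + a_n (N c_x)_x\right],$$

with the coefficient maps
$$D = \frac{P_m h^2}{4\tau},\quad \chi = \frac{P_m k h^2}{\tau},\quad
  \mu = \frac{P_m}{\tau},\quad \lambda = \frac{P_p}{\tau},\quad
  t_{IC} = \tau K_{IC}.$$

Useful structure to keep in mind:

* $a_n = 0$, $B=0$: linear diffusion plus the non-linear chemotactic flux
  $\big(N(1-N)\big)_x$ — for the linear TAF field the advective factor is
  $(1-2N)$, a viscous-Burgers-type velocity that *decreases* with density,
  so a dense tip front steepens at the back;
* $a_n = 1$, $B=0$: the non-volume-excluding limit — $(1-N)$ premultiplies
  transport and the familiar $-\mu N^2$ tip-to-tip sink appears;
* the branching source is clamped to zero once maximum density is reached
  ($N \ge 1$ in Model 1, $N + E \ge 1$ in Model 2), which keeps the models
  well posed; the implementation uses $\max(0,\, 1-N-BE)^2$, which is the
  same statement.

The PDEs are seeded with the automaton's own column averages at
$t_{IC} = \tau K_{IC}$ (by default $t_{IC}=0.2$), avoiding the
discontinuous $t=0$ condition, and integrate with the no-flux condition
$D N_x - \chi N(1-(1-a_n)N)c_x = 0$ at $x = 0, 1$. The stalk equation
contains no spatial derivatives of $E$ and needs only an initial profile.

`meanfield_lattice_iterate()` iterates the column-averaged difference
equations *before* the Taylor expansion — deterministic, on the lattice —
and serves as an independent oracle: its output approaches `solve_pde()` as
$h, \tau \to 0$ at fixed $(D, \chi, \mu, \lambda)$, which the tests verify
by refinement.

### The linear comparator

The classical phenomenological snail-trail description is linear in $N$ in
its transport and branching terms. The comparator implemented in
`bc_rhs()`/`solve_bc()` is
$$N_t = D_{bc} N_{xx} - \chi_{bc} (N c_x)_x + \lambda_{bc}\, c N
  - \beta_n N^2 - \beta_e N E, \qquad
  E_t = \mu\, N + 2\beta_n N^2,$$
with five fitted parameters $(D_{bc}, \chi_{bc}, \lambda_{bc}, \beta_n,
\beta_e)$ and EC production pinned to the motility rate $\mu$. The
$2\beta_n N^2$ EC gain mirrors the two tips converted per tip-to-tip event
and can be switched off (`ec_tip_tip = FALSE`). This reconstruction
follows the published description of the modified model (linear transport
and branching, quadratic anastomosis sinks, EC evolution driven by
$\mu N$); the original source's exact appendix form was not available to
this implementation, so the comparator should be treated as a faithful
re-derivation, not a verbatim transcription — a caveat that matters only
for quantitative comparator-specific claims.

## Numerical choices

* **Spatial discretization.** Uniform grid of $R+1$ nodes co-located with
  the automaton columns, so CA profiles seed the PDEs without
  interpolation. Second-order central differences; the conservative
  chemotactic flux is differenced in flux form. The mixed term
  $\big(N(1-N)c_x\big)_x + a_n N N_x c_x$ is discretized in the
  algebraically equivalent blended form
  $(1-a_n)\big(N(1-N)c_x\big)_x + a_n (1-N)(N c_x)_x$, which is
  conservative in the pure-exclusion limit and reduces *exactly* (to
  machine precision, node by node) to the two special-case forms at
  $a_n = 0$ and $a_n = 1$ — the reduction-identity tests exploit this.
* **Boundaries.** Ghost nodes encode the no-flux condition to second
  order; for the comparator the ghost uses the linear flux
  $D_{bc}N_x - \chi_{bc}N c_x = 0$.
* **Time integration.** `deSolve::ode` (lsoda) with `atol = 1e-8`,
  `rtol = 1e-6`; output at $t = 0.2, 0.4, \dots, 2.0$ to match the
  standard recording grid. A solver failure inside a calibration objective
  (possible at pathological parameter corners, e.g. maximal branching with
  no sinks) is treated as a bad fit via a large penalty rather than an
  abort.
* **Mass bookkeeping.** With $\lambda = 0$, $a_n = 0$, $B = 0$ the scheme
  conserves tip mass to integrator accuracy while the pulse is away from
  the boundaries. For $a_n > 0$ exact conservation is not expected even in
  the continuum: the non-divergence diffusion prefactor contributes
  $+ D a_n \int N_x^2\,dx$ to $\tfrac{d}{dt}\int N\,dx$ alongside the
  $-\mu a_n \int N^2 dx$ sink, and the mass-audit test verifies the budget
  *including* that term.

## Calibration

The mean-field closure degrades when branching and anastomosis are fast
relative to motility ($P_p$ not $\ll P_m$, or $a_n$ substantial): these
processes build correlations between nearby sites that independent-site
equations cannot see. Rather than correcting the closure, the parameters
that *originate* from those processes — the branching rate
$\tilde\lambda$ and the anastomosis parameters $\tilde a_n$ (Model 1) or
$\tilde a_e$ (Model 2) — are re-estimated by fitting the PDEs to averaged
CA ensembles.

* **Metric.** Per species, $\mathrm{RMSE} = \sqrt{\frac{1}{n_x n_t}
  \sum_{t}\sum_{x}(\text{model}-\text{ensemble})^2}$ over the fit times
  $t = 0.4, \dots, 2.0$ (the $t_{IC} = 0.2$ profile is the initial
  condition, not data). The objective is
  $\mathrm{RMSE}_N + \mathrm{RMSE}_E$ with equal weights; the weights are
  exposed in `fit_spec()` because the aggregation is a modelling choice.
* **Search.** Deterministic and derivative-free: a 21-point-per-axis grid
  scan over the box (3 per axis plus the parameter-mapped point for the
  5-parameter comparator fit), then Nelder–Mead refinement with box
  projection (golden-section for one parameter), parameter tolerance
  $10^{-5}$. No stochastic restarts, so a fit is a pure function of its
  inputs.
* **Boxes.** $\tilde\lambda \in [0, P_p/\tau]$ — the parameter-mapped
  branching rate is the upper end (1.6, 6.4, 16 for
  $P_p = 10^{-2}, 4\times10^{-2}, 10^{-1}$); $\tilde a_n \in [0,1]$;
  $\tilde a_e \in (0,1]$, floored at $10^{-3}$. The comparator boxes
  ($D_{bc} \in [0,4D]$, $\chi_{bc} \in [0,2\chi]$,
  $\lambda_{bc} \in [0, P_p/\tau]$, $\beta_{n,e} \in [0,\mu]$) are this
  package's choices, anchored at the mapped values.
* **Uncertainty.** The $\pm$ companion of an estimate is interpreted as
  ensemble-to-ensemble repeat variability: `repeat_uncertainty()` re-runs
  the whole pipeline on disjoint seed blocks (5 repeats by default) and
  reports mean $\pm$ sd. It is not an optimizer confidence interval.

With the reference parameters ($R = 200$, $h = 1/200$, $P_m = 1$,
$k = 100$, $\tau = 1/160$, $K_{IC} = 32$, i.e. $D = 10^{-3}$,
$\chi = 0.4$, $\mu = 160$, $t_{IC} = 0.2$) and $M = 200$ realizations, the
Model 1 calibration at $P_p = 10^{-2}$ behaves as the derivation predicts:
at $a_n = 0.2$ the jointly fitted pair lands near
$(\tilde\lambda, \tilde a_n) \approx (1.2, 0.31)$ — the branching rate
pulled well below its mapped value 1.6 and the anastomosis parameter above
its microscale value, absorbing the correlation effects — and at
$a_n = 1$ the single-parameter fit lands around $\tilde\lambda \approx
0.8$–$1.0$ depending on the ensemble (the estimator for this case has
ensemble-to-ensemble standard deviation near 0.06 even at $M = 200$,
because the shallow objective is dominated by the stalk-cell profile,
whose Model 1 equation is only approximate). The acceptance script
(below) recomputes these numbers from scratch; the test suite asserts
them at tolerances commensurate with that variability plus the residual
sensitivity to micro-level conventions (see Limitations).

## What the generator emulates, and what it does not

The automaton ensemble *is* the synthetic data source: there is no
external data anywhere in the pipeline. The generator reproduces the study
conditions — lattice geometry, the linear TAF field, the alternating
limbus seeding, the two-phase sequential update, and the standard
recording grid $t = 0.2, \dots, 2.0$ over $M$ realizations. It does not
emulate features of real corneal assays that the underlying model itself
abstracts away: TAF consumption and dynamics, three-dimensional geometry,
sprout mechanics and perfusion, length-dependent branching rules, or
measurement noise of imaging pipelines. Tests passing against this
generator therefore validate the discrete-to-continuum reasoning and the
calibration machinery, not the biological fidelity of the automaton
itself.

## Problem sizes

The test suite runs the full $M = 200$, $R = 200$ ensemble protocol for
the headline calibration (ensembles are cheap; calibration cost is
dominated by PDE solves, which are independent of $M$), $M = 50$ for the
qualitative regime checks, $M = 10^4$ single-tip realizations for the
random-walk law, and small lattices ($R = 10$–$20$) for event-level and
property tests. The acceptance script runs the full $M = 200$ protocol for
all three reported quantities.

## Known limitations

* The printed reference values for the fitted parameters carry very small
  repeat standard deviations ($\approx 10^{-3}$); reproducing them to that
  precision would require matching the original implementation's
  micro-conventions exactly (selection scheme, phase population counts,
  trail bookkeeping, RMSE aggregation), several of which are
  under-determined by the published description. This package documents
  its choices and reproduces the values to a few percent.
* The comparator model is a reconstruction (see above).
* Mean-field closure failure is *the point* of the calibration layer, but
  it also means the unfitted PDEs should only be trusted in the
  low-branching, weak-anastomosis regime; the package makes no attempt at
  moment-closure corrections.
* For strong stalk-cell exclusion ($a_e \lesssim 0.1$ at high branching)
  neither continuum model captures the long left tails of the tip density;
  the tests assert the tail's existence in the automaton, not its capture
  by the PDEs.

## A minimal session

```{r example, eval = FALSE}
cfg <- ca_config(P_p = 1e-2, a_n = 0.2)          # reference microscale set
ens <- run_ensemble(cfg, M = 200, base_seed = 1,
                    record_K = seq(32, 320, 32)) # t = 0.2 ... 2.0
sp  <- fit_spec("model1", fixed = map_parameters(cfg),
                free = default_bounds(cfg, c("lam", "a_n")))
fit <- fit_parameters(sp, ens)
fit
```
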