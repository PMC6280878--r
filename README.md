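# snailtrail

Multiscale modelling of corneal angiogenesis: a stochastic lattice
cellular automaton of tip-cell migration with volume exclusion, the
one-dimensional non-linear mean-field PDEs derived from it, and an
RMSE-based calibration that fits the continuum models to averaged
automaton ensembles.

## Who this is for

Researchers in mathematical biology studying how microscale cell-level
rules (exclusion, anastomosis, branching) shape macroscale vessel-density
dynamics, and anyone who needs a reproducible discrete-to-continuum
pipeline: simulate an agent-based model, average it, derive/solve the
matched PDEs, and quantify where the mean-field closure fails.

## The models

**Automaton.** On an `(R+1) x (R+1)` lattice with spacing `h = 1/R`, tip
cells (TCs) start at alternating sites of the limbus column `i = 0` and
perform biased random walks up a prescribed linear tumor-angiogenic-factor
field `c(x) = x`, with movement probabilities
`P^{x±} = (1 ± k (c_{i+1} − c_{i−1}))/4`, `P^{y±} = 1/4`. Every site a TC
vacates receives a stalk cell (EC) — the *snail-trail*. A TC stepping onto
a TC annihilates both with probability `a_n` (tip-to-tip anastomosis),
else the move aborts (volume exclusion); in Model 2 a TC stepping onto a
foreign EC is removed with probability `a_e` (tip-to-sprout), else
excluded, and moves onto its own trail are always aborted (no self-loops).
TCs branch into both transverse neighbors with probability `P_b = P_p c`
when both are vacant.

**Continuum limit.** Column-averaging and a mean-field closure give, with
`B = 0` (Model 1, TC-only exclusion) or `B = 1` (Model 2),

    N_t = D (1 − a_n N − B a_e E) N_xx
          − χ [ (N(1−N) c_x)_x + a_n N N_x c_x − B a_e E (N c_x)_x ]
          − μ (a_n N² + B a_e N E) + λ c N (1 − N − B E)²
    E_t = μ N (1 − N + 2 a_n N) − D (1 − 2 a_n) N N_xx
          − χ N [ (1 − a_n) c_x N_x + a_n (N c_x)_x ]

with `D = P_m h²/(4τ)`, `χ = P_m k h²/τ`, `μ = P_m/τ`, `λ = P_p/τ`,
no-flux boundaries, and automaton column averages at `t_IC = τ K_IC` as
initial data. A linear snail-trail comparator (the classical
Byrne–Chaplain form: linear transport and branching, quadratic anastomosis
sinks) is included as the fitting baseline.

**Calibration.** Because high branching/anastomosis rates build
correlations that break the mean-field closure, the parameters that stem
from those processes (`λ`, `a_n`, `a_e`; five parameters for the
comparator) are estimated by minimizing the combined TC + EC RMSE between
PDE solutions and averaged ensembles over `t = 0.4 … 2.0`, with a
deterministic grid-scan + Nelder–Mead search inside the standard boxes
(`λ ∈ [0, P_p/τ]`, `a_n ∈ [0,1]`, `a_e ∈ (0,1]`).

## Worked example

```r
library(snailtrail)

cfg <- ca_config(P_p = 1e-2, a_n = 0.2)   # reference microscale parameters
map_parameters(cfg)
#> continuum_params (Model 1): D = 0.001, chi = 0.4, mu = 160, lam = 1.6
#>   a_n = 0.2, a_e = 0, t_IC = 0.2

ens <- run_ensemble(cfg, M = 200, base_seed = 1,
                    record_K = seq(32, 320, by = 32))  # t = 0.2 ... 2.0
ens
#> ensemble_summary: M = 200 realizations, R = 200 columns, 10 times (t = 0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0)
#>   final TC mass 0.0018, EC mass 0.4784

sp  <- fit_spec("model1", fixed = map_parameters(cfg),
                free = default_bounds(cfg, c("lam", "a_n")))
fit <- fit_parameters(sp, ens)
fit
#> fit_result (model1)
#>   lam = 1.19571  (bounds [0, 1.6])
#>   a_n = 0.309163  (bounds [0, 1])
#>   rmse_N = 0.00020802, rmse_E = 0.0043974, 540 objective evaluations
```

Read: the automaton was run at branching scale `P_p = 1e-2` (mapped
branching rate 1.6) and tip-to-tip probability 0.2, but the PDE that best
matches the averaged ensemble needs a *smaller* branching rate
(`λ̃ ≈ 1.20`) and a *larger* anastomosis parameter (`ã_n ≈ 0.31`): the
fitted values absorb the site-to-site correlations that the mean-field
derivation ignores. The per-species RMSEs (≈ 2e-4 for tips, 4e-3 for
stalk cells, densities on [0, 1]) say the calibrated PDE tracks the
ensemble closely at every recorded time.

A command-line front end over the same functions is installed at
`inst/cli/snailtrail` (subcommands `simulate`, `solve`, `fit`,
`compare`).

## Package layout

- `R/ca_config.R`, `R/ca_engine.R`, `src/ca_engine.cpp` — automaton
  (validated configuration, pure-R reference engine, compiled engine;
  bit-identical RNG streams)
- `R/averaging.R` — ensemble/column averaging, mass metric
- `R/continuum.R` — coefficient maps, mean-field PDEs, lattice mean-field
  iteration (independent oracle)
- `R/bc_model.R` — linear comparator
- `R/calibration.R` — RMSE, bounded fitting, repeat uncertainty
- `R/io.R` — `(t, x, N, E)` tables, configs, snapshot and fit
  serialization
- `vignettes/snail-trail-models.Rmd` — model derivation, numerical and
  design choices, limitations
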