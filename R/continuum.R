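#' Macroscale parameters of the continuum models
#'
#' Container for the coefficients of the one-dimensional mean-field PDEs for
#' the column-averaged TC density `N(x, t)` and EC density `E(x, t)`:
#'
#' \deqn{N_t = D (1 - a_n N - B a_e E) N_{xx}
#'   - \chi [ (N (1 - N) c_x)_x + a_n N N_x c_x - B a_e E (N c_x)_x ]
#'   - \mu (a_n N^2 + B a_e N E) + \lambda c N (1 - N - B E)^2}
#' \deqn{E_t = \mu N (1 - N + 2 a_n N) - D (1 - 2 a_n) N N_{xx}
#'   - \chi N [ (1 - a_n) c_x N_x + a_n (N c_x)_x ]}
#'
#' with `c(x) = x` the linear TAF field. `B = 0` selects Model 1 (TC-only
#' exclusion/anastomosis) and `B = 1` Model 2 (TC and EC exclusion,
#' tip-to-sprout anastomosis). The branching term is clamped to zero once the
#' maximum density is reached (`N >= 1` for Model 1, `N + E >= 1` for
#' Model 2), which keeps the models well posed.
#'
#' @param D Diffusion coefficient.
#' @param chi Chemotactic coefficient.
#' @param mu Motility rate.
#' @param lam Branching rate.
#' @param a_n Tip-to-tip anastomosis parameter in `[0, 1]`.
#' @param a_e Tip-to-sprout anastomosis parameter in `[0, 1]` (enters only
#'   when `B = 1`).
#' @param B Model indicator, 0 (Model 1) or 1 (Model 2).
#' @param t_IC Initialization time: the continuum models are seeded with
#'   column-averaged automaton profiles recorded at this time.
#' @return An object of class `continuum_params`.
#' @seealso [map_parameters()], [solve_pde()], [model_rhs()]
#' @export
continuum_params <- function(D, chi, mu, lam, a_n = 0, a_e = 0, B = 0L,
                             t_IC = 0) {
  stopifnot(D >= 0, mu >= 0, lam >= 0, a_n >= 0, a_n <= 1,
            a_e >= 0, a_e <= 1, B %in% c(0L, 1L))
  structure(list(D = D, chi = chi, mu = mu, lam = lam,
                 a_n = a_n, a_e = a_e, B = as.integer(B), t_IC = t_IC),
            class = "continuum_params")
}

#' @export
print.continuum_params <- function(x, ...) {
  cat(sprintf("continuum_params (Model %d): D = %g, chi = %g, mu = %g, lam = %g\n",
              x$B + 1L, x$D, x$chi, x$mu, x$lam))
  cat(sprintf("  a_n = %g, a_e = %g, t_IC = %g\n", x$a_n, x$a_e, x$t_IC))
  invisible(x)
}

#' Map microscale automaton parameters to macroscale coefficients
#'
#' The discrete-to-continuum coefficient maps:
#' `D = P_m h^2 / (4 tau)`, `chi = P_m k h^2 / tau`, `mu = P_m / tau`,
#' `lam = P_p / tau`, and `t_IC = tau * K_IC`. Note `chi / D = 4 k`
#' independently of `P_m`, `h` and `tau`. For the reference parameter set
#' (`R = 200`, `h = 1/200`, `P_m = 1`, `k = 100`, `tau = 1/160`,
#' `K_IC = 32`): `D = 1e-3`, `chi = 0.4`, `mu = 160`, `t_IC = 0.2`, and
#' `P_p = 1e-2` gives `lam = 1.6`.
#'
#' @param config A [ca_config()].
#' @return A [continuum_params()] with `a_n`, `a_e` and `B` copied from the
#'   configuration (`a_e = 0`, `B = 0` for Model 1).
#' @examples
#' map_parameters(ca_config()) # D = 1e-3, chi = 0.4, mu = 160
#' @export
map_parameters <- function(config) {
  if (config$tau <= 0) stop("tau must be positive", call. = FALSE)
  continuum_params(D = config$P_m * config$h^2 / (4 * config$tau),
                   chi = config$P_m * config$k * config$h^2 / config$tau,
                   mu = config$P_m / config$tau,
                   lam = config$P_p / config$tau,
                   a_n = config$a_n,
                   a_e = if (config$mode == 2L) config$a_e else 0,
                   B = if (config$mode == 2L) 1L else 0L,
                   t_IC = config$tau * config$K_IC)
}

#' TAF profile on a continuum grid
#'
#' The linear TAF field `c(x) = x` with unit gradient, evaluated on a grid.
#'
#' @param x Grid nodes.
#' @return List with `x`, `c` and `dcdx`.
#' @export
taf_profile <- function(x) list(x = x, c = x, dcdx = rep(1, length(x)))

# Ghost-extend a TC profile to second order using the no-flux condition
# D N_x - chi N (1 - (1 - a_n) N) c_x = 0 at x = 0, 1.
.ghost_extend <- function(N, h, D, chi, a_n, dcdx) {
  n <- length(N)
  g <- function(Nb) Nb * (1 - (1 - a_n) * Nb)
  s0 <- if (D > 0) (chi / D) * g(N[1L]) * dcdx[1L] else 0
  s1 <- if (D > 0) (chi / D) * g(N[n]) * dcdx[n] else 0
  c(N[2L] - 2 * h * s0, N, N[n - 1L] + 2 * h * s1)
}

#' Right-hand side of the mean-field PDEs
#'
#' Evaluates the spatial semi-discretization of the Model 1 / Model 2 PDEs
#' (see [continuum_params()]) on a uniform grid: second-order central
#' differences, with the conservative chemotactic flux differenced in flux
#' form and the no-flux boundary condition encoded through ghost nodes. The
#' branching source uses the clamped vacancy factor `max(0, 1 - N - B E)^2`,
#' which also implements the rule that branching ceases at maximum density.
#'
#' @param N,E Density profiles on a shared uniform grid over `[0, 1]`.
#' @param params A [continuum_params()].
#' @param taf TAF profile from [taf_profile()] on the same grid (defaults to
#'   the linear field).
#' @return List with `dN` and `dE`, the time derivatives.
#' @export
model_rhs <- function(N, E, params, taf = NULL) {
  n <- length(N)
  if (length(E) != n) stop("N and E grids differ", call. = FALSE)
  if (is.null(taf)) taf <- taf_profile(seq(0, 1, length.out = n))
  if (length(taf$c) != n) stop("TAF grid does not match profiles", call. = FALSE)
  h <- 1 / (n - 1)
  D <- params$D; chi <- params$chi; mu <- params$mu; lam <- params$lam
  a_n <- params$a_n; B <- params$B
  ae <- if (B == 1L) params$a_e else 0
  dcdx <- taf$dcdx

  Ng <- .ghost_extend(N, h, D, chi, a_n, dcdx)
  tg <- c(dcdx[1L], dcdx, dcdx[n])
  lo <- 1:n; hi <- 3:(n + 2L)
  Nx <- (Ng[hi] - Ng[lo]) / (2 * h)
  Nxx <- (Ng[hi] - 2 * N + Ng[lo]) / h^2
  F1 <- Ng * (1 - Ng) * tg           # conservative chemotactic flux N(1-N)c_x
  F1x <- (F1[hi] - F1[lo]) / (2 * h)
  G <- Ng * tg                       # N c_x
  Gx <- (G[hi] - G[lo]) / (2 * h)

  cap <- pmax(0, 1 - N - B * E)
  # The chemotactic operator (N(1-N)c_x)_x + a_n N N_x c_x is discretized in
  # the algebraically equivalent blended form
  # (1-a_n) (N(1-N)c_x)_x + a_n (1-N)(N c_x)_x, which is conservative in the
  # pure-exclusion limit a_n = 0 and reduces term-by-term to the
  # non-volume-excluding form at a_n = 1.
  dN <- D * (1 - a_n * N - B * ae * E) * Nxx -
    chi * ((1 - a_n) * F1x + a_n * (1 - N) * Gx - B * ae * E * Gx) -
    mu * (a_n * N^2 + B * ae * N * E) +
    lam * taf$c * N * cap^2
  dE <- mu * N * (1 - N + 2 * a_n * N) -
    D * (1 - 2 * a_n) * N * Nxx -
    chi * N * ((1 - a_n) * dcdx * Nx + a_n * Gx)
  list(dN = dN, dE = dE)
}

#' Solve the mean-field PDEs
#'
#' Method-of-lines integration of the Model 1 / Model 2 PDEs with the no-flux
#' boundary condition `D N_x - chi N (1 - (1 - a_n) N) c_x = 0` at
#' `x = 0, 1` (the EC equation contains spatial derivatives of `N` only and
#' needs no boundary condition). The initial profiles are typically the
#' column-averaged automaton densities at `t_IC`.
#'
#' @param params A [continuum_params()].
#' @param N_ic,E_ic Initial profiles on a uniform grid over `[0, 1]`.
#' @param t_out Increasing output times, all `>= params$t_IC`.
#' @param taf Optional [taf_profile()] (defaults to the linear field).
#' @param atol,rtol Absolute/relative integration tolerances.
#' @return An object of class `pde_solution`: list with `x`, `times`
#'   (`t_IC` followed by `t_out`), matrices `N`, `E` (`length(x)` rows, one
#'   column per time), per-time trapezoidal masses `mass_N`, `mass_E`, and
#'   the solver diagnostics `istate`.
#' @examples
#' p <- continuum_params(D = 1e-3, chi = 0, mu = 0, lam = 0, t_IC = 0)
#' x <- seq(0, 1, length.out = 51)
#' sol <- solve_pde(p, exp(-100 * (x - 0.5)^2), rep(0, 51), t_out = 0.5)
#' @export
solve_pde <- function(params, N_ic, E_ic, t_out, taf = NULL,
                      atol = 1e-8, rtol = 1e-6) {
  n <- length(N_ic)
  stopifnot(length(E_ic) == n)
  t_out <- sort(unique(as.numeric(t_out)))
  if (any(t_out < params$t_IC - 1e-12))
    stop("output times must not precede t_IC", call. = FALSE)
  x <- seq(0, 1, length.out = n)
  if (is.null(taf)) taf <- taf_profile(x)
  times <- unique(c(params$t_IC, t_out))
  rhs <- function(t, y, p) {
    d <- model_rhs(y[1:n], y[(n + 1):(2 * n)], params, taf)
    list(c(d$dN, d$dE))
  }
  out <- deSolve::ode(y = c(N_ic, E_ic), times = times, func = rhs,
                      parms = NULL, method = "lsoda", atol = atol, rtol = rtol)
  if (attr(out, "istate")[1L] < 0)
    stop("PDE integration failed (istate = ", attr(out, "istate")[1L],
         "); try smaller tolerances or a finer grid", call. = FALSE)
  .as_pde_solution(out, x, n, params)
}

.as_pde_solution <- function(out, x, n, params) {
  times <- out[, 1L]
  N <- t(out[, 1L + (1:n), drop = FALSE])
  E <- t(out[, 1L + n + (1:n), drop = FALSE])
  structure(list(x = x, times = times, N = N, E = E,
                 mass_N = apply(N, 2L, total_mass, x = x),
                 mass_E = apply(E, 2L, total_mass, x = x),
                 params = params,
                 istate = attr(out, "istate")),
            class = "pde_solution")
}

#' @export
print.pde_solution <- function(x, ...) {
  nt <- length(x$times)
  cat(sprintf("pde_solution: %d nodes, t in [%g, %g] (%d outputs)\n",
              length(x$x), x$times[1L], x$times[nt], nt))
  cat(sprintf("  final masses: N %.4f, E %.4f\n", x$mass_N[nt], x$mass_E[nt]))
  invisible(x)
}

#' Deterministic column-averaged mean-field iteration
#'
#' Iterates the column-averaged difference equations of the automaton under
#' the mean-field (site independence) approximation, exactly as they stand
#' before the Taylor expansion that produces the PDEs. Per discrete step, on
#' the column grid `i = 0..R` with movement probabilities
#' `P^{x+-}_i` from [direction_probabilities()]:
#'
#' * movement in from the flanking columns with surviving-arrival factor
#'   `(1 - N_i - B a_e E_i)`, plus the within-column transverse attempts at
#'   combined rate 1/2 with the same factor;
#' * movement out impeded only by TC exclusion, with availability factor
#'   `(1 - (1 - a_n) N_target)` (the tip-to-sprout derivation takes
#'   `a_e = 1`, retaining `a_e` in the anastomosis penalties only);
#'   attempts across the lattice boundary abort;
#' * net branching `P_p c_i N_i (1 - N_i - B E_i)^2`;
#' * EC gain from every successful departure plus tip-to-tip conversions
#'   `a_n` times the arrival attempt rate times `N_i`.
#'
#' Restricted to the transversely-uniform linear TAF field. Serves as an
#' independent oracle for [solve_pde()]: at matched macroscale coefficients
#' the two agree in the limit of vanishing `h` and `tau`.
#'
#' @param config A [ca_config()] supplying `R`, `h`, `P_m`, `k`, `P_p`,
#'   `a_n`, `a_e`, `mode`.
#' @param N0,E0 Initial column profiles of length `R + 1`.
#' @param K_steps Number of discrete steps to iterate.
#' @param record_K Steps at which to record (default: all up to `K_steps`).
#' @return List with `K` (recorded steps), and `(R+1) x length(K)` matrices
#'   `N`, `E`.
#' @export
meanfield_lattice_iterate <- function(config, N0, E0, K_steps,
                                      record_K = K_steps) {
  R <- config$R
  n <- R + 1L
  stopifnot(length(N0) == n, length(E0) == n)
  record_K <- as.integer(record_K)
  stopifnot(all(record_K >= 0L), all(record_K <= K_steps))
  mp <- column_move_probs(config)
  pxp <- mp$xp; pxm <- mp$xm; cg <- mp$c
  Pm <- config$P_m; Pp <- config$P_p; a_n <- config$a_n
  B <- if (config$mode == 2L) 1 else 0
  ae <- if (config$mode == 2L) config$a_e else 0
  N <- as.numeric(N0); E <- as.numeric(E0)
  Nout <- matrix(0, n, length(record_K))
  Eout <- matrix(0, n, length(record_K))
  slot <- 1L
  rec <- function(K) {
    while (slot <= length(record_K) && record_K[slot] == K) {
      Nout[, slot] <<- N
      Eout[, slot] <<- E
      slot <<- slot + 1L
    }
  }
  rec(0L)
  for (K in seq_len(K_steps)) {
    # arrivals from flanking columns (dropped at the boundary columns)
    inL <- c(0, pxp[1:(n - 1L)] * N[1:(n - 1L)])
    inR <- c(pxm[2:n] * N[2:n], 0)
    survive <- 1 - N - B * ae * E
    move_in <- Pm * (inL + inR) * survive + Pm * 0.5 * N * survive
    # departures: target availability 1 - (1 - a_n) N_target; boundary aborts
    availR <- c(1 - (1 - a_n) * N[2:n], 0)
    availL <- c(0, 1 - (1 - a_n) * N[1:(n - 1L)])
    dep <- Pm * N * (pxp * availR + pxm * availL + 0.5 * (1 - (1 - a_n) * N))
    branch <- Pp * cg * N * pmax(0, 1 - N - B * E)^2
    tip_tip_ec <- Pm * a_n * N * (inL + inR + 0.5 * N)
    Nnew <- N + move_in - dep + branch
    Enew <- E + dep + tip_tip_ec
    N <- Nnew; E <- Enew
    rec(K)
  }
  list(K = record_K, N = Nout, E = Eout,
       x = (0:R) * config$h, times = record_K * config$tau)
}
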