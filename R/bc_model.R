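#' Parameters of the linear snail-trail comparator (BC model)
#'
#' The comparator is a phenomenological snail-trail model in the
#' Byrne–Chaplain tradition, linear in `N` in its diffusive, chemotactic and
#' branching terms, with quadratic anastomosis sinks:
#'
#' \deqn{N_t = D_{bc} N_{xx} - \chi_{bc} (N c_x)_x + \lambda_{bc} c N
#'   - \beta_n N^2 - \beta_e N E}
#' \deqn{E_t = \mu_{ec} N + 2 \beta_n N^2}
#'
#' EC production is `mu_ec * N` (the non-volume-excluding snail-trail rate);
#' the optional `2 beta_n N^2` EC gain accounts for the two TCs converted per
#' tip-to-tip event and can be toggled off. All five transport/interaction
#' parameters are free in the standard fitting setup; `mu_ec` is held at the
#' motility rate `mu` mapped from the automaton configuration.
#'
#' @param D_bc Diffusion coefficient, >= 0.
#' @param chi_bc Chemotactic coefficient, >= 0.
#' @param lam_bc Branching rate, >= 0.
#' @param beta_n Tip-to-tip sink rate, >= 0.
#' @param beta_e Tip-to-sprout sink rate, >= 0.
#' @param mu_ec EC production rate, >= 0.
#' @param t_IC Initialization time.
#' @param ec_tip_tip Logical; include the `2 beta_n N^2` EC source.
#' @return An object of class `bc_params`.
#' @export
bc_params <- function(D_bc, chi_bc, lam_bc, beta_n = 0, beta_e = 0,
                      mu_ec = 0, t_IC = 0, ec_tip_tip = TRUE) {
  stopifnot(D_bc >= 0, chi_bc >= 0, lam_bc >= 0, beta_n >= 0, beta_e >= 0,
            mu_ec >= 0)
  structure(list(D_bc = D_bc, chi_bc = chi_bc, lam_bc = lam_bc,
                 beta_n = beta_n, beta_e = beta_e, mu_ec = mu_ec,
                 t_IC = t_IC, ec_tip_tip = isTRUE(ec_tip_tip)),
            class = "bc_params")
}

#' @export
print.bc_params <- function(x, ...) {
  cat(sprintf("bc_params: D = %g, chi = %g, lam = %g, beta_n = %g, beta_e = %g, mu_ec = %g\n",
              x$D_bc, x$chi_bc, x$lam_bc, x$beta_n, x$beta_e, x$mu_ec))
  invisible(x)
}

#' Right-hand side of the BC comparator model
#'
#' Same discretization conventions as [model_rhs()]: central differences,
#' ghost nodes encoding the linear no-flux condition
#' `D_bc N_x - chi_bc N c_x = 0` at `x = 0, 1`.
#'
#' @inheritParams model_rhs
#' @param params A [bc_params()].
#' @return List with `dN` and `dE`.
#' @export
bc_rhs <- function(N, E, params, taf = NULL) {
  n <- length(N)
  if (length(E) != n) stop("N and E grids differ", call. = FALSE)
  if (is.null(taf)) taf <- taf_profile(seq(0, 1, length.out = n))
  if (length(taf$c) != n) stop("TAF grid does not match profiles", call. = FALSE)
  h <- 1 / (n - 1)
  # a_n = 1 in the ghost extension makes the boundary flux linear in N
  Ng <- .ghost_extend(N, h, params$D_bc, params$chi_bc, 1, taf$dcdx)
  tg <- c(taf$dcdx[1L], taf$dcdx, taf$dcdx[n])
  lo <- 1:n; hi <- 3:(n + 2L)
  Nxx <- (Ng[hi] - 2 * N + Ng[lo]) / h^2
  G <- Ng * tg
  Gx <- (G[hi] - G[lo]) / (2 * h)
  dN <- params$D_bc * Nxx - params$chi_bc * Gx + params$lam_bc * taf$c * N -
    params$beta_n * N^2 - params$beta_e * N * E
  dE <- params$mu_ec * N +
    (if (params$ec_tip_tip) 2 * params$beta_n * N^2 else 0)
  list(dN = dN, dE = dE)
}

#' Solve the BC comparator model
#'
#' Method-of-lines integration of the linear comparator with the same solver
#' machinery and output container as [solve_pde()].
#'
#' @param params A [bc_params()].
#' @inheritParams solve_pde
#' @return A `pde_solution`.
#' @export
solve_bc <- function(params, N_ic, E_ic, t_out, taf = NULL,
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
    d <- bc_rhs(y[1:n], y[(n + 1):(2 * n)], params, taf)
    list(c(d$dN, d$dE))
  }
  out <- deSolve::ode(y = c(N_ic, E_ic), times = times, func = rhs,
                      parms = NULL, method = "lsoda", atol = atol, rtol = rtol)
  if (attr(out, "istate")[1L] < 0)
    stop("BC model integration failed (istate = ", attr(out, "istate")[1L],
         ")", call. = FALSE)
  .as_pde_solution(out, x, n, params)
}

#' Map automaton parameters onto the BC comparator
#'
#' Anchors the comparator at the automaton's own macroscale coefficients:
#' `D_bc = D`, `chi_bc = chi`, `lam_bc = lam`, `beta_n = mu * a_n`,
#' `beta_e = mu * a_e * B`, `mu_ec = mu`. This is the natural starting point
#' for fitting the five free comparator parameters.
#'
#' @param params A [continuum_params()] (typically [map_parameters()] output).
#' @return A [bc_params()].
#' @export
bc_from_continuum <- function(params) {
  bc_params(D_bc = params$D, chi_bc = params$chi, lam_bc = params$lam,
            beta_n = params$mu * params$a_n,
            beta_e = params$mu * params$a_e * params$B,
            mu_ec = params$mu, t_IC = params$t_IC)
}

#' Default search boxes for the five BC parameters
#'
#' Boxes anchored at the parameter-mapped values: `D_bc` in `[0, 4 D]`,
#' `chi_bc` in `[0, 2 chi]`, `lam_bc` in `[0, P_p / tau]`, and the
#' anastomosis sink rates in `[0, mu]`.
#'
#' @param config A [ca_config()].
#' @return Named list of bounds usable as `free` in [fit_spec()].
#' @export
bc_default_bounds <- function(config) {
  p <- map_parameters(config)
  list(D_bc = c(0, 4 * p$D), chi_bc = c(0, 2 * p$chi),
       lam_bc = c(0, p$lam), beta_n = c(0, p$mu), beta_e = c(0, p$mu))
}
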