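#' Root-mean-square error between a model solution and an ensemble
#'
#' Per species, the root of the mean squared pointwise difference over all
#' `(x, t)` pairs with `t` in `times`:
#' `RMSE = sqrt( (1 / (n_x n_t)) sum_t sum_x (model - ensemble)^2 )`.
#'
#' @param model A `pde_solution` (from [solve_pde()] or [solve_bc()]).
#' @param ens An [ensemble_summary].
#' @param times Times over which to compare; must be present (to within
#'   `1e-9`) in both inputs.
#' @return Named numeric vector `c(rmse_N, rmse_E)`.
#' @examples
#' # identical inputs give (0, 0); a constant offset d gives rmse = |d|
#' @export
rmse <- function(model, ens, times) {
  if (length(model$x) != length(ens$x))
    stop("model and ensemble grids differ", call. = FALSE)
  im <- match_times(times, model$times)
  ie <- match_times(times, ens$times)
  dN <- model$N[, im, drop = FALSE] - ens$N[, ie, drop = FALSE]
  dE <- model$E[, im, drop = FALSE] - ens$E[, ie, drop = FALSE]
  c(rmse_N = sqrt(mean(dN^2)), rmse_E = sqrt(mean(dE^2)))
}

match_times <- function(times, available, tol = 1e-9) {
  idx <- vapply(times, function(t) {
    k <- which(abs(available - t) <= tol)
    if (length(k) == 0L)
      stop("time ", t, " not present (available: ",
           paste(format(available), collapse = ", "), ")", call. = FALSE)
    k[1L]
  }, integer(1L))
  idx
}

#' Specify a bounded calibration problem
#'
#' Describes which continuum parameters are estimated by fitting a model to a
#' column-averaged automaton ensemble, and over which box. The standard
#' search boxes follow the fitting protocol: the branching rate
#' `lam` is searched over `[0, P_p / tau]` (its parameter-mapped value is the
#' upper end), `a_n` over `[0, 1]`, and `a_e` over `(0, 1]` (floored at
#' `1e-3`). The five BC parameters default to boxes anchored at their
#' parameter-mapped analogues.
#'
#' @param model One of `"model1"`, `"model2"`, `"bc"`.
#' @param fixed The full parameter object holding every non-free value: a
#'   [continuum_params()] for the PDE models, a [bc_params()] for the
#'   comparator. Typically [map_parameters()] output.
#' @param free Named list of length-2 numeric bounds, e.g.
#'   `list(lam = c(0, 1.6), a_n = c(0, 1))`. Free names must be parameters of
#'   the chosen model.
#' @param fit_times Times entering the objective (default `0.4, ..., 2.0`).
#' @param weights Length-2 weights combining `(rmse_N, rmse_E)` into the
#'   scalar objective (default equal).
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(model = c("model1", "model2", "bc"), fixed, free,
                     fit_times = seq(0.4, 2.0, by = 0.2),
                     weights = c(1, 1)) {
  model <- match.arg(model)
  valid <- if (model == "bc") {
    c("D_bc", "chi_bc", "lam_bc", "beta_n", "beta_e")
  } else {
    c("lam", "a_n", "a_e")
  }
  if (length(free) == 0L) stop("at least one free parameter", call. = FALSE)
  if (!all(names(free) %in% valid))
    stop("free parameters for ", model, " must be among: ",
         paste(valid, collapse = ", "), call. = FALSE)
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || b[1L] > b[2L])
      stop("bounds for ", nm, " must be c(lo, hi) with lo <= hi",
           call. = FALSE)
    if (nm == "a_e" && b[1L] < 1e-3)
      free[[nm]][1L] <- 1e-3 # half-open bound (0, 1] floored
  }
  structure(list(model = model, fixed = fixed, free = free,
                 fit_times = as.numeric(fit_times),
                 weights = as.numeric(weights)),
            class = "fit_spec")
}

.apply_theta <- function(spec, theta) {
  p <- spec$fixed
  p[names(theta)] <- as.list(unname(theta))
  p
}

.solve_for_fit <- function(spec, params, N0, E0) {
  if (spec$model == "bc") {
    solve_bc(params, N0, E0, t_out = spec$fit_times)
  } else {
    solve_pde(params, N0, E0, t_out = spec$fit_times)
  }
}

#' Fit continuum parameters to an averaged ensemble
#'
#' Minimizes the weighted combined RMSE (TC plus EC) between the model
#' solution, seeded with the ensemble profile at `t_IC`, and the ensemble
#' over the fit times, within the search box of the [fit_spec()]. The search
#' is deterministic and derivative-free: a coarse grid scan (21 points per
#' axis for one or two free parameters; 3 per axis plus the parameter-mapped
#' point for larger problems such as the 5-parameter BC fit) followed by
#' local refinement (golden-section for one parameter, Nelder--Mead with box
#' projection otherwise) to parameter tolerance `1e-5`.
#'
#' @param spec A [fit_spec()].
#' @param ens An [ensemble_summary] containing `t_IC` and every fit time.
#' @return An object of class `fit_result`: `estimates` (named vector inside
#'   the bounds), `rmse_N`, `rmse_E` at the optimum, `objective`,
#'   `n_objective_evals`, `converged`, `bounds` and the `spec`.
#' @export
fit_parameters <- function(spec, ens) {
  t_ic <- spec$fixed$t_IC
  i_ic <- match_times(t_ic, ens$times)
  invisible(match_times(spec$fit_times, ens$times)) # fail early if absent
  N0 <- ens$N[, i_ic]
  E0 <- ens$E[, i_ic]
  free <- spec$free
  d <- length(free)
  lo <- vapply(free, `[`, numeric(1L), 1L)
  hi <- vapply(free, `[`, numeric(1L), 2L)
  nm <- names(free)

  n_eval <- 0L
  last <- new.env(parent = emptyenv())
  objective <- function(theta) {
    theta <- pmin(pmax(theta, lo), hi)
    names(theta) <- nm
    n_eval <<- n_eval + 1L
    # parameter corners can make the forward model blow up (e.g. strong
    # branching with no sinks); such points are simply bad fits
    sol <- tryCatch(
      suppressWarnings(.solve_for_fit(spec, .apply_theta(spec, theta),
                                      N0, E0)),
      error = function(e) NULL)
    if (is.null(sol)) return(1e6)
    r <- rmse(sol, ens, spec$fit_times)
    if (!all(is.finite(r))) return(1e6)
    last$r <- r
    sum(spec$weights * r)
  }

  # coarse deterministic grid scan
  npts <- if (d <= 2L) 21L else 3L
  axes <- Map(function(l, h) if (h > l) seq(l, h, length.out = npts) else l,
              lo, hi)
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  if (d > 2L) {
    mapped <- vapply(nm, function(p) {
      v <- spec$fixed[[p]]
      if (is.null(v)) mean(c(lo[[p]], hi[[p]])) else v
    }, numeric(1L))
    grid <- rbind(grid, pmin(pmax(mapped, lo), hi))
  }
  vals <- apply(grid, 1L, objective)
  best <- which.min(vals)
  theta0 <- grid[best, ]
  fbest <- vals[best]

  converged <- TRUE
  if (d == 1L && hi[1L] > lo[1L]) {
    stp <- (hi[1L] - lo[1L]) / (npts - 1L)
    br <- c(max(lo[1L], theta0 - stp), min(hi[1L], theta0 + stp))
    op <- stats::optimize(function(z) objective(z), interval = br, tol = 1e-6)
    if (op$objective < fbest) {
      theta0 <- op$minimum
      fbest <- op$objective
    }
  } else if (any(hi > lo)) {
    op <- stats::optim(theta0, objective, method = "Nelder-Mead",
                       control = list(reltol = 1e-7, maxit = 250L * d,
                                      warn.1d.NelderMead = FALSE))
    if (op$value < fbest) {
      theta0 <- op$par
      fbest <- op$value
    }
    # convergence is declared when a fresh restart no longer moves the
    # estimate beyond the 1e-5 parameter tolerance
    op2 <- stats::optim(op$par, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-7, maxit = 100L * d,
                                       warn.1d.NelderMead = FALSE))
    converged <- max(abs(pmin(pmax(op2$par, lo), hi) -
                           pmin(pmax(op$par, lo), hi))) < 1e-5
    if (op2$value < fbest) {
      theta0 <- op2$par
      fbest <- op2$value
    }
  }

  est <- pmin(pmax(theta0, lo), hi)
  names(est) <- nm
  fbest <- objective(est) # re-evaluate at the clamped optimum
  structure(list(estimates = est,
                 rmse_N = unname(last$r["rmse_N"]),
                 rmse_E = unname(last$r["rmse_E"]),
                 objective = fbest,
                 n_objective_evals = n_eval,
                 converged = converged,
                 bounds = free, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result (", x$spec$model, ")\n", sep = "")
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.6g  (bounds [%g, %g])\n", nm, x$estimates[[nm]],
                x$bounds[[nm]][1L], x$bounds[[nm]][2L]))
  cat(sprintf("  rmse_N = %.5g, rmse_E = %.5g, %d objective evaluations%s\n",
              x$rmse_N, x$rmse_E, x$n_objective_evals,
              if (x$converged) "" else " (local polish did not converge)"))
  invisible(x)
}

#' Across-ensemble repeat variability of fitted parameters
#'
#' Re-runs the full pipeline (ensemble generation and fitting) `n_repeats`
#' times with disjoint seed blocks and reports the mean and standard
#' deviation of each fitted parameter. This is the interpretation of the
#' plus/minus companion attached to fitted values: ensemble-to-ensemble
#' variability of the estimate, not an optimizer confidence interval.
#'
#' @param spec A [fit_spec()].
#' @param config The [ca_config()] generating the ensembles.
#' @param M Realizations per ensemble.
#' @param n_repeats Number of independent ensembles, >= 2.
#' @param base_seed Repeat `r` uses realization seeds
#'   `base_seed + (r - 1) * M + (1..M)`.
#' @param engine Passed to [run_ensemble()].
#' @return List with `mean`, `sd` (named vectors over the free parameters)
#'   and `fits` (the individual `fit_result`s).
#' @export
repeat_uncertainty <- function(spec, config, M, n_repeats, base_seed,
                               engine = "cpp") {
  stopifnot(n_repeats >= 2)
  record_K <- sort(unique(round(
    c(spec$fixed$t_IC, spec$fit_times) / config$tau)))
  fits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    ens <- run_ensemble(config, M = M,
                        base_seed = base_seed + (r - 1L) * M,
                        record_K = record_K, engine = engine)
    fits[[r]] <- fit_parameters(spec, ens)
  }
  est <- do.call(rbind, lapply(fits, `[[`, "estimates"))
  list(mean = colMeans(est), sd = apply(est, 2L, stats::sd), fits = fits)
}

#' Standard search boxes for the calibration problems
#'
#' Convenience constructor for the default bounds: `lam` in
#' `[0, P_p / tau]` (the parameter-mapped branching rate is the upper end),
#' `a_n` in `[0, 1]`, `a_e` in `(0, 1]`.
#'
#' @param config A [ca_config()].
#' @param params Which bounds to return.
#' @return Named list of bounds usable as `free` in [fit_spec()].
#' @export
default_bounds <- function(config, params = c("lam", "a_n", "a_e")) {
  all <- list(lam = c(0, config$P_p / config$tau),
              a_n = c(0, 1),
              a_e = c(1e-3, 1))
  all[match.arg(params, several.ok = TRUE)]
}
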