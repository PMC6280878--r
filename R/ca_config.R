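#' Cellular automaton configuration
#'
#' Collects every microscale parameter of the lattice automaton and validates
#' the constraints that make the rules well defined. Lattice sites are indexed
#' `(i, j)` with `0 <= i, j <= R`; the limbus (sprouting boundary) sits at
#' `i = 0` and the TAF source at `i = R`. Space and time are dimensionless:
#' `x = i*h` with `R*h = 1`, and `t = K*tau` where `K` is the discrete step
#' counter.
#'
#' Two model variants are supported. In Model 1 (`mode = 1`) tip cells (TCs)
#' interact only with other TCs: at most one TC per site, while stalk-cell
#' (EC) counts are unbounded non-negative integers and never impede movement.
#' In Model 2 (`mode = 2`) each site holds at most one cell of either type
#' (`TC + EC <= 1`), TCs are also excluded by ECs, and tip-to-sprout
#' anastomosis becomes possible.
#'
#' The defaults are the reference parameter set used throughout: `R = 200`,
#' `h = 1/200`, `P_m = 1`, `k = 100`, `tau = 1/160`, `K_IC = 32`, which map to
#' macroscale coefficients `D = 1e-3`, `chi = 0.4`, `mu = 160`, `t_IC = 0.2`
#' (see [map_parameters()]).
#'
#' @param R Number of lattice intervals per side; sites are indexed `0..R`.
#'   Must be even (the alternating initial condition requires it) and >= 2.
#' @param h Lattice spacing; `R*h` must equal 1.
#' @param P_m Motility probability per selection, in `[0, 1]`.
#' @param k Chemotactic sensitivity, >= 0. Constrained so that every movement
#'   probability produced by [direction_probabilities()] lies in `[0, 1]`,
#'   i.e. `k * 2h <= 1` for the linear TAF field.
#' @param tau Time step, > 0.
#' @param P_p Branching scale; the branching probability at a site is
#'   `P_b = P_p * c` and must not exceed 1, so `P_p <= 1` for `c` in `[0,1]`.
#' @param a_n Tip-to-tip anastomosis probability in `[0, 1]`; a TC moving onto
#'   a TC-occupied site annihilates both with this probability, otherwise the
#'   move is aborted (TC volume exclusion).
#' @param a_e Tip-to-sprout anastomosis probability in `[0, 1]` (Model 2
#'   only); a TC moving onto an EC-occupied site (not of its own trail) is
#'   annihilated with this probability, otherwise the move is aborted (EC
#'   volume exclusion). Ignored when `mode = 1`.
#' @param mode Model selector, 1 or 2.
#' @param K_IC Discrete time index whose column-averaged profile seeds the
#'   continuum models.
#' @param K_max Final discrete step of a default run.
#' @param seed Default RNG seed for [run_realization()].
#'
#' @return An object of class `ca_config` (a validated named list).
#' @seealso [init_lattice()], [run_realization()], [map_parameters()]
#' @examples
#' cfg <- ca_config(R = 20, k = 2, P_p = 0.05, a_n = 0.2)
#' cfg$h
#' @export
ca_config <- function(R = 200L, h = 1 / R, P_m = 1, k = 100, tau = 1 / 160,
                      P_p = 1e-2, a_n = 0, a_e = NA_real_, mode = 1L,
                      K_IC = 32L, K_max = 320L, seed = 1L) {
  R <- as.integer(R)
  mode <- as.integer(mode)
  if (R < 2L || R %% 2L != 0L)
    stop("R must be an even integer >= 2 (alternating initial placement is ",
         "undefined otherwise)", call. = FALSE)
  if (abs(R * h - 1) > 1e-12)
    stop("R * h must equal 1 (got ", R * h, ")", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (P_m < 0 || P_m > 1) stop("P_m must lie in [0, 1]", call. = FALSE)
  if (P_p < 0 || P_p > 1)
    stop("P_p must lie in [0, 1] so that P_b = P_p * c <= 1 for c in [0, 1]",
         call. = FALSE)
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  if (k * 2 * h > 1 + 1e-12)
    stop("k too large for the TAF gradient: k * 2h = ", k * 2 * h,
         " > 1 gives movement probabilities outside [0, 1]", call. = FALSE)
  if (a_n < 0 || a_n > 1) stop("a_n must lie in [0, 1]", call. = FALSE)
  if (!mode %in% c(1L, 2L)) stop("mode must be 1 or 2", call. = FALSE)
  if (mode == 2L) {
    if (is.na(a_e) || a_e < 0 || a_e > 1)
      stop("a_e must lie in [0, 1] when mode = 2", call. = FALSE)
  } else {
    a_e <- NA_real_ # unused in Model 1
  }
  if (K_IC < 0 || K_max < 0) stop("K_IC and K_max must be >= 0", call. = FALSE)
  structure(
    list(R = R, h = h, P_m = P_m, k = k, tau = tau, P_p = P_p,
         a_n = a_n, a_e = a_e, mode = mode,
         K_IC = as.integer(K_IC), K_max = as.integer(K_max),
         seed = as.integer(seed)),
    class = "ca_config")
}

#' @export
print.ca_config <- function(x, ...) {
  cat("Snail-trail CA configuration (Model ", x$mode, ")\n", sep = "")
  cat(sprintf("  lattice: (R+1) x (R+1) = %d x %d sites, h = %.6g, tau = %.6g\n",
              x$R + 1L, x$R + 1L, x$h, x$tau))
  cat(sprintf("  P_m = %g, k = %g, P_p = %g, a_n = %g, a_e = %s\n",
              x$P_m, x$k, x$P_p, x$a_n,
              if (is.na(x$a_e)) "(unused)" else format(x$a_e)))
  cat(sprintf("  K_IC = %d (t_IC = %g), K_max = %d (t = %g)\n",
              x$K_IC, x$K_IC * x$tau, x$K_max, x$K_max * x$tau))
  invisible(x)
}

#' Linear TAF concentration field
#'
#' The tumor angiogenic factor field is prescribed, quasi-steady and linear:
#' `c(x) = x` on `[0, 1]`, discretized as `c_i = i*h`. It is independent of
#' the transverse index `j`, so transverse movement probabilities are exactly
#' 1/4.
#'
#' @param config A [ca_config()] object (only `R` and `h` are used), or `NULL`
#'   to build from `R` directly.
#' @param R Lattice intervals, used when `config` is `NULL`.
#' @return An object of class `taf_field`: list with `c` (length `R + 1`
#'   concentrations) and `h`.
#' @examples
#' taf_field(R = 4)$c
#' @export
taf_field <- function(config = NULL, R = NULL) {
  if (!is.null(config)) {
    R <- config$R
    h <- config$h
  } else {
    stopifnot(!is.null(R))
    h <- 1 / R
  }
  structure(list(c = (0:R) * h, h = h, R = as.integer(R)), class = "taf_field")
}

#' Movement probabilities of the biased random walk
#'
#' Computes the four directional probabilities `(x+, x-, y+, y-)` for a TC at
#' column `i`:
#' `P^{x+-} = (1 +- k (c_{i+1} - c_{i-1})) / 4` and
#' `P^{y+-} = (1 +- k (c_{j+1} - c_{j-1})) / 4`.
#' The TAF field here depends on `x` only, so the transverse components are
#' exactly 1/4. At the lattice edges (`i = 0` or `i = R`) the central
#' difference uses the one available neighbor (clamped stencil), e.g.
#' `c_1 - c_0` at `i = 0`.
#'
#' @param taf A [taf_field()].
#' @param k Chemotactic sensitivity.
#' @param site Lattice site `c(i, j)` (0-based); only `i` matters for the
#'   linear field.
#' @return Numeric 4-vector `(x+, x-, y+, y-)`; components sum to 1.
#' @examples
#' tf <- taf_field(R = 200)
#' direction_probabilities(tf, k = 100, site = c(50, 10)) # (1/2, 0, 1/4, 1/4)
#' @export
direction_probabilities <- function(taf, k, site) {
  i <- site[[1]]
  R <- taf$R
  if (i < 0 || i > R) stop("site column outside lattice", call. = FALSE)
  cp <- taf$c[min(i + 1L, R) + 1L]
  cm <- taf$c[max(i - 1L, 0L) + 1L]
  g <- k * (cp - cm)
  p <- c(xp = (1 + g) / 4, xm = (1 - g) / 4, yp = 0.25, ym = 0.25)
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("movement probability outside [0, 1]: k too large for the TAF ",
         "gradient", call. = FALSE)
  pmin(pmax(p, 0), 1)
}

# Movement probabilities for every column at once; rows (xp, xm) over i = 0..R.
# Internal: used by both engines and by the mean-field iteration.
column_move_probs <- function(config) {
  taf <- taf_field(config)
  R <- config$R
  cp <- taf$c[pmin(1:(R + 1) + 1L, R + 1L)]
  cm <- taf$c[pmax(1:(R + 1) - 1L, 1L)]
  g <- config$k * (cp - cm)
  list(xp = (1 + g) / 4, xm = (1 - g) / 4, c = taf$c)
}
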