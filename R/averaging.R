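#' Ensemble summary container
#'
#' Holds column-averaged TC and EC density profiles over a set of recording
#' times, as produced by [run_ensemble()] or [column_average()]. Densities
#' carry the `1 / (M (R + 1))` normalization, so the TC density `N` lies in
#' `[0, 1]` everywhere and, in Model 2, `N + E <= 1` as well.
#'
#' @param times Recording times `t = tau * K`.
#' @param x Column centers `x_i = i * h` (length `R + 1`).
#' @param N,E `(R + 1) x length(times)` matrices of column-averaged
#'   densities.
#' @param M Realization count.
#' @param R Lattice intervals.
#' @param provenance Character provenance tag.
#' @return An object of class `ensemble_summary`.
#' @name ensemble_summary
#' @export
new_ensemble_summary <- function(times, x, N, E, M, R, provenance = "") {
  N <- as.matrix(N); E <- as.matrix(E)
  stopifnot(length(x) == R + 1, nrow(N) == R + 1, ncol(N) == length(times),
            all(dim(E) == dim(N)))
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 N = N, E = E, M = as.integer(M), R = as.integer(R),
                 provenance = provenance),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble_summary: M = %d realizations, R = %d columns, %d times (t = %s)\n",
              x$M, x$R, length(x$times),
              paste(format(x$times), collapse = ", ")))
  cat(sprintf("  final TC mass %.4f, EC mass %.4f\n",
              total_mass(x$N[, ncol(x$N)], x$x),
              total_mass(x$E[, ncol(x$E)], x$x)))
  invisible(x)
}

#' Column-average occupancy snapshots
#'
#' Averages per-site occupancies over realizations and over the transverse
#' index `j`:
#' `N_i = (1 / (M (R + 1))) * sum_m sum_j n^m_{i,j}`, and analogously for
#' `E_i`. Accepts a list of realizations recorded with `full = TRUE` (full
#' occupancy grids) or the per-column sums that [run_realization()] always
#' returns.
#'
#' @param realizations List of `ca_realization` objects sharing lattice size
#'   and recording times.
#' @param config The [ca_config()] used to generate them (supplies `tau` and
#'   `h`).
#' @return An [ensemble_summary].
#' @export
column_average <- function(realizations, config) {
  stopifnot(length(realizations) >= 1)
  K <- realizations[[1L]]$K
  n <- config$R + 1L
  Nsum <- matrix(0, n, length(K))
  Esum <- matrix(0, n, length(K))
  for (r in realizations) {
    if (!identical(as.integer(r$K), as.integer(K)) || nrow(r$tc_cols) != n)
      stop("realizations have mismatched lattice size or recording times",
           call. = FALSE)
    Nsum <- Nsum + r$tc_cols
    Esum <- Esum + r$ec_cols
  }
  M <- length(realizations)
  new_ensemble_summary(times = K * config$tau, x = (0:config$R) * config$h,
                       N = Nsum / (M * n), E = Esum / (M * n),
                       M = M, R = config$R,
                       provenance = ensemble_provenance(config, M, NA))
}

#' Total cell mass of a density profile
#'
#' Trapezoidal integral of a density profile over `x` in `[0, 1]`, the scalar
#' used to compare models (mass at a fixed time).
#'
#' @param profile Density values on the grid.
#' @param x Grid nodes (same length), or a scalar spacing `h` for a uniform
#'   grid starting at 0.
#' @return The integral as a scalar.
#' @examples
#' total_mass(rep(1, 11), seq(0, 1, 0.1)) # 1
#' @export
total_mass <- function(profile, x) {
  if (length(x) == 1L) x <- seq(0, by = x, length.out = length(profile))
  if (length(profile) != length(x))
    stop("profile length does not match grid", call. = FALSE)
  sum(diff(x) * (profile[-1L] + profile[-length(profile)]) / 2)
}
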