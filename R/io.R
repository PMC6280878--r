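#' Write / read the standard (t, x, N, E) density table
#'
#' Column-averaged and continuum density profiles are exchanged as a
#' delimited text table with fixed header `t, x, N, E`, one row per
#' recording time and column center, sorted by `(t, x)`. Floats are written
#' with 17 significant digits so the round trip is lossless.
#'
#' @param obj An [ensemble_summary] or `pde_solution`.
#' @param path Output file.
#' @return `write_table` returns `path` invisibly; `read_table_tne` returns
#'   a list with `times`, `x`, and matrices `N`, `E`.
#' @export
write_table <- function(obj, path) {
  df <- data.frame(
    t = rep(obj$times, each = length(obj$x)),
    x = rep(obj$x, times = length(obj$times)),
    N = as.vector(obj$N),
    E = as.vector(obj$E))
  df <- df[order(df$t, df$x), ]
  old <- options(digits = 17, scipen = 0)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tne <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x", "N", "E")
  if (!all(need %in% names(df)))
    stop("table must have columns t, x, N, E", call. = FALSE)
  times <- sort(unique(df$t))
  x <- sort(unique(df$x))
  if (nrow(df) != length(times) * length(x))
    stop("malformed table: ", nrow(df), " rows != ", length(times), " times x ",
         length(x), " columns", call. = FALSE)
  df <- df[order(df$t, df$x), ]
  list(times = times, x = x,
       N = matrix(df$N, nrow = length(x)),
       E = matrix(df$E, nrow = length(x)))
}

#' Read a density table as an ensemble summary
#'
#' @param path CSV written by [write_table()].
#' @param M Realization count to record on the object (provenance only).
#' @return An [ensemble_summary].
#' @export
read_ensemble <- function(path, M = NA_integer_) {
  tb <- read_table_tne(path)
  new_ensemble_summary(times = tb$times, x = tb$x, N = tb$N, E = tb$E,
                       M = if (is.na(M)) 0L else M,
                       R = length(tb$x) - 1L,
                       provenance = paste0("file=", path))
}

#' Write per-site occupancy snapshots
#'
#' One record per occupied site: `(t, i, j, species, count)` with `species`
#' in `TC, EC` — the format used to reproduce individual network
#' realizations.
#'
#' @param realization A `ca_realization` recorded with `full = TRUE`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(realization, path) {
  if (is.null(realization$tc_grids))
    stop("realization was not recorded with full = TRUE", call. = FALSE)
  tau <- realization$config$tau
  rows <- list()
  for (s in seq_along(realization$K)) {
    t <- realization$K[s] * tau
    for (sp in c("TC", "EC")) {
      g <- if (sp == "TC") realization$tc_grids[[s]] else realization$ec_grids[[s]]
      occ <- which(g > 0L, arr.ind = TRUE)
      if (nrow(occ) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          t = t, i = occ[, 1L] - 1L, j = occ[, 2L] - 1L, species = sp,
          count = g[occ])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = numeric(), i = integer(), j = integer(),
               species = character(), count = integer())
  df <- df[order(df$t, df$species, df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / parse a plain-text configuration file
#'
#' Configurations are serialized as `key = value` lines mirroring the
#' [ca_config()] field names; unknown keys are rejected and all invariants
#' are re-checked at load time.
#'
#' @param config A [ca_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `parse_config` returns a
#'   validated [ca_config()].
#' @export
write_config <- function(config, path) {
  keys <- c("R", "h", "P_m", "k", "tau", "P_p", "a_n", "a_e", "mode",
            "K_IC", "K_max", "seed")
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    paste0(k, " = ", format(v, digits = 17))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- vapply(kv, `[[`, character(1L), 1L)
  vals <- vapply(kv, `[[`, character(1L), 2L)
  known <- c("R", "h", "P_m", "k", "tau", "P_p", "a_n", "a_e", "mode",
             "K_IC", "K_max", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  num <- ifelse(vals %in% c("NA", "na"), NA_real_,
                suppressWarnings(as.numeric(vals)))
  bad <- is.na(num) & !vals %in% c("NA", "na")
  if (any(bad))
    stop("non-numeric value for key(s): ", paste(keys[bad], collapse = ", "),
         call. = FALSE)
  args <- stats::setNames(as.list(num), keys)
  do.call(ca_config, args)
}

#' Serialize a fit result to JSON
#'
#' Writes estimates, RMSE values, bounds, evaluation count and the fit
#' provenance as structured JSON.
#'
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  out <- list(model = fit$spec$model,
              estimates = as.list(fit$estimates),
              rmse_N = fit$rmse_N, rmse_E = fit$rmse_E,
              objective = fit$objective,
              n_objective_evals = fit$n_objective_evals,
              converged = fit$converged,
              bounds = fit$bounds,
              fit_times = fit$spec$fit_times,
              weights = fit$spec$weights)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
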