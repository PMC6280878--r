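#' Initialize the lattice
#'
#' Places TCs along the limbus column `i = 0` at alternating transverse sites
#' `j = 1, 3, ..., R - 1` (so `R/2` tip cells), with no ECs anywhere and the
#' step counter at zero. Each TC starts with an empty snail-trail.
#'
#' @param config A [ca_config()].
#' @param tc_positions Optional integer matrix with columns `(i, j)` (0-based)
#'   giving explicit initial TC positions instead of the alternating limbus
#'   seeding; positions must be distinct and on-lattice.
#' @return An object of class `lattice_state`: list with step counter `K`,
#'   `(R+1) x (R+1)` integer matrices `tc` (registry slot of the occupying TC,
#'   0 if none), `ec` (EC count; 0/1 in Model 2) and `ec_owner` (id of the TC
#'   that deposited the EC, used for the self-loop prohibition in Model 2),
#'   and the agent registry vectors `agent_id`, `agent_i`, `agent_j`.
#'   The registry encodes each live TC's trail implicitly: a site belongs to a
#'   TC's trail exactly when `ec_owner` holds that TC's id (in Model 2 every
#'   EC site has a unique depositor because occupancy is exclusive).
#' @examples
#' st <- init_lattice(ca_config(R = 4, k = 1, P_p = 0))
#' tc_count(st) # R/2 = 2
#' @export
init_lattice <- function(config, tc_positions = NULL) {
  R <- config$R
  n <- R + 1L
  if (is.null(tc_positions)) {
    j <- seq(1L, R - 1L, by = 2L)
    tc_positions <- cbind(rep(0L, length(j)), j)
  } else {
    tc_positions <- matrix(as.integer(tc_positions), ncol = 2L)
    if (any(tc_positions < 0L) || any(tc_positions > R))
      stop("initial TC positions outside lattice", call. = FALSE)
    if (anyDuplicated(tc_positions[, 1L] * n + tc_positions[, 2L]))
      stop("duplicate initial TC positions", call. = FALSE)
  }
  m <- nrow(tc_positions)
  tc <- matrix(0L, n, n)
  tc[cbind(tc_positions[, 1L] + 1L, tc_positions[, 2L] + 1L)] <- seq_len(m)
  structure(
    list(K = 0L,
         tc = tc,
         ec = matrix(0L, n, n),
         ec_owner = matrix(0L, n, n),
         agent_id = seq_len(m),
         agent_i = as.integer(tc_positions[, 1L]),
         agent_j = as.integer(tc_positions[, 2L]),
         next_id = m + 1L,
         R = R, mode = config$mode),
    class = "lattice_state")
}

#' Count live tip cells
#' @param state A `lattice_state`.
#' @return Integer TC count.
#' @export
tc_count <- function(state) length(state$agent_id)

#' Total stalk-cell count
#' @param state A `lattice_state`.
#' @return Integer total EC count over the lattice.
#' @export
ec_count <- function(state) sum(state$ec)

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("lattice_state: K = %d, %d TCs, %d ECs on a %d x %d lattice (Model %d)\n",
              x$K, tc_count(x), ec_count(x), x$R + 1L, x$R + 1L, x$mode))
  invisible(x)
}

# Deposit an EC at 1-based matrix indices (ii, jj), recording the depositor.
.deposit_ec <- function(state, ii, jj, owner_id) {
  if (state$mode == 2L) {
    state$ec[ii, jj] <- 1L
  } else {
    state$ec[ii, jj] <- state$ec[ii, jj] + 1L
  }
  state$ec_owner[ii, jj] <- owner_id
  state
}

# Swap-remove agent at registry slot idx; the last agent moves into the slot.
# This ordering is part of the documented RNG contract shared with the
# compiled engine.
.remove_agent <- function(state, idx) {
  last <- length(state$agent_id)
  if (idx != last) {
    state$agent_id[idx] <- state$agent_id[last]
    state$agent_i[idx] <- state$agent_i[last]
    state$agent_j[idx] <- state$agent_j[last]
    state$tc[state$agent_i[idx] + 1L, state$agent_j[idx] + 1L] <- idx
  }
  state$agent_id <- state$agent_id[-last]
  state$agent_i <- state$agent_i[-last]
  state$agent_j <- state$agent_j[-last]
  state
}

#' Give one tip cell the opportunity to move
#'
#' Implements one motility attempt of the automaton, drawing from R's global
#' RNG stream in the documented order: (1) a uniform draw against `P_m`
#' (failure: `no_attempt`); (2) a direction draw over
#' [direction_probabilities()]; then the outcome is resolved without further
#' draws unless the target is occupied, in which case (3) a single anastomosis
#' draw against `a_n` (target TC) or `a_e` (target EC, Model 2, not the
#' mover's own trail) decides between anastomosis and exclusion. Moves that
#' would leave the lattice are aborted (`boundary_aborted`) without consuming
#' an anastomosis draw. Every successful departure deposits one EC at the
#' origin.
#'
#' Outcomes: `moved` (relocation, EC at origin), `tip_tip` (both TCs removed,
#' ECs at origin and target), `tip_sprout` (Model 2: mover removed, EC at
#' origin, target EC remains), `excluded_tc`, `excluded_ec`,
#' `selfloop_aborted` (Model 2: target EC was deposited by the mover itself),
#' `boundary_aborted`, `no_attempt`.
#'
#' @param state A `lattice_state`.
#' @param agent_id Id of a live TC.
#' @param config The [ca_config()].
#' @return List with the updated `state` and an `outcome` list
#'   (`kind`, `origin`, `target`; sites are 0-based `(i, j)` pairs, `target`
#'   is `NULL` when no direction was drawn).
#' @export
attempt_move <- function(state, agent_id, config) {
  idx <- match(agent_id, state$agent_id)
  if (is.na(idx)) stop("unknown or dead agent id ", agent_id, call. = FALSE)
  .attempt_move_idx(state, idx, config)
}

.attempt_move_idx <- function(state, idx, config) {
  i <- state$agent_i[idx]
  j <- state$agent_j[idx]
  origin <- c(i, j)
  out <- function(kind, target = NULL)
    list(kind = kind, origin = origin, target = target)

  if (stats::runif(1) >= config$P_m)
    return(list(state = state, outcome = out("no_attempt")))

  p <- direction_probabilities(taf_field(config), config$k, origin)
  u <- stats::runif(1)
  if (u < p[1L]) {
    ti <- i + 1L; tj <- j
  } else if (u < p[1L] + p[2L]) {
    ti <- i - 1L; tj <- j
  } else if (u < p[1L] + p[2L] + p[3L]) {
    ti <- i; tj <- j + 1L
  } else {
    ti <- i; tj <- j - 1L
  }
  target <- c(ti, tj)
  R <- state$R
  if (ti < 0L || ti > R || tj < 0L || tj > R)
    return(list(state = state, outcome = out("boundary_aborted", target)))

  oi <- i + 1L; oj <- j + 1L # 1-based origin
  si <- ti + 1L; sj <- tj + 1L # 1-based target
  mover_id <- state$agent_id[idx]

  if (state$tc[si, sj] > 0L) {
    if (stats::runif(1) < config$a_n) {
      # tip-to-tip anastomosis: both TCs removed, ECs at origin and target
      ridx <- state$tc[si, sj]
      resident_id <- state$agent_id[ridx]
      state$tc[oi, oj] <- 0L
      state$tc[si, sj] <- 0L
      state <- .deposit_ec(state, oi, oj, mover_id)
      state <- .deposit_ec(state, si, sj, resident_id)
      hi <- max(idx, ridx); lo <- min(idx, ridx)
      state <- .remove_agent(state, hi)
      state <- .remove_agent(state, lo)
      return(list(state = state, outcome = out("tip_tip", target)))
    }
    return(list(state = state, outcome = out("excluded_tc", target)))
  }

  if (state$mode == 2L && state$ec[si, sj] > 0L) {
    if (state$ec_owner[si, sj] == mover_id)
      return(list(state = state, outcome = out("selfloop_aborted", target)))
    if (stats::runif(1) < config$a_e) {
      # tip-to-sprout anastomosis: mover removed, EC at origin, target remains
      state$tc[oi, oj] <- 0L
      state <- .deposit_ec(state, oi, oj, mover_id)
      state <- .remove_agent(state, idx)
      return(list(state = state, outcome = out("tip_sprout", target)))
    }
    return(list(state = state, outcome = out("excluded_ec", target)))
  }

  # vacant target: snail-trail move
  state$tc[oi, oj] <- 0L
  state <- .deposit_ec(state, oi, oj, mover_id)
  state$agent_i[idx] <- ti
  state$agent_j[idx] <- tj
  state$tc[si, sj] <- idx
  list(state = state, outcome = out("moved", target))
}

#' Give one tip cell the opportunity to branch
#'
#' A TC at `(i, j)` branches with probability `P_b = P_p * c_i` (one uniform
#' draw). If the draw succeeds and BOTH transverse neighbors `(i, j - 1)` and
#' `(i, j + 1)` are vacant (no TC in Model 1; no TC and no EC in Model 2), the
#' parent is removed and daughter TCs with fresh ids and empty trails are
#' placed at the two neighbors (net TC gain +1). Otherwise the branch is
#' `blocked`; a TC at `j = 0` or `j = R` is always blocked (one target is off
#' the lattice). Branching never creates ECs.
#'
#' @inheritParams attempt_move
#' @return List with updated `state` and `outcome` list (`kind` one of
#'   `branched`, `blocked`, `no_attempt`; `origin`).
#' @export
attempt_branch <- function(state, agent_id, config) {
  idx <- match(agent_id, state$agent_id)
  if (is.na(idx)) stop("unknown or dead agent id ", agent_id, call. = FALSE)
  .attempt_branch_idx(state, idx, config)
}

.attempt_branch_idx <- function(state, idx, config) {
  i <- state$agent_i[idx]
  j <- state$agent_j[idx]
  origin <- c(i, j)
  P_b <- config$P_p * i * config$h
  if (stats::runif(1) >= P_b)
    return(list(state = state, outcome = list(kind = "no_attempt", origin = origin)))
  R <- state$R
  blocked <- list(state = state, outcome = list(kind = "blocked", origin = origin))
  if (j - 1L < 0L || j + 1L > R) return(blocked)
  ii <- i + 1L
  up <- c(ii, j + 2L); dn <- c(ii, j) # 1-based (i, j+1) and (i, j-1)
  vac <- function(s) state$tc[s[1L], s[2L]] == 0L &&
    (state$mode == 1L || state$ec[s[1L], s[2L]] == 0L)
  if (!vac(up) || !vac(dn)) return(blocked)
  # parent removed (swap-remove), daughters appended: (i, j+1) then (i, j-1)
  state$tc[ii, j + 1L] <- 0L
  state <- .remove_agent(state, idx)
  for (tj in c(j + 1L, j - 1L)) {
    slot <- length(state$agent_id) + 1L
    state$agent_id[slot] <- state$next_id
    state$next_id <- state$next_id + 1L
    state$agent_i[slot] <- i
    state$agent_j[slot] <- tj
    state$tc[ii, tj + 1L] <- slot
  }
  list(state = state, outcome = list(kind = "branched", origin = origin))
}

#' Advance the automaton by one discrete time step
#'
#' One step is a random sequential update in two phases. Phase 1 makes
#' `N1` motility selections, where `N1` is the TC count at the start of the
#' step: each selection draws a TC uniformly at random (with replacement) from
#' the currently-alive TCs and processes it with [attempt_move()]. Phase 2
#' re-reads the TC count `N2` and makes `N2` branching selections the same
#' way, processed with [attempt_branch()]. TCs killed mid-phase leave the
#' sampling pool; if the pool empties, remaining selections are skipped
#' without consuming RNG draws. The step counter is incremented.
#'
#' @inheritParams attempt_move
#' @return The updated `lattice_state`.
#' @export
ca_step <- function(state, config) {
  n1 <- length(state$agent_id)
  for (s in seq_len(n1)) {
    na <- length(state$agent_id)
    if (na == 0L) break
    idx <- min(floor(stats::runif(1) * na) + 1, na)
    state <- .attempt_move_idx(state, idx, config)$state
  }
  n2 <- length(state$agent_id)
  for (s in seq_len(n2)) {
    na <- length(state$agent_id)
    if (na == 0L) break
    idx <- min(floor(stats::runif(1) * na) + 1, na)
    state <- .attempt_branch_idx(state, idx, config)$state
  }
  state$K <- state$K + 1L
  state
}

#' Run one automaton realization
#'
#' Runs the automaton from the initial condition to `max(record_K)` steps and
#' records occupancy snapshots at the requested discrete times. Deterministic
#' given `(config, seed)`: both engines consume R's RNG stream in the same
#' documented order, so `engine = "cpp"` (compiled, used for production
#' ensembles) and `engine = "R"` (reference implementation) produce
#' bit-identical output.
#'
#' @param config A [ca_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param record_K Increasing integer vector of discrete times to record;
#'   `0` records the initial condition.
#' @param engine `"cpp"` or `"R"`.
#' @param tc_positions Optional explicit initial TC positions, see
#'   [init_lattice()].
#' @param full Logical; if `TRUE` return full `(R+1) x (R+1)` occupancy grids
#'   per recorded time, otherwise only per-column occupancy sums (sufficient
#'   for column averaging and much lighter).
#' @return List of class `ca_realization`: `K` (recorded times), `tc_cols`,
#'   `ec_cols` (`(R+1) x length(K)` matrices of column occupancy sums) and,
#'   when `full = TRUE`, lists `tc_grids`, `ec_grids` of integer matrices
#'   (deep copies).
#' @examples
#' cfg <- ca_config(R = 10, k = 1, P_p = 0.1, a_n = 0.5)
#' r <- run_realization(cfg, seed = 1, record_K = c(0, 5, 10))
#' colSums(r$tc_cols) # TC counts at the recorded times
#' @export
run_realization <- function(config, seed = config$seed,
                            record_K = c(0L, config$K_max),
                            engine = c("cpp", "R"),
                            tc_positions = NULL, full = FALSE) {
  engine <- match.arg(engine)
  record_K <- as.integer(record_K)
  if (is.unsorted(record_K, strictly = TRUE))
    stop("record_K must be strictly increasing", call. = FALSE)
  if (any(record_K < 0L)) stop("record_K must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  if (engine == "cpp") {
    mp <- column_move_probs(config)
    if (is.null(tc_positions)) {
      j <- seq(1L, config$R - 1L, by = 2L)
      tc_positions <- cbind(rep(0L, length(j)), j)
    }
    res <- ca_run_cpp(config$R, config$P_m, mp$xp, mp$xm, config$P_p, mp$c,
                      config$a_n, if (is.na(config$a_e)) 0 else config$a_e,
                      config$mode, record_K, full,
                      matrix(as.integer(tc_positions), ncol = 2L))
  } else {
    state <- init_lattice(config, tc_positions)
    n <- config$R + 1L
    nr <- length(record_K)
    res <- list(K = record_K,
                tc_cols = matrix(0, n, nr), ec_cols = matrix(0, n, nr),
                tc_grids = if (full) vector("list", nr),
                ec_grids = if (full) vector("list", nr))
    rec <- function(res, state, slot) {
      occ <- state$tc > 0L
      res$tc_cols[, slot] <- rowSums(occ)
      res$ec_cols[, slot] <- rowSums(state$ec)
      if (full) {
        res$tc_grids[[slot]] <- matrix(as.integer(occ), n, n)
        res$ec_grids[[slot]] <- state$ec
      }
      res
    }
    slot <- 1L
    if (record_K[1L] == 0L) {
      res <- rec(res, state, slot)
      slot <- slot + 1L
    }
    for (K in seq_len(max(record_K))) {
      state <- ca_step(state, config)
      if (slot <= nr && K == record_K[slot]) {
        res <- rec(res, state, slot)
        slot <- slot + 1L
      }
    }
  }
  res$config <- config
  res$seed <- as.integer(seed)
  class(res) <- "ca_realization"
  res
}

#' Run an ensemble of realizations and column-average it
#'
#' Runs `M` independent realizations, realization `m` seeded `base_seed + m`
#' (`m = 1, ..., M`), and accumulates the ensemble- and column-averaged TC and
#' EC densities `N_i(K)` and `E_i(K)` with the `1 / (M (R + 1))`
#' normalization.
#'
#' @param config A [ca_config()].
#' @param M Number of realizations, >= 1.
#' @param base_seed Integer; realization `m` uses seed `base_seed + m`.
#' @param record_K Discrete times to record.
#' @param engine Passed to [run_realization()].
#' @return An [ensemble_summary] object (see [column_average()]).
#' @examples
#' cfg <- ca_config(R = 10, k = 1, P_p = 0.05)
#' ens <- run_ensemble(cfg, M = 4, base_seed = 10, record_K = c(0, 8))
#' ens$N[, 1] # TC density profile at K = 0
#' @export
run_ensemble <- function(config, M, base_seed = config$seed,
                         record_K = seq(0L, config$K_max, by = config$K_IC),
                         engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(M >= 1)
  n <- config$R + 1L
  nr <- length(record_K)
  Nsum <- matrix(0, n, nr)
  Esum <- matrix(0, n, nr)
  for (m in seq_len(M)) {
    r <- run_realization(config, seed = base_seed + m, record_K = record_K,
                         engine = engine)
    Nsum <- Nsum + r$tc_cols
    Esum <- Esum + r$ec_cols
  }
  new_ensemble_summary(times = record_K * config$tau,
                       x = (0:config$R) * config$h,
                       N = Nsum / (M * n), E = Esum / (M * n),
                       M = M, R = config$R,
                       provenance = ensemble_provenance(config, M, base_seed))
}

ensemble_provenance <- function(config, M, base_seed) {
  paste0("mode=", config$mode, ";R=", config$R, ";P_m=", config$P_m,
         ";k=", config$k, ";tau=", config$tau, ";P_p=", config$P_p,
         ";a_n=", config$a_n, ";a_e=", config$a_e,
         ";M=", M, ";base_seed=", base_seed)
}
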