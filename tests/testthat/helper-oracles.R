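# Small configurations and independent oracles shared across tests.

# A quick lattice for event-level tests: R = 10, mild chemotaxis.
small_config <- function(...) {
  args <- list(R = 10L, k = 2, P_m = 1, tau = 0.01, P_p = 0.1, a_n = 0.2,
               K_IC = 5L, K_max = 50L)
  args[names(list(...))] <- list(...)
  do.call(ca_config, args)
}

# Reference parameter set (Table-2-style defaults of ca_config()).
reference_config <- function(...) {
  args <- list(...)
  do.call(ca_config, args)
}

# Build a lattice state holding exactly the given TCs (0-based positions).
state_with_tcs <- function(config, positions) {
  init_lattice(config, tc_positions = positions)
}

# Transition matrix of the single-TC column-projected walk: one motility
# attempt per step, x+/x- with probability P_m * pxp/pxm, stay otherwise;
# attempts across the boundary abort (reflect-and-hold).
walk_transition_matrix <- function(config) {
  mp <- snailtrail:::column_move_probs(config)
  n <- config$R + 1L
  T <- matrix(0, n, n)
  for (i in 1:n) {
    pr <- config$P_m * mp$xp[i]
    pl <- config$P_m * mp$xm[i]
    if (i < n) T[i, i + 1L] <- pr else pr <- 0
    if (i > 1) T[i, i - 1L] <- pl else pl <- 0
    T[i, i] <- 1 - pr - pl
  }
  T
}

# Independent coding of the Model 1, a_n = 0 reduction (viscous-Burgers-like
# form): N_t = D N_xx - chi (N(1-N) c_x)_x + lam c N (1-N)^2, with its own
# ghost extension D N_x - chi N(1-N) c_x = 0.
burgers_reduction_rhs <- function(N, D, chi, lam, x) {
  n <- length(N)
  h <- x[2] - x[1]
  s0 <- if (D > 0) (chi / D) * N[1] * (1 - N[1]) else 0
  s1 <- if (D > 0) (chi / D) * N[n] * (1 - N[n]) else 0
  Ng <- c(N[2] - 2 * h * s0, N, N[n - 1] + 2 * h * s1)
  lo <- 1:n; hi <- 3:(n + 2)
  Nxx <- (Ng[hi] - 2 * N + Ng[lo]) / h^2
  F <- Ng * (1 - Ng)
  Fx <- (F[hi] - F[lo]) / (2 * h)
  D * Nxx - chi * Fx + lam * x * N * pmax(0, 1 - N)^2
}

# Independent coding of the Model 1, a_n = 1 reduction (non-volume-excluding
# limit): N_t = D(1-N) N_xx - chi (1-N)(N c_x)_x - mu N^2 + lam c N (1-N)^2,
# ghost extension from D N_x - chi N c_x = 0 (the a_n = 1 boundary flux).
nonexcluding_reduction_rhs <- function(N, D, chi, mu, lam, x) {
  n <- length(N)
  h <- x[2] - x[1]
  s0 <- if (D > 0) (chi / D) * N[1] else 0
  s1 <- if (D > 0) (chi / D) * N[n] else 0
  Ng <- c(N[2] - 2 * h * s0, N, N[n - 1] + 2 * h * s1)
  lo <- 1:n; hi <- 3:(n + 2)
  Nxx <- (Ng[hi] - 2 * N + Ng[lo]) / h^2
  Gx <- (Ng[hi] - Ng[lo]) / (2 * h)
  D * (1 - N) * Nxx - chi * (1 - N) * Gx - mu * N^2 +
    lam * x * N * pmax(0, 1 - N)^2
}

# Neumann heat-equation solution by cosine series, coefficients computed by
# trapezoidal quadrature of the initial profile on a fine auxiliary grid.
heat_cosine_solution <- function(ic_fun, D, x, t, n_modes = 80L) {
  xf <- seq(0, 1, length.out = 2001L)
  f <- ic_fun(xf)
  trapz <- function(y) sum(diff(xf) * (y[-1] + y[-length(y)]) / 2)
  a0 <- trapz(f)
  u <- rep(a0, length(x))
  for (m in seq_len(n_modes)) {
    am <- 2 * trapz(f * cos(m * pi * xf))
    u <- u + am * cos(m * pi * x) * exp(-D * m^2 * pi^2 * t)
  }
  u
}

# Gaussian bump used as a smooth test profile.
gaussian_bump <- function(x, center = 0.3, width = 0.06, amp = 0.3) {
  amp * exp(-((x - center) / width)^2)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
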