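test_that("initialization seeds alternating limbus sites with no stalk cells", {
  cfg <- reference_config()
  st <- init_lattice(cfg)
  expect_equal(tc_count(st), 100L)
  expect_equal(ec_count(st), 0L)
  expect_true(all(st$agent_i == 0L))
  expect_equal(sort(st$agent_j), seq(1L, 199L, by = 2L))
  # smallest even lattice: a single TC at (0, 1)
  st2 <- init_lattice(ca_config(R = 2, k = 1))
  expect_equal(tc_count(st2), 1L)
  expect_equal(c(st2$agent_i, st2$agent_j), c(0L, 1L))
  # TC count is R/2 for any even R
  for (R in c(4L, 8L, 50L))
    expect_equal(tc_count(init_lattice(ca_config(R = R, k = 1))), R %/% 2L)
})

test_that("movement resolves exclusion and anastomosis branches correctly", {
  # mover surrounded by TCs with a_n = 0: every attempt is excluded and the
  # state never changes (the exclusion branch has probability 1 - a_n = 1)
  cfg <- small_config(a_n = 0, k = 0, P_m = 1)
  st <- state_with_tcs(cfg, rbind(c(5, 5), c(4, 5), c(6, 5), c(5, 4), c(5, 6)))
  mover0 <- st$tc[6, 6]
  set.seed(11)
  for (r in 1:400) {
    out <- attempt_move(st, mover0, cfg)
    expect_equal(out$outcome$kind, "excluded_tc")
    expect_identical(out$state$tc, st$tc)
    expect_identical(out$state$ec, st$ec)
  }

  # anastomosis certain (a_n = 1): surround the mover so every direction
  # holds a TC, then the first successful attempt must annihilate both
  cfg1 <- small_config(a_n = 1, k = 0, P_m = 1)
  st <- state_with_tcs(cfg1, rbind(c(5, 5), c(4, 5), c(6, 5), c(5, 4), c(5, 6)))
  mover <- st$tc[6, 6]
  set.seed(2)
  out <- attempt_move(st, mover, cfg1)
  expect_equal(out$outcome$kind, "tip_tip")
  expect_equal(tc_count(out$state), 3L)
  expect_equal(ec_count(out$state), 2L)
  # ECs sit exactly at origin and target
  expect_equal(out$state$ec[6, 6], 1L)
  tgt <- out$outcome$target
  expect_equal(out$state$ec[tgt[1] + 1, tgt[2] + 1], 1L)

  # plain snail-trail move: TC relocates, EC left at origin
  cfg0 <- small_config(P_m = 1, k = 0)
  st <- state_with_tcs(cfg0, rbind(c(5, 5)))
  set.seed(3)
  out <- attempt_move(st, 1L, cfg0)
  expect_equal(out$outcome$kind, "moved")
  expect_equal(tc_count(out$state), 1L)
  expect_equal(out$state$ec[6, 6], 1L)
  expect_equal(ec_count(out$state), 1L)
})

test_that("boundary moves abort without changing state", {
  cfg <- small_config(P_m = 1, k = 0)
  st <- state_with_tcs(cfg, rbind(c(0, 0)))
  set.seed(5)
  n_aborted <- 0L
  for (r in 1:300) {
    out <- attempt_move(st, st$agent_id[1], cfg)
    if (out$outcome$kind == "boundary_aborted") {
      n_aborted <- n_aborted + 1L
      expect_identical(out$state$tc, st$tc)
      expect_identical(out$state$ec, st$ec)
    }
    st <- out$state
  }
  expect_gt(n_aborted, 0L)
})

test_that("Model 2 resolves self-loops, tip-to-sprout and EC exclusion", {
  surround_with_ecs <- function(st, owner) {
    for (s in list(c(6, 7), c(6, 5), c(5, 6), c(7, 6))) {
      st$ec[s[1], s[2]] <- 1L
      st$ec_owner[s[1], s[2]] <- owner
    }
    st
  }

  # all four neighbors hold the mover's own trail: every attempt aborts
  cfg <- small_config(mode = 2, a_e = 1, a_n = 0, P_m = 1, k = 0)
  st <- state_with_tcs(cfg, rbind(c(5, 5)))
  st <- surround_with_ecs(st, owner = st$agent_id[1])
  set.seed(8)
  for (r in 1:200) {
    out <- attempt_move(st, st$agent_id[1], cfg)
    expect_equal(out$outcome$kind, "selfloop_aborted")
    expect_identical(out$state$tc, st$tc)
    expect_identical(out$state$ec, st$ec)
  }

  # foreign ECs with a_e = 1: the first attempt is tip-to-sprout
  st <- state_with_tcs(cfg, rbind(c(5, 5)))
  st <- surround_with_ecs(st, owner = 999L)
  out <- attempt_move(st, st$agent_id[1], cfg)
  expect_equal(out$outcome$kind, "tip_sprout")
  st <- out$state
  expect_equal(tc_count(st), 0L)   # mover removed
  expect_equal(st$ec[6, 6], 1L)    # EC deposited at the origin
  tgt <- out$outcome$target
  expect_equal(st$ec[tgt[1] + 1, tgt[2] + 1], 1L) # target EC remains

  # EC exclusion when a_e = 0: moving onto a foreign EC never succeeds
  cfg0 <- small_config(mode = 2, a_e = 0, a_n = 0, P_m = 1, k = 0)
  st <- state_with_tcs(cfg0, rbind(c(5, 5)))
  st <- surround_with_ecs(st, owner = 999L)
  set.seed(9)
  for (r in 1:200) {
    out <- attempt_move(st, st$agent_id[1], cfg0)
    expect_equal(out$outcome$kind, "excluded_ec")
    st <- out$state
  }
  expect_equal(tc_count(st), 1L)
})

test_that("branching requires both transverse neighbors vacant", {
  cfg <- small_config(P_p = 1, k = 0) # P_b = c at the site
  # interior TC at maximal TAF: branches on first successful draw
  st <- state_with_tcs(cfg, rbind(c(10, 5)))
  set.seed(4)
  out <- attempt_branch(st, 1L, cfg)
  expect_equal(out$outcome$kind, "branched")
  expect_equal(tc_count(out$state), 2L)
  expect_equal(sort(out$state$agent_j), c(4L, 6L))
  expect_true(all(out$state$agent_i == 10L))
  expect_equal(ec_count(out$state), 0L) # branching never creates ECs
  # daughters have fresh ids
  expect_true(all(out$state$agent_id > 1L))

  # zero TAF at the limbus: P_b = 0, never branches
  st0 <- state_with_tcs(cfg, rbind(c(0, 5)))
  set.seed(6)
  for (r in 1:300)
    expect_equal(attempt_branch(st0, 1L, cfg)$outcome$kind, "no_attempt")

  # Model 2: an EC on one side blocks regardless of the draw
  cfg2 <- small_config(mode = 2, a_e = 1, P_p = 1, k = 0)
  st2 <- state_with_tcs(cfg2, rbind(c(10, 5)))
  st2$ec[11, 7] <- 1L
  st2$ec_owner[11, 7] <- 99L
  set.seed(7)
  for (r in 1:300) {
    out <- attempt_branch(st2, 1L, cfg2)
    expect_true(out$outcome$kind %in% c("blocked", "no_attempt"))
  }
  # a TC at the transverse edge can never branch
  ste <- state_with_tcs(cfg, rbind(c(10, 0)))
  set.seed(12)
  for (r in 1:100)
    expect_true(attempt_branch(ste, 1L, cfg)$outcome$kind
                %in% c("blocked", "no_attempt"))
})

test_that("per-event bookkeeping follows the birth-death ledger", {
  # Delta TC in {0, +1, -1, -2}, Delta EC in {0, +1, +2} keyed by outcome,
  # EC total never decreases, occupancy caps hold after every event
  cfgs <- list(small_config(a_n = 0.5, P_p = 0.3, k = 2),
               small_config(a_n = 0.3, P_p = 0.3, a_e = 0.5, mode = 2, k = 2))
  set.seed(101)
  for (cfg in cfgs) {
    st <- init_lattice(cfg)
    for (ev in 1:1500) {
      if (tc_count(st) == 0L) break
      n0 <- tc_count(st); e0 <- ec_count(st)
      id <- st$agent_id[sample.int(tc_count(st), 1L)]
      if (ev %% 3 == 0) {
        out <- attempt_branch(st, id, cfg)
        dtc_exp <- switch(out$outcome$kind, branched = 1L, 0L)
        dec_exp <- 0L
      } else {
        out <- attempt_move(st, id, cfg)
        dtc_exp <- switch(out$outcome$kind,
                          tip_tip = -2L, tip_sprout = -1L, 0L)
        dec_exp <- switch(out$outcome$kind,
                          moved = 1L, tip_sprout = 1L, tip_tip = 2L, 0L)
      }
      st <- out$state
      expect_identical(tc_count(st) - n0, dtc_exp)
      expect_identical(ec_count(st) - e0, dec_exp)
      # occupancy caps and registry consistency
      occ <- st$tc > 0L
      expect_true(all(occ + (cfg$mode == 2L) * (st$ec > 0L) <= 1L))
      expect_equal(sum(occ), tc_count(st))
      expect_true(all(st$tc[cbind(st$agent_i + 1L, st$agent_j + 1L)] ==
                        seq_along(st$agent_id)))
      if (tc_count(st) == 0L) break
    }
  }
})

test_that("tip cells are conserved without branching and anastomosis", {
  cfg <- small_config(P_p = 0, a_n = 0, k = 2)
  r <- run_realization(cfg, seed = 31, record_K = c(0L, 10L, 25L, 50L))
  expect_true(all(colSums(r$tc_cols) == cfg$R / 2))
  # Model 1 EC totals are non-decreasing in time
  expect_true(all(diff(colSums(r$ec_cols)) >= 0))
})

test_that("realizations are deterministic in the seed and engines agree", {
  for (cfg in list(small_config(a_n = 0.4, P_p = 0.25, k = 2),
                   small_config(a_n = 0.2, P_p = 0.3, a_e = 0.3, mode = 2,
                                k = 2))) {
    a <- run_realization(cfg, seed = 77, record_K = c(0L, 7L, 20L, 50L),
                         engine = "cpp", full = TRUE)
    b <- run_realization(cfg, seed = 77, record_K = c(0L, 7L, 20L, 50L),
                         engine = "R", full = TRUE)
    expect_identical(a$tc_cols, b$tc_cols)
    expect_identical(a$ec_cols, b$ec_cols)
    for (s in seq_along(a$K)) {
      expect_true(all(a$tc_grids[[s]] == b$tc_grids[[s]]))
      expect_true(all(a$ec_grids[[s]] == b$ec_grids[[s]]))
    }
    # same seed reproduces, different seed differs at K >= 1
    c1 <- run_realization(cfg, seed = 77, record_K = c(0L, 7L, 20L, 50L))
    expect_identical(c1$tc_cols, a$tc_cols)
    c2 <- run_realization(cfg, seed = 78, record_K = c(0L, 7L, 20L, 50L))
    expect_false(identical(c2$tc_cols, a$tc_cols))
    # record_K = 0 returns the initial condition
    r0 <- run_realization(cfg, seed = 1, record_K = 0L)
    expect_equal(sum(r0$tc_cols[1, 1]), cfg$R / 2)
    expect_equal(sum(r0$tc_cols[-1, 1]), 0)
    expect_equal(sum(r0$ec_cols), 0)
  }
})

test_that("single-tip outcome frequencies match the movement law", {
  # one TC mid-lattice: empirical outcome frequencies over many attempts
  # match P_m * direction probabilities within 3 standard errors
  cfg <- small_config(P_m = 0.7, k = 2, P_p = 0)
  st0 <- state_with_tcs(cfg, rbind(c(5, 5)))
  p <- direction_probabilities(taf_field(cfg), cfg$k, c(5, 5))
  n_trials <- 20000L
  set.seed(500)
  tally <- c(xp = 0, xm = 0, yp = 0, ym = 0, none = 0)
  for (r in seq_len(n_trials)) {
    out <- attempt_move(st0, 1L, cfg) # fresh state each trial
    oc <- out$outcome
    if (oc$kind == "no_attempt") {
      tally["none"] <- tally["none"] + 1
    } else {
      d <- oc$target - oc$origin
      key <- if (d[1] == 1) "xp" else if (d[1] == -1) "xm"
             else if (d[2] == 1) "yp" else "ym"
      tally[key] <- tally[key] + 1
    }
  }
  expect_equal(sum(tally), n_trials)
  probs <- c(cfg$P_m * p, none = 1 - cfg$P_m)
  for (key in names(probs)) {
    se <- sqrt(probs[[key]] * (1 - probs[[key]]) / n_trials)
    expect_lt(abs(tally[[key]] / n_trials - probs[[key]]), 3 * se)
  }
})

test_that("a single tip cell diffuses like the projected unbiased walk", {
  # symmetric-exclusion limit: k = 0, no branching, no anastomosis; the
  # column distribution after K steps matches brute-force iteration of the
  # 1-D walk transition matrix within 3 standard errors
  cfg <- ca_config(R = 20, k = 0, P_p = 0, a_n = 0, tau = 0.01,
                   K_IC = 1, K_max = 12)
  K <- 12L
  M <- 10000L
  counts <- numeric(cfg$R + 1L)
  for (m in seq_len(M)) {
    r <- run_realization(cfg, seed = 90000 + m, record_K = K,
                         tc_positions = rbind(c(2L, 10L)))
    counts <- counts + r$tc_cols[, 1L]
  }
  T <- walk_transition_matrix(cfg)
  p <- numeric(cfg$R + 1L); p[3L] <- 1 # start at column i = 2
  for (s in seq_len(K)) p <- as.vector(p %*% T)
  phat <- counts / M
  # compare bins with adequate expected counts; pool the far tail
  main <- which(M * p >= 5)
  for (i in main) {
    se <- sqrt(p[i] * (1 - p[i]) / M)
    expect_lt(abs(phat[i] - p[i]), 3 * se)
  }
  p_tail <- sum(p[-main])
  se_tail <- sqrt(p_tail * (1 - p_tail) / M)
  expect_lt(abs(sum(phat[-main]) - p_tail), 3 * se_tail + 1e-12)
})
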