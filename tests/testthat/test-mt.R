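test_that("lateral excitation applies both of its gates", {
  p <- mt_params()
  H <- 15L
  v_cs <- array(1, c(H, H, p$O))
  zero <- array(0, c(H, H, p$N))
  expect_true(all(lateral_excitation(zero, v_cs, p) == 0))
  # all 49 window units at 0.1 and the form gate open: lambda = 4.9
  v <- array(0, c(H, H, p$N)); v[, , 1] <- 0.1
  lam <- lateral_excitation(v, v_cs, p)
  expect_equal(lam[8, 8, 1], 4.9, tolerance = 1e-12)
  # form gate closed kills it
  expect_true(all(lateral_excitation(v, array(0, c(H, H, p$O)), p) == 0))
  # forcing the gate open restores it without form input
  lam2 <- lateral_excitation(v, NULL, p, force_gate_open = TRUE)
  expect_equal(lam2[8, 8, 1], 4.9, tolerance = 1e-12)
})

test_that("inter-directional inhibition counts the other channels", {
  v <- array(0, c(5, 5, 8))
  expect_true(all(interdirectional_inhibition(v) == 0))
  v[3, 3, 2] <- 0.5
  g <- interdirectional_inhibition(v)
  expect_equal(g[3, 3, 1], 0.5)
  expect_equal(g[3, 3, 2], 0)
  v2 <- array(1, c(5, 5, 8))
  expect_true(all(abs(interdirectional_inhibition(v2) - 7) < 1e-12))
})

test_that("long-range inhibition pools other channels over its window mean", {
  p <- mt_params()
  v <- array(0, c(20, 20, 8))
  expect_true(all(longrange_inhibition(v, p) == 0))
  v[10, 10, 3] <- 0.3
  xi <- longrange_inhibition(v, p)
  # window-mean semantics: a single active unit contributes 0.3/169 to
  # every other-channel unit within the 13 x 13 window
  expect_equal(xi[10, 10, 1], 0.3 / 169, tolerance = 1e-12)
  expect_equal(xi[16, 16, 1], 0.3 / 169, tolerance = 1e-12)
  expect_equal(xi[17, 17, 1], 0, tolerance = 1e-12)  # outside the window
  expect_equal(xi[10, 10, 3], 0)                     # own channel excluded
  v2 <- array(1, c(20, 20, 8))
  xi2 <- longrange_inhibition(v2, p)
  expect_equal(xi2[10, 10, 1], 7, tolerance = 1e-12)
})

test_that("one Euler step reproduces the hand-computed update", {
  p <- mt_params()
  H <- 9L
  state <- mt_state_init(H, H, p)
  state$v_mt[5, 5, 1] <- 0.5
  v_cx <- array(0, c(H, H, p$N)); v_cx[5, 5, 1] <- 0.2
  zero <- array(0, c(H, H, p$N))
  # Lambda = c_r and Delta = 0 put the surround exactly at its crossover,
  # so chi = 0 and the drive reduces to Gmtcx v_cx - tau_mt v_mt
  Lam <- matrix(p$c_r, H, H)
  res <- mt_step(state, v_cx, zero, zero, Lam, zero, NULL, p,
                 force_gate_open = TRUE)
  expect_equal(res$state$v_mt[5, 5, 1], 0.50095, tolerance = 1e-12)
  expect_true(all(res$state$v_mt[-5 * H] >= 0))
  # upper clip: v at 1 with non-negative drive stays 1
  state2 <- mt_state_init(H, H, p)
  state2$v_mt[5, 5, 1] <- 1
  v_cx2 <- array(0, c(H, H, p$N)); v_cx2[5, 5, 1] <- 1
  res2 <- mt_step(state2, v_cx2, zero, zero, Lam, zero, NULL, p,
                  force_gate_open = TRUE)
  expect_equal(res2$state$v_mt[5, 5, 1], 1)
})

test_that("the all-zero state is a fixed point", {
  p <- mt_params()
  H <- 9L
  state <- mt_state_init(H, H, p)
  zero <- array(0, c(H, H, p$N))
  for (i in 1:5)
    state <- mt_step(state, zero, zero, zero, matrix(0, H, H), zero, NULL,
                     p, force_gate_open = TRUE)$state
  expect_true(all(state$v_mt == 0))
})

test_that("delayed inhibition reads the state exactly T_in in the past", {
  p <- mt_params()
  H <- 9L
  n_delay <- as.integer(round(p$T_in / p$dt))
  state <- mt_state_init(H, H, p)
  zero <- array(0, c(H, H, p$N))
  Lam <- matrix(0, H, H)
  set.seed(99)
  history <- vector("list", 50L)
  for (t in 1:50) {
    # delayed state visible before this step
    del <- mtsurround:::.delayed_state(state)
    if (t <= n_delay) expect_null(del)
    else expect_identical(del, history[[t - n_delay]])
    history[[t]] <- state$v_mt
    v_cx <- array(runif(H * H * p$N, 0, 0.2), c(H, H, p$N))
    state <- mt_step(state, v_cx, zero, zero, Lam, zero, NULL, p,
                     force_gate_open = TRUE)$state
  }
})

test_that("a blank stimulus leaves the MT sheet silent", {
  p <- mt_params()
  frames <- mtsurround:::frame_sequence(array(0, c(32, 32, 45)), 0.25, 0.01)
  trace <- run_model(frames, p, mode = "component", store_chi = FALSE)
  expect_true(all(trace$v_mt == 0))
})

test_that("full runs keep every activity variable within [0, 1]", {
  trace <- bars_trace()
  expect_gte(min(trace$v_mt), 0)
  expect_lte(max(trace$v_mt), 1)
  expect_gte(min(trace$v_es), 0)
  expect_lte(max(trace$v_es), 1)
})
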