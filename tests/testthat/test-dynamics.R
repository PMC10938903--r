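sync <- update_schedule("synchronous")

test_that("synchronous steps reproduce the mutual-inhibition transitions", {
  net <- fixture("mutual_inhibition")
  e <- walker_ensemble(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  out <- step(e, net, sync)$states
  expect_identical(
    out,
    matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE), ncol = 2)
  )
  expect_equal(out[2, ], c(TRUE, FALSE)) # (1,0) is a steady state
})

test_that("asynchronous step updates exactly one node per walker", {
  net <- parse_network("A, !A")
  e <- walker_ensemble(matrix(FALSE, 5, 1))
  out <- step(e, net, update_schedule("asynchronous", seed = 3))
  expect_true(all(out$states)) # the only node is always selected and flips
  expect_identical(out$t, 1L)

  net2 <- fixture("three_cycle")
  e2 <- sample_initial_states(3, 50, seed = 4)
  out2 <- step(e2, net2, update_schedule("asynchronous", seed = 5))
  changed <- rowSums(out2$states != e2$states)
  expect_true(all(changed <= 1))
})

test_that("schedule and initial-state sampling are reproducible", {
  e1 <- sample_initial_states(4, 100, seed = 9)
  e2 <- sample_initial_states(4, 100, seed = 9)
  expect_identical(e1$states, e2$states)
  expect_false(identical(e1$states, sample_initial_states(4, 100, seed = 10)$states))

  net <- fixture("three_cycle")
  e3 <- sample_initial_states(3, 100, seed = 9)
  s1 <- step(e3, net, update_schedule("asynchronous", seed = 2))
  s2 <- step(e3, net, update_schedule("asynchronous", seed = 2))
  expect_identical(s1$states, s2$states)

  e <- sample_initial_states(1, 1, seed = 1)
  expect_true(e$states[1, 1] %in% c(TRUE, FALSE))
})

test_that("uniform initial sampling hits all states at the expected rate", {
  W <- 4e5
  e <- sample_initial_states(2, W, seed = 17)
  code <- e$states[, 1] + 2 * e$states[, 2]
  freq <- as.vector(table(factor(code, levels = 0:3))) / W
  # binomial sd is sqrt(.25*.75/W) ~ 0.00068; 0.005 is > 7 sigma
  expect_true(all(abs(freq - 0.25) < 0.005))
})

test_that("window means match closed-form values on the worked examples", {
  osc <- parse_network("A, !A")
  avg <- run_with_window(osc, walker_ensemble(matrix(0)), sync, T_b = 10, T_w = 40)
  expect_equal(as.vector(avg$means), 0.5)

  mi <- fixture("mutual_inhibition")
  avg <- run_with_window(mi, walker_ensemble(matrix(c(1, 0), 1)), sync, T_b = 8, T_w = 16)
  expect_equal(as.vector(avg$means), c(1, 0))

  ops <- fixture("oscillator_plus_source")
  avg <- run_with_window(ops, walker_ensemble(matrix(c(0, 1), 1)), sync, T_b = 8, T_w = 16)
  expect_equal(as.vector(avg$means), c(0.5, 1))

  expect_error(run_with_window(osc, walker_ensemble(matrix(0)), sync, 4, 2), "multiple of 4")
})

test_that("window means are integer multiples of 1/T_w", {
  net <- fixture("three_cycle")
  for (scheme in c("synchronous", "asynchronous")) {
    sched <- update_schedule(scheme, seed = 8)
    avg <- run_with_window(net, sample_initial_states(3, 40, seed = 3), sched,
      T_b = 20, T_w = 24
    )
    expect_true(all(abs(avg$means * 24 - round(avg$means * 24)) < 1e-9))
    expect_true(all(avg$means >= 0 & avg$means <= 1))
  }
})

test_that("convergence check measures quarter-mean disagreement", {
  # point attractor: zero disagreement
  avg <- run_with_window(
    fixture("all_constant"),
    sample_initial_states(2, 20, seed = 2), sync,
    T_b = 4, T_w = 16
  )
  cc <- convergence_check(avg, tol = 0)
  expect_true(cc$converged)
  expect_equal(cc$worst, 0)

  # period-2 oscillator with T_w a multiple of 8: quarters agree exactly
  avg <- run_with_window(
    parse_network("A, !A"), walker_ensemble(matrix(0)), sync,
    T_b = 3, T_w = 16
  )
  expect_equal(convergence_check(avg)$worst, 0)

  # asynchronous mutual inhibition at defaults passes the stated tolerance
  avg <- run_with_window(
    fixture("mutual_inhibition"),
    sample_initial_states(2, 2500, seed = 21),
    update_schedule("asynchronous", seed = 22)
  )
  expect_true(convergence_check(avg, tol = 0.0066)$converged)
})

test_that("synchronous dynamics is deterministic", {
  net <- fixture("three_cycle")
  e <- sample_initial_states(3, 64, seed = 6)
  a <- run_with_window(net, e, sync, T_b = 13, T_w = 20)
  b <- run_with_window(net, e, sync, T_b = 13, T_w = 20)
  expect_identical(a$states, b$states)
  expect_identical(a$means, b$means)
})

test_that("paired runs: constants recover, source flips are permanent", {
  # flipped constant node re-agrees after its first update
  net <- fixture("all_constant")
  X0 <- sample_initial_states(2, 100, seed = 12)$states
  for (scheme in c("synchronous", "asynchronous")) {
    sched <- update_schedule(scheme, seed = 13)
    pr <- run_pair_window(net, X0, 1L, sched, T_b = 200, T_w = 40)
    expect_true(all(pr$hamming == 0))
  }
  # flipped source node never re-agrees
  net <- fixture("oscillator_plus_source")
  X0 <- sample_initial_states(2, 100, seed = 14)$states
  for (scheme in c("synchronous", "asynchronous")) {
    sched <- update_schedule(scheme, seed = 15)
    pr <- run_pair_window(net, X0, 2L, sched, T_b = 50, T_w = 40)
    expect_true(all(abs(pr$mean_x[, 2] - pr$mean_y[, 2]) == 1))
    expect_true(all(pr$hamming >= 1))
  }
})

test_that("ensemble means converge to the exact long-run averages", {
  # W = 2500 keeps the standard error of a mean binary value below 0.01
  for (name in c("mutual_inhibition", "three_cycle")) {
    net <- fixture(name)
    for (scheme in c("synchronous", "asynchronous")) {
      sched <- update_schedule(scheme, seed = 31)
      avg <- run_with_window(net, sample_initial_states(net$N, 2500, seed = 30), sched)
      expect_true(
        all(abs(colMeans(avg$means) - exact_node_means(net, scheme)) < 3 * 0.01),
        info = paste(name, scheme)
      )
    }
  }
})

test_that("asynchronous schedules require a seed", {
  expect_error(update_schedule("asynchronous"), "seed")
})
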