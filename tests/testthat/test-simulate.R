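chain_net <- logical_network(c("input E", "A = E", "B = A"),
                             name = "chain")

test_that("constant drive saturates a pure activation chain", {
  sim <- simulate_network(chain_net, env = c(E = 100),
                          config = sim_config(seed = 1))
  expect_equal(unname(sim$activity[c("E", "A", "B")]), c(100, 100, 100))
  sim0 <- simulate_network(chain_net, env = c(E = 0),
                           config = sim_config(seed = 1))
  expect_equal(unname(sim0$activity[c("E", "A", "B")]), c(0, 0, 0))
})

test_that("external activity tracks its level within Bernoulli sampling error", {
  # 4 SE of a Bernoulli(0.5) mean over a window of 300: ~11.5 points
  sim <- simulate_network(chain_net, env = c(E = 50),
                          config = sim_config(seed = 2))
  tol <- 4 * 100 * sqrt(0.25 / 300)
  expect_lt(abs(sim$activity[["E"]] - 50), tol)
  expect_lt(abs(sim$activity[["A"]] - 50), tol)
})

test_that("knockout clamps and forced activation override the rules", {
  sim <- simulate_network(chain_net, env = c(E = 100),
                          pert = perturbation(clamp_off = "A"),
                          config = sim_config(seed = 3))
  expect_identical(sim$activity[["A"]], 0)
  expect_identical(sim$activity[["B"]], 0)  # downstream of the clamp

  for (level in c(20, 50, 80)) {
    simf <- simulate_network(chain_net, env = c(E = 0),
                             pert = perturbation(forced = c(A = level)),
                             config = sim_config(seed = 4))
    tol <- 4 * 100 * sqrt(level / 100 * (1 - level / 100) / 300)
    expect_lt(abs(simf$activity[["A"]] - level), tol)
  }
  expect_error(perturbation(clamp_off = "A", forced = c(A = 50)),
               "both clamped and forced")
  expect_error(
    simulate_network(chain_net, env = c(E = 0),
                     pert = perturbation(clamp_off = "nope")),
    "absent from network")
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- sim_config(seed = 99, return_trajectory = TRUE)
  s1 <- simulate_network(chain_net, env = c(E = 37), config = cfg)
  s2 <- simulate_network(chain_net, env = c(E = 37), config = cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$activity, s2$activity)
})

test_that("trajectories have the documented shape and recompute activity", {
  cfg <- sim_config(total_iterations = 120, window = 50, seed = 5,
                    return_trajectory = TRUE)
  sim <- simulate_network(chain_net, env = c(E = 60), config = cfg)
  expect_equal(dim(sim$trajectory), c(121, 3))
  expect_true(all(sim$trajectory %in% 0:1))
  expect_equal(activity_from_trajectory(sim$trajectory, 50), sim$activity)
  expect_true(all(sim$activity >= 0 & sim$activity <= 100))
})

test_that("single steps follow the update semantics", {
  state <- c(E = 1, A = 0, B = 1)
  set.seed(1)
  nxt <- step_network(chain_net, state, env = c(E = 0))
  expect_identical(nxt[["E"]], 0L)        # level 0: never ON
  expect_identical(nxt[["A"]], 1L)        # copies current E
  expect_identical(nxt[["B"]], 0L)        # copies current A
  set.seed(1)
  nxt2 <- step_network(chain_net, state, env = c(E = 100),
                       pert = perturbation(clamp_off = "A"))
  expect_identical(nxt2[["A"]], 0L)
})

test_that("fixed-environment mode holds external nodes at their initial draw", {
  cfg <- sim_config(seed = 8, env_resample = "fixed",
                    return_trajectory = TRUE)
  sim <- simulate_network(chain_net, env = c(E = 50), config = cfg)
  expect_equal(length(unique(sim$trajectory[, "E"])), 1)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(total_iterations = 100, window = 200),
               "window must not exceed")
  expect_error(sim_config(initial_state_policy = "fixed"),
               "requires fixed_state")
  expect_error(
    simulate_network(chain_net, env = c(E = 150),
                     config = sim_config(seed = 1)),
    "\\[0, 100\\]")
  expect_error(
    simulate_network(chain_net, env = c(Z = 10),
                     config = sim_config(seed = 1)),
    "absent from network")
  expect_error(
    simulate_network(chain_net, env = setNames(numeric(0), character(0)),
                     config = sim_config(seed = 1)),
    "no activity level")
})
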