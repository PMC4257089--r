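ref_model <- build_reference_model()
wt_env <- build_environment("Tissue_WT")

test_that("knockout experiments clamp the target to zero in every simulation", {
  ko <- suppressMessages(run_experiment(
    ref_model, wt_env, "KO", sim_config(seed = 71), n_simulations = 20))
  expect_true(all(ko$activity[, "CAV1"] == 0))
  expect_equal(ko$summary$mean[ko$summary$node == "CAV1"], 0)
})

test_that("heterozygous forcing holds the target near 50 percent activity", {
  het <- suppressMessages(run_experiment(
    ref_model, wt_env, "Het50", sim_config(seed = 72), n_simulations = 200))
  expect_lt(abs(het$summary$mean[het$summary$node == "CAV1"] - 50), 2)
})

test_that("experiments are pure functions of their seed", {
  cfg <- sim_config(seed = 73)
  r1 <- suppressMessages(run_experiment(ref_model, wt_env, "RandomActivation",
                                        cfg, n_simulations = 15))
  r2 <- suppressMessages(run_experiment(ref_model, wt_env, "RandomActivation",
                                        cfg, n_simulations = 15))
  expect_identical(r1$activity, r2$activity)
  expect_identical(r1$summary, r2$summary)
  expect_error(
    run_experiment(ref_model, wt_env, "WT", sim_config(), n_simulations = 10),
    "seed must be set")
  expect_error(
    run_experiment(ref_model, wt_env, "WT", cfg, n_simulations = 1),
    "at least 2")
})

test_that("ranking orders nodes by absolute shift with lexicographic ties", {
  base <- fake_experiment(c(A = 50, B = 50, C = 50, X = 50))
  cond <- fake_experiment(c(A = 50, B = 50, C = 50, X = 90), genotype = "KO")
  top <- rank_most_affected(cond, base, k = 2)
  expect_equal(top$node[1], "X")
  expect_equal(top$delta[1], 40)

  same <- rank_most_affected(base, base)
  expect_equal(same$delta, rep(0, 4))
  expect_equal(same$node, sort(same$node))   # lexicographic on full tie

  base3 <- fake_experiment(c(A = 50, B = 50, C = 50))
  cond3 <- fake_experiment(c(A = 60, B = 20, C = 70))
  top2 <- rank_most_affected(cond3, base3, k = 2)
  expect_equal(top2$node, c("B", "C"))       # |-30| then |+20|
  expect_equal(top2$delta, c(-30, 20))       # signs preserved

  other <- fake_experiment(c(A = 1, Z = 2))
  expect_error(rank_most_affected(cond3, other), "different node sets")
})

test_that("dose-response sweeps track an identity chain", {
  net <- logical_network(c("input E", "A = E", "B = A"))
  curve <- dose_response(net, "E", "B", grid = seq(0, 100, 25), reps = 12,
                         config = sim_config(seed = 74),
                         background = c(E = 0))
  tol <- 4 * 100 * sqrt(0.25 / 300) / sqrt(12) + 1e-9
  expect_true(all(abs(curve$mean_response - curve$level) <=
                    pmax(tol, 4 * 100 * sqrt(curve$level / 100 *
                           (1 - curve$level / 100) / 300) / sqrt(12)) + 1e-9))
  expect_equal(curve$mean_response[curve$level == 0], 0)  # no other drive
  expect_error(dose_response(net, "A", "B", config = sim_config(seed = 1)),
               "not an external node")
})

test_that("monotonicity score is Spearman rho with average-rank ties", {
  up <- data.frame(level = c(0, 50, 100), mean_response = c(10, 40, 80))
  expect_equal(monotonicity_score(up), 1)
  down <- data.frame(level = c(0, 50, 100), mean_response = c(80, 40, 10))
  expect_equal(monotonicity_score(down), -1)
  tied <- data.frame(level = c(0, 50, 100), mean_response = c(10, 10, 80))
  expect_equal(monotonicity_score(tied),
               brute_force_spearman(tied$level, tied$mean_response))
  expect_error(monotonicity_score(up[1:2, ]), "at least 3")
})
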