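test_that("tissue conditions carry the published stimulus categories", {
  wt <- build_environment("Tissue_WT")
  expect_equal(unname(wt$categories[c("ECM", "GP130", "IL4", "IL10")]),
               c("High", "Zero", "Low", "Med"))
  da <- build_environment("Tissue_DiseaseA")
  expect_equal(unname(da$categories[c("IL2", "IL10", "ECM", "CGC")]),
               c("High", "High", "High", "MedHigh"))
  db <- build_environment("Tissue_DiseaseB")
  expect_equal(unname(db$categories[["IL10"]]), "FullRange")
  # all three conditions categorize the same 29 stimuli
  expect_length(wt$categories, 29)
  expect_identical(names(wt$categories), names(da$categories))
  expect_identical(names(wt$categories), names(db$categories))
})

test_that("unknown conditions fail with the list of valid ones", {
  expect_error(build_environment("Blood_WT"), "Tissue_WT")
})

test_that("randomized sampling respects category subranges", {
  spec <- build_environment("Tissue_DiseaseB")
  set.seed(61)
  draws <- replicate(2000, sample_environment(spec))
  expect_true(all(draws["GP130", ] == 0))                 # Zero: exactly 0
  il10 <- draws["IL10", ]                                  # FullRange
  expect_gt(min(il10), 0 - 1e-9)
  expect_lt(max(il10), 100 + 1e-9)
  expect_lt(abs(mean(il10) - 50), 2)
  ecm <- draws["ECM", ]                                    # High subrange
  expect_true(all(ecm >= category_range("High")[1]))
  il4 <- draws["IL4", ]                                    # Low subrange
  expect_true(all(il4 <= category_range("Low")[2]))
})

test_that("fixed mode pins categories to their representative levels", {
  spec <- build_environment("Tissue_WT")
  lv <- sample_environment(spec, level_mode = "fixed")
  expect_equal(unname(lv[c("ECM", "GP130", "IL4", "IL10")]),
               c(90, 0, 25, 50))
  # repeated draws identical (no randomness consumed)
  expect_identical(lv, sample_environment(spec, level_mode = "fixed"))
})

test_that("stimulus names map onto network inputs, missing ones default", {
  spec <- build_environment("Tissue_WT")
  lv <- sample_environment(spec, level_mode = "fixed")
  expect_true("Galpha12_13_L" %in% names(lv))   # Alpha_13L mapped
  expect_false("Alpha_13L" %in% names(lv))
  net <- build_reference_model()
  env <- env_assignment_for_network(lv, net)
  expect_setequal(names(env), network_nodes(net, "external"))
  expect_equal(unname(env[["GalphaQ_L"]]), 0)   # not in the condition table
  expect_equal(unname(env[["CAV1_Activator"]]), 0)
})
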