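test_that("the reference model is structurally valid and frozen", {
  net <- build_reference_model()
  rep <- validate_network(net)
  expect_equal(nrow(rep$errors), 0)
  expect_equal(nrow(rep$warnings), 0)
  expect_identical(reference_model_digest(net),
                   reference_model_frozen_digest())
  shipped <- system.file("extdata", "cd4_tcell_cav1_model.txt",
                         package = "tcellsim")
  expect_identical(unname(tools::md5sum(shipped)),
                   reference_model_frozen_digest())
})

test_that("the reference model contains the curated pathway components", {
  net <- build_reference_model()
  required <- c("CAV1", "TCR", "LCK", "FYN", "ZAP70", "TCRzeta", "LAT",
                "GRB2", "SHC1", "SOS", "RAS", "KSR1", "RAF", "MEK", "ERK",
                "CARMA1", "BCL10", "MALT1", "NFKB", "CD26", "CD28", "PI3K",
                "AKT", "RAC1", "ARP2_3", "F_actin", "GATA3", "SHP2",
                "NOS2A", "Cdc42", "IL2R", "IL10R", "Integrin",
                "Proliferation", "Survival", "Cytoskeletal_Rearrangement")
  expect_true(all(required %in% network_nodes(net, "internal")))
  ext_required <- c("APC", "ECM", "IL2", "IL10", "GalphaQ_L",
                    "Galpha12_13_L", "CAV1_Activator", "TGFB", "IL4")
  expect_true(all(ext_required %in% network_nodes(net, "external")))
  # the activator feeds CAV1 so forcing can bypass upstream regulation
  expect_true("CAV1_Activator" %in% net$nodes[["CAV1"]]$rule$regulators)
})

test_that("CD28 signaling is structurally independent of CAV1", {
  net <- build_reference_model()
  ancestors <- function(node) {
    seen <- character(0)
    frontier <- node
    while (length(frontier) > 0) {
      nxt <- unique(unlist(lapply(frontier, function(n) {
        spec <- net$nodes[[n]]
        if (spec$kind == "internal") spec$rule$regulators else character(0)
      })))
      frontier <- setdiff(nxt, seen)
      seen <- union(seen, frontier)
    }
    seen
  }
  expect_false("CAV1" %in% ancestors("CD28"))
  expect_false("CAV1" %in% ancestors("PI3K"))
  expect_false("CAV1" %in% ancestors("AKT"))
  # while the knockout signature nodes all depend on CAV1
  for (node in c("CD26", "CARMA1", "FYN", "SHC1", "SOS", "SHP2",
                 "NOS2A", "BCL10", "GRB2")) {
    expect_true("CAV1" %in% ancestors(node), label = node)
  }
})

test_that("manifest covers every edge with a sign and an annotation", {
  man <- reference_model_manifest()
  net <- build_reference_model()
  internal <- man[man$kind == "internal", ]
  for (nm in network_nodes(net, "internal")) {
    regs <- net$nodes[[nm]]$rule$regulators
    expect_setequal(internal$regulator[internal$node == nm], regs)
  }
  expect_true(all(nzchar(man$annotation)))
  expect_true(all(internal$sign %in% c("activation", "inhibition", "dual")))
  expect_equal(internal$sign[internal$node == "CD26" &
                               internal$regulator == "CAV1"], "inhibition")
  expect_equal(internal$sign[internal$node == "KSR1" &
                               internal$regulator == "CAV1"], "activation")
})

test_that("random network generation is seeded and respects its parameters", {
  n1 <- generate_random_network(8, 3, max_regulators = 3, seed = 81)
  n2 <- generate_random_network(8, 3, max_regulators = 3, seed = 81)
  expect_identical(write_rule_lines <- capture.output(print(n1)),
                   capture.output(print(n2)))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_rule_file(n1, p1); write_rule_file(n2, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_length(network_nodes(n1, "external"), 3)
  expect_length(network_nodes(n1, "internal"), 5)
  for (nm in network_nodes(n1, "internal")) {
    expect_lte(length(n1$nodes[[nm]]$rule$regulators), 3)
  }
  expect_error(generate_random_network(5, 5, seed = 1), "n_inputs < n_nodes")
})

test_that("zero-bias networks are constitutively OFF", {
  net <- generate_random_network(7, 2, max_regulators = 2, bias = 0,
                                 seed = 82)
  for (nm in network_nodes(net, "internal")) {
    expect_true(all(rule_truth_table(net$nodes[[nm]]$rule) == 0L))
  }
  env <- setNames(c(80, 60), network_nodes(net, "external"))
  o <- stationary_oracle(net, env)
  expect_equal(unname(o[network_nodes(net, "internal")]), rep(0, 5))
})
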