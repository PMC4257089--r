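expect_same_semantics <- function(a, b) {
  expect_setequal(network_nodes(a), network_nodes(b))
  expect_setequal(network_nodes(a, "external"), network_nodes(b, "external"))
  for (nm in network_nodes(a, "internal")) {
    expect_identical(b$nodes[[nm]]$rule$regulators,
                     a$nodes[[nm]]$rule$regulators)
    expect_identical(rule_truth_table(b$nodes[[nm]]$rule),
                     rule_truth_table(a$nodes[[nm]]$rule))
  }
}

test_that("write then read preserves networks node-by-node", {
  for (seed in c(31, 32, 33)) {
    net <- generate_random_network(8, 3, max_regulators = 3, seed = seed)
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml_qual(net, path)
    expect_same_semantics(net, read_sbml_qual(path))
  }
})

test_that("the packaged reference model round-trips with identical truth tables", {
  net <- build_reference_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml_qual(net, path)
  expect_same_semantics(net, read_sbml_qual(path))
  # and the shipped copy is the same model
  shipped <- system.file("extdata", "cd4_tcell_cav1_model.sbml.xml",
                         package = "tcellsim")
  expect_same_semantics(net, read_sbml_qual(shipped))
})

sbml_stub <- function(species, transitions = "") {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" ',
    'level="3" version="1" qual:required="true"><model id="m">',
    '<qual:listOfQualitativeSpecies>', species,
    '</qual:listOfQualitativeSpecies>',
    '<qual:listOfTransitions>', transitions, '</qual:listOfTransitions>',
    '</model></sbml>')
}

qs <- function(id, max_level = 1) {
  sprintf(paste0('<qual:qualitativeSpecies qual:id="%s" qual:maxLevel="%d" ',
                 'qual:compartment="cell" qual:constant="false"/>'),
          id, max_level)
}

test_that("multi-valued species are rejected", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_stub(paste0(qs("A", 2), qs("B"))), path)
  expect_error(read_sbml_qual(path), "multi-valued species unsupported")
})

test_that("transitions without a default term are rejected", {
  tr <- paste0(
    '<qual:transition qual:id="tr_B">',
    '<qual:listOfInputs><qual:input qual:qualitativeSpecies="A" ',
    'qual:transitionEffect="none"/></qual:listOfInputs>',
    '<qual:listOfOutputs><qual:output qual:qualitativeSpecies="B" ',
    'qual:transitionEffect="assignmentLevel"/></qual:listOfOutputs>',
    '<qual:listOfFunctionTerms>',
    '<qual:functionTerm qual:resultLevel="1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><eq/><ci>A</ci><cn type="integer">1</cn></apply>',
    '</math></qual:functionTerm>',
    '</qual:listOfFunctionTerms></qual:transition>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_stub(paste0(qs("A"), qs("B")), tr), path)
  expect_error(read_sbml_qual(path), "missing defaultTerm")
})

test_that("unsupported MathML operators are rejected", {
  tr <- paste0(
    '<qual:transition qual:id="tr_B">',
    '<qual:listOfOutputs><qual:output qual:qualitativeSpecies="B" ',
    'qual:transitionEffect="assignmentLevel"/></qual:listOfOutputs>',
    '<qual:listOfFunctionTerms>',
    '<qual:defaultTerm qual:resultLevel="0"/>',
    '<qual:functionTerm qual:resultLevel="1">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><plus/><ci>A</ci><ci>B</ci></apply>',
    '</math></qual:functionTerm>',
    '</qual:listOfFunctionTerms></qual:transition>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_stub(paste0(qs("A"), qs("B")), tr), path)
  expect_error(read_sbml_qual(path), "unparseable MathML")
})
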