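## Curated reference CD4+ T-cell logical model.
##
## A miniature (~40 internal nodes) logical model of CD4+ T-cell signaling
## centred on caveolin-1 (CAV1). Every interaction encodes an established
## qualitative relationship: CAV1 scaffolds the TCR-proximal kinases (LCK,
## FYN) and the KSR1-organised RAF/MEK/ERK cascade, is required for
## integrin-dependent MAPK activation, and restrains the CD26, BCL10, RAC1
## and GATA3 branches (so knockout up-regulates them), while CD28
## co-stimulatory signaling to PI3K/AKT is CAV1-independent. The
## environment inputs are the stimuli of the tissue condition table plus
## the GalphaQ ligand and the synthetic CAV1 activator species used to
## force CAV1 activity independently of its upstream regulators.
##
## The model reproduces the qualitative simulation phenotypes (monotone
## dose-response validation curves; the knockout dysregulation signature);
## it is not a reconstruction of any larger published rule set.

reference_model_nodes <- function() {
  ext <- function(name, note) external_node(name, annotation = note)
  int <- function(name, rule, note) internal_node(name, rule,
                                                  annotation = note)
  passthrough <- "tissue-condition stimulus; aggregated into a milieu readout, does not gate the CAV1 phenotypes"
  list(
    ## --- environment inputs -------------------------------------------
    ext("APC", "antigen-presenting cell contact; drives TCR engagement and CD28 co-stimulation"),
    ext("ECM", "extracellular matrix; engages integrins"),
    ext("IL2", "interleukin-2; cytokine input to the MAPK pathway"),
    ext("IL2RB", "IL-2 receptor beta chain availability"),
    ext("IL10", "interleukin-10; immunosuppressive cytokine"),
    ext("IL10RA", "IL-10 receptor alpha chain availability"),
    ext("IL4", "interleukin-4; drives GATA3 induction"),
    ext("GalphaQ_L", "GalphaQ-coupled GPCR ligand; activates PI3K"),
    ext("Galpha12_13_L", "Galpha12/13-coupled GPCR ligand (the Alpha_13L stimulus); activates Cdc42"),
    ext("CAV1_Activator", "synthetic activator species used to force CAV1 activity independently of its upstream regulators"),
    ext("GalphaS_L", passthrough), ext("CGC", passthrough),
    ext("GP130", passthrough), ext("IFNB", passthrough),
    ext("IFNG", passthrough), ext("IFNGR1", passthrough),
    ext("IFNGR2", passthrough), ext("IL10RB", passthrough),
    ext("IL12", passthrough), ext("IL15", passthrough),
    ext("IL15RA", passthrough), ext("IL18", passthrough),
    ext("IL21", passthrough), ext("IL22", passthrough),
    ext("IL23", passthrough), ext("IL27", passthrough),
    ext("IL27RA", passthrough), ext("IL6", passthrough),
    ext("IL6RA", passthrough), ext("IL9", passthrough),
    ext("TGFB", passthrough),

    ## --- receptors and membrane-proximal signaling --------------------
    int("TCR", "APC",
        "T-cell receptor engagement by antigen-presenting cells"),
    int("CD28", "APC",
        "co-stimulatory receptor engaged at the immune synapse; CAV1-independent"),
    int("Integrin", "ECM",
        "integrin engagement by extracellular matrix"),
    int("CAV1", "CAV1_Activator | TCR | Integrin",
        "caveolin-1 scaffold, recruited on TCR and integrin engagement; the activator species bypasses this regulation"),
    int("LCK", "TCR & CAV1",
        "CAV1-dependent phosphorylation of p56lck after TCR engagement"),
    int("FYN", "TCR & CAV1",
        "CAV1-dependent FYN activation at the TCR"),
    int("TCRzeta", "TCR & (LCK | FYN)",
        "TCR-zeta chain phosphorylation by Src-family kinases"),
    int("ZAP70", "TCRzeta",
        "ZAP70 recruitment to phosphorylated TCR-zeta"),
    int("LAT", "ZAP70",
        "LAT adaptor phosphorylation by ZAP70"),
    int("GRB2", "LAT",
        "GRB2 recruitment to phosphorylated LAT"),
    int("SHC1", "LAT",
        "SHC1 adaptor recruitment downstream of LAT"),
    int("SOS", "GRB2 | SHC1",
        "SOS guanine-exchange activity via GRB2/SHC1 adaptors"),
    int("SHP2", "LAT & CAV1",
        "SHP2 phosphatase recruitment to the CAV1-scaffolded TCR signalosome"),
    int("CD26", "!CAV1",
        "CD26 surface availability; sequestered by interaction with CAV1, so knockout de-represses it"),

    ## --- NF-kB branch --------------------------------------------------
    int("CARMA1", "LAT & CAV1",
        "CARMA1 scaffold assembly downstream of TCR, CAV1-dependent"),
    int("BCL10", "TCR & !CAV1",
        "BCL10 signaling; restrained by CAV1, de-repressed on knockout"),
    int("MALT1", "BCL10 | CARMA1",
        "MALT1 paracaspase within the CBM complex"),
    int("IL10R", "IL10 & IL10RA",
        "IL-10 receptor engagement; immunosuppressive signal"),
    int("NFKB", "MALT1 & !IL10R",
        "NF-kB activation via the CBM complex, suppressed by IL-10 signaling"),
    int("NOS2A", "NFKB & CAV1",
        "inducible nitric-oxide synthase, NF-kB target requiring CAV1"),

    ## --- MAPK cascade ---------------------------------------------------
    int("IL2R", "IL2 & IL2RB",
        "IL-2 receptor engagement"),
    int("RAS", "SOS | IL2R",
        "RAS activation by SOS or IL-2 receptor signaling"),
    int("KSR1", "CAV1",
        "KSR1 scaffold organisation of the RAF/MEK/ERK cascade, CAV1-dependent"),
    int("RAF", "RAS & KSR1",
        "RAF activation on the KSR1 scaffold"),
    int("MEK", "RAF & Integrin",
        "MEK activation; full MAPK activation requires integrin co-engagement"),
    int("ERK", "MEK",
        "ERK activation by MEK"),
    int("MAPK", "ERK",
        "MAPK-pathway activity readout"),

    ## --- PI3K / cytoskeleton / effectors --------------------------------
    int("PI3K", "CD28 | GalphaQ_L",
        "PI3-kinase activation via CD28 co-stimulation or GalphaQ-coupled GPCRs; CAV1-independent"),
    int("AKT", "PI3K",
        "AKT activation downstream of PI3K"),
    int("RAC1", "Integrin | !CAV1",
        "RAC1 GTPase; integrin-activated and restrained by CAV1 (dysregulated on knockout)"),
    int("Cdc42", "Galpha12_13_L",
        "Cdc42 GTPase activation via Galpha12/13-coupled receptors"),
    int("ARP2_3", "RAC1 | Cdc42",
        "ARP2/3 actin-nucleation complex activated by Rho-family GTPases"),
    int("F_actin", "ARP2_3 & Integrin",
        "filamentous actin polymerisation at sites of adhesion"),
    int("GATA3", "IL4 | !CAV1",
        "GATA3 transcription factor; IL-4-driven and de-repressed on CAV1 knockout"),
    int("Proliferation", "ERK",
        "cellular proliferation downstream of the MAPK cascade"),
    int("Survival", "AKT | IL2R",
        "cell survival via AKT and IL-2 signals"),
    int("Cytoskeletal_Rearrangement", "F_actin",
        "cytoskeletal rearrangement / immune-synapse formation readout"),

    ## --- aggregated milieu readouts -------------------------------------
    int("STAT_Milieu",
        "IFNB | IFNG | IFNGR1 | IFNGR2 | IL12 | IL15 | IL15RA | IL18 | IL21 | IL22 | IL23",
        "aggregate readout of interferon/common-gamma-chain cytokine milieu"),
    int("Accessory_Milieu",
        "GalphaS_L | CGC | GP130 | IL10RB | IL27 | IL27RA | IL6 | IL6RA | IL9 | TGFB",
        "aggregate readout of accessory stimuli and receptor-chain availability")
  )
}

#' Build the packaged reference CD4+ T-cell model
#'
#' Deterministically constructs the curated CAV1-centred logical model of
#' CD4+ T-cell signaling described in the package vignette. The model
#' passes [validate_network()] with an empty report and satisfies the
#' documented qualitative constraints: six monotone dose-response
#' validation pairs, a CAV1-knockout dysregulation signature (CD26,
#' CARMA1, FYN, SHC1, SOS, SHP2, NOS2A, BCL10, GRB2) across all tissue
#' conditions, and CAV1-independence of CD28.
#'
#' @return A `logical_network`.
#' @export
build_reference_model <- function() {
  logical_network(reference_model_nodes(),
                  name = "CD4_Tcell_CAV1_reference", version = "1.0")
}

## Frozen MD5 of the canonical rule file; guards the packaged model (and
## with it the whole acceptance surface) against silent drift.
REFERENCE_MODEL_MD5 <- "d126661200164378c8ac681c82470dd1"

#' Frozen digest of the reference model
#'
#' MD5 of the model's canonical plain-text rule file. Used to detect
#' accidental drift of the packaged model: tests compare the constructed
#' model's digest against the stored constant.
#'
#' @param network A `logical_network` (defaults to the freshly built
#'   reference model).
#' @return MD5 hex string.
#' @export
reference_model_digest <- function(network = build_reference_model()) {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  write_rule_file(network, path)
  unname(tools::md5sum(path))
}

#' @rdname reference_model_digest
#' @export
reference_model_frozen_digest <- function() REFERENCE_MODEL_MD5

#' Reference model manifest
#'
#' One row per regulator -> node edge of the reference model, with the
#' interaction sign (activation / inhibition, from the rule's syntax) and
#' the node's curation annotation.
#'
#' @return Data frame (node, kind, regulator, sign, annotation).
#' @export
reference_model_manifest <- function() {
  net <- build_reference_model()
  rows <- list()
  for (n in net$nodes) {
    if (n$kind == "external") {
      rows[[length(rows) + 1L]] <- data.frame(
        node = n$name, kind = "external", regulator = NA_character_,
        sign = NA_character_, annotation = n$annotation,
        stringsAsFactors = FALSE)
      next
    }
    signs <- regulator_signs(n$rule)
    for (reg in names(signs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        node = n$name, kind = "internal", regulator = reg,
        sign = signs[[reg]], annotation = n$annotation,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Sign of each regulator from the expression tree (negated context ->
## inhibition; a regulator used in both contexts -> "dual").
regulator_signs <- function(rule) {
  signs <- list()
  walk <- function(node, neg) {
    switch(node$type,
      var = {
        s <- if (neg) "inhibition" else "activation"
        prev <- signs[[node$name]]
        signs[[node$name]] <<- if (is.null(prev) || identical(prev, s)) s
                               else "dual"
      },
      not = walk(node$arg, !neg),
      and = { walk(node$lhs, neg); walk(node$rhs, neg) },
      or  = { walk(node$lhs, neg); walk(node$rhs, neg) }
    )
  }
  walk(rule$expr, FALSE)
  unlist(signs)
}

#' Generate a random logical network
#'
#' Test-fixture generator: `n_inputs` external nodes (`E1`, `E2`, ...) and
#' `n_nodes - n_inputs` internal nodes (`N1`, ...) wired by drawing, for
#' each internal node, between 1 and `max_regulators` regulators uniformly
#' from all nodes (self-loops and cycles permitted) and a random truth
#' table whose entries are ON with probability `bias`. The truth table is
#' realised as a disjunctive-normal-form rule, so the generated network
#' round-trips through the rule grammar and SBML-qual unchanged.
#'
#' @param n_nodes Total number of nodes.
#' @param n_inputs Number of external nodes (`1 <= n_inputs < n_nodes`).
#' @param max_regulators Maximum regulators per internal node.
#' @param bias Probability that a truth-table row is ON (default 0.5).
#' @param seed Integer seed; the same seed reproduces the same network.
#' @return A `logical_network`.
#' @export
generate_random_network <- function(n_nodes, n_inputs, max_regulators = 2L,
                                    bias = 0.5, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  n_inputs <- as.integer(n_inputs)
  max_regulators <- as.integer(max_regulators)
  if (n_inputs < 1L || n_inputs >= n_nodes) {
    stop("need 1 <= n_inputs < n_nodes", call. = FALSE)
  }
  if (max_regulators < 1L) stop("max_regulators must be >= 1", call. = FALSE)
  stopifnot(bias >= 0, bias <= 1)
  set.seed(as.integer(seed))
  all_names <- c(paste0("E", seq_len(n_inputs)),
                 paste0("N", seq_len(n_nodes - n_inputs)))
  nodes <- lapply(seq_len(n_inputs), function(i) external_node(all_names[[i]]))
  for (i in seq.int(n_inputs + 1L, n_nodes)) {
    k <- sample.int(max_regulators, 1L)
    regs <- sample(all_names, k)
    tt <- stats::rbinom(2L^k, 1L, bias)
    nodes[[length(nodes) + 1L]] <-
      internal_node(all_names[[i]], dnf_from_truth_table(regs, tt))
  }
  logical_network(nodes,
                  name = sprintf("random_%d_%d_seed%d", n_nodes, n_inputs,
                                 as.integer(seed)))
}

## Express a truth table over `regs` (first regulator = least significant
## bit) as a rule string. Constant tables use a tautology/contradiction in
## the first regulator so the grammar (which has no literals) can hold them.
dnf_from_truth_table <- function(regs, tt) {
  k <- length(regs)
  stopifnot(length(tt) == 2L^k)
  if (all(tt == 0L)) return(sprintf("%s & !%s", regs[[1]], regs[[1]]))
  if (all(tt == 1L)) return(sprintf("%s | !%s", regs[[1]], regs[[1]]))
  terms <- character(0)
  for (row in which(tt == 1L) - 1L) {
    lits <- vapply(seq_len(k), function(j) {
      bit <- bitwAnd(row %/% 2L^(j - 1L), 1L)
      if (bit == 1L) regs[[j]] else paste0("!", regs[[j]])
    }, character(1))
    terms[[length(terms) + 1L]] <-
      if (k == 1L) lits else paste0("(", paste(lits, collapse = " & "), ")")
  }
  paste(terms, collapse = " | ")
}
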