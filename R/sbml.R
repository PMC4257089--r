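## SBML Level 3 qualitative-models (qual) import/export.
##
## Dialect: Boolean models only (qual:maxLevel = 1). Each internal node is a
## transition whose listOfFunctionTerms holds a defaultTerm with resultLevel
## 0 and a single functionTerm with resultLevel 1 carrying the rule as
## MathML (and/or/not over `eq(ci, 1)` atoms). External nodes are
## qualitative species with no transition.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_QUAL_NS <- "http://www.sbml.org/sbml/level3/version1/qual/version1"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Write a logical network as SBML-qual
#'
#' @param network A `logical_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sbml_qual()]
#' @export
write_sbml_qual <- function(network, path) {
  report <- validate_network(network)
  if (nrow(report$errors) > 0L) {
    stop("refusing to write invalid network", call. = FALSE)
  }
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:qual=\"%s\" level=\"3\" ",
                   "version=\"1\" qual:required=\"true\">"),
            SBML_CORE_NS, SBML_QUAL_NS),
    sprintf("  <model id=\"%s\">", xml_escape(network$metadata$name)),
    "    <listOfCompartments>",
    "      <compartment id=\"cell\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <qual:listOfQualitativeSpecies>"
  )
  for (n in network$nodes) {
    out <- c(out, sprintf(
      paste0("      <qual:qualitativeSpecies qual:id=\"%s\" ",
             "qual:compartment=\"cell\" qual:constant=\"false\" ",
             "qual:maxLevel=\"1\"/>"), n$name))
  }
  out <- c(out, "    </qual:listOfQualitativeSpecies>",
           "    <qual:listOfTransitions>")
  for (n in network$nodes) {
    if (n$kind != "internal") next
    out <- c(out, sprintf("      <qual:transition qual:id=\"tr_%s\">", n$name),
             "        <qual:listOfInputs>")
    for (reg in n$rule$regulators) {
      out <- c(out, sprintf(
        paste0("          <qual:input qual:qualitativeSpecies=\"%s\" ",
               "qual:transitionEffect=\"none\"/>"), reg))
    }
    out <- c(out,
      "        </qual:listOfInputs>",
      "        <qual:listOfOutputs>",
      sprintf(paste0("          <qual:output qual:qualitativeSpecies=\"%s\" ",
                     "qual:transitionEffect=\"assignmentLevel\"/>"), n$name),
      "        </qual:listOfOutputs>",
      "        <qual:listOfFunctionTerms>",
      "          <qual:defaultTerm qual:resultLevel=\"0\"/>",
      "          <qual:functionTerm qual:resultLevel=\"1\">",
      sprintf("            <math xmlns=\"%s\">", MATHML_NS),
      expr_to_mathml(n$rule$expr, indent = "              "),
      "            </math>",
      "          </qual:functionTerm>",
      "        </qual:listOfFunctionTerms>",
      "      </qual:transition>")
  }
  out <- c(out, "    </qual:listOfTransitions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

expr_to_mathml <- function(expr, indent = "") {
  nxt <- paste0(indent, "  ")
  switch(expr$type,
    var = c(paste0(indent, "<apply><eq/><ci>", expr$name,
                   "</ci><cn type=\"integer\">1</cn></apply>")),
    not = c(paste0(indent, "<apply><not/>"),
            expr_to_mathml(expr$arg, nxt),
            paste0(indent, "</apply>")),
    and = c(paste0(indent, "<apply><and/>"),
            expr_to_mathml(expr$lhs, nxt),
            expr_to_mathml(expr$rhs, nxt),
            paste0(indent, "</apply>")),
    or  = c(paste0(indent, "<apply><or/>"),
            expr_to_mathml(expr$lhs, nxt),
            expr_to_mathml(expr$rhs, nxt),
            paste0(indent, "</apply>"))
  )
}

## namespace-agnostic attribute lookup ("qual:maxLevel" vs "maxLevel")
qual_attr <- function(node, name) {
  attrs <- xml2::xml_attrs(node)
  hits <- attrs[sub("^.*:", "", names(attrs)) == name]
  if (length(hits) == 0L) NA_character_ else hits[[1L]]
}

#' Read a Boolean SBML-qual model
#'
#' Accepts SBML Level 3 files using the qualitative-models package with
#' Boolean species only (`qual:maxLevel = 1`). Species without a transition
#' become external nodes. Function terms must consist of MathML
#' `and`/`or`/`not`/`eq` over species compared with 0/1; a `defaultTerm`
#' with `resultLevel` 0 and one `functionTerm` with `resultLevel` 1 are
#' required per transition.
#'
#' @param path Path to an SBML-qual file.
#' @param name Metadata name for the returned network (defaults to the model
#'   id when present).
#' @return A `logical_network` whose rules reproduce the file's function
#'   terms.
#' @export
read_sbml_qual <- function(path, name = NULL) {
  doc <- xml2::read_xml(path)
  species <- xml2::xml_find_all(doc, "//*[local-name()='qualitativeSpecies']")
  if (length(species) == 0L) {
    stop("no qualitative species found; not an SBML-qual model?",
         call. = FALSE)
  }
  ids <- vapply(species, qual_attr, character(1), name = "id")
  max_levels <- vapply(species, qual_attr, character(1), name = "maxLevel")
  bad <- !is.na(max_levels) & max_levels != "1"
  if (any(bad)) {
    stop(sprintf("multi-valued species unsupported (maxLevel > 1): %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }

  transitions <- xml2::xml_find_all(doc, "//*[local-name()='transition']")
  rules <- list()
  for (tr in transitions) {
    outputs <- xml2::xml_find_all(tr, ".//*[local-name()='output']")
    if (length(outputs) != 1L) {
      stop("each transition must have exactly one output", call. = FALSE)
    }
    target <- qual_attr(outputs[[1L]], "qualitativeSpecies")
    default_terms <- xml2::xml_find_all(tr, ".//*[local-name()='defaultTerm']")
    if (length(default_terms) != 1L) {
      stop(sprintf("transition for '%s': missing defaultTerm", target),
           call. = FALSE)
    }
    if (qual_attr(default_terms[[1L]], "resultLevel") != "0") {
      stop(sprintf("transition for '%s': only defaultTerm resultLevel 0 is supported",
                   target), call. = FALSE)
    }
    fun_terms <- xml2::xml_find_all(tr, ".//*[local-name()='functionTerm']")
    if (length(fun_terms) != 1L ||
        qual_attr(fun_terms[[1L]], "resultLevel") != "1") {
      stop(sprintf("transition for '%s': expected one functionTerm with resultLevel 1",
                   target), call. = FALSE)
    }
    math <- xml2::xml_find_first(fun_terms[[1L]], ".//*[local-name()='math']")
    kids <- xml2::xml_children(math)
    if (length(kids) != 1L) {
      stop(sprintf("transition for '%s': malformed MathML", target),
           call. = FALSE)
    }
    rules[[target]] <- new_logic_rule(mathml_to_expr(kids[[1L]], target))
  }

  nodes <- lapply(ids, function(id) {
    if (!is.null(rules[[id]])) internal_node(id, rules[[id]])
    else external_node(id)
  })
  model_node <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  model_id <- if (!inherits(model_node, "xml_missing")) {
    xml2::xml_attr(model_node, "id")
  } else NA_character_
  if (is.null(name)) {
    name <- if (!is.na(model_id)) model_id else basename(path)
  }
  logical_network(nodes, name = name)
}

mathml_to_expr <- function(node, target) {
  bad <- function(why) {
    stop(sprintf("transition for '%s': unparseable MathML (%s)", target, why),
         call. = FALSE)
  }
  nm <- xml2::xml_name(node)
  if (nm == "ci") {
    return(list(type = "var", name = trimws(xml2::xml_text(node))))
  }
  if (nm != "apply") bad(sprintf("unexpected element '%s'", nm))
  kids <- xml2::xml_children(node)
  if (length(kids) < 2L) bad("empty apply")
  op <- xml2::xml_name(kids[[1L]])
  args <- kids[-1L]
  if (op == "eq") {
    if (length(args) != 2L) bad("eq needs two arguments")
    names_ <- vapply(args, xml2::xml_name, character(1))
    ci <- args[names_ == "ci"]
    cn <- args[names_ == "cn"]
    if (length(ci) != 1L || length(cn) != 1L) bad("eq must compare ci to cn")
    value <- trimws(xml2::xml_text(cn[[1L]]))
    var <- list(type = "var", name = trimws(xml2::xml_text(ci[[1L]])))
    if (value == "1") return(var)
    if (value == "0") return(list(type = "not", arg = var))
    bad(sprintf("species compared to non-Boolean level '%s'", value))
  }
  if (op == "not") {
    if (length(args) != 1L) bad("not needs one argument")
    return(list(type = "not", arg = mathml_to_expr(args[[1L]], target)))
  }
  if (op %in% c("and", "or")) {
    if (length(args) < 2L) bad(sprintf("%s needs >= 2 arguments", op))
    exprs <- lapply(args, mathml_to_expr, target = target)
    out <- exprs[[1L]]
    for (i in seq_along(exprs)[-1L]) {
      out <- list(type = op, lhs = out, rhs = exprs[[i]])
    }
    return(out)
  }
  bad(sprintf("unsupported operator '%s'", op))
}
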