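## Logical network container.
##
## A network is a named list of node specs plus free-text metadata. External
## nodes carry no rule (their state is driven by the environment); internal
## nodes carry exactly one logic_rule.

#' Construct a logical network
#'
#' @param nodes A list of node specs created by [external_node()] /
#'   [internal_node()], or a character vector of rule lines understood by
#'   [parse_rule_lines()].
#' @param name,version Free-text metadata.
#' @param check Validate invariants on construction (default `TRUE`).
#' @return An object of class `logical_network`.
#' @seealso [read_rule_file()], [read_sbml_qual()], [build_reference_model()]
#' @export
logical_network <- function(nodes, name = "unnamed", version = "0",
                            check = TRUE) {
  if (is.character(nodes)) nodes <- parse_rule_lines(nodes)
  node_names <- vapply(nodes, function(n) n$name, character(1))
  names(nodes) <- node_names
  net <- structure(
    list(nodes = nodes, metadata = list(name = name, version = version)),
    class = "logical_network"
  )
  if (check) {
    report <- validate_network(net)
    if (nrow(report$errors) > 0L) {
      stop("invalid network:\n",
           paste0("  - ", report$errors$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  net
}

#' @rdname logical_network
#' @param name Node name (unique, non-empty identifier).
#' @param annotation Free-text provenance for the node's interactions.
#' @export
external_node <- function(name, annotation = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  list(name = name, kind = "external", rule = NULL, annotation = annotation)
}

#' @rdname logical_network
#' @param rule A `logic_rule` or a rule string passed to [parse_rule()].
#' @export
internal_node <- function(name, rule, annotation = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(rule)) rule <- parse_rule(rule)
  stopifnot(inherits(rule, "logic_rule"))
  list(name = name, kind = "internal", rule = rule, annotation = annotation)
}

#' @export
print.logical_network <- function(x, ...) {
  kinds <- vapply(x$nodes, function(n) n$kind, character(1))
  cat(sprintf("<logical_network> %s (version %s)\n",
              x$metadata$name, x$metadata$version))
  cat(sprintf("  %d nodes: %d internal, %d external\n",
              length(x$nodes), sum(kinds == "internal"),
              sum(kinds == "external")))
  invisible(x)
}

#' Node names of a network
#'
#' @param network A `logical_network`.
#' @param kind `"all"`, `"external"` or `"internal"`.
#' @return Character vector of node names.
#' @export
network_nodes <- function(network, kind = c("all", "external", "internal")) {
  kind <- match.arg(kind)
  nm <- names(network$nodes)
  if (kind == "all") return(nm)
  kinds <- vapply(network$nodes, function(n) n$kind, character(1))
  nm[kinds == kind]
}

#' Validate a logical network
#'
#' Checks the structural invariants: unique node names, no dangling
#' regulator references, every internal node has a rule, at least one
#' internal node, and (as a warning-level entry) external nodes that are
#' never referenced by any rule.
#'
#' @param network A `logical_network` (checked structurally even if built
#'   with `check = FALSE`).
#' @return A list with data frames `errors` and `warnings` (columns `type`,
#'   `node`, `message`). The network satisfies all invariants iff both are
#'   empty.
#' @export
validate_network <- function(network) {
  nodes <- network$nodes
  node_names <- vapply(nodes, function(n) n$name, character(1))
  errors <- list()
  warnings <- list()
  add <- function(store, type, node, message) {
    store[[length(store) + 1L]] <- data.frame(
      type = type, node = node, message = message,
      stringsAsFactors = FALSE
    )
    store
  }

  dup <- unique(node_names[duplicated(node_names)])
  for (d in dup) {
    errors <- add(errors, "duplicate_name", d,
                  sprintf("node name '%s' is duplicated", d))
  }
  kinds <- vapply(nodes, function(n) n$kind, character(1))
  if (!any(kinds == "internal")) {
    errors <- add(errors, "no_internal_nodes", NA_character_,
                  "network has no internal node")
  }
  referenced <- character(0)
  for (n in nodes) {
    if (n$kind == "internal") {
      if (is.null(n$rule)) {
        errors <- add(errors, "missing_rule", n$name,
                      sprintf("internal node '%s' has no rule", n$name))
        next
      }
      for (reg in n$rule$regulators) {
        if (!reg %in% node_names) {
          errors <- add(errors, "dangling_reference", n$name,
                        sprintf("rule of '%s' references absent node '%s'",
                                n$name, reg))
        }
      }
      referenced <- union(referenced, n$rule$regulators)
    } else if (!is.null(n$rule)) {
      errors <- add(errors, "external_with_rule", n$name,
                    sprintf("external node '%s' must not carry a rule", n$name))
    }
  }
  for (nm in node_names[kinds == "external"]) {
    if (!nm %in% referenced) {
      warnings <- add(warnings, "unreferenced_external", nm,
                      sprintf("external node '%s' is not referenced by any rule",
                              nm))
    }
  }
  empty <- data.frame(type = character(0), node = character(0),
                      message = character(0), stringsAsFactors = FALSE)
  list(
    errors = if (length(errors)) do.call(rbind, errors) else empty,
    warnings = if (length(warnings)) do.call(rbind, warnings) else empty
  )
}

## ---- plain-text rule format -------------------------------------------
##
## One declaration per line:
##   input NAME          external node
##   NAME = EXPRESSION   internal node
## '#' starts a comment; blank lines ignored.

#' Parse rule-file lines into node specs
#'
#' @param lines Character vector in the plain-text rule format (see
#'   [write_rule_file()]).
#' @return A list of node specs suitable for [logical_network()].
#' @export
parse_rule_lines <- function(lines) {
  nodes <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^input\\s+", line)) {
      nm <- trimws(sub("^input\\s+", "", line))
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", nm)) {
        stop(sprintf("line %d: invalid input declaration '%s'", i, line),
             call. = FALSE)
      }
      nodes[[length(nodes) + 1L]] <- external_node(nm)
    } else if (grepl("=", line, fixed = TRUE)) {
      eq <- regexpr("=", line, fixed = TRUE)
      nm <- trimws(substr(line, 1L, eq - 1L))
      expr <- trimws(substr(line, eq + 1L, nchar(line)))
      if (!grepl("^[A-Za-z_][A-Za-z0-9_.]*$", nm)) {
        stop(sprintf("line %d: invalid node name '%s'", i, nm), call. = FALSE)
      }
      nodes[[length(nodes) + 1L]] <- internal_node(nm, expr)
    } else {
      stop(sprintf("line %d: cannot parse '%s'", i, line), call. = FALSE)
    }
  }
  nodes
}

#' Read / write the plain-text rule format
#'
#' `write_rule_file()` emits one `input NAME` line per external node and one
#' `NAME = expression` line per internal node; `read_rule_file()` parses it
#' back. The round trip preserves every rule's expression tree.
#'
#' @param network A `logical_network`.
#' @param path File path.
#' @param name,version Metadata for the network read back.
#' @return `read_rule_file()` returns a `logical_network`;
#'   `write_rule_file()` returns `path` invisibly.
#' @export
read_rule_file <- function(path, name = basename(path), version = "0") {
  logical_network(readLines(path, warn = FALSE), name = name,
                  version = version)
}

#' @rdname read_rule_file
#' @export
write_rule_file <- function(network, path) {
  lines <- character(0)
  for (n in network$nodes) {
    lines <- c(lines, if (n$kind == "external") {
      paste("input", n$name)
    } else {
      paste(n$name, "=", format_rule(n$rule))
    })
  }
  writeLines(lines, path)
  invisible(path)
}
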