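## Tabular exports and run manifests for the analysis workflow.

#' Export experiment results
#'
#' `write_experiment_summary()` writes the per-node summary (node, mean,
#' sd, and `delta_vs_baseline` when a baseline experiment is supplied);
#' `write_ranked_table()` writes a ranking from [rank_most_affected()];
#' `write_dose_response()` writes a [dose_response()] curve;
#' `write_trajectory()` writes a 0/1 trajectory matrix as TSV.
#'
#' @param result An `experiment_result`.
#' @param path Output file path.
#' @param baseline Optional baseline `experiment_result` for the delta
#'   column.
#' @return `path`, invisibly.
#' @export
write_experiment_summary <- function(result, path, baseline = NULL) {
  stopifnot(inherits(result, "experiment_result"))
  tab <- result$summary
  if (!is.null(baseline)) {
    stopifnot(identical(baseline$summary$node, tab$node))
    tab$delta_vs_baseline <- tab$mean - baseline$summary$mean
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_summary
#' @param ranked Data frame from [rank_most_affected()].
#' @export
write_ranked_table <- function(ranked, path) {
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_summary
#' @param curve A `dose_response_curve`.
#' @export
write_dose_response <- function(curve, path) {
  tab <- as.data.frame(curve)
  tab$input_node <- attr(curve, "input_node")
  tab$output_node <- attr(curve, "output_node")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_experiment_summary
#' @param trajectory 0/1 matrix from a `simulation_result`.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an output byte-for-byte: the
#' package version, the seed and the full parameter set. Written alongside
#' analysis outputs.
#'
#' @param params Named list of run parameters (must include `seed`).
#' @param path Output path (`.json`-style plain text).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(params, path) {
  stopifnot(is.list(params), "seed" %in% names(params))
  params <- c(list(package = "tcellsim",
                   version = as.character(utils::packageVersion("tcellsim"))),
              params)
  fmt <- function(x) {
    if (is.character(x)) paste0("\"", x, "\"") else format(x, digits = 15)
  }
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    val <- if (length(v) == 1L) fmt(v) else {
      paste0("[", paste(vapply(v, fmt, character(1)), collapse = ", "), "]")
    }
    sprintf("  \"%s\": %s", k, val)
  }, character(1))
  writeLines(c("{", paste(lines, collapse = ",\n"), "}"), path)
  invisible(path)
}
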