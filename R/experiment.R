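## In-silico experiments: genotype regimes, 1,000-simulation screens,
## most-affected-protein ranking, dose-response validation curves.

#' Genotype regimes for the perturbation target
#'
#' Maps a genotype label onto a [perturbation()] of the target node:
#' \describe{
#'   \item{WT}{no perturbation (healthy cellular conditions).}
#'   \item{KO}{target clamped OFF (knockout).}
#'   \item{Het50}{target forced ON 50\% of iterations via its activator,
#'     bypassing upstream regulation (heterozygote).}
#'   \item{RandomActivation}{target forced at a level drawn uniformly from
#'     `[0, 100]` independently for every simulation.}
#' }
#'
#' @param label Genotype label.
#' @param target Perturbed node (default `"CAV1"`).
#' @return A list of class `genotype_condition`.
#' @export
genotype_condition <- function(label = c("WT", "KO", "Het50",
                                         "RandomActivation"),
                               target = "CAV1") {
  label <- match.arg(label)
  structure(list(label = label, target = target),
            class = "genotype_condition")
}

## Perturbation for one simulation (RandomActivation redraws per call).
genotype_perturbation <- function(genotype) {
  stopifnot(inherits(genotype, "genotype_condition"))
  switch(genotype$label,
    WT = perturbation(),
    KO = perturbation(clamp_off = genotype$target),
    Het50 = perturbation(forced = stats::setNames(50, genotype$target)),
    RandomActivation = perturbation(
      forced = stats::setNames(stats::runif(1, 0, 100), genotype$target))
  )
}

#' Run an in-silico experiment
#'
#' Runs `n_simulations` independent simulations of a network under an
#' environment specification and a genotype regime. For each simulation the
#' per-stimulus activity levels are redrawn from the environment's
#' categories, the genotype's perturbation is applied, and activity is
#' computed by [simulate_network()]. Simulation `i` uses seed
#' `base_seed + i`, so results are a pure function of
#' (network, spec, genotype, config, seed).
#'
#' @param network A `logical_network`.
#' @param env_spec An `environment_spec` from [build_environment()].
#' @param genotype A [genotype_condition()] (or a genotype label).
#' @param config A [sim_config()]; its `seed` is the experiment base seed
#'   and must be set.
#' @param n_simulations Number of simulations (default 1000; minimum 2).
#' @param level_mode Passed to [sample_environment()].
#' @param env_default Level for external nodes not covered by the
#'   environment specification (default 0).
#' @return A list of class `experiment_result` with `activity`
#'   (`n_simulations` x nodes matrix of per-simulation activities),
#'   `summary` (data frame: node, mean, sd), and the run metadata.
#' @export
run_experiment <- function(network, env_spec, genotype,
                           config = sim_config(), n_simulations = 1000L,
                           level_mode = "randomized", env_default = 0) {
  if (is.character(genotype)) genotype <- genotype_condition(genotype)
  stopifnot(inherits(genotype, "genotype_condition"),
            inherits(env_spec, "environment_spec"),
            inherits(config, "sim_config"))
  n_simulations <- as.integer(n_simulations)
  if (n_simulations < 2L) {
    stop("n_simulations must be at least 2", call. = FALSE)
  }
  if (is.null(config$seed)) {
    stop("config$seed must be set for experiments", call. = FALSE)
  }
  compiled <- compile_network(network)
  ext <- network_nodes(compiled$network, "external")
  covered <- names(sample_environment_names(env_spec))
  uncovered <- setdiff(ext, c(covered, genotype$target))
  if (length(uncovered) > 0L) {
    message(sprintf("external node(s) not in environment spec held at %g: %s",
                    env_default, paste(uncovered, collapse = ", ")))
  }

  sim_cfg <- config
  sim_cfg$seed <- NULL  # per-simulation seeds are set below
  node_names <- compiled$node_names
  activity <- matrix(NA_real_, nrow = n_simulations,
                     ncol = length(node_names),
                     dimnames = list(NULL, node_names))
  for (i in seq_len(n_simulations)) {
    set.seed(config$seed + i)
    levels <- sample_environment(env_spec, level_mode = level_mode)
    env <- env_assignment_for_network(levels, compiled$network,
                                      default = env_default)
    pert <- genotype_perturbation(genotype)
    sim <- simulate_network(compiled, env, pert, sim_cfg)
    activity[i, ] <- sim$activity
  }
  summary <- data.frame(
    node = node_names,
    mean = colMeans(activity),
    sd = apply(activity, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    activity = activity,
    summary = summary,
    condition = env_spec$condition,
    genotype = genotype$label,
    target = genotype$target,
    n_simulations = n_simulations,
    level_mode = level_mode,
    base_seed = config$seed,
    total_iterations = config$total_iterations,
    window = config$window
  ), class = "experiment_result")
}

## stimulus -> node names covered by a spec (after node_map)
sample_environment_names <- function(spec) {
  nm <- names(spec$categories)
  mapped <- names(spec$node_map)
  hit <- nm %in% mapped
  nm[hit] <- unname(spec$node_map[nm[hit]])
  stats::setNames(rep(NA_real_, length(nm)), nm)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s / %s: %d simulations x %d iterations (window %d)\n",
    x$condition, x$genotype, x$n_simulations, x$total_iterations, x$window))
  invisible(x)
}

#' Rank the proteins most affected by a perturbation
#'
#' Computes, per node, the difference in mean activity (% ON) between a
#' condition experiment and its baseline (typically the WT genotype under
#' the same environment), and returns the top `k` nodes by absolute shift.
#' Ties are broken lexicographically by node name.
#'
#' @param result,baseline_result `experiment_result` objects over the same
#'   network.
#' @param k Number of rows to keep (default 15; `Inf` for all).
#' @param exclude Nodes to drop before ranking (e.g. the perturbation
#'   target's activator); default none.
#' @return Data frame (node, mean_activity_condition,
#'   mean_activity_baseline, delta), sorted by `|delta|` descending.
#' @export
rank_most_affected <- function(result, baseline_result, k = 15L,
                               exclude = character(0)) {
  stopifnot(inherits(result, "experiment_result"),
            inherits(baseline_result, "experiment_result"))
  if (!identical(result$summary$node, baseline_result$summary$node)) {
    stop("experiments cover different node sets", call. = FALSE)
  }
  tab <- data.frame(
    node = result$summary$node,
    mean_activity_condition = result$summary$mean,
    mean_activity_baseline = baseline_result$summary$mean,
    stringsAsFactors = FALSE
  )
  tab$delta <- tab$mean_activity_condition - tab$mean_activity_baseline
  tab <- tab[!tab$node %in% exclude, , drop = FALSE]
  ord <- order(-abs(tab$delta), tab$node)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, n = k)
}

#' Input-output dose-response curve
#'
#' Sweeps one external input over a level grid while all other inputs are
#' held at a fixed background (by default the wild-type tissue categories
#' in fixed mode, with inputs outside the environment table at 0), running
#' `reps` simulations per level and recording the mean output activity.
#'
#' @param network A `logical_network`.
#' @param input_node External node to sweep.
#' @param output_node Node whose activity is recorded.
#' @param grid Strictly increasing levels in `[0, 100]` (default 0..100 by
#'   10).
#' @param reps Simulations per grid level (default 30).
#' @param config A [sim_config()]; `seed` is the base seed and must be set.
#' @param background Named numeric vector of background levels; defaults to
#'   the `Tissue_WT` environment in fixed mode.
#' @return Data frame of class `dose_response_curve` (level, mean_response,
#'   sd, reps) with the input/output names as attributes.
#' @export
dose_response <- function(network, input_node, output_node,
                          grid = seq(0, 100, by = 10), reps = 30L,
                          config = sim_config(), background = NULL) {
  compiled <- compile_network(network)
  ext <- network_nodes(compiled$network, "external")
  if (!input_node %in% ext) {
    stop(sprintf("input_node '%s' is not an external node", input_node),
         call. = FALSE)
  }
  if (!output_node %in% compiled$node_names) {
    stop(sprintf("output_node '%s' not in network", output_node),
         call. = FALSE)
  }
  stopifnot(all(diff(grid) > 0), all(grid >= 0 & grid <= 100))
  if (is.null(config$seed)) {
    stop("config$seed must be set for dose-response sweeps", call. = FALSE)
  }
  if (is.null(background)) {
    levels <- sample_environment(build_environment("Tissue_WT"),
                                 level_mode = "fixed")
    background <- env_assignment_for_network(levels, compiled$network)
  } else {
    background <- env_assignment_for_network(background, compiled$network)
  }
  sim_cfg <- config
  sim_cfg$seed <- NULL
  out <- data.frame(level = grid, mean_response = NA_real_, sd = NA_real_,
                    reps = as.integer(reps))
  for (li in seq_along(grid)) {
    env <- background
    env[input_node] <- grid[[li]]
    vals <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(config$seed + (li - 1L) * reps + r)
      sim <- simulate_network(compiled, env, NULL, sim_cfg)
      vals[[r]] <- sim$activity[[output_node]]
    }
    out$mean_response[[li]] <- mean(vals)
    out$sd[[li]] <- stats::sd(vals)
  }
  structure(out, class = c("dose_response_curve", "data.frame"),
            input_node = input_node, output_node = output_node)
}

#' Spearman monotonicity of a dose-response curve
#'
#' Spearman rank correlation between the level grid and the mean responses
#' (average-rank tie handling), quantifying how consistently the output
#' rises with the stimulus.
#'
#' @param curve A `dose_response_curve` (or any data frame with `level` and
#'   `mean_response`).
#' @return Correlation in `[-1, 1]`.
#' @export
monotonicity_score <- function(curve) {
  if (nrow(curve) < 3L) {
    stop("need at least 3 grid points", call. = FALSE)
  }
  stats::cor(curve$level, curve$mean_response, method = "spearman")
}
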