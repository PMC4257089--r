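## Stochastic semi-synchronous simulation of a logical network.
##
## External stimuli carry continuous activity levels in [0, 100]; at every
## iteration each external node is resampled ON with probability level/100
## while internal nodes update synchronously through their Boolean rules.
## A node's activity is the percentage of iterations it was ON over the
## trailing window. This reproduces graded dose-response behaviour from
## purely Boolean rules.

#' Simulation configuration
#'
#' @param total_iterations Iterations per simulation (default 800).
#' @param window Trailing window over which activity is computed
#'   (default 300; must not exceed `total_iterations`).
#' @param seed Integer seed, or `NULL` to continue from the current RNG
#'   state.
#' @param initial_state_policy `"random_uniform"` (internal nodes start ON
#'   with probability 1/2), `"all_off"`, or `"fixed"` (supply
#'   `fixed_state`).
#' @param fixed_state Named 0/1 vector of starting values for
#'   `initial_state_policy = "fixed"`; nodes not named start at 0.
#' @param env_resample `"per_iteration"` (default: external nodes are
#'   redrawn every step) or `"fixed"` (drawn once at initialisation and
#'   held for the whole simulation).
#' @param return_trajectory Keep the full iterations x nodes 0/1 matrix.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(total_iterations = 800L, window = 300L, seed = NULL,
                       initial_state_policy = c("random_uniform", "all_off",
                                                "fixed"),
                       fixed_state = NULL,
                       env_resample = c("per_iteration", "fixed"),
                       return_trajectory = FALSE) {
  total_iterations <- as.integer(total_iterations)
  window <- as.integer(window)
  stopifnot(total_iterations >= 1L, window >= 1L)
  if (window > total_iterations) {
    stop("window must not exceed total_iterations", call. = FALSE)
  }
  initial_state_policy <- match.arg(initial_state_policy)
  if (initial_state_policy == "fixed" && is.null(fixed_state)) {
    stop("initial_state_policy = \"fixed\" requires fixed_state",
         call. = FALSE)
  }
  structure(list(
    total_iterations = total_iterations,
    window = window,
    seed = if (!is.null(seed)) as.integer(seed),
    initial_state_policy = initial_state_policy,
    fixed_state = fixed_state,
    env_resample = match.arg(env_resample),
    return_trajectory = isTRUE(return_trajectory)
  ), class = "sim_config")
}

#' Perturbation of a network (genotype regime)
#'
#' @param clamp_off Character vector of nodes clamped OFF (knockout).
#' @param forced Named numeric vector: nodes forced ON with probability
#'   `level/100` at every iteration, bypassing their rule (the
#'   activator-driven regime). Levels in `[0, 100]`.
#' @return A list of class `perturbation`.
#' @export
perturbation <- function(clamp_off = character(0), forced = numeric(0)) {
  stopifnot(is.character(clamp_off))
  if (length(forced) > 0L) {
    stopifnot(!is.null(names(forced)), all(nzchar(names(forced))))
    if (any(forced < 0 | forced > 100)) {
      stop("forced levels must lie in [0, 100]", call. = FALSE)
    }
  }
  overlap <- intersect(clamp_off, names(forced))
  if (length(overlap) > 0L) {
    stop(sprintf("nodes cannot be both clamped and forced: %s",
                 paste(overlap, collapse = ", ")), call. = FALSE)
  }
  structure(list(clamp_off = clamp_off, forced = forced),
            class = "perturbation")
}

## Compile a network into the index/truth-table form the C++ stepper wants.
compile_network <- function(network) {
  if (inherits(network, "compiled_network")) return(network)
  stopifnot(inherits(network, "logical_network"))
  node_names <- network_nodes(network)
  n <- length(node_names)
  is_external <- logical(n)
  reg_idx <- vector("list", n)
  truth <- vector("list", n)
  for (j in seq_len(n)) {
    node <- network$nodes[[j]]
    if (node$kind == "external") {
      is_external[[j]] <- TRUE
    } else {
      regs <- node$rule$regulators
      reg_idx[[j]] <- match(regs, node_names) - 1L
      truth[[j]] <- rule_truth_table(node$rule)
    }
  }
  structure(list(
    node_names = node_names,
    is_external = is_external,
    reg_idx = reg_idx,
    truth = truth,
    network = network
  ), class = "compiled_network")
}

## Resolve env/perturbation into per-node probability vectors.
resolve_sim_inputs <- function(compiled, env, pert) {
  node_names <- compiled$node_names
  n <- length(node_names)
  if (is.null(pert)) pert <- perturbation()
  stopifnot(inherits(pert, "perturbation"))
  unknown <- setdiff(c(pert$clamp_off, names(pert$forced)), node_names)
  if (length(unknown) > 0L) {
    stop(sprintf("perturbation names absent from network: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  ext_names <- node_names[compiled$is_external]
  if (length(env) > 0L) {
    stopifnot(!is.null(names(env)))
    bad_env <- setdiff(names(env), node_names)
    if (length(bad_env) > 0L) {
      stop(sprintf("environment names absent from network: %s",
                   paste(bad_env, collapse = ", ")), call. = FALSE)
    }
    if (any(env < 0 | env > 100)) {
      stop("environment levels must lie in [0, 100]", call. = FALSE)
    }
  }
  missing_env <- setdiff(ext_names, names(env))
  if (length(missing_env) > 0L) {
    stop(sprintf("no activity level for external node(s): %s",
                 paste(missing_env, collapse = ", ")), call. = FALSE)
  }
  ext_prob <- numeric(n)
  ext_prob[match(names(env), node_names)] <- unname(env) / 100
  clamp <- node_names %in% pert$clamp_off
  forced <- node_names %in% names(pert$forced)
  forced_prob <- numeric(n)
  forced_prob[match(names(pert$forced), node_names)] <-
    unname(pert$forced) / 100
  list(ext_prob = ext_prob, clamp = clamp, forced = forced,
       forced_prob = forced_prob)
}

## Initial state draw; one pass in node order so the RNG stream is
## well-defined. Returns integer vector.
draw_initial_state <- function(compiled, inputs, config) {
  node_names <- compiled$node_names
  n <- length(node_names)
  fixed <- numeric(0)
  if (config$initial_state_policy == "fixed") {
    fixed <- config$fixed_state
  }
  state <- integer(n)
  for (j in seq_len(n)) {
    state[[j]] <- if (inputs$clamp[[j]]) {
      0L
    } else if (inputs$forced[[j]]) {
      as.integer(stats::runif(1) < inputs$forced_prob[[j]])
    } else if (compiled$is_external[[j]]) {
      as.integer(stats::runif(1) < inputs$ext_prob[[j]])
    } else {
      switch(config$initial_state_policy,
        random_uniform = as.integer(stats::runif(1) < 0.5),
        all_off = 0L,
        fixed = {
          v <- fixed[node_names[[j]]]
          if (is.na(v)) 0L else as.integer(v)
        })
    }
  }
  state
}

#' Simulate a logical network
#'
#' Runs one stochastic simulation: `total_iterations` update steps from a
#' drawn initial state, with per-node activity (% ON) computed over the
#' final `window` states.
#'
#' @param network A `logical_network` (or a pre-compiled network, as used
#'   internally by [run_experiment()]).
#' @param env Named numeric vector of activity levels in `[0, 100]`, one per
#'   external node.
#' @param pert A [perturbation()], or `NULL` for none.
#' @param config A [sim_config()].
#' @return A list of class `simulation_result` with `activity` (named
#'   percentages in `[0, 100]`) and, if requested, `trajectory`
#'   (`total_iterations + 1` rows including the initial state).
#' @examples
#' net <- logical_network(c("input E", "A = E"))
#' sim <- simulate_network(net, env = c(E = 100), config = sim_config(seed = 1))
#' sim$activity
#' @export
simulate_network <- function(network, env, pert = NULL,
                             config = sim_config()) {
  compiled <- compile_network(network)
  stopifnot(inherits(config, "sim_config"))
  inputs <- resolve_sim_inputs(compiled, env, pert)
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- draw_initial_state(compiled, inputs, config)
  raw <- simulate_compiled_cpp(
    compiled$reg_idx, compiled$truth, compiled$is_external,
    inputs$ext_prob, inputs$clamp, inputs$forced, inputs$forced_prob,
    init, config$total_iterations, config$window,
    config$env_resample == "fixed", config$return_trajectory
  )
  activity <- as.numeric(raw$activity)
  names(activity) <- compiled$node_names
  out <- list(activity = activity)
  if (config$return_trajectory) {
    traj <- raw$trajectory
    colnames(traj) <- compiled$node_names
    out$trajectory <- traj
  }
  structure(out, class = "simulation_result")
}

#' One synchronous update step (reference implementation)
#'
#' Pure-R single step with the same semantics as the compiled engine:
#' external nodes resampled Bernoulli(level/100), internal nodes updated
#' synchronously from `state`, then knockout clamps and forced activation
#' applied. Mainly useful for inspection and testing.
#'
#' @inheritParams simulate_network
#' @param state Named 0/1 vector, a complete assignment over the network.
#' @return Named integer 0/1 vector: the next state.
#' @export
step_network <- function(network, state, env, pert = NULL) {
  compiled <- compile_network(network)
  inputs <- resolve_sim_inputs(compiled, env, pert)
  node_names <- compiled$node_names
  missing <- setdiff(node_names, names(state))
  if (length(missing) > 0L) {
    stop(sprintf("state is missing node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cur <- as.integer(state[node_names])
  nxt <- cur
  for (j in seq_along(node_names)) {
    if (inputs$clamp[[j]] || inputs$forced[[j]]) next
    if (compiled$is_external[[j]]) {
      nxt[[j]] <- as.integer(stats::runif(1) < inputs$ext_prob[[j]])
    } else {
      regs <- compiled$reg_idx[[j]] + 1L
      idx <- sum(cur[regs] * 2L^(seq_along(regs) - 1L))
      nxt[[j]] <- compiled$truth[[j]][[idx + 1L]]
    }
  }
  for (j in seq_along(node_names)) {
    if (inputs$clamp[[j]]) {
      nxt[[j]] <- 0L
    } else if (inputs$forced[[j]]) {
      nxt[[j]] <- as.integer(stats::runif(1) < inputs$forced_prob[[j]])
    }
  }
  names(nxt) <- node_names
  nxt
}

#' Recompute activity from a stored trajectory
#'
#' @param trajectory 0/1 matrix as returned in a `simulation_result`
#'   (rows = initial state + one row per iteration).
#' @param window Trailing window length.
#' @return Named numeric vector of activities (% ON).
#' @export
activity_from_trajectory <- function(trajectory, window) {
  n_states <- nrow(trajectory) - 1L
  stopifnot(window >= 1L, window <= n_states)
  rows <- seq.int(nrow(trajectory) - window + 1L, nrow(trajectory))
  100 * colMeans(trajectory[rows, , drop = FALSE])
}
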