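## Exact expectation oracle for small networks.
##
## Under the step semantics, the next state factorises: internal
## (non-forced) nodes are a deterministic function of the current state,
## while external and forced nodes are independent Bernoulli draws. The
## state distribution can therefore be propagated exactly: mass is pooled
## by the deterministic-bit signature of the successor and multiplied by
## the stochastic-bit product probability. Cost is O(2^n) per iteration.

#' Exact expected activity of a small network
#'
#' Propagates the exact state distribution of the Markov chain implied by
#' [simulate_network()]'s update semantics for `horizon` iterations and
#' returns each node's expected ON-probability averaged over the trailing
#' `window` iterations, scaled to `[0, 100]` — the exact expectation of the
#' simulated activity profile. Only `env_resample = "per_iteration"`
#' semantics are modelled.
#'
#' @inheritParams simulate_network
#' @param horizon Number of iterations to propagate (the simulation's
#'   `total_iterations`).
#' @param window Trailing window (must not exceed `horizon`).
#' @param initial_state_policy,fixed_state As in [sim_config()].
#' @param max_nodes Guard on state-space size (default 12, i.e. 4096
#'   states).
#' @return Named numeric vector: exact expected activity per node.
#' @examples
#' net <- logical_network(c("input E1", "input E2", "A = E1 & E2"))
#' stationary_oracle(net, env = c(E1 = 50, E2 = 50))["A"]  # exactly 25
#' @export
stationary_oracle <- function(network, env, pert = NULL, horizon = 800L,
                              window = 300L,
                              initial_state_policy = c("random_uniform",
                                                       "all_off", "fixed"),
                              fixed_state = NULL, max_nodes = 12L) {
  compiled <- compile_network(network)
  initial_state_policy <- match.arg(initial_state_policy)
  node_names <- compiled$node_names
  n <- length(node_names)
  if (n > max_nodes) {
    stop(sprintf("state space too large: %d nodes (max %d)", n, max_nodes),
         call. = FALSE)
  }
  horizon <- as.integer(horizon)
  window <- as.integer(window)
  stopifnot(horizon >= 1L, window >= 1L, window <= horizon)
  inputs <- resolve_sim_inputs(compiled, env, pert)

  n_states <- 2L^n
  s <- seq_len(n_states) - 1L
  ## bit matrix: column j = value of node j in each state
  bits <- matrix(0L, nrow = n_states, ncol = n)
  for (j in seq_len(n)) bits[, j] <- bitwAnd(s %/% 2L^(j - 1L), 1L)

  ## classify nodes
  det <- which((!compiled$is_external | inputs$clamp) & !inputs$forced)
  stoch <- setdiff(seq_len(n), det)

  ## deterministic successor bit of each det node, for every current state
  det_next <- matrix(0L, nrow = n_states, ncol = length(det))
  for (jj in seq_along(det)) {
    j <- det[[jj]]
    if (inputs$clamp[[j]]) next  # stays 0
    regs <- compiled$reg_idx[[j]] + 1L
    idx <- rep(0L, n_states)
    for (b in seq_along(regs)) {
      idx <- idx + bits[, regs[[b]]] * 2L^(b - 1L)
    }
    det_next[, jj] <- compiled$truth[[j]][idx + 1L]
  }
  pow_det <- 2L^(seq_along(det) - 1L)
  g <- as.integer(det_next %*% pow_det)          # det signature of successor
  h <- as.integer(bits[, det, drop = FALSE] %*% pow_det)  # det bits of state

  ## stochastic product probability of each state (independent of origin)
  node_prob <- function(j) {
    if (inputs$forced[[j]]) inputs$forced_prob[[j]] else inputs$ext_prob[[j]]
  }
  q <- rep(1, n_states)
  for (j in stoch) {
    p <- node_prob(j)
    q <- q * ifelse(bits[, j] == 1L, p, 1 - p)
  }

  ## initial distribution: product over independent per-node start probs
  init_prob <- vapply(seq_len(n), function(j) {
    if (inputs$clamp[[j]]) return(0)
    if (inputs$forced[[j]]) return(inputs$forced_prob[[j]])
    if (compiled$is_external[[j]]) return(inputs$ext_prob[[j]])
    switch(initial_state_policy,
      random_uniform = 0.5,
      all_off = 0,
      fixed = {
        v <- fixed_state[node_names[[j]]]
        if (is.na(v)) 0 else as.numeric(v)
      })
  }, numeric(1))
  p <- rep(1, n_states)
  for (j in seq_len(n)) {
    p <- p * ifelse(bits[, j] == 1L, init_prob[[j]], 1 - init_prob[[j]])
  }

  n_groups <- 2L^length(det)
  acc <- numeric(n)
  window_start <- horizon - window + 1L
  for (iter in seq_len(horizon)) {
    if (length(det) == 0L) {
      p <- q
    } else {
      m <- numeric(n_groups)
      sums <- rowsum(p, g)
      m[as.integer(rownames(sums)) + 1L] <- sums
      p <- q * m[h + 1L]
    }
    if (iter >= window_start) {
      acc <- acc + as.numeric(crossprod(bits, p))
    }
  }
  activity <- 100 * acc / window
  names(activity) <- node_names
  activity
}
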