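# Independent oracles and fixture builders used across the suite.

# Naive recursive rule evaluator: written independently of the package's
# vectorized evaluation path.
naive_eval <- function(expr, assignment) {
  switch(expr$type,
    var = as.logical(assignment[[expr$name]]),
    not = !naive_eval(expr$arg, assignment),
    and = naive_eval(expr$lhs, assignment) && naive_eval(expr$rhs, assignment),
    or  = naive_eval(expr$lhs, assignment) || naive_eval(expr$rhs, assignment)
  )
}

naive_truth_table <- function(rule) {
  regs <- rule$regulators
  k <- length(regs)
  vapply(seq_len(2^k) - 1, function(row) {
    assignment <- as.list(setNames(
      vapply(seq_len(k), function(j) (row %/% 2^(j - 1)) %% 2, numeric(1)),
      regs))
    as.integer(naive_eval(rule$expr, assignment))
  }, integer(1))
}

# Random expression tree over a variable pool (for grammar round-trip
# properties).
random_expr <- function(vars, depth = 3) {
  if (depth == 0 || runif(1) < 0.3) {
    return(list(type = "var", name = sample(vars, 1)))
  }
  op <- sample(c("not", "and", "or"), 1)
  if (op == "not") {
    list(type = "not", arg = random_expr(vars, depth - 1))
  } else {
    list(type = op, lhs = random_expr(vars, depth - 1),
         rhs = random_expr(vars, depth - 1))
  }
}

# Brute-force unweighted average-linkage agglomeration on distance
# 1 - uncentered similarity, recomputing every pairwise cluster distance
# from the original items at every step. Ties: lowest original item index.
brute_force_upgma <- function(mat) {
  n <- nrow(mat)
  cosim <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - cosim(mat[i, ], mat[j, ])
  }
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dist_ij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dist_ij < best$dist - 1e-12 ||
            (abs(dist_ij - best$dist) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, dist = dist_ij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    pair <- if (min(clusters[[i]]) <= min(clusters[[j]])) {
      c(ids[i], ids[j])
    } else c(ids[j], ids[i])
    merges[[length(merges) + 1]] <- pair
    heights <- c(heights, best$dist)
    clusters[[i]] <- sort(c(clusters[[i]], clusters[[j]]))
    ids[i] <- length(merges)
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = do.call(rbind, merges), height = heights)
}

# Brute-force Spearman rho with average ranks, from the definition.
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Minimal experiment_result stub for ranking tests.
fake_experiment <- function(means, condition = "Tissue_WT",
                            genotype = "WT") {
  structure(list(
    activity = NULL,
    summary = data.frame(node = names(means), mean = unname(means),
                         sd = 0, stringsAsFactors = FALSE),
    condition = condition, genotype = genotype, target = "CAV1",
    n_simulations = 2L, level_mode = "randomized", base_seed = 1L,
    total_iterations = 800L, window = 300L
  ), class = "experiment_result")
}
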