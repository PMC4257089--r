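## Downstream expression analysis: fold-change vs controls, hierarchical
## clustering with the uncentered-correlation metric and average linkage
## (Cluster 3.0 conventions, with .cdt/.gtr export for Java TreeView), and
## Pearson correlation of each gene's fold-change profile against a
## reference gene (CAV1) across disease-subtype columns.

#' Log2 fold-change of group means versus a control group
#'
#' @param matrix Genes x samples matrix of positive intensities, with row
#'   (gene) and column (sample) names.
#' @param groups Named character vector or factor assigning every sample
#'   (column) to a group.
#' @param control_group Group used as the denominator (default
#'   `"Healthy"`); it is excluded from the output columns.
#' @return Genes x non-control-groups matrix:
#'   `log2(mean(group) / mean(control))`.
#' @export
compute_fold_change <- function(matrix, groups, control_group = "Healthy") {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)),
            !is.null(rownames(matrix)))
  if (anyDuplicated(rownames(matrix))) {
    stop("gene names must be unique", call. = FALSE)
  }
  if (any(matrix <= 0)) {
    stop("all intensities must be positive", call. = FALSE)
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  missing <- setdiff(colnames(matrix), names(groups))
  if (length(missing) > 0L) {
    stop(sprintf("sample(s) without group assignment: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  groups <- groups[colnames(matrix)]
  if (!control_group %in% groups) {
    stop(sprintf("control group '%s' has no samples", control_group),
         call. = FALSE)
  }
  group_levels <- unique(groups)
  test_groups <- setdiff(group_levels, control_group)
  control_mean <- rowMeans(matrix[, groups == control_group, drop = FALSE])
  fc <- sapply(test_groups, function(g) {
    log2(rowMeans(matrix[, groups == g, drop = FALSE]) / control_mean)
  })
  fc <- base::matrix(fc, nrow = nrow(matrix),
                     dimnames = list(rownames(matrix), test_groups))
  fc
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Uncentered correlation (cosine similarity)
#'
#' The Cluster 3.0 "uncentered correlation":
#' `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))` — Pearson without mean
#' centering.
#'
#' @param x,y Numeric vectors of equal length, neither of zero norm.
#' @return Similarity in `[-1, 1]`.
#' @export
uncentered_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("uncentered correlation undefined for a zero vector", call. = FALSE)
  }
  sum(x * y) / (nx * ny)
}

row_similarity_matrix <- function(matrix, similarity) {
  n <- nrow(matrix)
  simfun <- switch(similarity,
    uncentered = uncentered_correlation,
    pearson = pearson_correlation
  )
  s <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      s[i, j] <- s[j, i] <- simfun(matrix[i, ], matrix[j, ])
    }
  }
  s
}

#' Agglomerative clustering with average linkage (UPGMA)
#'
#' Hierarchically clusters the rows of a matrix on distance
#' `1 - similarity` with unweighted average linkage: the distance between
#' two clusters is the mean of all pairwise distances between their
#' original items. Ties are broken deterministically in favour of the pair
#' containing the lowest original item index.
#'
#' @param matrix Items x variables numeric matrix (at least 2 rows); row
#'   names label the items.
#' @param similarity `"uncentered"` (default, Cluster 3.0 style) or
#'   `"pearson"`.
#' @return A list of class `cluster_tree`: `merge` (hclust convention:
#'   negative = original item, positive = earlier merge), `height`
#'   (distance at each merge), `similarity` (`1 - height`), `order` (leaf
#'   order), `labels`.
#' @seealso [as_hclust()], [write_gtr()], [write_cdt()]
#' @export
hierarchical_cluster <- function(matrix,
                                 similarity = c("uncentered", "pearson")) {
  similarity <- match.arg(similarity)
  stopifnot(is.matrix(matrix))
  n <- nrow(matrix)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(matrix)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))
  d <- 1 - row_similarity_matrix(matrix, similarity)

  ## active clusters: list of original-item index vectors
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)               # hclust convention
  merge <- base::matrix(0L, nrow = n - 1L, ncol = 2L)
  height <- numeric(n - 1L)

  cluster_dist <- function(a, b) mean(d[members[[a]], members[[b]]])

  for (step in seq_len(n - 1L)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        dist_ij <- cluster_dist(i, j)
        if (is.null(best) || dist_ij < best$dist - 1e-12 ||
            (abs(dist_ij - best$dist) <= 1e-12 &&
             tie_before(members[[i]], members[[j]],
                        members[[best$i]], members[[best$j]]))) {
          best <- list(i = i, j = j, dist = dist_ij)
        }
      }
    }
    i <- best$i; j <- best$j
    ## child order: cluster containing the lowest original item first
    ci <- ids[[i]]; cj <- ids[[j]]
    if (min(members[[i]]) <= min(members[[j]])) {
      merge[step, ] <- c(ci, cj)
    } else {
      merge[step, ] <- c(cj, ci)
    }
    height[[step]] <- best$dist
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    ids[[i]] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
  }

  order <- leaf_order(merge, n)
  structure(list(
    merge = merge, height = height, similarity = 1 - height,
    order = order, labels = labels, linkage = "average",
    metric = similarity
  ), class = "cluster_tree")
}

## TRUE if pair (a1, a2) precedes pair (b1, b2) under the
## lowest-item-index tie-break.
tie_before <- function(a1, a2, b1, b2) {
  ka <- sort(c(min(a1), min(a2)))
  kb <- sort(c(min(b1), min(b2)))
  if (ka[[1]] != kb[[1]]) return(ka[[1]] < kb[[1]])
  ka[[2]] < kb[[2]]
}

leaf_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0L) return(-id)
    c(expand(merge[id, 1L]), expand(merge[id, 2L]))
  }
  expand(nrow(merge))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d items, %s linkage on 1 - %s similarity\n",
              length(x$labels), x$linkage, x$metric))
  invisible(x)
}

#' Convert a cluster tree to an `hclust` object
#'
#' @param tree A `cluster_tree`.
#' @return An object of class `hclust` (for plotting / cutree).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  structure(list(
    merge = tree$merge, height = tree$height, order = tree$order,
    labels = tree$labels, method = tree$linkage,
    dist.method = paste0("1 - ", tree$metric),
    call = match.call()
  ), class = "hclust")
}

#' Correlate every gene's profile with a reference gene
#'
#' Pearson correlation of each gene's fold-change profile against the
#' reference gene's profile across the matrix columns (disease-subtype
#' fold changes), sorted by correlation descending. Regression slope and
#' intercept (gene on reference) are included for completeness. Genes with
#' a constant profile are skipped with a warning.
#'
#' @param fc_matrix Genes x group-columns numeric matrix (at least 3
#'   columns) with row names.
#' @param reference_gene Row to correlate against (default `"CAV1"`).
#' @return Data frame (gene, r, slope, intercept) sorted by `r`
#'   descending; the reference gene itself is first with `r = 1`.
#' @export
correlate_with_reference <- function(fc_matrix, reference_gene = "CAV1") {
  stopifnot(is.matrix(fc_matrix), !is.null(rownames(fc_matrix)))
  if (ncol(fc_matrix) < 3L) {
    stop("need at least 3 group columns", call. = FALSE)
  }
  if (!reference_gene %in% rownames(fc_matrix)) {
    stop(sprintf("reference gene '%s' absent", reference_gene),
         call. = FALSE)
  }
  ref <- fc_matrix[reference_gene, ]
  if (stats::sd(ref) == 0) {
    stop("reference gene has a constant profile", call. = FALSE)
  }
  genes <- rownames(fc_matrix)
  keep <- vapply(genes, function(g) {
    ok <- stats::sd(fc_matrix[g, ]) > 0
    if (!ok) warning(sprintf("gene '%s' has a constant profile; skipped", g),
                     call. = FALSE)
    ok
  }, logical(1))
  genes <- genes[keep]
  r <- vapply(genes, function(g) pearson_correlation(fc_matrix[g, ], ref),
              numeric(1))
  slope <- vapply(genes, function(g) {
    stats::cov(fc_matrix[g, ], ref) / stats::var(ref)
  }, numeric(1))
  intercept <- vapply(genes, function(g) {
    mean(fc_matrix[g, ]) - slope[[g]] * mean(ref)
  }, numeric(1))
  out <- data.frame(gene = genes, r = unname(r), slope = unname(slope),
                    intercept = unname(intercept),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Synthetic fold-change matrix with planted reference correlations
#'
#' Generates a fold-change-like matrix in which each gene has a chosen
#' target Pearson correlation with a reference profile: the reference
#' profile `z` is standard normal over the columns and gene `g` is
#' `r_g * z + sqrt(1 - r_g^2) * noise_sd * e_g` with independent standard
#' normal noise `e_g` (at `noise_sd = 1` the population correlation equals
#' the planted `r_g` exactly).
#'
#' @param planted Named numeric vector of target correlations in
#'   `(-1, 1)`, one per gene.
#' @param n_columns Number of profile columns (at least 3; the width of
#'   the subtype design drives how precisely the planted values can be
#'   recovered).
#' @param noise_sd Scale of the independent noise component (default 1).
#' @param seed Integer seed.
#' @param reference_gene Name of the reference row prepended to the output
#'   (default `"CAV1"`).
#' @param column_names Optional column names (default `C1..Cn`).
#' @return `(1 + length(planted))` x `n_columns` matrix whose first row is
#'   the reference profile.
#' @export
generate_synthetic_foldchange <- function(planted, n_columns = 100L,
                                          noise_sd = 1, seed = 1L,
                                          reference_gene = "CAV1",
                                          column_names = NULL) {
  stopifnot(is.numeric(planted), !is.null(names(planted)))
  if (any(abs(planted) >= 1)) {
    stop("planted correlations must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  n_columns <- as.integer(n_columns)
  if (n_columns < 3L) stop("need at least 3 columns", call. = FALSE)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n_columns)
  rows <- lapply(planted, function(r) {
    r * z + sqrt(1 - r^2) * noise_sd * stats::rnorm(n_columns)
  })
  out <- rbind(z, do.call(rbind, rows))
  rownames(out) <- c(reference_gene, names(planted))
  colnames(out) <- if (is.null(column_names)) {
    paste0("C", seq_len(n_columns))
  } else column_names
  out
}

## ---- Cluster 3.0 output ------------------------------------------------

#' Write Cluster 3.0 compatible .gtr / .cdt files
#'
#' `write_gtr()` writes the gene-tree file (one `NODEkX  childA  childB
#' similarity` line per merge); `write_cdt()` writes the clustered data
#' table with rows in leaf order. The pair loads in Java TreeView.
#'
#' @param tree A `cluster_tree` over the rows of `matrix`.
#' @param matrix The clustered matrix (for `write_cdt()`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtr <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  id <- function(x) {
    if (x < 0L) sprintf("GENE%dX", -x) else sprintf("NODE%dX", x)
  }
  lines <- vapply(seq_len(nrow(tree$merge)), function(k) {
    sprintf("NODE%dX\t%s\t%s\t%.6f", k,
            id(tree$merge[k, 1L]), id(tree$merge[k, 2L]),
            tree$similarity[[k]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gtr
#' @export
write_cdt <- function(tree, matrix, path) {
  stopifnot(inherits(tree, "cluster_tree"), is.matrix(matrix),
            nrow(matrix) == length(tree$labels))
  cols <- colnames(matrix)
  if (is.null(cols)) cols <- paste0("COL", seq_len(ncol(matrix)))
  header <- paste(c("GID", "UNIQID", "NAME", "GWEIGHT", cols),
                  collapse = "\t")
  eweight <- paste(c("EWEIGHT", "", "", "", rep("1", length(cols))),
                   collapse = "\t")
  rows <- vapply(tree$order, function(i) {
    paste(c(sprintf("GENE%dX", i), tree$labels[[i]], tree$labels[[i]], "1",
            format(matrix[i, ], digits = 6, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, eweight, rows), path)
  invisible(path)
}
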