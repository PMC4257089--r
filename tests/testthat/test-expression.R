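test_that("fold change is the log2 ratio of group means to control", {
  mat <- rbind(g1 = c(2, 2, 8, 8, 4), g2 = c(10, 10, 2.5, 2.5, 10))
  colnames(mat) <- paste0("s", 1:5)
  groups <- c(s1 = "Healthy", s2 = "Healthy", s3 = "ACUT", s4 = "ACUT",
              s5 = "CHRN")
  fc <- compute_fold_change(mat, groups)
  expect_equal(fc["g1", "ACUT"], 2)      # log2(8/2)
  expect_equal(fc["g2", "ACUT"], -2)     # log2(2.5/10)
  expect_equal(fc["g2", "CHRN"], 0)      # equal means
  expect_false("Healthy" %in% colnames(fc))
  bad <- mat; bad[1, 1] <- 0
  expect_error(compute_fold_change(bad, groups), "positive")
  expect_error(compute_fold_change(mat, groups, "Nope"), "no samples")
})

test_that("Pearson correlation matches the direct formula", {
  expect_equal(pearson_correlation(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(1:3, c(6, 4, 2)), -1)
  expect_equal(pearson_correlation(1:4, c(1, 3, 2, 4)), 0.8)
  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  set.seed(91)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson_correlation(x, y), direct(x, y), tolerance = 1e-12)
    expect_equal(pearson_correlation(x, y), pearson_correlation(y, x))
    expect_lte(abs(pearson_correlation(x, y)), 1)
    # scale invariance under positive affine maps
    expect_equal(pearson_correlation(2.5 * x + 3, y),
                 pearson_correlation(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("uncentered correlation is cosine similarity", {
  expect_equal(uncentered_correlation(c(1, 1), c(2, 2)), 1)
  expect_equal(uncentered_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(uncentered_correlation(c(1, 2), c(-1, -2)), -1)
  set.seed(92)
  for (i in 1:20) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(uncentered_correlation(x, y),
                 sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tolerance = 1e-12)
    expect_equal(uncentered_correlation(x, y), uncentered_correlation(y, x))
    expect_lte(abs(uncentered_correlation(x, y)), 1 + 1e-12)
  }
  expect_error(uncentered_correlation(c(0, 0), c(1, 2)), "zero vector")
})

test_that("clustering joins identical profiles first and makes n-1 merges", {
  mat <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, -1, 0),
               d = c(0, 5, 1))
  tree <- hierarchical_cluster(mat)
  expect_equal(nrow(tree$merge), 3)
  expect_equal(tree$merge[1, ], c(-1, -2))   # a and b are parallel vectors
  expect_equal(tree$similarity[1], 1)
  # merge similarities non-increasing under average linkage
  expect_true(all(diff(tree$similarity) <= 1e-12))
})

test_that("clustering agrees with brute-force agglomeration", {
  set.seed(93)
  for (n in c(3, 5, 8)) {
    mat <- matrix(runif(n * 4, 0.1, 5), nrow = n)
    rownames(mat) <- paste0("g", seq_len(n))
    tree <- hierarchical_cluster(mat)
    oracle <- brute_force_upgma(mat)
    expect_equal(tree$merge, oracle$merge, ignore_attr = TRUE)
    expect_equal(tree$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("clustering agrees with hclust average linkage on tie-free data", {
  set.seed(94)
  mat <- matrix(runif(7 * 5, 0.1, 5), nrow = 7)
  rownames(mat) <- paste0("g", 1:7)
  sim <- matrix(1, 7, 7, dimnames = list(rownames(mat), rownames(mat)))
  for (i in 1:7) for (j in 1:7) {
    sim[i, j] <- uncentered_correlation(mat[i, ], mat[j, ])
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  tree <- hierarchical_cluster(mat)
  expect_equal(sort(tree$height), sort(hc$height), tolerance = 1e-12)
  expect_equal(stats::cophenetic(as_hclust(tree)),
               stats::cophenetic(hc), tolerance = 1e-12)
})

test_that("reference correlation report is sorted and complete", {
  set.seed(95)
  z <- rnorm(6)
  fc <- rbind(CAV1 = z, same = z, anti = -z, noise = rnorm(6))
  rep <- correlate_with_reference(fc)
  expect_equal(rep$gene[1:2], c("CAV1", "same"))
  expect_equal(rep$r[1:2], c(1, 1))
  expect_equal(rep$gene[nrow(rep)], "anti")
  expect_equal(rep$r[nrow(rep)], -1)
  expect_equal(rep$slope[rep$gene == "anti"], -1)
  expect_error(correlate_with_reference(fc, "missing"), "absent")
  fc2 <- rbind(fc, flat = rep(1, 6))
  expect_warning(rep2 <- correlate_with_reference(fc2), "constant profile")
  expect_false("flat" %in% rep2$gene)
})

test_that("planted correlations are recovered from wide synthetic matrices", {
  planted <- c(BCL10 = 0.9, GATA3 = 0.6, null = 0, FYN = -0.9)
  fc <- generate_synthetic_foldchange(planted, n_columns = 100, seed = 96)
  expect_identical(fc,
                   generate_synthetic_foldchange(planted, n_columns = 100,
                                                 seed = 96))
  rep <- correlate_with_reference(fc)
  rec <- setNames(rep$r, rep$gene)[names(planted)]
  expect_lt(abs(rec[["BCL10"]] - 0.9), 0.1)
  expect_lt(abs(rec[["FYN"]] + 0.9), 0.1)
  expect_lt(abs(rec[["null"]]), 0.35)        # ~3.5 / sqrt(100)
  expect_gte(brute_force_spearman(planted, rec), 0.9)
  expect_error(generate_synthetic_foldchange(c(a = 1)), "inside \\(-1, 1\\)")
  expect_error(generate_synthetic_foldchange(c(a = 0.5), n_columns = 2),
               "at least 3")
})

test_that("Cluster 3.0 outputs have the documented shape", {
  set.seed(97)
  mat <- matrix(runif(5 * 4, 0.1, 3), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  tree <- hierarchical_cluster(mat)
  gtr <- withr::local_tempfile(fileext = ".gtr")
  cdt <- withr::local_tempfile(fileext = ".cdt")
  write_gtr(tree, gtr)
  write_cdt(tree, mat, cdt)
  gtr_lines <- readLines(gtr)
  expect_length(gtr_lines, 4)                   # n - 1 merges
  expect_match(gtr_lines[1], "^NODE1X\t(GENE|NODE)")
  cdt_lines <- readLines(cdt)
  expect_length(cdt_lines, 2 + 5)               # header + EWEIGHT + genes
  expect_match(cdt_lines[1], "^GID\tUNIQID\tNAME\tGWEIGHT\tc1")
  # rows follow the leaf order of the tree
  gids <- sub("\t.*", "", cdt_lines[-(1:2)])
  expect_equal(gids, sprintf("GENE%dX", tree$order))
})
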