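test_that("the three distance metrics match their definitions", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.matrix(pairwise_distance(m, "spearman"))["a", "b"], 0)

  m2 <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.matrix(pairwise_distance(m2, "correlation"))["a", "b"], 2)

  m3 <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(as.matrix(pairwise_distance(m3, "euclidean"))["a", "b"], 5)

  m4 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(pairwise_distance(m4, "correlation"), "constant row")
  expect_error(pairwise_distance(m3[1, , drop = FALSE]), "2 participants")
})

test_that("distance tables satisfy metric axioms on random matrices", {
  set.seed(55)
  for (metric in c("euclidean", "spearman", "correlation")) {
    m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(paste0("P", 1:8), NULL))
    d <- as.matrix(pairwise_distance(m, metric))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_equal(unname(diag(d)), rep(0, 8))
  }
})

test_that("hierarchical clustering recovers well-separated clouds", {
  # location-separated clouds for the euclidean metric
  m <- two_clouds()
  res <- hierarchical_two_clusters(m, metric = "euclidean")
  lab <- as.integer(res$labels)
  expect_equal(lab[1:5], rep(lab[1], 5))
  expect_equal(lab[6:10], rep(lab[6], 5))
  expect_true(lab[1] != lab[6])
  expect_equal(lab[1], 0L)  # first participant anchors class 0

  # pattern-separated rows (rising vs falling profiles) for the
  # correlation metrics, which are blind to location shifts
  set.seed(14)
  mp <- rbind(matrix(rep(c(1, 2, 3, 4), 5), 5, byrow = TRUE),
              matrix(rep(c(4, 3, 2, 1), 5), 5, byrow = TRUE)) +
    matrix(rnorm(40, 0, 0.1), 10, 4)
  rownames(mp) <- sprintf("P%02d", 1:10)
  for (metric in c("correlation", "spearman")) {
    resp <- hierarchical_two_clusters(mp, metric = metric)
    labp <- as.integer(resp$labels)
    expect_equal(labp[1:5], rep(labp[1], 5))
    expect_equal(labp[6:10], rep(labp[6], 5))
    expect_true(labp[1] != labp[6])
  }
})

test_that("n = 2 gives singleton clusters and chaining splits at the big gap", {
  m <- rbind(a = c(0, 0), b = c(1, 1))
  res <- hierarchical_two_clusters(m)
  expect_setequal(as.integer(res$labels), c(0L, 1L))

  # collinear points with growing gaps: single linkage chains from the left,
  # so the 2-cluster cut isolates the far endpoint
  x <- cbind(c(0, 1, 2.2, 3.6, 5.4, 9))
  rownames(x) <- paste0("P", 1:6)
  res2 <- hierarchical_two_clusters(x, metric = "euclidean", linkage = "single")
  lab <- as.integer(res2$labels)
  expect_equal(sum(lab == lab[6]), 1)
})

test_that("k-means separates the frozen 1-D instance with known inertia", {
  m <- cbind(c(0, 0.1, 9.9, 10))
  rownames(m) <- paste0("P", 1:4)
  res <- kmeans_two_clusters(m, seed = 1)
  lab <- as.integer(res$labels)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_true(lab[1] != lab[3])
  expect_equal(res$inertia, 0.01, tolerance = 1e-9)

  dup <- matrix(1, 5, 2, dimnames = list(paste0("P", 1:5), NULL))
  expect_error(kmeans_two_clusters(dup, seed = 1), "distinct")
})

test_that("k-means inertia never beats the exhaustive best 2-partition", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    m <- matrix(rnorm(n * 2, sd = runif(1, 0.5, 3)), n, 2,
                dimnames = list(paste0("P", seq_len(n)), NULL))
    res <- kmeans_two_clusters(m, seed = i)
    expect_gte(res$inertia, bf_best_partition_inertia(m) - 1e-9)
  }
})

test_that("k-means is reproducible for a fixed seed and row-order invariant", {
  m <- two_clouds(sep = 4)
  r1 <- kmeans_two_clusters(m, seed = 7)
  r2 <- kmeans_two_clusters(m, seed = 7)
  expect_identical(as.integer(r1$labels), as.integer(r2$labels))
  expect_identical(r1$inertia, r2$inertia)

  perm <- sample(nrow(m))
  r3 <- kmeans_two_clusters(m[perm, ], seed = 7)
  ref <- label_table(names(r1$labels), as.integer(r1$labels), "cluster")
  aligned <- assign_polarity(r3, ref, "best_match")
  expect_equal(mean(as.integer(aligned$labels[names(ref)]) == as.integer(ref)), 1)
})

test_that("polarity assignment follows the fixed and best-match rules", {
  ids <- paste0("P", 1:4)
  res <- edaffect:::cluster_result(label_table(ids, c(0, 0, 1, 1), "cluster"),
                                   "kmeans")
  ref <- label_table(ids, c(1, 1, 0, 0), "jaws")
  best <- assign_polarity(res, ref, "best_match")
  expect_equal(mean(as.integer(best$labels) == as.integer(ref)), 1)
  fixed <- assign_polarity(res, ref, "fixed")
  expect_equal(mean(as.integer(fixed$labels) == as.integer(ref)), 0)

  res2 <- edaffect:::cluster_result(label_table(ids, c(0, 1, 0, 1), "cluster"),
                                    "kmeans")
  ref2 <- label_table(ids, c(0, 0, 1, 1), "jaws")
  either <- assign_polarity(res2, ref2, "best_match")
  expect_equal(mean(as.integer(either$labels) == as.integer(ref2)), 0.5)

  ref3 <- label_table(c("Q1", "Q2", "Q3", "Q4"), c(0, 0, 1, 1), "jaws")
  expect_error(assign_polarity(res2, ref3), "participant sets")
})
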