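test_that("coefficient of variation matches hand computations", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  expect_equal(coefficient_of_variation(-c(2, 4, 6)),
               -coefficient_of_variation(c(2, 4, 6)))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("CV filter keeps ties, drops constants, and is idempotent", {
  m <- cbind(at_threshold = c(2, 4, 6),      # cv exactly 0.5
             constant = c(3, 3, 3),          # cv 0
             low_var = c(10, 10.5, 11),      # rpm-like, cv ~0.05
             spread = c(1, 5, 20))
  rownames(m) <- paste0("P", 1:3)
  out <- cv_filter(m, 0.5)
  expect_setequal(colnames(out$matrix), c("at_threshold", "spread"))
  rep <- out$report
  expect_equal(rep$reason[rep$feature == "constant"], "cv_reject")
  expect_equal(rep$reason[rep$feature == "low_var"], "cv_reject")
  again <- cv_filter(out$matrix, 0.5)
  expect_identical(colnames(again$matrix), colnames(out$matrix))
  expect_identical(unname(again$matrix), unname(out$matrix))

  expect_error(cv_filter(m[, "constant", drop = FALSE], 0.5), "every feature")
})

test_that("univariate WCSS matches the frozen two-cluster examples", {
  expect_equal(wcss_1d(c(0, 0, 10, 10)), 0)
  expect_equal(wcss_1d(c(0, 1, 9, 10)), 1.0)
  expect_equal(wcss_1d(c(5, 5, 5)), 0)
  expect_error(wcss_1d(c(1), k = 2), "clusters")
})

test_that("wcss_1d equals exhaustive 2-partition enumeration", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    x <- if (i %% 3 == 0) sample(0:5, n, TRUE) else rnorm(n, sd = runif(1, 0.5, 10))
    expect_equal(wcss_1d(x), bf_wcss2(x), tolerance = 1e-9)
  }
})

test_that("WCSS filter applies thresholds, top-k, and is idempotent", {
  set.seed(5)
  m <- cbind(tight = rep(c(0, 1), each = 5) + rnorm(10, 0, 0.1),
             diffuse = rnorm(10, 0, 10),
             mid = rep(c(0, 3), each = 5) + rnorm(10, 0, 1))
  rownames(m) <- paste0("P", 1:10)
  w <- vapply(1:3, function(j) wcss_1d(m[, j]), numeric(1))
  thr <- sort(w)[2] + 1e-9
  out <- wcss_filter(m, threshold = thr)
  expect_equal(sum(out$report$kept), 2)
  again <- wcss_filter(out$matrix, threshold = thr)
  expect_identical(colnames(again$matrix), colnames(out$matrix))

  topk <- wcss_filter(m, top_k = 1)
  expect_equal(colnames(topk$matrix), names(which.min(setNames(w, colnames(m)))))

  expect_error(wcss_filter(m, threshold = 0), "> 0")
  expect_error(wcss_filter(m, threshold = 1, top_k = 1), "exactly one")
  expect_error(wcss_filter(m, threshold = min(w) / 2), "every feature")
})

test_that("a study-shaped run keeps 13 of the canonical features", {
  coh <- simulate_cohort(synth_config(seed = 4))
  fm <- session_features(coh$sessions)$exercise_1
  sel <- wcss_filter(fm, top_k = 13)
  expect_equal(ncol(sel$matrix), 13)
  expect_equal(sum(sel$report$kept), 13)
})

test_that("contextual sets select the published groupings", {
  m <- matrix(rnorm(5 * 26), 5, 26,
              dimnames = list(paste0("P", 1:5), canonical_features()))
  expect_identical(colnames(contextual_set(m, "statistical")),
                   c("standard_deviation", "quartile_deviation", "skewness",
                     "kurtosis", "reg_slope"))
  expect_equal(ncol(contextual_set(m, "signal")), 4)
  expect_equal(ncol(contextual_set(m, "error")), 4)
  m2 <- m[, setdiff(colnames(m), "kurtosis")]
  expect_error(contextual_set(m2, "statistical"), "kurtosis")

  expect_equal(ncol(preset_features(m, "paper_ex1")), 4)
  expect_equal(ncol(preset_features(m, "paper_ex2")), 10)
  expect_equal(ncol(preset_features(m, "paper_ex3")), 12)
})

test_that("PCA keeps all components and conserves variance and distances", {
  set.seed(13)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("P", 1:10), letters[1:4]))
  sc <- pca_transform(m)
  expect_equal(dim(sc), c(10, 4))
  # total variance conserved (standardized input: p units)
  expect_equal(sum(apply(sc, 2, var)), 4, tolerance = 1e-9)
  # variance ordering
  expect_true(all(diff(apply(sc, 2, var)) <= 1e-9))
  # orthogonal rotation preserves pairwise distances of the standardized data
  z <- scale(m)
  expect_equal(as.matrix(dist(sc)), as.matrix(dist(z)), tolerance = 1e-9)

  mc <- cbind(m, const = 1)
  expect_warning(sc2 <- pca_transform(mc), "constant column")
  expect_equal(ncol(sc2), 4)

  expect_error(pca_transform(m[1, , drop = FALSE]), "at least 2")
})
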