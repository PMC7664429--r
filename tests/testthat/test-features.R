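test_that("GSR detection matches the worked examples", {
  ev <- detect_gsr_events(c(0, 0.5, 2.0, 1.0, 0.2), fs = 4)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 2.0)
  expect_true(ev$significant)
  expect_lte(ev$trigger_index, ev$peak_index)

  expect_equal(nrow(detect_gsr_events(5:1, fs = 4)), 0)

  # two separated ramps peaking at 1.0 uS: two non-significant events
  ramp <- c(0, 0.2, 1.0, 0.3, 0.1, 0, 0.2, 1.0, 0.3, 0.1)
  ev2 <- detect_gsr_events(ramp, fs = 4)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$amplitude, c(1, 1))
  expect_false(any(ev2$significant))

  expect_error(detect_gsr_events(c(1, 2), fs = 4), "3 samples")
})

test_that("GSR detector agrees with the brute-force scan on random traces", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    # mixture of smooth and quantized traces to exercise plateaus and ties
    x <- if (i %% 2 == 0) round(cumsum(rnorm(n)), 1) else cumsum(rnorm(n))
    got <- detect_gsr_events(x, fs = 4)
    want <- bf_gsr(x)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("GSR aggregation arithmetic", {
  ev <- data.frame(trigger_index = 3L, peak_index = 5L, amplitude = 2,
                   energy = 4, significant = TRUE)
  g <- gsr_features(ev, duration = 10)
  expect_equal(g$n_gsr, 1)
  expect_equal(g$rpm, 6)
  expect_equal(g$gsr_energy, 4)
  expect_equal(g$n_sig_gsr, 1)
  expect_equal(g$sig_gsr_energy, 4)

  g0 <- gsr_features(detect_gsr_events(5:1, 4), duration = 10)
  expect_true(all(unlist(g0) == 0))

  ev5 <- do.call(rbind, replicate(5, ev, simplify = FALSE))
  expect_equal(gsr_features(ev5, 60)$rpm, 5)
  expect_error(gsr_features(ev, 0), "> 0")
})

test_that("statistical features reproduce frozen hand computations", {
  st <- statistical_features(c(1, 2, 3, 4))
  expect_equal(st$mean, 2.5)
  expect_equal(st$p25, 1.75)
  expect_equal(st$p75, 3.25)
  expect_equal(st$quartile_deviation, 0.75)
  expect_equal(st$reg_slope, 1.0, tolerance = 1e-12)
  expect_equal(st$reg_rmse, 0, tolerance = 1e-9)
  expect_equal(st$n_crossings, 0L)
  expect_equal(st$total_sum, 10)
  expect_equal(st$rms, sqrt(7.5))
  expect_equal(st$moment5, 0, tolerance = 1e-12)
  expect_equal(st$variance, var(c(1, 2, 3, 4)))
})

test_that("degenerate and two-level segments follow the conventions", {
  st <- statistical_features(c(5, 5, 5, 5))
  expect_equal(st$variance, 0)
  expect_equal(st$entropy, 0)
  expect_equal(st$skewness, 0)
  expect_equal(st$kurtosis, 0)
  expect_equal(st$reg_slope, 0, tolerance = 1e-12)

  st2 <- statistical_features(c(1, 1, 1, 2, 2, 2))
  expect_equal(st2$entropy, 1)  # two equiprobable bins = 1 bit
})

test_that("features respond to scaling as they must", {
  set.seed(21)
  x <- runif(50, 1, 6)
  c0 <- 3.7
  a <- statistical_features(x)
  b <- statistical_features(c0 * x)
  for (f in c("mean", "standard_deviation", "median", "minimum", "maximum",
              "total_sum"))
    expect_equal(b[[f]], c0 * a[[f]], tolerance = 1e-9)
  expect_equal(b$variance, c0^2 * a$variance, tolerance = 1e-9)
  expect_equal(b$skewness, a$skewness, tolerance = 1e-9)
  expect_equal(b$n_crossings, a$n_crossings)

  ph <- c(0, 0.3, 1.2, 0.4, 0.1, 0, 0.5, 2.2, 0.8, 0.2)
  expect_equal(detect_gsr_events(c0 * ph, 4)$amplitude,
               c0 * detect_gsr_events(ph, 4)$amplitude)
})

test_that("order statistics invariants hold on random segments", {
  set.seed(33)
  for (i in 1:25) {
    st <- statistical_features(rnorm(sample(4:200, 1), sd = runif(1, 0.1, 4)))
    expect_equal(st$quartile_deviation, (st$p75 - st$p25) / 2)
    expect_lte(st$minimum, st$median)
    expect_lte(st$median, st$maximum)
    expect_true(all(is.finite(unlist(st))))
  }
})

test_that("feature matrices assemble with canonical shape and ordering", {
  seg <- function(id) {
    s <- structure(list(participant_id = id, exercise_id = 3, fs = 4,
                        samples = runif(40, 2, 5), duration = 10),
                   class = "segment")
    tp <- decompose_tonic_phasic(s)
    list(segment = s, tonic_phasic = tp)
  }
  set.seed(2)
  m <- extract_feature_matrix(list(seg("P1"), seg("P2")))
  expect_equal(dim(m), c(2, 26))
  expect_identical(colnames(m), canonical_features())
  expect_identical(rownames(m), c("P1", "P2"))
  expect_true(all(is.finite(m)))

  expect_error(extract_feature_matrix(list()), "empty")
  expect_error(extract_feature_matrix(list(seg("P1"), seg("P1"))), "duplicate")
})

test_that("the default synthetic cohort yields a 41-row feature matrix", {
  coh <- simulate_cohort(synth_config(seed = 2))
  fm <- session_features(coh$sessions)
  expect_length(fm, 3)
  expect_equal(nrow(fm$exercise_1), 41)
  expect_equal(ncol(fm$exercise_1), 26)
  expect_true(all(is.finite(fm$exercise_1)))
})
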