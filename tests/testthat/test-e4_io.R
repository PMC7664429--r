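write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("EDA CSV reader parses the E4 header dialect", {
  f <- write_lines_tmp(c("1600000000", "4", as.character(1:8)))
  s <- read_eda_csv(f, participant_id = "P01")
  expect_s3_class(s, "eda_session")
  expect_equal(s$start_time, 1600000000)
  expect_equal(s$fs, 4)
  expect_length(s$samples, 8)
  expect_equal(length(s$samples) / s$fs, 2)  # 2 s of recording
})

test_that("a 60 s exercise at 4 Hz is 240 data lines", {
  f <- write_lines_tmp(c("1600000000", "4", format(runif(240, 1, 5))))
  s <- read_eda_csv(f, participant_id = "P01")
  expect_equal(length(s$samples) / s$fs, 60)
})

test_that("EDA CSV reader rejects malformed files with located errors", {
  expect_error(read_eda_csv(write_lines_tmp(c("start", "4", "1", "2", "3")), "P"),
               "line 1")
  expect_error(read_eda_csv(write_lines_tmp(c("1600000000", "0", "1", "2")), "P"),
               "sample rate must be > 0")
  expect_error(read_eda_csv(write_lines_tmp(c("1600000000", "4", "1", "oops", "3")), "P"),
               "line 4")
  expect_error(read_eda_csv(write_lines_tmp(c("1600000000", "4")), "P"),
               "no data lines")
})

test_that("EDA write/read round trip reproduces samples exactly", {
  set.seed(7)
  s <- eda_session("P09", 1600000123.25, 4, runif(100, 0.3, 8),
                   c(1600000125, 1600000140))
  f <- withr::local_tempfile(fileext = ".csv")
  write_eda_csv(s, f)
  s2 <- read_eda_csv(f, participant_id = "P09", markers = s$markers)
  expect_identical(s2$samples, s$samples)
  expect_identical(s2$start_time, s$start_time)
  expect_identical(s2$fs, s$fs)
})

test_that("session invariants are enforced", {
  expect_error(eda_session("P", 0, 4, numeric(0)), "non-empty")
  expect_error(eda_session("P", 0, 4, c(1, NA, 2)), "finite")
  expect_error(eda_session("P", 0, 4, 1:10, markers = c(2, 1)), "non-decreasing")
  expect_error(eda_session("P", 0, 4, 1:10, markers = 99), "within the recording")
})

test_that("tags reader returns markers and rejects disorder", {
  f <- write_lines_tmp(c("1600000010", "1600000075"))
  expect_equal(read_tags_csv(f), c(1600000010, 1600000075))
  expect_error(read_tags_csv(write_lines_tmp(c("1600000075", "1600000010"))),
               "non-decreasing")
  f_empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f_empty)
  expect_warning(tags <- read_tags_csv(f_empty), "no markers")
  expect_length(tags, 0)
})

test_that("JAWS reader validates items and cohort shape", {
  f <- write_lines_tmp(c("participant_id,item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12",
                         paste0("P01,", paste(rep(3, 12), collapse = ","))))
  resp <- read_jaws_csv(f)
  expect_length(resp, 1)
  expect_equal(resp[[1]]$items, rep(3L, 12))
  expect_equal(sum(resp[[1]]$polarity == "positive"), 6)

  f_bad <- write_lines_tmp(c("participant_id,item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12",
                             paste0("P01,6,", paste(rep(3, 11), collapse = ","))))
  expect_error(read_jaws_csv(f_bad), "P01")
  f_cols <- write_lines_tmp(c("participant_id,item1", "P01,3"))
  expect_error(read_jaws_csv(f_cols), "13 columns")
})

test_that("a 41-row JAWS table yields a full cohort", {
  rows <- vapply(1:41, function(i)
    paste0(sprintf("P%02d,", i), paste(sample(1:5, 12, TRUE), collapse = ",")),
    character(1))
  f <- write_lines_tmp(c(paste0("participant_id,", paste0("item", 1:12, collapse = ",")),
                         rows))
  expect_length(read_jaws_csv(f), 41)
})

test_that("label tables enforce binary unique-id labelling", {
  lt <- label_table(c("a", "b"), c(0, 1), "expert")
  expect_s3_class(lt, "label_table")
  expect_equal(attr(lt, "provenance"), "expert")
  expect_error(label_table(c("a", "a"), c(0, 1)), "unique")
  expect_error(label_table(c("a", "b"), c(0, 2)), "0 or 1")
  f <- withr::local_tempfile(fileext = ".csv")
  write_labels_csv(lt, f)
  expect_equal(as.integer(read_labels_csv(f)), c(0L, 1L))
})

test_that("feature matrix CSV round trip preserves values and names", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("P1", "P2", "P3"), c("mean", "rms", "n_gsr", "entropy")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(m, f)
  m2 <- read_feature_matrix(f)
  expect_equal(m2, m, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(dimnames(m2), dimnames(m))
})
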