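test_that("read_cohort parses kinds, missing tokens, and preserves rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tMDI\tSEX",
               "S1\t85\ttrue",
               "S2\tNA\tfalse",
               "S3\t64.5\ttrue"), path)
  tbl <- read_cohort(path, schema = c(MDI = "continuous", SEX = "binary"))
  expect_s3_class(tbl, "cohort_table")
  expect_equal(nrow(tbl), 3L)
  expect_identical(cohort_kinds(tbl), c(MDI = "continuous", SEX = "binary"))
  expect_equal(tbl$MDI, c(85, NA, 64.5))
  expect_identical(tbl$SEX, c(TRUE, FALSE, TRUE))
})

test_that("read_cohort infers the delimiter from a csv extension", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,VENT", "S1,8", "S2,3"), path)
  tbl <- read_cohort(path, schema = c(VENT = "continuous"))
  expect_equal(tbl$VENT, c(8, 3))
})

test_that("read_cohort rejects duplicate ids, absent columns, bad tokens", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tMDI", "S1\t85", "S1\t70"), path)
  err <- expect_error(read_cohort(path, schema = c(MDI = "continuous")),
                      class = "svbn_validation_error")
  expect_match(conditionMessage(err), "S1")

  writeLines(c("subject_id\tMDI", "S1\t85"), path)
  expect_error(read_cohort(path, schema = c(PDI = "continuous")),
               class = "svbn_schema_error")

  writeLines(c("subject_id\tMDI", "S1\tseventy"), path)
  err <- expect_error(read_cohort(path, schema = c(MDI = "continuous")),
                      class = "svbn_parse_error")
  expect_match(conditionMessage(err), "MDI")
  expect_match(conditionMessage(err), "row 1")
})

test_that("filter_complete_cases keeps rows complete on the named variables", {
  df <- data.frame(subject_id = paste0("S", 1:5),
                   VENT = c(3, NA, 8, NA, 5),
                   MDI = c(80, 90, NA, 70, 60))
  tbl <- cohort_table(df, kinds = c(VENT = "continuous", MDI = "continuous"))

  out <- filter_complete_cases(tbl, "VENT")
  expect_equal(nrow(out), 3L)
  expect_identical(out$subject_id, c("S1", "S3", "S5"))
  expect_equal(attr(out, "n_removed"), 2L)

  ident <- filter_complete_cases(tbl, character())
  expect_equal(as.data.frame(ident), as.data.frame(tbl),
               ignore_attr = TRUE)
  expect_equal(attr(ident, "n_removed"), 0L)
  full <- filter_complete_cases(tbl, c("VENT", "MDI"))
  expect_identical(full$subject_id, c("S1", "S5"))
  expect_error(filter_complete_cases(tbl, "GA"),
               class = "svbn_validation_error")
})

test_that("threshold comparators are literal at the boundary", {
  df <- data.frame(subject_id = paste0("S", 1:4),
                   VENT = c(8, 7, 6, 9),
                   MDI = c(70, 71, 100, 101),
                   dGV = c(TRUE, FALSE, TRUE, FALSE))
  tbl <- cohort_table(df, kinds = c(VENT = "continuous", MDI = "continuous",
                                    dGV = "binary"))
  dc <- apply_thresholds(tbl, list(
    threshold_rule("VENT", 7, "gt", "prolonged", "not_prolonged"),
    threshold_rule("MDI", 70, "le", "low", "not_low")))
  expect_identical(as.character(dc$VENT),
                   c("prolonged", "not_prolonged", "not_prolonged", "prolonged"))
  expect_identical(as.character(dc$MDI), c("low", "not_low", "not_low", "not_low"))
  expect_identical(as.character(dc$dGV), c("true", "false", "true", "false"))

  fav <- apply_thresholds(tbl, list(
    threshold_rule("MDI", 100, "gt", "normal", "not_normal")))
  # MDI = 100 is NOT favorable under the strict > 100 rule
  expect_identical(as.character(fav$MDI),
                   c("not_normal", "not_normal", "not_normal", "normal"))
})

test_that("threshold rules reject binary or absent columns and re-application", {
  df <- data.frame(subject_id = "S1", MDI = 80, dGV = TRUE)
  tbl <- cohort_table(df, kinds = c(MDI = "continuous", dGV = "binary"))
  expect_error(apply_thresholds(tbl, list(threshold_rule("dGV", 0.5, "gt"))),
               class = "svbn_validation_error")
  expect_error(apply_thresholds(tbl, list(threshold_rule("GA", 37, "lt"))),
               class = "svbn_validation_error")
  expect_error(threshold_rule("MDI", Inf, "le"),
               class = "svbn_validation_error")
  expect_error(threshold_rule("MDI", 70, "le", "low", "low"),
               class = "svbn_validation_error")
})

test_that("a rule partitions the non-missing values exactly", {
  set.seed(401)
  for (dir in c("le", "lt", "gt")) {
    df <- data.frame(subject_id = paste0("S", 1:50),
                     LAZ = round(stats::rnorm(50, -0.5, 1.5), 2))
    tbl <- cohort_table(df, kinds = c(LAZ = "continuous"))
    dc <- apply_thresholds(tbl, list(threshold_rule("LAZ", -1.6, dir,
                                                    "low", "not_low")))
    counts <- table(dc$LAZ)
    expect_equal(sum(counts), 50L)
    expect_setequal(names(counts), c("not_low", "low"))
  }
})

test_that("discrete cohorts round-trip through TSV + sidecar bit-exactly", {
  df <- data.frame(subject_id = paste0("S", 1:6),
                   MDI = c(60, 75, 85, 100, 101, 70),
                   dGV = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  tbl <- cohort_table(df, kinds = c(MDI = "continuous", dGV = "binary"))
  dc <- apply_thresholds(tbl, list(threshold_rule("MDI", 70, "le",
                                                  "low", "not_low")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_discrete_cohort(dc, path)
  back <- read_discrete_cohort(path)
  expect_identical(as.data.frame(back), as.data.frame(dc))
  expect_identical(cohort_states(back), cohort_states(dc))
  expect_identical(cohort_flags(back), cohort_flags(dc))
})

test_that("discrete cohorts refuse missing cells", {
  df <- data.frame(subject_id = c("S1", "S2"), MDI = c(60, NA))
  tbl <- cohort_table(df, kinds = c(MDI = "continuous"))
  expect_error(apply_thresholds(tbl, list(threshold_rule("MDI", 70, "le"))),
               class = "svbn_validation_error")
})
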