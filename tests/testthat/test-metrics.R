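# the eight published classification-table rows: bin counts and the
# formatted cells they must reproduce
published_rows <- list(
  list(counts = c(738, 0, 1013, 5),  sens = "100%",  prec = "0.5%",  f1 = "0.010"),
  list(counts = c(1088, 0, 663, 5),  sens = "100%",  prec = "0.7%",  f1 = "0.015"),
  list(counts = c(1549, 1, 203, 4),  sens = "80.0%", prec = "1.9%",  f1 = "0.038"),
  list(counts = c(1357, 0, 394, 5),  sens = "100%",  prec = "1.3%",  f1 = "0.025"),
  list(counts = c(1546, 0, 205, 5),  sens = "100%",  prec = "2.4%",  f1 = "0.047"),
  list(counts = c(1547, 0, 204, 5),  sens = "100%",  prec = "2.4%",  f1 = "0.047"),
  list(counts = c(1672, 0, 79, 5),   sens = "100%",  prec = "6.0%",  f1 = "0.112"),
  list(counts = c(1735, 0, 16, 5),   sens = "100%",  prec = "23.8%", f1 = "0.385"))

test_that("Test #1 reproduces every published row from its bin counts", {
  for (row in published_rows) {
    b <- binned_cohort_from_counts(row$counts[1], row$counts[2],
                                   row$counts[3], row$counts[4])
    r <- confusion_test1(b)
    expect_equal(r$tp, row$counts[4])
    expect_equal(r$fp, row$counts[3])
    expect_equal(r$tn, row$counts[1])
    expect_equal(r$fn, row$counts[2])
    fmt <- format_report_row(r, b)
    expect_equal(unname(fmt["sensitivity"]), row$sens)
    expect_equal(unname(fmt["precision"]), row$prec)
    expect_equal(unname(fmt["f1"]), row$f1)
  }
})

test_that("format_report_row renders bins and percentages in table layout", {
  b <- binned_cohort_from_counts(1672, 0, 79, 5)
  fmt <- format_report_row(confusion_test1(b), b)
  expect_equal(unname(fmt[c("hq", "lq")]), c("1672 (0)", "84 (5)"))
  expect_equal(unname(fmt[c("sensitivity", "precision", "f1")]),
               c("100%", "6.0%", "0.112"))
  expect_equal(format_percent(5 / 21), "23.8%")
  # NA metrics render as NA
  empty_lq <- binned_cohort_from_counts(10, 0, 0, 0)
  fmt2 <- format_report_row(confusion_test1(empty_lq), empty_lq)
  expect_equal(unname(fmt2[c("sensitivity", "precision", "f1")]),
               c("NA", "NA", "NA"))
})

test_that("NA semantics: degenerate denominators never divide by zero", {
  # no unconfirmed variants at all -> Test #1 sensitivity NA
  b <- binned_cohort_from_counts(90, 0, 10, 0)
  r <- confusion_test1(b)
  expect_true(is.na(r$sensitivity))
  expect_equal(r$precision, 0)
  expect_true(is.na(r$f1))
  # empty LQ bin -> precision NA, F1 NA
  r2 <- confusion_test1(binned_cohort_from_counts(90, 2, 0, 0))
  expect_true(is.na(r2$precision))
  expect_true(is.na(r2$f1))
})

test_that("Test #2 orientation and identities hold", {
  b <- binned_cohort_from_counts(1735, 0, 16, 5)
  r2 <- confusion_test2(b)
  expect_equal(r2$tp, 1735)
  expect_equal(r2$precision, 1)   # fp = 0 forces precision 1
  expect_equal(format_percent(r2$precision), "100%")
  # identity: Test1.tp + Test2.tn equals the total unconfirmed count
  for (seed in c(5, 6)) {
    rec <- random_cohort(200, seed)
    bb <- bin_cohort(rec, builtin_policy_catalog()[[7]])
    expect_equal(confusion_test1(bb)$tp + 0L,
                 sum(!rec$confirmed) - bb$hq_unconfirmed)
    expect_equal(confusion_test1(bb)$tp + confusion_test2(bb)$tn,
                 2L * bb$lq_unconfirmed)
  }
})

test_that("both tests match the brute-force oracle on random cohorts", {
  for (seed in 31:34) {
    rec <- random_cohort(200, seed)
    for (p in builtin_policy_catalog()[c(2, 5, 8)]) {
      b <- bin_cohort(rec, p)
      o1 <- brute_test1(rec, p); o2 <- brute_test2(rec, p)
      r1 <- confusion_test1(b); r2 <- confusion_test2(b)
      expect_equal(c(r1$tp, r1$fp, r1$tn, r1$fn), c(o1$tp, o1$fp, o1$tn, o1$fn))
      expect_equal(r1$sensitivity, o1$sensitivity)
      expect_equal(r1$precision, o1$precision)
      expect_equal(r1$f1, o1$f1)
      expect_equal(c(r2$tp, r2$fp, r2$tn, r2$fn), c(o2$tp, o2$fp, o2$tn, o2$fn))
      expect_equal(r2$f1, o2$f1)
    }
  }
})

test_that("F1 lies between precision and recall and collapses when equal", {
  for (seed in 41:45) {
    rec <- random_cohort(150, seed)
    b <- bin_cohort(rec, builtin_policy_catalog()[[6]])
    r <- confusion_test1(b)
    if (!is.na(r$f1)) {
      expect_gte(r$f1, min(r$sensitivity, r$precision) - 1e-12)
      expect_lte(r$f1, max(r$sensitivity, r$precision) + 1e-12)
    }
  }
  eq <- confusion_test1(binned_cohort_from_counts(0, 2, 2, 8))
  expect_equal(eq$sensitivity, eq$precision)
  expect_equal(eq$f1, eq$precision)
})

test_that("concordance matches the published cohort summary", {
  rec <- variant_records(chrom = "chr1", pos = 1:1756, ref = "A", alt = "G",
                         qual = 100, dp = 30, af = 0.5,
                         confirmed = c(rep(TRUE, 1751), rep(FALSE, 5)))
  cc <- concordance(rec)
  expect_equal(round_half_up(100 * cc$concordance, 2), 99.72)
  expect_equal(round_half_up(100 * cc$discordant_fraction, 2), 0.28)
  expect_equal(cc$n_discordant, 5L)

  all_conf <- variant_records("chr1", 1:3, "A", "G", 1, dp = 1, af = 1,
                              confirmed = TRUE)
  expect_equal(concordance(all_conf)$concordance, 1)
  none <- variant_records("chr1", 1:3, "A", "G", 1, dp = 1, af = 1,
                          confirmed = FALSE)
  expect_equal(concordance(none)$concordance, 0)
  expect_error(concordance(none[0, ]), "empty")
})

test_that("rounding is half-up, not half-even", {
  expect_equal(round_half_up(0.0465, 3), 0.047)
  expect_equal(round_half_up(0.0455, 3), 0.046)
  expect_equal(round_half_up(2.35, 1), 2.4)
  expect_equal(round_half_up(-2.35, 1), -2.4)
})

test_that("evaluation TSV and JSON outputs carry identical numbers", {
  rec <- table2_cohort()
  ev <- evaluate_policies(rec, builtin_policy_catalog()[c(5, 7)])
  prefix <- tempfile()
  write_evaluation(ev, prefix)
  tsv <- utils::read.delim(paste0(prefix, ".tsv"))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(tsv$lq_size, ev$lq_size)
  expect_equal(js$lq_size, ev$lq_size)
  expect_equal(js$precision, ev$precision, tolerance = 1e-12)
  expect_equal(tsv$precision_display, c("2.4%", "6.0%"))
})
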