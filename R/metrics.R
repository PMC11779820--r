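#' Classification reports for confirmation-policy tests
#'
#' Two orientations of the same confusion matrix are used to score an HQ/LQ
#' binning against Sanger outcomes:
#'
#' * **Test #1** — "the LQ bin identifies unconfirmed variants": TP are
#'   unconfirmed variants in LQ, FP confirmed in LQ, TN confirmed in HQ, FN
#'   unconfirmed in HQ. Sensitivity (recall) is then the fraction of all
#'   unconfirmed variants caught by the LQ bin, and precision is the
#'   unconfirmed fraction *of* the LQ bin — the yield of confirmatory
#'   testing.
#' * **Test #2** — the reverse, "the HQ bin identifies confirmed variants":
#'   TP confirmed in HQ, FP unconfirmed in HQ, TN unconfirmed in LQ, FN
#'   confirmed in LQ.
#'
#' F1 is the harmonic mean of precision and recall. Degenerate denominators
#' give `NA` (sensitivity when there are no unconfirmed variants at all,
#' precision when the positive-call bin is empty); F1 is `NA` when either
#' input is `NA` or both are zero.
#'
#' @param binned a `binned_cohort` from [bin_cohort()] or
#'   [binned_cohort_from_counts()].
#' @return a `classification_report`: `test`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `precision`, `f1` (full precision; formatting is applied
#'   only by [format_report_row()]).
#' @export
confusion_test1 <- function(binned) {
  make_report("TEST1",
              tp = binned$lq_unconfirmed, fp = binned$lq_confirmed,
              tn = binned$hq_confirmed, fn = binned$hq_unconfirmed)
}

#' @rdname confusion_test1
#' @export
confusion_test2 <- function(binned) {
  make_report("TEST2",
              tp = binned$hq_confirmed, fp = binned$hq_unconfirmed,
              tn = binned$lq_unconfirmed, fn = binned$lq_confirmed)
}

make_report <- function(test, tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  structure(list(test = test, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, precision = prec, f1 = f1),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s  tp=%d fp=%d tn=%d fn=%d\n", x$test,
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s  precision %s  F1 %s\n",
              format_percent(x$sensitivity), format_percent(x$precision),
              format_f1(x$f1)))
  invisible(x)
}

#' Concordance of a labeled cohort with its orthogonal validation
#'
#' @param records labeled [variant_records]; all rows must have known
#'   `confirmed`.
#' @return list: `n`, `n_confirmed`, `n_discordant`, `concordance`
#'   (confirmed/total), `discordant_fraction`.
#' @export
concordance <- function(records) {
  if (nrow(records) == 0L) stop_input("empty cohort")
  if (any(is.na(records$confirmed)))
    stop_input("all records must have a known confirmation label")
  n <- nrow(records)
  nc <- sum(records$confirmed)
  list(n = n, n_confirmed = nc, n_discordant = n - nc,
       concordance = nc / n, discordant_fraction = (n - nc) / n)
}

#' Render one report row in the published-table layout
#'
#' Bins are rendered as `"N (u)"` (bin size with its unconfirmed count in
#' parentheses), sensitivity and precision as percentages (one decimal,
#' except a bare `"100%"` when exact), F1 to three decimals; all rounding is
#' half-up. `NA` metrics render as `"NA"`.
#'
#' @param report a `classification_report`.
#' @param binned the `binned_cohort` the report was computed from.
#' @return named character vector: `hq`, `lq`, `sensitivity`, `precision`,
#'   `f1`.
#' @export
format_report_row <- function(report, binned) {
  c(hq = sprintf("%d (%d)", binned$hq_confirmed + binned$hq_unconfirmed,
                 binned$hq_unconfirmed),
    lq = sprintf("%d (%d)", binned$lq_confirmed + binned$lq_unconfirmed,
                 binned$lq_unconfirmed),
    sensitivity = format_percent(report$sensitivity),
    precision = format_percent(report$precision),
    f1 = format_f1(report$f1))
}

#' Evaluate a catalog of policies on a labeled cohort
#'
#' Bins the cohort under every policy and computes both test orientations;
#' the workhorse behind a published-style classification-statistics table.
#'
#' @param records labeled [variant_records].
#' @param policies list of [threshold_policy] objects (default: the built-in
#'   catalog).
#' @inheritParams bin_cohort
#' @return data frame, one row per policy: name, thresholds description, bin
#'   counts, and Test #1 and Test #2 sensitivity/precision/F1 at full
#'   precision.
#' @export
evaluate_policies <- function(records, policies = builtin_policy_catalog(),
                              unknown = "error", missing_filter_pass = FALSE) {
  rows <- lapply(policies, function(p) {
    b <- bin_cohort(records, p, unknown, missing_filter_pass)
    t1 <- confusion_test1(b)
    t2 <- confusion_test2(b)
    data.frame(policy = p$name,
               thresholds = paste(vapply(p$predicates, format, ""),
                                  collapse = ","),
               dp_min = policy_threshold(p, "DP"),
               af_min = policy_threshold(p, "AF"),
               qual_min = policy_threshold(p, "QUAL"),
               hq_confirmed = b$hq_confirmed, hq_unconfirmed = b$hq_unconfirmed,
               lq_confirmed = b$lq_confirmed, lq_unconfirmed = b$lq_unconfirmed,
               lq_size = b$lq_confirmed + b$lq_unconfirmed,
               sensitivity = t1$sensitivity, precision = t1$precision,
               f1 = t1$f1,
               sensitivity_test2 = t2$sensitivity,
               precision_test2 = t2$precision, f1_test2 = t2$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("policy_evaluation", "data.frame")
  out
}

policy_threshold <- function(policy, parameter) {
  for (p in policy$predicates)
    if (p$parameter == parameter && !is.null(p$value)) return(p$value)
  NA_real_
}

#' Write a policy evaluation as TSV and JSON
#'
#' Both files carry the same numbers; the TSV additionally carries the
#' formatted (rounded) display cells.
#'
#' @param evaluation output of [evaluate_policies()] or [grid_search()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @export
write_evaluation <- function(evaluation, prefix) {
  df <- as.data.frame(evaluation)
  if (all(c("hq_confirmed", "sensitivity") %in% names(df))) {
    df$hq_display <- sprintf("%d (%d)", df$hq_confirmed + df$hq_unconfirmed,
                             df$hq_unconfirmed)
    df$lq_display <- sprintf("%d (%d)", df$lq_confirmed + df$lq_unconfirmed,
                             df$lq_unconfirmed)
    df$sensitivity_display <- format_percent(df$sensitivity)
    df$precision_display <- format_percent(df$precision)
    df$f1_display <- format_f1(df$f1)
  }
  utils::write.table(df, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.data.frame(evaluation), paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(prefix)
}
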