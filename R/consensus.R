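#' Score consensus-caller validation against orthogonal confirmation
#'
#' Treats a secondary variant caller's re-call of a variant as a predictor of
#' Sanger confirmation and scores it as a binary classifier: TP = confirmed
#' and re-called, FP = unconfirmed but re-called, FN = confirmed but missed,
#' TN = unconfirmed and not called. This orientation — the secondary call
#' predicts confirmation — is stated explicitly in the report.
#'
#' Precision is `NA` when the secondary caller calls nothing, but F1 is then
#' reported as 0 with a warning: a validator that never fires is useless, not
#' unmeasurable.
#'
#' @param records labeled [variant_records]; every row must have known
#'   `confirmed` and `called_by_secondary` (filter to the subset under
#'   evaluation first, e.g. the low-QUAL bin).
#' @return a `consensus_report`: `n_records`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `orientation`.
#' @export
consensus_f1 <- function(records) {
  if (nrow(records) == 0L) stop_input("empty cohort")
  bad <- is.na(records$confirmed) | is.na(records$called_by_secondary)
  if (any(bad))
    stop_input("record(s) with unknown labels at row(s): ",
               paste(utils::head(which(bad), 10), collapse = ", "),
               if (sum(bad) > 10) " ..." else "")
  conf <- records$confirmed
  called <- records$called_by_secondary
  tp <- sum(conf & called)
  fp <- sum(!conf & called)
  fn <- sum(conf & !called)
  tn <- sum(!conf & !called)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  if (tp + fp == 0) {
    warning("secondary caller called no variants; F1 reported as 0")
    f1 <- 0
  } else if (is.na(rec) || prec + rec == 0) {
    f1 <- if (is.na(rec)) NA_real_ else 0
  } else {
    f1 <- 2 * prec * rec / (prec + rec)
  }
  structure(list(n_records = nrow(records), tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = prec, recall = rec, f1 = f1,
                 orientation = "secondary-caller call predicts confirmation"),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> n=%d (%s)\n", x$n_records, x$orientation))
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d  precision %s recall %s F1 %s\n",
              x$tp, x$fp, x$fn, x$tn, format_percent(x$precision),
              format_percent(x$recall), format_f1(x$f1)))
  invisible(x)
}
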