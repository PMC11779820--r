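#' Define a threshold search grid
#'
#' Defaults span all published hard-filter thresholds for short variants:
#' DP 5..40, AF 0.05..0.50 in 0.01 steps; a QUAL axis is off by default
#' because QUAL is caller-specific (supply `qual_values` to add one).
#'
#' @param dp_values integer depth thresholds (ascending).
#' @param af_values allele-fraction thresholds in `[0, 1]` (ascending).
#' @param qual_values optional QUAL thresholds (ascending), `NULL` for a
#'   caller-agnostic DP x AF grid.
#' @param constraint_sensitivity Test #1 sensitivity floor used by
#'   [best_policies()]; default 1.0 (no unconfirmed variant may escape to
#'   HQ).
#' @return a `search_grid` list.
#' @export
search_grid <- function(dp_values = 5:40,
                        af_values = seq(0.05, 0.50, by = 0.01),
                        qual_values = NULL,
                        constraint_sensitivity = 1.0) {
  if (length(dp_values) == 0L && length(af_values) == 0L &&
      length(qual_values) == 0L)
    stop_input("empty search grid")
  if (length(af_values) && (min(af_values) < 0 || max(af_values) > 1))
    stop_input("af_values must lie in [0, 1]")
  if ((length(dp_values) && min(dp_values) < 0) ||
      (length(qual_values) && min(qual_values) < 0))
    stop_input("dp_values and qual_values must be >= 0")
  structure(list(dp_values = sort(dp_values), af_values = sort(af_values),
                 qual_values = if (is.null(qual_values)) NULL else sort(qual_values),
                 constraint_sensitivity = constraint_sensitivity),
            class = "search_grid")
}

#' Exhaustive threshold grid search
#'
#' Evaluates every grid point (a minimum-inclusive policy over the axes
#' present in the grid) on the labeled cohort with Test #1 statistics.
#' Rows are ordered by DP, then AF, then QUAL ascending, and results do not
#' depend on record order.
#'
#' @param records labeled [variant_records] (known `confirmed` everywhere).
#' @param grid a [search_grid].
#' @return data frame of class `policy_evaluation`, one row per grid point:
#'   `dp_min`, `af_min`, `qual_min`, bin counts, `lq_size`, Test #1
#'   `sensitivity`, `precision`, `f1`.
#' @export
grid_search <- function(records, grid = search_grid()) {
  if (!inherits(grid, "search_grid")) stop_input("grid must be a search_grid")
  if (nrow(records) == 0L) stop_input("empty cohort")
  if (any(is.na(records$confirmed)))
    stop_input("all records must have a known confirmation label")

  dp_axis <- if (length(grid$dp_values)) grid$dp_values else NA_real_
  af_axis <- if (length(grid$af_values)) grid$af_values else NA_real_
  q_axis <- if (length(grid$qual_values)) grid$qual_values else NA_real_
  pts <- expand.grid(qual_min = q_axis, af_min = af_axis, dp_min = dp_axis,
                     KEEP.OUT.ATTRS = FALSE)
  pts <- pts[order(pts$dp_min, pts$af_min, pts$qual_min), , drop = FALSE]

  dp <- records$dp; af <- records$af; qual <- records$qual
  conf <- records$confirmed
  af[is.na(af)] <- -Inf  # an unmeasurable AF fails any minimum threshold
  n_unconf <- sum(!conf)

  m <- nrow(pts)
  hq_c <- hq_u <- integer(m)
  for (k in seq_len(m)) {
    hq <- rep(TRUE, length(dp))
    if (!is.na(pts$dp_min[k])) hq <- hq & dp >= pts$dp_min[k]
    if (!is.na(pts$af_min[k])) hq <- hq & af >= pts$af_min[k]
    if (!is.na(pts$qual_min[k])) hq <- hq & qual >= pts$qual_min[k]
    hq_c[k] <- sum(hq & conf)
    hq_u[k] <- sum(hq & !conf)
  }
  lq_c <- sum(conf) - hq_c
  lq_u <- n_unconf - hq_u
  lq_size <- lq_c + lq_u
  sens <- if (n_unconf > 0) lq_u / n_unconf else NA_real_
  prec <- ifelse(lq_size > 0, lq_u / lq_size, NA_real_)
  f1 <- ifelse(!is.na(sens) & !is.na(prec) & (sens + prec) > 0,
               2 * sens * prec / (sens + prec), NA_real_)
  out <- data.frame(
    policy = sprintf("grid_dp%s_af%s_qual%s", fmt_axis(pts$dp_min),
                     fmt_axis(pts$af_min), fmt_axis(pts$qual_min)),
    dp_min = pts$dp_min, af_min = pts$af_min, qual_min = pts$qual_min,
    hq_confirmed = hq_c, hq_unconfirmed = hq_u,
    lq_confirmed = lq_c, lq_unconfirmed = lq_u, lq_size = lq_size,
    sensitivity = sens, precision = prec, f1 = f1,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("policy_evaluation", "data.frame")
  out
}

# canonical, grid-independent axis label ("20", "0.2", "NA")
fmt_axis <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%g", round(x, 6)))
}

# rebuild the minimum-threshold policy a grid/evaluation row describes
row_policy <- function(row) {
  policy_spec(row$policy,
              dp = if (is.na(row$dp_min)) NULL else row$dp_min,
              af = if (is.na(row$af_min)) NULL else row$af_min,
              qual = if (is.na(row$qual_min)) NULL else row$qual_min)
}

#' Select the best policies under a sensitivity constraint
#'
#' Filters evaluations to those meeting the Test #1 sensitivity floor and
#' returns the maximal-precision subset. Ties are broken toward the smaller
#' LQ bin (fewer confirmations at equal safety), then toward lower DP, AF
#' and QUAL thresholds (more permissive for future data). When a baseline
#' policy name is given, the result carries the LQ-bin shrink factor
#' relative to it (`attr(, "shrink_factor")`), the published way of stating
#' the confirmatory-testing saving.
#'
#' @param evaluations a `policy_evaluation` data frame from
#'   [evaluate_policies()] or [grid_search()].
#' @param constraint_sensitivity Test #1 sensitivity floor (default 1.0).
#' @param baseline optional policy name present in `evaluations`.
#' @return the selected rows (possibly several on exact ties), with
#'   attributes `shrink_factor` and `diagnostic`; zero rows (with a
#'   diagnostic) when no evaluation meets the constraint.
#' @export
best_policies <- function(evaluations, constraint_sensitivity = 1.0,
                          baseline = NULL) {
  ev <- as.data.frame(evaluations)
  ok <- !is.na(ev$sensitivity) & ev$sensitivity >= constraint_sensitivity
  if (!any(ok)) {
    out <- ev[0, , drop = FALSE]
    attr(out, "diagnostic") <- sprintf(
      "no evaluation reaches sensitivity >= %g (best available: %g)",
      constraint_sensitivity, suppressWarnings(max(ev$sensitivity, na.rm = TRUE)))
    return(out)
  }
  cand <- ev[ok, , drop = FALSE]
  cand <- cand[!is.na(cand$precision) & cand$precision == max(cand$precision, na.rm = TRUE), ,
               drop = FALSE]
  key_na <- function(v) ifelse(is.na(v), -Inf, v)  # absent axis = most permissive
  ord <- order(cand$lq_size, key_na(cand$dp_min), key_na(cand$af_min),
               key_na(cand$qual_min))
  cand <- cand[ord, , drop = FALSE]
  best <- cand[cand$lq_size == cand$lq_size[1] &
                 key_na(cand$dp_min) == key_na(cand$dp_min[1]) &
                 key_na(cand$af_min) == key_na(cand$af_min[1]) &
                 key_na(cand$qual_min) == key_na(cand$qual_min[1]), ,
               drop = FALSE]
  if (!is.null(baseline)) {
    bi <- match(baseline, ev$policy)
    if (is.na(bi)) stop_input("baseline policy '", baseline,
                              "' not among the evaluations")
    attr(best, "shrink_factor") <- ev$lq_size[bi] / best$lq_size[1]
    attr(best, "baseline") <- baseline
  }
  attr(best, "diagnostic") <- "ok"
  best
}

#' Threshold fragility analysis
#'
#' Perturbs one threshold of a policy through a sequence of values and
#' reports, for each, the Test #1 sensitivity and the number of unconfirmed
#' variants that enter the HQ bin — how close unconfirmed variants sit to
#' the boundary. Raising a minimum threshold can only move records toward
#' LQ, so sensitivity is monotone non-decreasing along increasing values.
#'
#' @param records labeled [variant_records].
#' @param policy a [threshold_policy] containing `parameter`.
#' @param parameter `"DP"`, `"AF"` or `"QUAL"`.
#' @param values threshold values to substitute for that parameter.
#' @return data frame: `threshold`, `sensitivity`, `hq_unconfirmed`,
#'   `lq_size`.
#' @export
fragility <- function(records, policy, parameter, values) {
  parameter <- match.arg(parameter, c("DP", "AF", "QUAL"))
  idx <- which(vapply(policy$predicates, `[[`, "", "parameter") == parameter)
  if (length(idx) == 0L)
    stop_input("policy '", policy$name, "' has no ", parameter, " predicate")
  rows <- lapply(values, function(v) {
    p2 <- policy
    p2$predicates[[idx]]$value <- v
    b <- bin_cohort(records, p2)
    r <- confusion_test1(b)
    data.frame(threshold = v, sensitivity = r$sensitivity,
               hq_unconfirmed = b$hq_unconfirmed,
               lq_size = b$lq_confirmed + b$lq_unconfirmed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
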