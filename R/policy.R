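#' Threshold predicates and policies
#'
#' A `threshold_policy` is a named set of hard-filter predicates over the
#' quality parameters `DP`, `AF`, `QUAL` and `FILTER`. A variant is
#' high-quality (HQ, exempt from confirmation) iff it satisfies every
#' predicate; otherwise it is low-quality (LQ, confirmation required).
#' Supported predicate kinds are `min_inclusive` (`>=`), `min_strict` (`>`),
#' and `equals_pass` (FILTER literally equal to `PASS`).
#'
#' @param parameter one of `"DP"`, `"AF"`, `"QUAL"`, `"FILTER"`.
#' @param kind `"min_inclusive"`, `"min_strict"` or `"equals_pass"`.
#' @param value numeric threshold; omitted for `equals_pass`. Must be in
#'   `[0, 1]` for AF and non-negative for DP/QUAL.
#' @return a `threshold_predicate` list.
#' @export
threshold_predicate <- function(parameter, kind = "min_inclusive", value = NULL) {
  parameter <- match.arg(parameter, c("DP", "AF", "QUAL", "FILTER"))
  kind <- match.arg(kind, c("min_inclusive", "min_strict", "equals_pass"))
  if (parameter == "FILTER") {
    if (kind != "equals_pass") stop_input("FILTER predicates must be equals_pass")
    value <- NULL
  } else {
    if (kind == "equals_pass") stop_input("equals_pass applies to FILTER only")
    if (is.null(value)) stop_input("a numeric threshold is required for ", parameter)
    value <- as.numeric(value)
    if (value < 0) stop_input(parameter, " threshold must be >= 0")
    if (parameter == "AF" && value > 1) stop_input("AF threshold must be in [0, 1]")
  }
  structure(list(parameter = parameter, kind = kind, value = value),
            class = "threshold_predicate")
}

#' @rdname threshold_predicate
#' @param name policy name.
#' @param predicates list of `threshold_predicate`s, at most one per parameter.
#' @param source free-text citation for where the thresholds come from.
#' @export
threshold_policy <- function(name, predicates, source = "") {
  if (inherits(predicates, "threshold_predicate")) predicates <- list(predicates)
  if (length(predicates) == 0L) stop_input("a policy needs at least one predicate")
  params <- vapply(predicates, `[[`, "", "parameter")
  if (anyDuplicated(params))
    stop_input("at most one predicate per parameter (duplicated: ",
               paste(unique(params[duplicated(params)]), collapse = ", "), ")")
  structure(list(name = name, predicates = predicates, source = source),
            class = "threshold_policy")
}

#' @export
format.threshold_predicate <- function(x, ...) {
  switch(x$kind,
         equals_pass = "FILTER=PASS",
         min_inclusive = sprintf("%s>=%g", x$parameter, x$value),
         min_strict = sprintf("%s>%g", x$parameter, x$value))
}

#' @export
format.threshold_policy <- function(x, ...) {
  paste0(x$name, " {",
         paste(vapply(x$predicates, format, ""), collapse = ", "), "}")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("<threshold_policy>", format(x), "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

# shorthand used throughout tests and the catalog
policy_spec <- function(name, dp = NULL, af = NULL, qual = NULL,
                        qual_strict = FALSE, filter_pass = FALSE, source = "") {
  preds <- list()
  if (!is.null(dp)) preds <- c(preds, list(threshold_predicate("DP", value = dp)))
  if (!is.null(af)) preds <- c(preds, list(threshold_predicate("AF", value = af)))
  if (filter_pass) preds <- c(preds, list(threshold_predicate("FILTER", "equals_pass")))
  if (!is.null(qual))
    preds <- c(preds, list(threshold_predicate(
      "QUAL", if (qual_strict) "min_strict" else "min_inclusive", qual)))
  threshold_policy(name, preds, source)
}

#' Built-in catalog of published confirmation policies
#'
#' The eight hard-filter policies evaluated against the WGS Sanger-validation
#' cohort, in their conventional comparison order: thresholds from prior
#' targeted-panel/exome studies (Zheng, De Cario, Yohe, Nelson,
#' Arteche-Lopez), the caller-agnostic reduction of the Arteche-Lopez set,
#' the WGS-tuned caller-agnostic pair DP>=15 & AF>=0.25, and the
#' caller-specific QUAL>=100 rule (HaplotypeCaller scale). All thresholds are
#' inclusive except Nelson's QUAL, which is strict (> 300) as published.
#'
#' @return list of eight [threshold_policy] objects.
#' @export
builtin_policy_catalog <- function() {
  list(
    policy_spec("DP35_AF35", dp = 35, af = 0.35, source = "Zheng et al. targeted panel/WES"),
    policy_spec("DP30_QUAL30", dp = 30, qual = 30, source = "De Cario et al. targeted panel"),
    policy_spec("DP20", dp = 20, source = "Yohe et al. targeted panel"),
    policy_spec("DP20_AF30_PASS_QUALgt300", dp = 20, af = 0.3, qual = 300,
                qual_strict = TRUE, filter_pass = TRUE,
                source = "Nelson et al. targeted panel"),
    policy_spec("DP20_AF20_PASS_QUAL100", dp = 20, af = 0.2, qual = 100,
                filter_pass = TRUE, source = "Arteche-Lopez et al. clinical exome"),
    policy_spec("DP20_AF20", dp = 20, af = 0.2, source = "caller-agnostic reduction"),
    policy_spec("DP15_AF25", dp = 15, af = 0.25, source = "WGS caller-agnostic (this package's reference study)"),
    policy_spec("QUAL100", qual = 100, source = "WGS caller-specific, HaplotypeCaller v4.2 scale")
  )
}

# logical vector: does each record satisfy every predicate of the policy?
# NA parameter values fail the predicate (an unmeasurable variant goes LQ).
satisfies_policy <- function(records, policy, missing_filter_pass = FALSE) {
  ok <- rep(TRUE, nrow(records))
  for (p in policy$predicates) {
    v <- switch(p$parameter, DP = records$dp, AF = records$af,
                QUAL = records$qual, FILTER = records$filter_status)
    hit <- switch(p$kind,
                  min_inclusive = v >= p$value,
                  min_strict = v > p$value,
                  equals_pass = v == "PASS" |
                    (missing_filter_pass & v == "MISSING"))
    hit[is.na(hit)] <- FALSE
    ok <- ok & hit
  }
  ok
}

#' Assign one variant record to the HQ or LQ bin
#'
#' @param record a single-row [variant_records] data frame.
#' @param policy a [threshold_policy].
#' @param missing_filter_pass treat FILTER `"MISSING"` (`.`) as PASS. Default
#'   `FALSE`: an unfiltered variant is not PASS, the safe clinical reading.
#' @return `"HQ"` or `"LQ"`.
#' @export
assign_bin <- function(record, policy, missing_filter_pass = FALSE) {
  ifelse(satisfies_policy(record, policy, missing_filter_pass), "HQ", "LQ")
}

#' Partition a labeled cohort into HQ/LQ bins under a policy
#'
#' @param records labeled [variant_records]; every row must have a known
#'   `confirmed` label unless `unknown = "exclude"`.
#' @param policy a [threshold_policy].
#' @param unknown `"error"` (default) or `"exclude"` rows with unknown
#'   confirmation.
#' @inheritParams assign_bin
#' @return a `binned_cohort`: policy, the four bin counts
#'   (`hq_confirmed`, `hq_unconfirmed`, `lq_confirmed`, `lq_unconfirmed`),
#'   `n`, and per-record `assignments` (`"HQ"`/`"LQ"`).
#' @export
bin_cohort <- function(records, policy, unknown = c("error", "exclude"),
                       missing_filter_pass = FALSE) {
  unknown <- match.arg(unknown)
  if (nrow(records) == 0L) stop_input("empty cohort")
  na_lab <- is.na(records$confirmed)
  if (any(na_lab)) {
    if (unknown == "error")
      stop_input(sum(na_lab), " record(s) have unknown confirmation; ",
                 "label them or use unknown = \"exclude\"")
    records <- records[!na_lab, , drop = FALSE]
    if (nrow(records) == 0L) stop_input("no labeled records left after exclusion")
  }
  hq <- satisfies_policy(records, policy, missing_filter_pass)
  res <- structure(list(
    policy = policy,
    hq_confirmed = sum(hq & records$confirmed),
    hq_unconfirmed = sum(hq & !records$confirmed),
    lq_confirmed = sum(!hq & records$confirmed),
    lq_unconfirmed = sum(!hq & !records$confirmed),
    n = nrow(records),
    assignments = ifelse(hq, "HQ", "LQ")
  ), class = "binned_cohort")
  stopifnot(res$hq_confirmed + res$hq_unconfirmed +
              res$lq_confirmed + res$lq_unconfirmed == res$n)
  res
}

# build a binned_cohort directly from the four counts (e.g. a published
# table row), bypassing per-record assignment
binned_counts <- function(hq_confirmed, hq_unconfirmed, lq_confirmed,
                          lq_unconfirmed, policy = NULL) {
  structure(list(policy = policy, hq_confirmed = hq_confirmed,
                 hq_unconfirmed = hq_unconfirmed, lq_confirmed = lq_confirmed,
                 lq_unconfirmed = lq_unconfirmed,
                 n = hq_confirmed + hq_unconfirmed + lq_confirmed + lq_unconfirmed,
                 assignments = NULL),
            class = "binned_cohort")
}

#' @rdname bin_cohort
#' @param hq_confirmed,hq_unconfirmed,lq_confirmed,lq_unconfirmed bin counts.
#' @export
binned_cohort_from_counts <- function(hq_confirmed, hq_unconfirmed,
                                      lq_confirmed, lq_unconfirmed,
                                      policy = NULL) {
  counts <- c(hq_confirmed, hq_unconfirmed, lq_confirmed, lq_unconfirmed)
  if (any(counts < 0) || any(counts != as.integer(counts)))
    stop_input("bin counts must be non-negative integers")
  binned_counts(hq_confirmed, hq_unconfirmed, lq_confirmed, lq_unconfirmed,
                policy)
}

#' @export
print.binned_cohort <- function(x, ...) {
  nm <- if (is.null(x$policy)) "(counts only)" else format(x$policy)
  cat(sprintf("<binned_cohort> %s\n  HQ: %d (%d unconfirmed)  LQ: %d (%d unconfirmed)  n=%d\n",
              nm, x$hq_confirmed + x$hq_unconfirmed, x$hq_unconfirmed,
              x$lq_confirmed + x$lq_unconfirmed, x$lq_unconfirmed, x$n))
  invisible(x)
}

#' Read or write a policy catalog as JSON
#'
#' Catalogs are stored as a JSON array of `{name, source, predicates:
#' [{parameter, kind, value}]}` entries.
#'
#' @param path file path.
#' @return for `read_policy_catalog`, a list of [threshold_policy] objects.
#' @export
read_policy_catalog <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(e) {
    preds <- lapply(e$predicates, function(p)
      threshold_predicate(p$parameter, p$kind, p$value))
    threshold_policy(e$name, preds, e$source %||% "")
  })
}

#' @rdname read_policy_catalog
#' @param catalog list of [threshold_policy] objects.
#' @export
write_policy_catalog <- function(catalog, path) {
  out <- lapply(catalog, function(p) list(
    name = p$name, source = p$source,
    predicates = lapply(p$predicates, function(q)
      Filter(Negate(is.null),
             list(parameter = q$parameter, kind = q$kind, value = q$value)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
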