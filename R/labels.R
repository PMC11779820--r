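#' Read a confirmation label table
#'
#' Reads a UTF-8 TSV with header columns `chrom`, `pos`, `ref`, `alt`,
#' `confirmed` and optionally `secondary_call`, the format a lab's Sanger
#' result ledger is assumed to be exported in. Booleans accept
#' yes/no, true/false, t/f, y/n, 1/0 (case-insensitive); `NA`, `unknown` or
#' empty mean unknown. Rows identical under key normalisation are
#' de-duplicated; duplicate keys with conflicting labels are an error.
#'
#' @param table_source path to the TSV file.
#' @return data frame of class `label_table` with columns `key`, `chrom`,
#'   `pos`, `ref`, `alt`, `confirmed`, `called_by_secondary`.
#' @export
read_label_table <- function(table_source) {
  if (!file.exists(table_source)) stop_input("label table not found: ", table_source)
  df <- utils::read.delim(table_source, colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("chrom", "pos", "ref", "alt", "confirmed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_input("label table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop_input("label table '", table_source, "' is empty")
  conf <- parse_tristate(df$confirmed, "confirmed")
  sec <- if ("secondary_call" %in% names(df))
    parse_tristate(df$secondary_call, "secondary_call")
  else rep(NA, nrow(df))
  out <- data.frame(
    key = normalize_variant_key(df$chrom, df$pos, df$ref, df$alt),
    chrom = df$chrom, pos = as.integer(df$pos),
    ref = toupper(df$ref), alt = toupper(df$alt),
    confirmed = conf, called_by_secondary = sec,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  dup <- duplicated(out$key)
  if (any(dup))
    stop_input("conflicting labels for key(s): ",
               paste(unique(out$key[dup]), collapse = ", "))
  class(out) <- c("label_table", "data.frame")
  out
}

parse_tristate <- function(x, col) {
  lx <- tolower(trimws(x))
  lx[is.na(lx)] <- "na"
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[lx %in% c("no", "n", "false", "f", "0")] <- FALSE
  bad <- !(lx %in% c("yes", "y", "true", "t", "1", "no", "n", "false", "f",
                     "0", "na", "unknown", "", "nan"))
  if (any(bad))
    stop_input("unparseable boolean in column '", col, "', row(s) ",
               paste(which(bad), collapse = ", "), ": ",
               paste(unique(x[bad]), collapse = ", "))
  out
}

#' Write a confirmation label table
#'
#' Inverse of [read_label_table()]; booleans are written as yes/no/NA.
#'
#' @param labels a `label_table` or `variant_records` data frame.
#' @param path output TSV path.
#' @export
write_label_table <- function(labels, path) {
  tri <- function(v) ifelse(is.na(v), "NA", ifelse(v, "yes", "no"))
  out <- data.frame(chrom = labels$chrom, pos = labels$pos, ref = labels$ref,
                    alt = labels$alt, confirmed = tri(labels$confirmed),
                    secondary_call = tri(labels$called_by_secondary),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Join confirmation labels onto variant records
#'
#' Labels are matched by normalised variant key (see
#' [normalize_variant_key()]); unmatched records keep unknown labels, and the
#' join is reported rather than failing.
#'
#' @param records a [variant_records] data frame.
#' @param label_map a `label_table` from [read_label_table()].
#' @return list with `records` (labels filled in) and `join`, a list of
#'   `n_matched`, `n_unmatched_records`, `n_unmatched_labels`.
#' @export
attach_labels <- function(records, label_map) {
  keys <- variant_key(records)
  idx <- match(keys, label_map$key)
  hit <- !is.na(idx)
  records$confirmed[hit] <- label_map$confirmed[idx[hit]]
  records$called_by_secondary[hit] <- label_map$called_by_secondary[idx[hit]]
  list(records = records,
       join = list(n_matched = sum(hit),
                   n_unmatched_records = sum(!hit),
                   n_unmatched_labels = sum(!(label_map$key %in% keys))))
}
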