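#' Build a table of per-variant quality records
#'
#' The central container of the package: one row per (site, alternate allele)
#' with the quality parameters a hard-filtering policy can test (QUAL, FILTER,
#' DP, allele fraction) and the orthogonal-confirmation labels. Missing values
#' are encoded as `NA`: `af = NA` means the fraction could not be established
#' (zero depth), `confirmed = NA` / `called_by_secondary = NA` mean the label
#' is unknown.
#'
#' @param chrom chromosome names (character).
#' @param pos 1-based positions (integer, >= 1).
#' @param ref reference alleles (non-empty strings over ACGTN).
#' @param alt single alternate alleles (non-empty strings over ACGTN).
#' @param qual caller confidence scores (non-negative; caller-specific scale).
#' @param filter_status VCF FILTER labels; `"."` is normalised to `"MISSING"`.
#' @param dp sample read depth at the site (non-negative integer).
#' @param af alternate-allele fraction in `[0, 1]`, `NA` when depth is zero.
#' @param region `"exon"`, `"intron"` or `"unknown"`.
#' @param confirmed logical: Sanger confirmation outcome (`NA` = unknown).
#' @param called_by_secondary logical: re-called by a secondary caller
#'   (`NA` = unknown).
#' @param variant_class `"SNV"` or `"INDEL"`; derived from allele lengths when
#'   omitted (an SNV has single-base ref and alt).
#' @return a `data.frame` of class `variant_records`.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual, filter_status = "PASS",
                            dp = NA_integer_, af = NA_real_,
                            region = "unknown", confirmed = NA,
                            called_by_secondary = NA, variant_class = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt), length(qual),
           length(filter_status), length(dp), length(af), length(confirmed),
           length(called_by_secondary))
  fs <- as.character(rep_len(filter_status, n))
  df <- data.frame(
    chrom = as.character(rep_len(chrom, n)),
    pos = as.integer(rep_len(pos, n)),
    ref = toupper(as.character(rep_len(ref, n))),
    alt = toupper(as.character(rep_len(alt, n))),
    qual = as.numeric(rep_len(qual, n)),
    filter_status = ifelse(fs == ".", "MISSING", fs),
    dp = as.integer(rep_len(dp, n)),
    af = as.numeric(rep_len(af, n)),
    region = as.character(rep_len(region, n)),
    confirmed = as.logical(rep_len(confirmed, n)),
    called_by_secondary = as.logical(rep_len(called_by_secondary, n)),
    stringsAsFactors = FALSE
  )
  df$variant_class <- if (is.null(variant_class)) {
    ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "INDEL")
  } else {
    as.character(rep_len(variant_class, n))
  }
  validate_variant_records(df)
  class(df) <- c("variant_records", "data.frame")
  df
}

validate_variant_records <- function(df) {
  if (any(df$pos < 1L, na.rm = TRUE)) stop_input("pos must be >= 1")
  if (any(df$dp < 0L, na.rm = TRUE)) stop_input("dp must be >= 0")
  if (any(df$qual < 0, na.rm = TRUE)) stop_input("qual must be >= 0")
  bad_af <- !is.na(df$af) & (df$af < 0 | df$af > 1)
  if (any(bad_af)) stop_input("af must lie in [0, 1]")
  if (any(!grepl("^[ACGTN]+$", df$ref)) || any(!grepl("^[ACGTN]+$", df$alt)))
    stop_input("ref/alt must be non-empty strings over ACGTN")
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  if (any(df$variant_class != ifelse(snv, "SNV", "INDEL")))
    stop_input("variant_class inconsistent with allele lengths")
  invisible(df)
}

#' @export
print.variant_records <- function(x, ...) {
  n_lab <- sum(!is.na(x$confirmed))
  cat(sprintf("<variant_records> %d records (%d SNV, %d INDEL), %d labeled\n",
              nrow(x), sum(x$variant_class == "SNV"),
              sum(x$variant_class == "INDEL"), n_lab))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Compute an alternate-allele fraction from allelic depths
#'
#' @param allele_depths integer vector of per-allele read depths, reference
#'   first (the VCF FORMAT `AD` convention).
#' @param alt_index which alternate allele (1 = first ALT, i.e. the second
#'   element of `allele_depths`).
#' @return `allele_depths[alt_index + 1] / sum(allele_depths)`, or `NA` when
#'   the total depth is zero.
#' @examples
#' compute_allele_fraction(c(17, 16), 1)  # 16/33
#' @export
compute_allele_fraction <- function(allele_depths, alt_index = 1L) {
  ad <- as.numeric(allele_depths)
  if (any(is.na(ad))) return(NA_real_)
  if (any(ad < 0)) stop_input("allele depths must be non-negative")
  if (alt_index < 1L || alt_index + 1L > length(ad))
    stop_input("alt_index ", alt_index, " does not address an ALT entry of AD")
  tot <- sum(ad)
  if (tot == 0) return(NA_real_)
  ad[alt_index + 1L] / tot
}

#' Normalise a variant identity key
#'
#' Produces a representation-robust key for joining confirmation labels to
#' VCF records: shared trailing then leading bases are trimmed (keeping at
#' least one base of each allele, advancing `pos` over trimmed leading bases)
#' and any `chr` prefix is dropped, so `chr1:100 AT>GT` and `1:100 A>G` map to
#' the same key. Full left-alignment against a reference genome is out of
#' scope; trimming covers the padded representations callers actually emit.
#'
#' @param chrom,pos,ref,alt vectors describing the variants.
#' @return character vector of keys `"chrom:pos:ref:alt"`.
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  mapply(function(c1, p1, r1, a1) {
    # trim shared trailing bases
    while (nchar(r1) > 1L && nchar(a1) > 1L &&
           substr(r1, nchar(r1), nchar(r1)) == substr(a1, nchar(a1), nchar(a1))) {
      r1 <- substr(r1, 1L, nchar(r1) - 1L)
      a1 <- substr(a1, 1L, nchar(a1) - 1L)
    }
    # trim shared leading bases, advancing the position
    while (nchar(r1) > 1L && nchar(a1) > 1L &&
           substr(r1, 1L, 1L) == substr(a1, 1L, 1L)) {
      r1 <- substr(r1, 2L, nchar(r1))
      a1 <- substr(a1, 2L, nchar(a1))
      p1 <- p1 + 1L
    }
    paste(c1, p1, r1, a1, sep = ":")
  }, chrom, pos, ref, alt, USE.NAMES = FALSE)
}

variant_key <- function(records) {
  normalize_variant_key(records$chrom, records$pos, records$ref, records$alt)
}
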