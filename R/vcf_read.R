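#' Read per-variant quality records from a VCF file
#'
#' Extracts QUAL, FILTER, read depth and alternate-allele fraction for every
#' (site, ALT allele) pair of a VCFv4.x file, in input order. Multi-allelic
#' sites are decomposed into one record per ALT allele. Confirmation labels
#' are set to unknown; attach them with [attach_labels()].
#'
#' Field precedence (caller-agnostic by design):
#' * depth: sample FORMAT `DP`, then `sum(AD)`, then INFO `DP`;
#' * allele fraction: derived from sample FORMAT `AD` (that ALT's depth over
#'   the total), then sample FORMAT `VAF`/`AF`, then INFO `AF`.
#' The source actually used is recorded in the `dp_source` / `af_source`
#' columns. A FILTER of `"."` becomes `"MISSING"`.
#'
#' @param vcf_source path to a plain or bgzipped VCF file.
#' @param sample_name sample to extract FORMAT fields from; defaults to the
#'   first sample. Must exist in the header when given.
#' @return a [variant_records] data frame with extra `dp_source`/`af_source`
#'   columns; labels (`confirmed`, `called_by_secondary`) are `NA`.
#' @export
read_vcf_records <- function(vcf_source, sample_name = NULL) {
  if (!file.exists(vcf_source)) stop_input("VCF not found: ", vcf_source)
  prescan_vcf(vcf_source)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(vcf_source)),
    error = function(e) stop_input("malformed VCF '", vcf_source, "': ",
                                   conditionMessage(e)))
  samples <- colnames(vcf)
  si <- 1L
  if (!is.null(sample_name)) {
    si <- match(sample_name, samples)
    if (is.na(si))
      stop_input("sample '", sample_name, "' not in VCF; available: ",
                 paste(samples, collapse = ", "))
  }
  has_sample <- length(samples) >= 1L

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)  # CharacterList / DNAStringSetList
  alts <- lapply(seq_along(alts), function(i) as.character(alts[[i]]))
  quals <- VariantAnnotation::qual(vcf)
  filts <- VariantAnnotation::filt(vcf)

  g <- VariantAnnotation::geno(vcf)
  inf <- VariantAnnotation::info(vcf)
  ad_m <- if (has_sample && "AD" %in% names(g)) g$AD else NULL
  dp_m <- if (has_sample && "DP" %in% names(g)) g$DP else NULL
  fmt_af_name <- if (has_sample) intersect(c("VAF", "AF"), names(g))[1] else NA
  af_m <- if (!is.na(fmt_af_name)) g[[fmt_af_name]] else NULL
  info_af <- if ("AF" %in% names(inf)) inf$AF else NULL
  info_dp <- if ("DP" %in% names(inf)) inf$DP else NULL

  out <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    n_alt <- length(alts[[i]])
    if (n_alt == 0L) next
    ad <- if (!is.null(ad_m)) unlist(ad_m[i, si]) else NULL
    if (!is.null(ad) && all(is.na(ad))) ad <- NULL

    dp_i <- NA_integer_; dp_src <- "none"
    if (!is.null(dp_m) && !is.na(dp_m[i, si])) {
      dp_i <- as.integer(dp_m[i, si]); dp_src <- "format_DP"
    } else if (!is.null(ad)) {
      dp_i <- as.integer(sum(ad, na.rm = TRUE)); dp_src <- "sum_AD"
    } else if (!is.null(info_dp) && !is.na(info_dp[i])) {
      dp_i <- as.integer(info_dp[i]); dp_src <- "info_DP"
    }

    rows <- lapply(seq_len(n_alt), function(j) {
      af_j <- NA_real_; af_src <- "none"
      if (!is.null(ad) && length(ad) >= j + 1L && sum(ad, na.rm = TRUE) > 0) {
        af_j <- compute_allele_fraction(ad, j); af_src <- "format_AD"
      } else if (!is.null(af_m)) {
        v <- unlist(af_m[i, si])
        if (length(v) >= j && !is.na(v[j])) {
          af_j <- as.numeric(v[j]); af_src <- paste0("format_", fmt_af_name)
        }
      }
      if (af_src == "none" && !is.null(info_af)) {
        v <- unlist(info_af[i])
        if (length(v) >= j && !is.na(v[j])) {
          af_j <- as.numeric(v[j]); af_src <- "info_AF"
        }
      }
      data.frame(chrom = chrom[i], pos = pos[i], ref = refs[i],
                 alt = alts[[i]][j],
                 qual = if (is.na(quals[i])) 0 else quals[i],
                 filter_status = if (is.na(filts[i]) || filts[i] == ".")
                   "MISSING" else filts[i],
                 dp = dp_i, af = af_j, dp_source = dp_src, af_source = af_src,
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  flat <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(flat)) stop_input("VCF '", vcf_source, "' contains no variants")
  rec <- variant_records(flat$chrom, flat$pos, flat$ref, flat$alt, flat$qual,
                         flat$filter_status, flat$dp, flat$af)
  rec$dp_source <- flat$dp_source
  rec$af_source <- flat$af_source
  rownames(rec) <- NULL
  rec
}

# light structural pre-pass so malformed files fail with a line number,
# which readVcf does not always report
prescan_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0L || !grepl("^##fileformat=VCF", lines[1]))
    stop_input("malformed VCF '", path, "': line 1 must be ##fileformat=VCFv4.x")
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L)
      stop_input("malformed VCF '", path, "': line ", i,
                 " has ", length(f), " fields (expected >= 8)")
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop_input("malformed VCF '", path, "': line ", i,
                 " has non-numeric POS '", f[2], "'")
  }
  invisible(TRUE)
}
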