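#' Configuration for the synthetic labeled cohort generator
#'
#' Defaults emulate the whole-genome Sanger-validation cohort the package's
#' reference analysis was built on: 1756 labeled variants (1555 SNVs / 201
#' INDELs, exon/intron composition per class as published), per-variant depth
#' with mean 33 hard-bounded to \[3, 81\], QUAL with mean about 492
#' hard-bounded to \[30, 2106\], and 5 unconfirmed variants concentrated in
#' the low-QUAL / low-DP region: every unconfirmed variant has QUAL < 100 and
#' DP < 15, so it lands in the LQ bin of both the QUAL >= 100 and the
#' DP >= 15 & AF >= 0.25 policies by construction. Exactly
#' `n_lowqual_confirmed` confirmed variants also sit below QUAL 100, so the
#' QUAL >= 100 bin holds 21 variants (16 confirmed + 5 unconfirmed) as
#' published, and secondary-caller flags on that low-QUAL subset default to
#' the published consensus counts (11/16 confirmed re-called, 2/5 unconfirmed
#' re-called).
#'
#' Distribution families are package choices (the source study published only
#' means, ranges and bin counts): DP is a rounded truncated normal; QUAL for
#' ordinary confirmed variants is `qual_per_dp * DP` plus Gaussian noise,
#' clipped to \[100, 2106\]; allele fractions are exact read ratios
#' `alt_reads / DP` with alt reads drawn binomially from a heterozygous
#' (p ~ Beta centred 0.5) or homozygous (p near 1) component.
#'
#' @param n_total cohort size.
#' @param n_unconfirmed number of Sanger-unconfirmed variants.
#' @param snv_fraction fraction of SNVs.
#' @param exonic_fraction_snv,exonic_fraction_indel exonic fractions per class.
#' @param dp_mean,dp_sd,dp_range depth model (truncated normal, integer).
#' @param qual_per_dp,qual_sd,qual_range QUAL model for confirmed variants.
#' @param lowqual_threshold QUAL boundary of the "low-QUAL" component.
#' @param n_lowqual_confirmed confirmed variants forced below the boundary.
#' @param hom_fraction fraction of homozygous-like allele fractions.
#' @param unconfirmed_dp_range depth range for unconfirmed variants
#'   (upper bound must stay below 15 so they fail `DP >= 15`).
#' @param n_lowqual_confirmed_called,n_unconfirmed_called secondary-caller
#'   re-call counts on the low-QUAL subset.
#' @param dp20_escape place one unconfirmed variant at DP in \[20, 30\] with
#'   AF < 0.2, reproducing the published single escape of the DP >= 20 policy.
#' @param seed default seed used when [generate_cohort()] is not given one.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_total = 1756L, n_unconfirmed = 5L,
                                    snv_fraction = 1555 / 1756,
                                    exonic_fraction_snv = 1374 / 1555,
                                    exonic_fraction_indel = 181 / 201,
                                    dp_mean = 33, dp_sd = 12,
                                    dp_range = c(3L, 81L),
                                    qual_per_dp = 15, qual_sd = 150,
                                    qual_range = c(30, 2106),
                                    lowqual_threshold = 100,
                                    n_lowqual_confirmed = 16L,
                                    hom_fraction = 1 / 3,
                                    unconfirmed_dp_range = c(3L, 14L),
                                    n_lowqual_confirmed_called = 11L,
                                    n_unconfirmed_called = 2L,
                                    dp20_escape = FALSE,
                                    seed = 7L) {
  cfg <- as.list(environment())
  if (cfg$n_unconfirmed > cfg$n_total)
    stop_input("n_unconfirmed (", cfg$n_unconfirmed,
               ") exceeds n_total (", cfg$n_total, ")")
  if (cfg$n_lowqual_confirmed > cfg$n_total - cfg$n_unconfirmed)
    stop_input("n_lowqual_confirmed exceeds the number of confirmed variants")
  if (cfg$n_lowqual_confirmed_called > cfg$n_lowqual_confirmed ||
      cfg$n_unconfirmed_called > cfg$n_unconfirmed)
    stop_input("secondary-call counts exceed their subsets")
  frac <- c(cfg$snv_fraction, cfg$exonic_fraction_snv, cfg$exonic_fraction_indel,
            cfg$hom_fraction)
  if (any(frac < 0 | frac > 1)) stop_input("fractions must lie in [0, 1]")
  if (cfg$unconfirmed_dp_range[2] >= 15)
    stop_input("unconfirmed_dp_range must stay below 15")
  structure(cfg, class = "synthetic_cohort_config")
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  x <- round(stats::rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  as.integer(x)
}

#' Generate a fully labeled synthetic cohort
#'
#' Deterministic for a given `(config, seed)` pair; a single integer seed
#' governs every draw. See [synthetic_cohort_config()] for the stated world
#' the defaults encode.
#'
#' @param config a [synthetic_cohort_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return labeled [variant_records], sorted by chromosome and position.
#' @export
generate_cohort <- function(config = synthetic_cohort_config(),
                            seed = config$seed) {
  if (!inherits(config, "synthetic_cohort_config"))
    stop_input("config must be a synthetic_cohort_config")
  set.seed(as.integer(seed))
  n <- config$n_total
  n_u <- config$n_unconfirmed
  n_c <- n - n_u

  confirmed <- rep(TRUE, n)
  unconf_idx <- if (n_u > 0) sample.int(n, n_u) else integer(0)
  confirmed[unconf_idx] <- FALSE

  # depth
  dp <- rtruncnorm_int(n, config$dp_mean, config$dp_sd,
                       config$dp_range[1], config$dp_range[2])
  if (n_u > 0)
    dp[unconf_idx] <- sample(seq(config$unconfirmed_dp_range[1],
                                 config$unconfirmed_dp_range[2]),
                             n_u, replace = TRUE)

  # allele fraction as an exact read ratio alt/dp
  hom <- stats::runif(n) < config$hom_fraction
  p <- ifelse(hom, stats::rbeta(n, 90, 4), stats::rbeta(n, 20, 20))
  if (n_u > 0) p[unconf_idx] <- stats::rbeta(n_u, 3, 9)  # unconfirmed skew low
  alt <- stats::rbinom(n, dp, p)
  alt <- pmin(pmax(alt, 1L), dp)
  af <- alt / dp

  # QUAL: linear in depth for ordinary confirmed variants; a distinct
  # low-QUAL component for the forced-low confirmed subset and all
  # unconfirmed variants
  qual <- config$qual_per_dp * dp + stats::rnorm(n, 0, config$qual_sd)
  qual <- pmin(pmax(qual, config$lowqual_threshold), config$qual_range[2])
  lowq_conf_idx <- sample(which(confirmed), config$n_lowqual_confirmed)
  qual[lowq_conf_idx] <- stats::runif(config$n_lowqual_confirmed,
                                      config$qual_range[1],
                                      config$lowqual_threshold - 1)
  if (n_u > 0)
    qual[unconf_idx] <- stats::runif(n_u, config$qual_range[1],
                                     config$lowqual_threshold - 1)
  qual <- round(qual, 1)

  # optional single unconfirmed escape of the DP >= 20 policy
  if (config$dp20_escape && n_u > 0) {
    esc <- unconf_idx[1]
    dp[esc] <- sample(20:30, 1)
    alt_max <- max(1L, as.integer(ceiling(0.2 * dp[esc])) - 1L)
    alt[esc] <- sample.int(alt_max, 1)
    af[esc] <- alt[esc] / dp[esc]
  }

  # class and region composition
  n_snv <- round(config$snv_fraction * n)
  is_snv <- rep(FALSE, n)
  is_snv[sample.int(n, n_snv)] <- TRUE
  region <- rep("intron", n)
  snv_ex <- sample(which(is_snv), round(config$exonic_fraction_snv * n_snv))
  region[snv_ex] <- "exon"
  ind_idx <- which(!is_snv)
  ind_ex <- sample(ind_idx, round(config$exonic_fraction_indel * length(ind_idx)))
  region[ind_ex] <- "exon"

  bases <- c("A", "C", "G", "T")
  ref <- character(n); altseq <- character(n)
  ref[is_snv] <- sample(bases, n_snv, replace = TRUE)
  altseq[is_snv] <- vapply(ref[is_snv],
                           function(b) sample(setdiff(bases, b), 1), "")
  for (i in which(!is_snv)) {
    anchor <- sample(bases, 1)
    tail <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    if (stats::runif(1) < 0.5) {        # insertion
      ref[i] <- anchor; altseq[i] <- paste0(anchor, tail)
    } else {                            # deletion
      ref[i] <- paste0(anchor, tail); altseq[i] <- anchor
    }
  }

  chroms <- c(paste0("chr", 1:22), "chrX")
  chrom <- sample(chroms, n, replace = TRUE,
                  prob = c(22:1, 10) / sum(c(22:1, 10)))
  pos <- sample.int(2e8, n)
  while (anyDuplicated(paste(chrom, pos)))
    pos[duplicated(paste(chrom, pos))] <-
      sample.int(2e8, sum(duplicated(paste(chrom, pos))))

  filt <- rep("PASS", n)
  if (n_u > 0)
    filt[unconf_idx] <- sample(c("PASS", "LowQual"), n_u, replace = TRUE)

  sec <- rep(NA, n)
  sec[lowq_conf_idx] <- FALSE
  sec[sample(lowq_conf_idx, config$n_lowqual_confirmed_called)] <- TRUE
  if (n_u > 0) {
    sec[unconf_idx] <- FALSE
    sec[sample(unconf_idx, config$n_unconfirmed_called)] <- TRUE
  }

  rec <- variant_records(chrom, pos, ref, altseq, qual, filt, dp, af, region,
                         confirmed, sec)
  ord <- order(match(rec$chrom, chroms), rec$pos)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("variant_records", "data.frame")
  rec
}

#' Write a cohort as a VCF plus label table
#'
#' Emits a plain-text VCFv4.2 (QUAL and FILTER columns, FORMAT `GT:AD:DP`
#' with `AD` alt count `round(af * dp)`) and a companion label TSV readable
#' by [read_label_table()]. Reading the VCF back through
#' [read_vcf_records()] reproduces `dp` exactly and `af` to within
#' `1 / (2 * dp)` (exactly, when `af` is an exact read ratio as
#' [generate_cohort()] produces).
#'
#' @param records [variant_records] to write.
#' @param vcf_path,labels_path output paths.
#' @param sample_name sample column name in the VCF.
#' @return invisibly, `c(vcf_path, labels_path)`.
#' @export
write_cohort <- function(records, vcf_path, labels_path,
                         sample_name = "SYNTHETIC1") {
  validate_variant_records(records)
  alt_ad <- as.integer(round(records$af * records$dp))
  ref_ad <- records$dp - alt_ad
  gt <- ifelse(!is.na(records$af) & records$af > 0.9, "1/1", "0/1")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=sangerbin-synthetic-cohort",
    "##FILTER=<ID=LowQual,Description=\"Low quality call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                sprintf("%.1f", records$qual),
                ifelse(records$filter_status == "MISSING", ".",
                       records$filter_status),
                ".", "GT:AD:DP",
                sprintf("%s:%d,%d:%d", gt, ref_ad, alt_ad, records$dp),
                sep = "\t")
  writeLines(c(hdr, body), vcf_path)
  write_label_table(records, labels_path)
  invisible(c(vcf_path, labels_path))
}
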