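# Independent brute-force oracles. These deliberately re-derive bin
# assignment and confusion statistics record-by-record with scalar code, so
# they share no path with the vectorised implementations they check.

brute_assign_one <- function(dp, af, qual, filter_status, policy) {
  for (p in policy$predicates) {
    v <- if (p$parameter == "DP") dp
    else if (p$parameter == "AF") af
    else if (p$parameter == "QUAL") qual
    else filter_status
    pass <- if (p$kind == "equals_pass") {
      !is.na(v) && v == "PASS"
    } else if (p$kind == "min_strict") {
      !is.na(v) && v > p$value
    } else {
      !is.na(v) && v >= p$value
    }
    if (!pass) return("LQ")
  }
  "HQ"
}

brute_bin_counts <- function(records, policy) {
  k <- c(hq_confirmed = 0, hq_unconfirmed = 0, lq_confirmed = 0,
         lq_unconfirmed = 0)
  for (i in seq_len(nrow(records))) {
    bin <- brute_assign_one(records$dp[i], records$af[i], records$qual[i],
                            records$filter_status[i], policy)
    slot <- paste0(tolower(bin), if (records$confirmed[i]) "_confirmed"
                   else "_unconfirmed")
    k[slot] <- k[slot] + 1
  }
  k
}

brute_metrics <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && sens + prec > 0)
    2 * sens * prec / (sens + prec) else NA_real_
  list(sensitivity = sens, precision = prec, f1 = f1)
}

brute_test1 <- function(records, policy) {
  k <- brute_bin_counts(records, policy)
  c(list(tp = unname(k["lq_unconfirmed"]), fp = unname(k["lq_confirmed"]),
         tn = unname(k["hq_confirmed"]), fn = unname(k["hq_unconfirmed"])),
    brute_metrics(k["lq_unconfirmed"], k["lq_confirmed"], k["hq_unconfirmed"]))
}

brute_test2 <- function(records, policy) {
  k <- brute_bin_counts(records, policy)
  c(list(tp = unname(k["hq_confirmed"]), fp = unname(k["hq_unconfirmed"]),
         tn = unname(k["lq_unconfirmed"]), fn = unname(k["lq_confirmed"])),
    brute_metrics(k["hq_confirmed"], k["hq_unconfirmed"], k["lq_confirmed"]))
}

# a small random labeled cohort exercising boundaries, NAs and all FILTER
# labels; quality values land on and around the catalog thresholds
random_cohort <- function(n, seed) {
  set.seed(seed)
  dp <- sample(0:45, n, replace = TRUE)
  af <- round(stats::runif(n), 2)
  af[sample.int(n, max(1, n %/% 20))] <- NA  # unmeasurable AF
  variant_records(
    chrom = sample(c("chr1", "chr2", "chrX"), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    qual = round(stats::runif(n, 0, 600), 1),
    filter_status = sample(c("PASS", "LowQual", "."), n, replace = TRUE),
    dp = dp, af = af,
    confirmed = stats::runif(n) < 0.9
  )
}

# Table-2-shaped labeled cohort: bin counts under the published baseline
# (DP>=20, AF>=0.2, FILTER=PASS, QUAL>=100; LQ 210 with 5 unconfirmed) and
# under the caller-agnostic pair (DP>=15, AF>=0.25; LQ 84 with the same 5)
# reproduce the published rows exactly by construction.
table2_cohort <- function() {
  strat <- rbind(
    data.frame(n = 1546, dp = 30, af = 0.50, qual = 500, confirmed = TRUE),
    data.frame(n = 126,  dp = 17, af = 0.50, qual = 500, confirmed = TRUE),
    data.frame(n = 79,   dp = 8,  af = 0.50, qual = 500, confirmed = TRUE),
    data.frame(n = 5,    dp = 8,  af = 0.10, qual = 50,  confirmed = FALSE))
  idx <- rep(seq_len(nrow(strat)), strat$n)
  variant_records(
    chrom = "chr1", pos = seq_along(idx), ref = "A", alt = "G",
    qual = strat$qual[idx], filter_status = "PASS",
    dp = strat$dp[idx], af = strat$af[idx], confirmed = strat$confirmed[idx])
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

mini_vcf_header <- function(samples = "S1") {
  c("##fileformat=VCFv4.2",
    "##FILTER=<ID=LowQual,Description=\"Low quality\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
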