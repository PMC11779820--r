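test_that("compute_allele_fraction handles arithmetic, limits and zero depth", {
  expect_equal(compute_allele_fraction(c(17, 16), 1), 16 / 33)
  expect_equal(compute_allele_fraction(c(0, 20), 1), 1.0)
  expect_true(is.na(compute_allele_fraction(c(0, 0), 1)))
  expect_error(compute_allele_fraction(c(-1, 5), 1), "non-negative")
  expect_error(compute_allele_fraction(c(10, 5), 2), "alt_index")
})

test_that("read_vcf_records extracts QUAL/FILTER/DP/AF and decomposes multi-allelics", {
  path <- write_mini_vcf(c(
    mini_vcf_header(),
    "chr1\t100\t.\tA\tG\t492.3\tPASS\t.\tGT:AD:DP\t0/1:17,16:33",
    "chr1\t200\t.\tC\tA,T\t80\t.\t.\tGT:AD:DP\t1/2:2,8,10:20",
    "chr2\t300\t.\tAT\tA\t50\tLowQual\t.\tGT:AD:DP\t0/1:9,3:12"))
  rec <- read_vcf_records(path)
  # decomposition: one record per ALT allele, input order preserved
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$alt, c("G", "A", "T", "A"))
  expect_equal(rec$qual, c(492.3, 80, 80, 50))
  expect_equal(rec$filter_status, c("PASS", "MISSING", "MISSING", "LowQual"))
  expect_equal(rec$dp, c(33L, 20L, 20L, 12L))
  expect_equal(rec$af, c(16 / 33, 8 / 20, 10 / 20, 3 / 12))
  expect_equal(unique(rec$dp_source), "format_DP")
  expect_equal(unique(rec$af_source), "format_AD")
  expect_true(all(is.na(rec$confirmed)))
})

test_that("AF/DP precedence falls back from AD to FORMAT AF to INFO", {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  path <- write_mini_vcf(c(
    hdr,
    "chr1\t10\t.\tA\tG\t10\tPASS\tAF=0.9;DP=44\tGT:AF\t0/1:0.33",
    "chr1\t20\t.\tA\tC\t10\tPASS\tAF=0.7;DP=55\tGT\t0/1"))
  rec <- read_vcf_records(path)
  expect_equal(rec$af, c(0.33, 0.7))
  expect_equal(rec$af_source, c("format_AF", "info_AF"))
  expect_equal(rec$dp, c(44L, 55L))
  expect_equal(unique(rec$dp_source), "info_DP")
})

test_that("sample selection works and unknown samples list what is available", {
  path <- write_mini_vcf(c(
    mini_vcf_header(c("S1", "S2")),
    "chr1\t100\t.\tA\tG\t90\tPASS\t.\tGT:AD:DP\t0/1:17,16:33\t0/1:10,5:15"))
  expect_equal(read_vcf_records(path, "S2")$dp, 15L)
  expect_equal(read_vcf_records(path, "S2")$af, 5 / 15)
  expect_equal(read_vcf_records(path)$dp, 33L)  # default: first sample
  expect_error(read_vcf_records(path, "S9"), "available: S1, S2")
})

test_that("malformed VCFs fail with the offending line number", {
  bad <- write_mini_vcf(c(mini_vcf_header(), "chr1\t100\tonly-three-fields"))
  expect_error(read_vcf_records(bad), "line 9")
  bad2 <- write_mini_vcf(c(mini_vcf_header(),
                           "chr1\tNOTPOS\t.\tA\tG\t9\tPASS\t.\tGT:AD:DP\t0/1:1,1:2"))
  expect_error(read_vcf_records(bad2), "POS")
  notvcf <- write_mini_vcf(c("just", "text"))
  expect_error(read_vcf_records(notvcf), "fileformat")
})

test_that("label tables parse booleans, de-duplicate, and reject conflicts", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tconfirmed\tsecondary_call",
               "chr1\t100\tA\tG\tyes\tno",
               "chr1\t100\tA\tG\tyes\tno",      # duplicate identical row
               "chr2\t200\tC\tT\tno\tNA",
               "chr3\t300\tG\tA\tNA\tyes"), p)
  lab <- read_label_table(p)
  expect_equal(nrow(lab), 3L)
  expect_equal(lab$confirmed, c(TRUE, FALSE, NA))
  expect_equal(lab$called_by_secondary, c(FALSE, NA, TRUE))

  writeLines(c("chrom\tpos\tref\talt\tconfirmed",
               "chr1\t100\tA\tG\tyes",
               "1\t100\tA\tG\tno"), p)   # same key after chr-prefix strip
  expect_error(read_label_table(p), "conflicting")

  writeLines(c("chrom\tpos\tref\talt\tconfirmed", "chr1\t100\tA\tG\tmaybe"), p)
  expect_error(read_label_table(p), "row")
})

test_that("label round-trip is key-equivalent", {
  rec <- random_cohort(40, seed = 11)
  p <- tempfile(fileext = ".tsv")
  write_label_table(rec, p)
  lab <- read_label_table(p)
  expect_setequal(lab$key, unique(normalize_variant_key(rec$chrom, rec$pos,
                                                        rec$ref, rec$alt)))
  p2 <- tempfile(fileext = ".tsv")
  write_label_table(lab, p2)
  expect_equal(read_label_table(p2)$key, lab$key)
})

test_that("key normalization matches padded representations; attach_labels reports the join", {
  # label written in padded "AT>GT" style must match the trimmed record
  expect_equal(normalize_variant_key("chr1", 100, "AT", "GT"),
               normalize_variant_key("1", 100, "A", "G"))
  # leading shared base: pos advances
  expect_equal(normalize_variant_key("chr1", 100, "TA", "TG"),
               normalize_variant_key("chr1", 101, "A", "G"))
  # indels keep their anchor base
  expect_equal(normalize_variant_key("chr1", 100, "ATT", "A"),
               "1:100:ATT:A")

  rec <- variant_records(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                         qual = 50, dp = 10, af = 0.5)
  p <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tconfirmed", "1\t100\tAT\tGT\tyes"), p)
  joined <- attach_labels(rec, read_label_table(p))
  expect_true(joined$records$confirmed)
  expect_equal(joined$join, list(n_matched = 1L, n_unmatched_records = 0L,
                                 n_unmatched_labels = 0L))

  none <- attach_labels(random_cohort(5, 1)[, ],
                        read_label_table(p))
  expect_equal(none$join$n_matched, 0L)
  expect_equal(none$join$n_unmatched_records, 5L)
  expect_equal(none$join$n_unmatched_labels, 1L)
})

test_that("decomposition invariant: one record per ALT allele", {
  path <- write_mini_vcf(c(
    mini_vcf_header(),
    "chr1\t1\t.\tA\tG\t9\tPASS\t.\tGT:AD:DP\t0/1:5,5:10",
    "chr1\t2\t.\tC\tA,T,G\t9\tPASS\t.\tGT:AD:DP\t1/2:1,2,3,4:10",
    "chr1\t3\t.\tG\tC,T\t9\tPASS\t.\tGT:AD:DP\t1/2:2,4,4:10"))
  rec <- read_vcf_records(path)
  expect_equal(nrow(rec), 1L + 3L + 2L)
  # per-alt AD over total AD
  expect_equal(rec$af[2:4], c(2, 3, 4) / 10)
})
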