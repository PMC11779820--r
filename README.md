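# sangerbin

Threshold policies for orthogonal confirmation of clinical sequencing
variants.

Clinical labs confirm NGS-reported variants with Sanger sequencing. Because
almost all variants confirm, current guidance lets each lab define a
*confirmation policy*: hard-filter thresholds on per-variant quality
parameters — caller-agnostic depth `DP` and alternate-allele fraction `AF`,
caller-specific `QUAL` and `FILTER` — that split variants into a
high-quality (HQ) bin exempt from confirmation and a low-quality (LQ) bin
that still gets a Sanger reaction. `sangerbin` evaluates such policies for
whole-genome data at ~30x, where panel/exome thresholds like `DP >= 20` are
too aggressive.

Given a cohort labeled with confirmation outcomes, a policy is scored as a
classifier ("the LQ bin identifies unconfirmed variants"):

- TP = unconfirmed in LQ, FP = confirmed in LQ, TN = confirmed in HQ,
  FN = unconfirmed in HQ;
- sensitivity = TP / (TP + FN) — the fraction of bad variants caught;
- precision = TP / (TP + FP) — the yield of the confirmatory testing;
- F1 = harmonic mean of the two.

The package provides: VCF quality extraction (`read_vcf_records`, with
documented AD/DP/AF precedence and multi-allelic decomposition), label
joining by normalized variant identity (`read_label_table`,
`attach_labels`), policy binning (`bin_cohort`, `builtin_policy_catalog`
with the eight published comparison policies), both confusion-test
orientations plus published-table formatting (`confusion_test1`,
`confusion_test2`, `format_report_row`), constrained threshold grid search
(`grid_search`, `best_policies`, `fragility`), consensus-caller validation
scoring (`consensus_f1`), a calibrated synthetic labeled-cohort generator
(`generate_cohort`, `write_cohort`) standing in for the restricted study
data, and a CLI (`sangerbin_cli`, wrapper in `inst/exec/sangerbin`).

## Worked example

```r
library(sangerbin)

rec <- generate_cohort(synthetic_cohort_config(), seed = 7)
concordance(rec)$concordance            # 0.9971526  (99.72% confirm)

ev <- evaluate_policies(rec, builtin_policy_catalog())
ev[7:8, c("policy", "lq_size", "lq_unconfirmed", "sensitivity", "precision")]
#>      policy lq_size lq_unconfirmed sensitivity  precision
#> 7 DP15_AF25     123              5           1 0.04065041
#> 8   QUAL100      21              5           1 0.23809524

b <- bin_cohort(rec, builtin_policy_catalog()[[8]])   # QUAL >= 100
format_report_row(confusion_test1(b), b)
#>       hq         lq sensitivity   precision          f1
#> "1735 (0)"  "21 (5)"      "100%"     "23.8%"     "0.385"

consensus_f1(rec[rec$qual < 100, ])
#> <consensus_report> n=21 (secondary-caller call predicts confirmation)
#>   tp=11 fp=2 fn=5 tn=3  precision 84.6% recall 68.8% F1 0.759
```

Reading: under `QUAL >= 100` every unconfirmed variant stays in the LQ bin
(100% sensitivity — no bad variant would be reported unconfirmed) and that
bin is only 21 variants, so 23.8% of the Sanger reactions it mandates would
catch a real discordance. The consensus report scores a secondary caller's
re-call of those 21 low-QUAL variants as a predictor of confirmation:
F1 0.76 — suggestive, not a replacement for confirmation.

Threshold search under a full-sensitivity constraint:

```r
g <- grid_search(rec, search_grid())          # DP 5..40 x AF 0.05..0.50
best_policies(g, constraint_sensitivity = 1.0)
```

## CLI

```sh
SB=$(Rscript -e 'cat(system.file("exec/sangerbin", package = "sangerbin"))')
Rscript $SB simulate --seed 7 --out-vcf cohort.vcf --out-labels labels.tsv
Rscript $SB evaluate --vcf cohort.vcf --labels labels.tsv --out-prefix report
Rscript $SB concordance --vcf cohort.vcf --labels labels.tsv
```

Subcommands: `extract`, `evaluate`, `search`, `simulate`, `consensus`,
`concordance`. Logs go to stderr, results to files/stdout; every TSV report
has a JSON twin with identical numbers. Exit codes: 0 success, 2 input
error, 3 constraint unsatisfiable.

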