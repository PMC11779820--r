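---
title: "Evaluating Sanger-confirmation policies for sequencing variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating Sanger-confirmation policies for sequencing variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangerbin)
```

## The problem

Clinical laboratories historically confirmed every NGS-reported variant with
an orthogonal method, usually Sanger sequencing. With mature pipelines the
overwhelming majority of reported variants confirm, so current guidance lets
each laboratory establish its own confirmation policy: define a set of
hard-filter thresholds on per-variant quality parameters, exempt variants
that pass all of them ("high quality", HQ), and confirm only the rest
("low quality", LQ). A good policy keeps every variant that would fail
confirmation inside the LQ bin while making that bin as small as possible,
because each LQ variant costs a Sanger reaction.

`sangerbin` implements this evaluation end to end for whole-genome data at
typical ~30x depth, where thresholds tuned on deep panels and exomes
(e.g. DP >= 20) are too aggressive.

## Quality parameters and the two test orientations

Four parameters are tested, all extracted from the VCF: `QUAL` (the caller's
Phred-like site confidence, caller-specific), `FILTER` (PASS or not,
caller-specific), `DP` (sample read depth, caller-agnostic) and `AF` (the
alternate-allele read fraction, caller-agnostic). A policy is a conjunction
of minimum thresholds (inclusive by default; strict where a published rule
says so) plus optionally `FILTER = PASS`. A record missing a tested value —
for example `AF` at zero depth — fails that predicate and goes LQ: a variant
whose quality cannot be established must be confirmed.

Binning against Sanger outcomes is scored in two orientations:

* **Test #1**, "the LQ bin identifies unconfirmed variants": TP =
  unconfirmed variants in LQ, FP = confirmed in LQ, TN = confirmed in HQ,
  FN = unconfirmed in HQ. Sensitivity is the fraction of all unconfirmed
  variants caught by the LQ bin — the safety of the policy — and precision
  is the unconfirmed fraction of the LQ bin, i.e. the yield of the
  confirmatory testing it mandates. This is the orientation that matters for
  policy selection and the one `grid_search()`/`best_policies()` optimise.
* **Test #2** is the reverse ("the HQ bin identifies confirmed variants"),
  provided for completeness via `confusion_test2()`.

F1 is the harmonic mean of precision and recall. Degenerate denominators
yield `NA` rather than a silent 0/0: sensitivity when the cohort has no
unconfirmed variants, precision when the positive bin is empty, F1 when
either input is `NA`. The one deliberate exception is consensus validation
(below), where a secondary caller that calls nothing scores F1 = 0 with a
warning — a useless validator should score zero, not vanish.

All metrics are kept at full floating precision; rounding happens only at
the formatting layer (`format_report_row()`), which rounds half-up —
percentages to one decimal (a bare `100%` when exact), F1 to three decimals
— so that every cell of the published comparison table is reproduced from
its bin counts.

## Worked example

```{r example}
rec <- generate_cohort(synthetic_cohort_config(), seed = 7)
ev <- evaluate_policies(rec, builtin_policy_catalog())
ev[, c("policy", "lq_size", "lq_unconfirmed", "sensitivity", "precision")]

best_policies(ev, constraint_sensitivity = 1.0,
              baseline = "DP20_AF20_PASS_QUAL100")
```

## The built-in policy catalog

`builtin_policy_catalog()` carries the eight policies compared in the
reference analysis, from prior panel/exome studies (Zheng, De Cario, Yohe,
Nelson, Arteche-Lopez) through the caller-agnostic WGS pair
`DP >= 15 & AF >= 0.25` to the caller-specific `QUAL >= 100`. Two encoding
decisions deserve a note:

* every threshold is inclusive except Nelson's `QUAL > 300`, encoded strict
  exactly as published; `QUAL >= 100` is encoded inclusive, the only reading
  consistent with its published notation;
* Nelson's genotype-conditional AF rule (0.3–0.6 heterozygous, > 0.9
  homozygous) is represented by its operational simplification `AF >= 0.3`,
  the form the published comparison actually evaluated; the
  genotype-conditional form is out of scope.

## VCF extraction decisions

The reference analysis states only that quality, allele fraction and depth
were extracted from VCFs, not from which fields. The package's precedence is
a design decision, chosen to be caller-agnostic:

* **AF**: sample `FORMAT/AD` arithmetic first (that ALT's depth over the
  total), then `FORMAT/VAF` or `FORMAT/AF`, then `INFO/AF`;
* **DP**: sample `FORMAT/DP` first, then `sum(AD)`, then `INFO/DP`.

The source used is recorded per record (`af_source`, `dp_source`).
Multi-allelic sites are decomposed into one record per ALT allele, each with
its own AD-derived fraction, because thresholds apply per variant. A FILTER
of `.` is treated as *not* PASS by default (`missing_filter_pass = FALSE`),
the conservative clinical reading, with a switch for pipelines that leave
FILTER unset. Label joins use a normalised identity key — shared
leading/trailing allele bases trimmed, `chr` prefix ignored — which covers
the padded representations callers emit; full left-alignment against a
reference genome is not attempted.

## The synthetic cohort: what it emulates and what it does not

The study cohort behind the reference analysis is restricted patient data,
so `generate_cohort()` produces a stand-in with the *published* statistical
structure, and its defaults are fixed by those published facts, not tuned:
1756 labeled variants, 5 of them unconfirmed (99.72% concordance); 1555
SNVs / 201 INDELs with the published exon/intron split; per-variant DP with
mean 33 hard-bounded to [3, 81]; QUAL with mean ~492 hard-bounded to
[30, 2106]; all 5 unconfirmed variants below QUAL 100 **and** below DP 15,
mirroring the published bins in which every policy except `DP >= 20` kept
zero unconfirmed variants in HQ; exactly 16 confirmed variants below QUAL
100, so the `QUAL >= 100` LQ bin is the published 21; and secondary-caller
flags on that low-QUAL subset at the published counts (11/16 confirmed
re-called, 2/5 unconfirmed re-called, giving consensus F1 0.76). The single
published escape of `DP >= 20` (one unconfirmed variant at DP >= 20) is
reproduced by the `dp20_escape` flag rather than by default.

Where the published record gives only means and ranges, the distribution
families are package choices: DP is a rounded truncated normal (sd 12);
QUAL for ordinary confirmed variants is `15 * DP` plus Gaussian noise
(sd 150) clipped to [100, 2106], a crude but adequate stand-in for the
roughly depth-proportional behaviour of a Phred-scale site score; allele
fractions are exact read ratios `alt/DP` with alt counts drawn binomially
from a heterozygous (p ~ Beta(20, 20)) or homozygous (p ~ Beta(90, 4),
about one third of records) component. Exact ratios make the VCF `AD`
round-trip reproduce `af` bit-for-bit, strictly inside the documented
`1/(2*DP)` bound.

A green calibration test therefore establishes that the pipeline reproduces
the published bin-level behaviour on a cohort with the published summary
statistics — not that it would reproduce the study's per-variant scatter,
which was never published. The generator deliberately omits read-level
realism, sequence context, and the PCR/enrichment allele-balance bias that
panel data show (the reference cohort is PCR-free WGS, where that bias is
absent).

## Threshold search

`grid_search()` evaluates minimum-threshold policies over a DP x AF (and
optionally QUAL) grid whose defaults, DP 5–40 and AF 0.05–0.50 in 0.01
steps, span all published thresholds. `best_policies()` keeps evaluations
meeting a Test #1 sensitivity floor (default 1.0) and returns the
maximal-precision subset; ties break toward the smaller LQ bin (fewer
confirmations at equal safety), then toward lower DP, AF and QUAL
thresholds (more permissive for future data). The sensitivity constraint is
evaluated on the given cohort only; `fragility()` quantifies how close
unconfirmed variants sit to each boundary — e.g. how many enter HQ when a
threshold is nudged — as the honest caveat against claiming generalisation.
No cross-validation or bootstrap machinery is provided, matching the scope
of the reference analysis.

## Known limitations

* QUAL thresholds are HaplotypeCaller-scale; the package makes no attempt
  to translate them across callers, and neither did the reference analysis.
* Identity normalisation trims but does not left-align indels; pathological
  representations in repeat regions may fail to join.
* The generator's DP/AF/QUAL joint distribution is a modelling convenience;
  only its bin-level behaviour and summary statistics are calibrated.
* With 5 unconfirmed variants, sensitivity estimates are quantised in steps
  of 20 percentage points; the package reports counts alongside percentages
  for this reason.
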