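# repdiv

TCR-β repertoire diversity, clonal expansion and cohort statistics in R.

## What problem this solves

T cell–mediated autoimmune diseases such as Graves' disease can persist
for years under anti-thyroid drugs.  One line of evidence for why comes
from T cell receptor β-chain (TCR-β) repertoire sequencing of patient
cohorts: persistent-disease patients show a *less diverse, more
clonally expanded* repertoire than newly diagnosed patients — lower
Shannon entropy, dominant V–J recombinations, more clonotypes shared
across donors ("public" clones) — and repertoire diversity correlates
negatively with the expression of inflammation and chemotaxis genes.

`repdiv` packages that entire analysis as reusable, tested R functions
for anyone running a two-arm repertoire + expression cohort:

* **Synthetic cohorts** (`cohort_config()`, `simulate_cohort()`,
  `simulate_repertoire()`, `synthesize_reads()`): germline V/J
  references with IMGT anchors, V(D)J-style clonotypes (junctional
  trimming + N-regions), Zipf clone sizes with a clonal-expansion knob,
  a shared public-clone pool, error-bearing reads, and an expression
  matrix with planted entropy-dependent genes — all reproducible from
  one seed, with truth tables for validation.
* **Annotation** (`annotate_repertoire()`, `assign_segments()`,
  `extract_cdr3()`, `merge_read_pairs()`): read-pair merging, V/J
  assignment by a k-mer-seeded banded local aligner (C++ core, scores
  +2/−2 with affine gaps −5/−2), IMGT junction extraction
  (2nd-CYS → F/W-G-X-G, inclusive), productivity flags, AIRR-style
  rearrangement tables.
* **Repertoire statistics** (`summarize_repertoire()`, `vj_usage()`,
  `public_clonotypes()`): Shannon entropy
  H = −Σ pᵢ ln pᵢ, clone- and V–J-level Gini coefficients
  G = Σᵢⱼ|xᵢ−xⱼ|/(2n²μ), highly expanded clones (frequency > 0.1%,
  strict), read-weighted V/J usage, cross-donor sharing cores and
  overlap matrices.
* **Cohort statistics** (`compare_groups()`, `chi_square_2x2()`,
  `pearson_regression()`, `expression_group_screen()`,
  `correlate_diversity_expression()`): the clinical-paper recipe —
  Kolmogorov–Smirnov-gated Student's t vs Mann–Whitney U (exact by
  enumeration for small tie-free groups), Pearson χ² without continuity
  correction, Pearson regression with Fisher-z 95% CIs, and the
  |log₂FC| > 1 & FDR < 0.05 screen with Benjamini–Hochberg adjustment.

Everything is data-frame-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(repdiv)
library(dplyr)

cfg <- cohort_config(seed = 1)        # 13 pGD-like vs 20 nGD-like samples
coh <- simulate_cohort(cfg)

obs <- coh$clonotypes |>
  filter(count > 0) |>
  group_by(sample_id, group, v_call, j_call, junction, junction_aa) |>
  summarise(count = sum(count), .groups = "drop") |>
  mutate(frequency = count / sum(count), .by = sample_id)

summaries <- summarize_repertoire(obs)
compare_groups(summaries$entropy[summaries$group == "pGD-like"],
               summaries$entropy[summaries$group == "nGD-like"],
               variable = "entropy")
#> <repdiv_comparison> entropy: 5.09±0.4108 vs 5.6±0.01048, t test, p = 3.804e-06

correlate_diversity_expression(
  summaries[summaries$group == "pGD-like", ],
  coh$expression, c("FASLG", "IL18R1", "CCL24", "CCL14")) |>
  select(gene_id, n, r, ci_low, ci_high, p_value)
#> # A tibble: 4 × 6
#>   gene_id     n      r ci_low ci_high  p_value
#> 1 IL18R1     13 -0.847 -0.953  -0.554 0.000262
#> 2 CCL14      13 -0.824 -0.946  -0.500 0.000531
#> 3 CCL24      13 -0.793 -0.935  -0.430 0.00122
#> 4 FASLG      13 -0.788 -0.934  -0.420 0.00136
```

The persistent-like arm has lower repertoire entropy (5.09 vs 5.60
nats, p ≈ 4 × 10⁻⁶), and the four planted genes are recovered with
strong negative entropy–expression correlations — the qualitative
pattern the analysis is designed to detect.  Public-clone cores for the
same cohort: 2,596 (pGD-like) vs 1,806 (nGD-like) shared amino-acid
junctions.

`public_clonotypes()`, `plot_diversity()`, `plot_segment_usage()` and
`autoplot()` on a correlation fit cover the sharing summaries and the
standard figures.

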