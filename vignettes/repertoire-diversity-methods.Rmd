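---
title: "Models and methods behind repdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repdiv)
library(dplyr)
```

# Scope

`repdiv` analyses T cell receptor beta-chain (TCR-beta) repertoires in
two-arm patient cohorts of the kind used to contrast persistent with
newly diagnosed autoimmune thyroid disease: one arm with long-standing,
treatment-refractory disease ("pGD-like") and one newly diagnosed arm
("nGD-like").  The scientific questions it serves are (i) whether the
persistent arm carries a more clonally expanded, less diverse TCR
repertoire, (ii) whether clonotypes are shared across donors ("public"
clones) more often in that arm, and (iii) whether repertoire diversity
co-varies with the expression of inflammation- and chemotaxis-related
genes.

Because raw patient sequencing data cannot ship with a package, the
first-class entry point is a synthetic cohort generator whose defaults
encode the study design the package emulates; every downstream stage is
developed and tested against the generator's known truth.

# The repertoire model

## Clone-size law

A sample's repertoire holds `clones_per_sample` clonotypes.  Background
clone frequencies follow a Zipf law with exponent `zipf_alpha`
(frequency of the rank-\(i\) clone proportional to \(i^{-\alpha}\)),
the standard single-parameter power-law model of repertoire clone
sizes; `zipf_alpha = 0` is the uniform limit.  On top of the
background, `n_expanded` clones evenly share a total frequency mass
`expanded_mass`, so clonal expansion is a single knob: mass 0 leaves
the background untouched, mass 0.3 concentrates 30% of all reads on a
handful of clones.

Within a cohort arm, each sample draws its own expanded mass uniformly
on \((0, 2\bar m)\), where \(\bar m\) is the arm's configured mean.
This matters: with one fixed mass per arm, every same-arm sample would
have an *identical* true frequency vector, and per-sample diversity
would differ only through multinomial counting noise (about 0.01 nats
at 50,000 reads).  Real patients vary; the uniform draw gives each arm
a realistic spread of diversities and makes diversity-expression
correlations estimable at all.

## Recombination and junctions

Each clonotype is built like a V(D)J rearrangement: a germline V
segment whose 3' end is exonuclease-trimmed by 0-6 nt (never into the
conserved 2nd-CYS anchor codon), an untemplated N-region of 0-12 nt
with uniform base composition, and a germline J segment trimmed by 0-6
nt at its 5' end (never into the F/W anchor).  The junction (CDR3) runs
from the first base of the V cysteine codon through the last base of
the J phenylalanine/tryptophan codon, inclusive — the IMGT convention.
Junctional trimming is included because without it every zero-N-region
clone of a given V-J pair has a byte-identical junction, which floods
cross-donor sharing statistics with artefactual "public" clones; with
trimming, chance junction collisions still occur (as convergent
recombination does in real repertoires) but no longer drown the
planted public-pool signal.

No D segment is modelled: the analysis reports V and J usage only, and
the D contribution is absorbed into the N-region.  Rearrangements are
not forced in frame; about one third of simulated junctions are
productive, mirroring the nonproductive fraction real rearrangement
produces, and downstream statistics exclude nonproductive clonotypes by
default (a `keep_nonproductive` flag retains them).

## Public clones

A configurable pool of `public_pool_size` pre-built rearrangements is
shared by all samples of a cohort; each clone independently takes its
identity from the pool with probability `public_prob` (per arm).  With
the defaults (pool 5,000, probabilities 0.3 vs 0.05), the
persistent-like arm shows a core of roughly 2,500 shared amino-acid
junctions against roughly 2,000 in the larger newly diagnosed arm — the
qualitative ordering reported for persistent disease, with chance
convergent sharing providing the baseline in both arms.

## Reads and errors

Sequencing reads are drawn multinomially from the true clone
frequencies; each base is substituted independently with probability
`error_rate`.  Read identifiers encode the generating clone so the
annotation stage can be scored against truth.  No PCR bias, chimeras,
indels or quality decay are modelled, and default read depth (50,000
per sample) is a choice, not an estimate: published depth for this
assay class varies widely and the tests hold at this scale.

## The expression matrix

For `planted_genes`, per-sample expression follows
\(\log_2 x_{gs} = \beta_0 + \beta_g H_s + \varepsilon_{gs}\), with
\(H_s\) the sample's true clonotype Shannon entropy in nats,
\(\beta_g\) the planted slope (default -2 for four genes named after
inflammation/chemotaxis markers), and Gaussian noise (SD 0.5).  The
intercept default (16) puts planted genes in a realistic FPKM range of
roughly 10-100, so the pseudocount used by the screening rule does not
swamp them.  All other genes are independent log-normal noise.  What
the generator does *not* emulate — library-size variation,
gene-gene correlation, count overdispersion — bounds what passing tests
show: they validate the statistical machinery, not performance on real
RNA-seq.

# Annotation

Contigs (or read pairs merged on their best 3' overlap, at least 10 nt
with at most 10% mismatches, conflicts resolved toward the
higher-quality base) are annotated in three steps:

1. **Segment assignment.** Exact 12-mers shared between contig and
   reference seed candidate segments and diagonals; the top candidates
   are extended by a banded affine local aligner (match +2, mismatch
   -2, gap open -5, gap extend -2; a length-\(L\) gap costs
   \(5 + 2(L-1)\)).  The V search is restricted 5' of the J alignment
   start.  Ties break deterministically: higher score, longer aligned
   span, then lexicographically smaller segment id.  The aligner is
   implemented in C++ and its scores are checked against a full
   dynamic-programming Smith-Waterman oracle in the test suite.
2. **Anchor projection and junction extraction.** Reference anchor
   positions are projected through the alignment onto contig
   coordinates (extrapolated past the aligned ends where no indels
   intervene); the junction is the substring between the projected
   anchors, inclusive of both codons.  If the J anchor fails to
   project, the region 3' of the V anchor is scanned for the first
   in-frame F/W-G-X-G motif.  A rearrangement is productive when its
   junction is in frame, stop-free, starts with C and ends with F/W.
3. **Collapse.** Identical `(v_call, j_call, junction)` rows merge with
   summed duplicate counts; identical input sequences are annotated
   once and share their result, which makes deep error-free samples
   cheap.  Order of the input stream cannot affect the result.

Quality control is deliberately minimal and transparent: contigs with
mean Phred below 20 or a run of five or more N's are dropped and
counted in the log.  All coordinates in the package are 1-based and
inclusive, the R and Bioconductor convention; the anchor sidecar TSV
stores 1-based positions too.

# Diversity and sharing statistics

* **Shannon entropy** \(H = -\sum_i p_i \ln p_i\), in nats.  The
  logarithm base is a display choice (a `base` argument offers bits);
  all between-group comparisons are invariant to it.
* **Gini coefficient** \(G = \sum_{ij} |x_i - x_j| / (2 n^2 \mu)\),
  computed both over clonotype frequencies (`gini_clone`) and over V-J
  pair read frequencies (`gini_vj`); the latter is what "V-J evenness"
  refers to in repertoire figures.  Both are reported because the
  phrase is ambiguous in the literature.
* **Highly expanded clones (HECs)**: frequency strictly greater than
  0.1% — "more than" read literally, so exactly 0.001 does not
  qualify.
* **V/J usage** is weighted by reads, not clonotypes, matching figure
  axes labelled "frequency of reads"; the top V-J pair and its share
  quantify dominant recombinations.
* **Public clonotypes** are keys present in at least two samples.  The
  default key is the amino-acid junction alone, since convergent
  recombination makes nucleotide-level sharing comparatively rare; a
  nucleotide mode is available.  No normalisation for unequal arm
  sizes is applied — the per-arm core counts are raw, and readers
  comparing arms of different size should keep that in mind.

# Cohort statistics

The comparison pipeline mirrors a common clinical-paper recipe
exactly, rather than a statistician's first choice, because its role
is to reproduce that analysis:

* Normality of each group is gated by a one-sample Kolmogorov-Smirnov
  test of the standardised values against the standard normal
  (asymptotic p; the Lilliefors correction for estimated parameters is
  documented as the stricter alternative).  Both groups p > 0.05 sends
  the comparison to a pooled-variance Student's t-test with mean ± SD
  summaries; otherwise the Mann-Whitney U test with median (range)
  summaries.  Welch's t sits behind a flag.
* The Mann-Whitney p-value is exact (full permutation null) when both
  groups have at most 10 tie-free observations, else the normal
  approximation with tie and continuity corrections.
* Categorical 2x2 tables use Pearson's chi-squared *without* continuity
  correction — the variant that reproduces the printed p-values of the
  motivating cohort table (0.376, 0.327, 0.633) from its counts.
* Diversity-expression association uses Pearson correlation with the
  t-based p-value, least-squares line, Fisher-z 95% interval for r and
  a 95% mean-response band for plotting.  Expression is used raw by
  default (`log2_expr` is available); which scale the motivating
  analyses used is typically unstated.
* The expression screen is a transparent stand-in, not a
  negative-binomial model: per-gene log2 ratio of group means with a
  pseudocount of 1, Mann-Whitney p, Benjamini-Hochberg adjustment, and
  the significance rule |log2FC| > 1 and FDR < 0.05.  It applies the
  threshold rule faithfully; it does not claim to reproduce a DESeq2
  fit.

Degenerate inputs error early and explicitly: constant vectors for the
KS gate and correlation, empty margins for the chi-squared table,
all-zero frequency vectors, fewer than three samples per group.  Genes
missing from the expression matrix during correlation are reported and
skipped, not fatal.  Fully tied genes in the screen get p = 1.

# Problem sizes used by the checks

The test suite regenerates everything it needs: oracle equivalence on
1,000 random frequency vectors; exact Mann-Whitney against full
enumeration for all group sizes up to 7; annotation identity on one
error-free sample of 2,000 clonotypes at 50,000 reads (uniform clone
sizes, where every clone's expected depth is 25 reads and exact
recovery is a meaningful demand; under a Zipf(1) tail the rarest
clones receive no reads at this depth and *no* annotator could return
them); 100 simulated cohorts at the study's 13-vs-20 design for the
group-contrast checks; 2,000 replicates for type-I error and Fisher-z
coverage calibration.  V/J call accuracy on error-bearing reads is
checked on 10,000 reads at a 0.005 per-base error rate.

# A short worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1)
coh <- simulate_cohort(cfg)

obs <- coh$clonotypes |>
  filter(count > 0) |>
  mutate(frequency = count / sum(count), .by = sample_id)

summaries <- summarize_repertoire(obs)
tidy(compare_groups(summaries$entropy[summaries$group == "pGD-like"],
                    summaries$entropy[summaries$group == "nGD-like"],
                    variable = "entropy"))

corr <- correlate_diversity_expression(
  summaries[summaries$group == "pGD-like", ],
  coh$expression, c("FASLG", "IL18R1", "CCL24", "CCL14"))
autoplot(corr$fit[[1]])
```

# Known limitations

* The generator's repertoires are far smaller than patient repertoires
  (thousands, not hundreds of thousands, of clonotypes); absolute
  values of richness, HEC counts and public-clone cores scale with
  that choice, while the group *contrasts* are designed to be
  scale-stable.
* No allele-level segment calls, no TCR-alpha chain, no
  somatic-hypermutation modelling, no chimera or indel errors.
* The KS normality gate with estimated parameters is anti-conservative;
  it is retained because reproducing the downstream recipe is the
  point.
* Public-clone counting applies no correction for unequal group sizes.
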