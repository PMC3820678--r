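---
title: "Combinatorial promoter occupancy analysis: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial promoter occupancy analysis: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During calcium-induced differentiation, mouse keratinocytes remodel their
transcriptional program. The bZIP factors CREB, C/EBP&beta; and c-Jun bind
overlapping but distinct sets of promoters, and the *combination* of
factors bound at a promoter — rather than any single factor — correlates
with whether RNA polymerase II (RNAP) occupancy, H3K9 acetylation and mRNA
output are induced, repressed or unchanged by differentiation. `combichip`
implements that analysis as a reproducible pipeline over promoter-array
(ChIP-chip) enrichment tracks, with a synthetic data generator that lets
every stage be validated without access to the original arrays.

## The model and procedure

**Promoter universe.** Each promoter is a strand-aware 1500-bp window,
−1000..+500 relative to the TSS. Coordinates are 0-based half-open; on the
minus strand a relative position $r$ maps to genomic $t - r$ for TSS $t$.
Three exclusion rules define the analysis universe: sex-chromosome
promoters; promoters whose sequence contains an unsequenced (N) run
strictly longer than 150 bp; and promoters carrying an exact 150-bp
stretch of sequence (either strand) shared with 10 or more other
promoters. The two length rules are worded differently ("larger than
150 bp" vs "&ge;150 bp identical regions") and are implemented literally:
a strict `> 150` N-run test, and any shared exact 150-mer for duplication.
Exclusion sets may overlap; a promoter is removed once.

**Binding.** Binding of a factor at a promoter is the arithmetic mean of
the log2 IP/input values of all probes inside the region, averaged over
replicates (in log space; missing replicates are skipped). A promoter is
*bound* when this mean strictly exceeds the factor's threshold: CREB 0.4,
C/EBP&beta; 0.4, C/EBP&alpha; 0.36, c-Jun 0.36, RNAP 0.4 (log2 units, so
0.4 &asymp; 1.3-fold enrichment).

**Differential calls.** RNAP is *induced* when its differentiated-state
binding exceeds 0.4 *and* the gain over the undifferentiated state exceeds
0.3; H3K9ac uses 0.4/0.36. Only induction rules are printed in the source
study; repression is the mirror image (undifferentiated value above the
level, loss above the delta), a symmetric decision also used for the
reported repressed counts. mRNA is induced/repressed when the log2 fold
change exceeds &plusmn;0.5 (a 1.4-fold change — the study states both
phrasings of the same cutoff). All inequalities are strict.

**Patterns and enrichment.** Promoters are classified into the $2^3$
occupancy patterns of the ordered triple (CREB, C/EBP&beta;, c-Jun) —
or the C/EBP&alpha; variant — using differentiated-condition calls by
default. For a pattern group and a status, the *enrichment ratio* is the
group's status fraction divided by the universe-wide status rate ("expected
by chance"). Significance uses the chi-square goodness of fit
$\sum_i (o_i - e_i)^2/e_i$ on the (status, non-status) split against the
chance split, with $k-1$ degrees of freedom — the semantics of a
spreadsheet CHITEST on observed vs expected counts. Group comparisons of
continuous quantities use a two-sample t test, pooled variance by default
(spreadsheet TTEST type 2; the study does not state the type, so Welch is
available via `var_equal = FALSE`). Distribution summaries use 15/50/85
percentiles with linear-interpolation (type 7) quantiles. Raw per-group
p-values are reported by default, matching the source analysis; a
Benjamini–Hochberg column is available via `p_adjust = TRUE`.

**Methylation.** MeDIP enrichment is reduced to a binary methylation call
with a strict cutoff. The source study delegates the MeDIP protocol to a
prior publication and prints no threshold, so the default (0.4, the same
scale as the binding cutoffs) is an exposed configuration value, not a
reproduced constant. Enrichment tables can be stratified by methylation
status, and the methylated fraction per pattern is itself tested against
the universe rate.

**Motifs.** Consensus sites — CRE `TGACGTCA`, C/EBP `TTGCGCAA`, TRE
`TGA(C/G)TCA` — and the printed composite motifs are compiled from IUPAC
letters, `(X/Y)` alternations and `n` wildcards into per-position base
sets, and scanned over the −500..0 window on both strands. A hit must lie
fully inside the window; sequence `N` never matches, even a wildcard
position; forward and reverse hits at one offset (palindromes) are
reported once. Combination statistics are driven by motif *presence*, not
site counts. "Containing only" combinations are implemented as an
`exclusive` flag (default on): a promoter counts for a combination when it
has every motif of the combination and none of the other consensus
motifs. Colocalization ratios normalise the within-group co-occurrence
rate by the all-promoter rate. Motif discovery is out of scope; the motif
set is a plain-text config preloaded with every printed motif, including
*both* printed variants of the long C/EBP–c-Jun composite
(`CCCACCATGCTTTGGTCA` / `CCCACCATGCTTTTGGTCA`), which differ by one T in
the source and are shipped unreconciled.

## The synthetic world

`synthetic_config()` states the world once; `generate_dataset()` is a pure
function of it (mandatory seed; byte-identical bundles per seed).

* ~20,000 promoters, 15 probes per 1500-bp region, positions uniform and
  shared across tracks (a fixed array design); probe values are the
  promoter's true mean plus Gaussian noise, SD 0.25 log2 units.
* Bound promoters have true mean 0.8 vs baseline 0 — with two replicates
  the mean's standard error is ~0.046, so calls at the 0.36–0.4 thresholds
  are nearly always correct, which is what the >95% recovery criterion
  establishes.
* Pattern prevalences loosely mirror the published Euler counts (CREB the
  most common single factor; 55% of promoters bound by none).
* Per-pattern induction probabilities were calibrated **once** so the
  prevalence-weighted universe rate is 0.0400 while the
  C/EBP&beta;+c-Jun (no CREB) group is 0.20: the planted enrichment ratio
  is exactly 5.0, the study's headline quantity (797/20,328 &asymp; 3.9%
  chance rate; "five times more than expected"). Differential promoters
  get their active-condition mean shifted to level+delta+0.1, clearing
  thresholds with margin; "unchanged" promoters can be constitutively
  RNAP-bound, with higher probability when CREB is bound, mimicking the
  observed high constitutive RNAP on CREB promoters.
* Methylation probability is 0.10 given CREB binding vs 0.45 otherwise
  (CREB-depleted methylation); consensus motifs are planted with
  probability 0.6 per bound factor at recorded offsets, in disjoint zones
  of the −500..0 window so plants never overwrite each other.
* Decoys exercise the filters: 1% sex-chromosome promoters, 0.5% with a
  200-bp N run, and 12 promoters sharing an identical 150-bp block (12 >
  the 10-other threshold, so all are flagged).

What the generator does **not** emulate: realistic base composition and
CpG islands, probe-specific effects and cross-hybridization, dye bias,
spatially varying probe density, correlated noise between factors, or the
long-tailed enrichment distributions of real arrays. A green recovery test
therefore establishes that the pipeline's arithmetic and decision rules
are correct under the stated statistical structure — not that the original
biological counts are reproduced. The published genome-scale counts would
require the deposited arrays (GEO GSE48383) and upstream image
quantification, which are out of scope.

## Numerical choices and edge cases

* Strict `>` everywhere a threshold is compared, after the source's
  "higher than" wording; boundary values are therefore negative calls.
* Replicates are averaged after log2 transformation (the upstream order is
  unstated; promoter means are already log-scale quantities).
* A promoter with no probe in a factor's region is missing for that
  factor and silently absent from that factor's universe (counted in the
  dropped-row attributes); it is dropped from pattern assignment only if a
  pattern factor is missing.
* Chi-square requires all expected cells positive and equal totals within
  rounding; degenerate groups (empty, or universe rate 0/1) get `NA`
  statistics and are flagged rather than fabricated.
* The duplicated-window filter canonicalizes windows over strands
  (min of forward and reverse-complement hashes) so reverse-complemented
  copies count as sharing; windows containing N are skipped — unsequenced
  stretches are the N-run rule's responsibility.
* The Monte-Carlo check of the chi-square p-value runs at 1e5 events:
  at smaller totals the exact multinomial tail measurably departs from the
  asymptotic chi-square tail, which would fail the comparison for reasons
  unrelated to the implementation.
* Expression identifiers match exactly but case-insensitively; all
  matches are kept (one row can feed several promoters, several rows are
  averaged into one promoter), with source-row counts retained for audit.

## Known limitations

* The scanner reports at most one hit per offset; a non-palindromic motif
  matching both strands at the same offset (impossible for the shipped
  motifs' lengths) would be collapsed with the palindrome rule.
* Exact window duplication uses 64-bit hashing; collisions are possible in
  principle (~3e7 windows against 2^64) and are guarded only by the
  brute-force oracle tests.
* The MeDIP threshold and the perturbation (A-C/EBP, A-Fos, 5-AZA)
  repression threshold are configuration values without printed
  counterparts in the source; conclusions that depend on them should be
  checked for robustness.
* Percentile tables use the whole pattern group; the source figures
  sometimes restrict to induced promoters — compose `group_percentiles()`
  with a status filter to reproduce those variants.
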