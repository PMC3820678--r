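# combichip

Combinatorial transcription-factor occupancy analysis of promoters from
ChIP-chip enrichment tracks, built around the keratinocyte-differentiation
setting: which *combinations* of CREB, C/EBPβ (or C/EBPα) and c-Jun bound
at a promoter predict induction or repression of RNA polymerase II
binding, H3K9 acetylation and mRNA output upon differentiation, how
promoter methylation stratifies those effects, and whether the matching
consensus DNA motifs co-occur in the bound promoters.

The package is aimed at regulatory-genomics analysts who have (or want to
simulate) probe-level log2 IP/input enrichment tracks over promoter
regions, and who need the full chain from tracks to per-pattern enrichment
statistics as plain, auditable tables.

## The statistic at the core

Each promoter is a strand-aware −1000..+500 window around its TSS. A
factor *f* is **bound** when the replicate-averaged mean probe enrichment
over the window exceeds its threshold θ_f (log2; CREB 0.4, C/EBPβ 0.4,
C/EBPα 0.36, c-Jun 0.36, RNAP 0.4). Promoters are classified into the 2³
occupancy patterns of the factor triple. For a pattern group *G* and a
differential status *s* (e.g. RNAP induced: Diff > 0.4 and
Diff − Undiff > 0.3), the enrichment over chance is

    ratio(G, s) = ( |G ∩ s| / |G| ) / ( |s| / N )

with the universe-wide rate |s|/N as the chance expectation, tested by the
chi-square goodness of fit Σ(o−e)²/e on the (s, ¬s) split (df = 1 for two
cells). Group comparisons of continuous binding use a pooled-variance
two-sample t test; distributions are summarised by 15/50/85 percentiles.

## Worked example

Everything below is computed from a seeded synthetic bundle — no
downloads. The generator plants a known truth: a 0.8 log2 binding effect
(probe noise SD 0.25), an induction probability of 0.20 in the
C/EBPβ+c-Jun (no CREB) group against a 0.04 universe rate (a planted
five-fold enrichment), and methylation depleted on CREB-bound promoters.

```r
library(combichip)

cfg <- synthetic_config(n_promoters = 2000, seed = 1)
gen <- generate_dataset(cfg)
res <- analyze_bundle(gen$bundle)

unlist(res$filter_report[1:5])
#>       n_input         n_excluded_sex n_excluded_unsequenced
#>          2000                     20                     10
#> n_excluded_duplicated          n_retained
#>            12                    1958
```

20 sex-chromosome decoys, 10 long-N-run decoys and the 12 promoters
sharing an identical 150-bp block are excluded; 1958 promoters remain.

```r
res$enrichment_rnap[status == "induced",
                    .(label, n_group, n_status,
                      ratio = round(enrichment_ratio, 2), p = signif(p, 2))]
#>              label n_group n_status ratio       p
#> 1:            none    1034       30  0.59 2.9e-03
#> 2:            CREB     237        2  0.17 3.8e-03
#> 3:           CEBPB     169       27  3.26 2.6e-11
#> 4:            CJUN      95        4  0.86 7.5e-01
#> 5:      CREB+CEBPB      93        5  1.10 8.3e-01
#> 6:       CREB+CJUN      97        3  0.63 4.1e-01
#> 7:      CEBPB+CJUN     115       18  3.19 9.4e-08
#> 8: CREB+CEBPB+CJUN     118        7  1.21 6.0e-01
```

The C/EBPβ-containing groups without CREB are strongly enriched for RNAP
induction (ratios 3.2–3.3, p < 1e-7), CREB-bound groups are at or below
chance — the planted structure. At this demonstration size (115 promoters
in the key group) the ratio estimate carries binomial noise; at the
acceptance scale (n = 20,000, run in the test suite) the same pipeline
recovers 5.24 against the planted 5.0, inside the 95% CI.

```r
res$methylation_by_pattern[status == "methylated" & label == "CREB",
                           .(label, fraction = round(fraction, 3),
                             expected = round(expected_fraction, 3),
                             p = signif(p, 2))]
#>    label fraction expected       p
#> 1:  CREB    0.105     0.38 3.1e-18
```

CREB-bound promoters are methylated at 10.5% against a 38% universe rate:
the planted methylation depletion, detected at p ≈ 3e-18.

## Command line

```sh
Rscript inst/scripts/combichip simulate --n 20000 --seed 1 --outdir bundle/
Rscript inst/scripts/combichip run-all --bundle bundle/ --outdir reports/
```

`run-all` writes the filter report (JSON), binding/differential call
tables, Euler counts, per-pattern enrichment tables (overall and
methylation-stratified), RNAP percentile summaries, motif combination and
colocalization tables, and a machine-readable `summary.json`.

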