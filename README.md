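# slimmi — mutual-information discovery of short linear protein motifs

slimmi discovers short, degenerate amino-acid motifs (SLiMs, e.g.
`SP.[RK]`) whose presence or absence across a proteome is maximally
informative about a per-protein behavior profile: interaction-partner
status, sub-cellular localization classes, or quantitative measurements
such as half-life or abundance split into equally populated bins. It is
aimed at anyone with a FASTA proteome and a per-protein measurement table
who wants candidate regulatory elements with honest, non-parametric
statistics attached.

## The method in brief

For a motif *M* (fixed-width pattern of allowed residue sets) and a
behavior profile *B* (class per protein), slimmi scores the plug-in mutual
information between the binary motif profile and *B*:

    I(M;B) = sum_{m,b} p(m,b) log2[ p(m,b) / (p(m) p(b)) ]   [bits]

Discovery is two-step: (1) every abundant exact k-mer is scored as a seed;
(2) seeds are greedily refined — single-residue set additions/removals and
interior wildcards — accepting only strict MI gains. A motif is reported
only if it beats **all** `n_rand` label-shuffled MI values (default
10,000), survives a fresh re-test after refinement, scores at least 6/10 on
a jackknife robustness score, and still carries conditional information
given every previously accepted motif. Reported motifs are then
characterized: per-class hypergeometric enrichment (signed -log10 p
heatmap with Bonferroni flags), positional bias along the normalized
sequence, motif-motif co-occurrence/co-localization, domain co-occurrence
and overlap z-scores, disorder scores, and similarity to a known-motif
catalog.

A seeded synthetic-data module generates proteomes with planted motifs,
pairs, domains, and quantitative couplings, with exact ground truth — every
statistic in the package is validated against it.

## Worked example

Simulate a kinase-interactor-style dataset (2,000 proteins, a 250-protein
target class, `SP.[RK]` planted at 70% penetrance), then rediscover the
motif:

```r
library(slimmi)

sim <- run_simulate("demo_data", n = 2000, n_target = 250,
                    motif = "SP.[RK]", penetrance = 0.7, seed = 101)

cfg <- discovery_config(k_values = 4, n_rand = 1000, seed = 101)
res <- run_discover(file.path("demo_data", "proteome.fasta"),
                    file.path("demo_data", "behavior.tsv"),
                    "demo_out", config = cfg, seed = 101)
res
#> <slim_result_set> 4 motif(s)
#>   SP.[KR]        MI = 0.1494  z =  305.8  p = 0.000999  robustness = 10/10  carriers = 312
#>   [AIPQ][CFNS][PR][KRT] MI = 0.0154  z =   29.2  p = 0.000999  robustness = 10/10  carriers = 470
#>   [FV]M[AGKMQ][HKN] MI = 0.0131  z =   25.4  p = 0.000999  robustness = 10/10  carriers = 143
#>   [NRTY][APR][EI][FP] MI = 0.0097  z =   17.0  p = 0.000999  robustness = 9/10  carriers = 222
```

The top motif is the planted pattern: its MI (0.15 bits) is ~300 null
standard deviations above the shuffled-label mean, its empirical p is the
minimum attainable at 1,000 shuffles (1/1001), it stays significant in all
10 jackknife trials, and its 312 carriers are the planted target-class
proteins plus the pattern's chance matches elsewhere. `demo_out/` contains
`motifs.tsv`, the signed per-class enrichment heatmap (`heatmap.tsv`),
instance coordinates, per-motif PWMs, positional histograms, and the
interaction map. The remaining rows show what marginal motifs look like —
MI an order of magnitude lower, barely above the null maximum. They appear
here because this quick demo tests ~5,000 seeds against only 1,000
shuffles; at the default `n_rand = 10000` (the configuration the
specificity control is calibrated for) they vanish, at the cost of a
10-fold longer gate (see the methods vignette).

A shell entry point with `simulate` / `discover` / `characterize`
subcommands is installed at:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "slimmi.R", package = "slimmi"))') \
  discover --fasta proteome.fasta --behavior behavior.tsv \
  --out results --seed 7 --k 3,4,5 --nrand 10000
```

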