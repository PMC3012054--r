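Package: slimmi
Type: Package
Title: Mutual-Information Discovery of Short Linear Protein Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers short, degenerate amino-acid motifs (SLiMs) whose
    presence or absence across a proteome is maximally informative, in the
    mutual-information sense, about a per-protein behavior profile such as
    interaction-partner status, sub-cellular localization, or quantile-binned
    quantitative measurements (half-life, abundance). Abundant exact k-mers
    are scored as seeds and greedily refined into degenerate patterns; motif
    significance uses strict non-parametric randomization tests (a motif must
    beat every shuffled-profile information value), with jackknife robustness
    scores and conditional-information redundancy filtering. Reported motifs
    are characterized by per-class hypergeometric enrichment, positional bias
    along the normalized sequence, motif-motif co-occurrence and
    co-localization, domain co-occurrence and overlap z-scores, flat term
    enrichment, disorder scoring, and similarity to known-motif catalogs. A
    synthetic proteome generator with planted ground truth makes every
    statistic testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
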