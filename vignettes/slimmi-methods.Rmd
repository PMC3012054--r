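---
title: "slimmi: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slimmi: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short linear motifs (SLiMs) are degenerate amino-acid patterns of roughly
2-10 residues that mediate localization, post-translational modification,
degradation, and protein-protein interaction. Because they are short and
degenerate, they cannot be found by alignment; because proteome-scale
behavior measurements (interaction partners, compartments, half-lives,
abundances) now exist for thousands of proteins at once, a discovery method
should exploit the *whole* measurement profile rather than a small
foreground set against a background model.

slimmi frames discovery information-theoretically. A *motif* is a
fixed-width sequence of allowed residue sets, written in the usual dialect:
`SP.[RK]` allows only S at position 1, P at position 2, any canonical
residue at position 3, and R or K at position 4. Its *motif profile* is the
binary vector over the proteome recording whether each protein contains at
least one exact match. The *behavior profile* assigns each protein one of C
classes — either given discrete labels, or equally populated bins of a
quantitative measurement. The score of a motif is the plug-in mutual
information

$$ I(M; B) \;=\; \sum_{m \in \{0,1\}} \sum_{b=1}^{C}
   \hat p(m,b)\, \log_2 \frac{\hat p(m,b)}{\hat p(m)\,\hat p(b)} $$

in bits, where the probabilities are empirical frequencies over the
analysis universe. MI handles binary, multi-class, and discretized
quantitative behaviors uniformly, and detects under-representation as
readily as over-representation without any explicit background model.

## Discovery: seeds, then greedy degeneracy

Discovery is two-step. First, every exact k-mer (defaults k = 3, 4, 5)
occurring in at least `min_carrier_proteins` distinct proteins (default 10)
is scored by MI — a coarse but exhaustive pass over motif space. Second,
seeds are taken in rank order and greedily refined: at each position, the
algorithm proposes adding any single residue to the allowed set (while the
set stays within `max_degeneracy_per_position`, default 5), removing any
residue, or replacing an interior set with the full wildcard; the proposal
with the largest strict MI gain (more than 1e-12 bits, guarding against
floating-point ties) is accepted, and passes repeat until nothing improves
(at most `max_refine_passes`). Width is fixed at seed width — multi-width
motifs come from iterating k, not from growing patterns — and terminal
positions never become wildcards, since a terminal wildcard changes no
carrier set and would only create duplicate motifs with shifted instance
offsets. Proposal order is fixed (positions left to right, residues
alphabetical), so the greedy search is exactly reproducible.

Degenerate sets only ever grow or shrink by one residue per accepted
proposal, which makes the MI trajectory across accepted proposals strictly
increasing — a property the test suite checks on random data.

## Significance: the strict randomization gate

A motif is deemed significant only if its observed MI exceeds **every one
of** `n_rand` MI values computed against independently shuffled behavior
profiles (default 10,000). Seeds must pass this gate before refinement and
refined motifs are re-tested against a fresh null (strictly more
conservative than gating only once). Alongside the pass/fail decision the
package reports an add-one empirical p-value, `(1 + #{null >= observed}) /
(1 + n_rand)`, which is never zero, and a z-score computed from the same
null sample, with no parametric assumption.

Because the gate is an order statistic, its family-wise behavior is
transparent: testing S seeds at strictness `n_rand` admits about
`S / (n_rand + 1)` false seeds under a null dataset. This is why the
default is 10,000 shuffles: a typical proteome-scale run enumerates a few
thousand abundant k-mers, so the expected number of false seeds per run
stays below one. Reducing `n_rand` to 1,000 while testing ~5,000 seeds
*necessarily* admits several false motifs per run regardless of any
downstream filter; users who lower `n_rand` for speed should read the
reported motif count on label-shuffled data accordingly. The label-shuffle
control is built into the test suite and the acceptance script.

Two further guards follow discovery:

* **Robustness (0-10).** Ten jackknife trials each keep a random two-thirds
  of the universe and re-run the strict test with 1,000 shuffles; the score
  is the number of passing trials. Motifs below `robust_floor` (default
  6/10) are reported in `attr(results, "below_floor")` rather than in the
  main list — visible, but not presented as discoveries.
* **Redundancy.** A candidate is kept only if a conditional-information
  test passes against every already-accepted motif: the statistic is
  `sum_g p(g) * MI(candidate; behavior | accepted = g)` with the null built
  by shuffling behavior labels *within* the accepted motif's presence
  strata. A candidate whose information is fully explained by an accepted
  motif (in the limit, an identical profile) has conditional MI near zero
  and is dropped.

## Quantitative behaviors

Quantitative measurements are discretized into equally populated bins
(default 10): values are sorted (ties keep input order) and cut into
contiguous bins whose sizes differ by at most one, larger bins first. This
maximum-entropy discretization imposes no distributional assumption. For a
motif coupled to, say, short half-lives, the per-bin signed enrichment
scores then show a gradual transition from over-representation in the low
bins to under-representation in the high bins; the acceptance suite checks
this monotonicity (Spearman |rho| > 0.8) on synthetic data with effect 3
and unit noise.

## Characterization statistics

* **Per-class enrichment.** For each class, both hypergeometric tails of
  the carrier overlap; the signed score is `-log10(p_over)` when
  over-representation is the smaller tail and `+log10(p_under)` otherwise
  (p floored at 1e-300 to stay finite). Significance is Bonferroni
  corrected over classes x 2 tails per motif — both tails are displayed, so
  both are counted; the correction deliberately does not multiply by the
  number of reported motifs, and output metadata records the counts needed
  to do so.
* **Positional bias.** Instance positions are normalized by the number of
  valid starts, `s / (L - w + 1)` (so any width can reach the full range),
  binned into ten equal-width bins, and tested by MI between instance bin
  and host-protein class with instance-level label shuffling. The statistic
  abstains below 20 instances, where the permutation null is too coarse to
  be meaningful. Histograms split instances into "targets" (classes where
  the motif is significantly over-represented) versus all others.
* **Co-occurrence / co-localization.** Co-occurrence is MI between two
  presence profiles with a permutation null; direction (co-occurrence vs
  co-avoidance) comes from the sign of the observed joint-presence count
  against its independence expectation. Co-localization asks whether the
  *distance* between the motifs (minimum over instance pairs of
  |start_a - start_b|, per co-carrying protein) is informative of behavior:
  distances are split into three equally populated bins and tested by MI
  against host class, shuffling labels among co-carriers only. It abstains
  below 20 co-carriers.
* **Domain reports.** Per domain name, a hypergeometric co-occurrence
  p-value, plus an overlap z-score: each instance in a domain-bearing
  protein contributes an indicator of window overlap and an exact
  uniform-placement success probability `p_i` (the fraction of valid starts
  whose window would intersect the domain), giving
  `z = (sum O_i - sum p_i) / sqrt(sum p_i (1 - p_i))`. Positive z marks a
  domain signature (the motif is part of the domain); negative z marks a
  motif lying away from the domain it co-occurs with. The binomial
  placement null is checked against a Monte-Carlo repositioning oracle in
  the test suite (sign always agrees; |z| within 0.5).
* **Disorder.** The disorder score is the fraction of instances with more
  than half their residues inside disorder intervals; the majority rule is
  needed because instances and intervals rarely nest exactly, and it is
  deliberately coarse — users comparing motifs should use the companion
  percentile against all same-width k-mers, which shares the same rule.
* **Known-motif similarity.** Over all ungapped offsets with at least two
  aligned positions, the score is the best mean per-position Jaccard index
  of allowed sets, with any wildcard-involving position contributing a
  fixed 0.05 so that wildcard-heavy patterns cannot match everything. A
  catalog match requires a score of at least 0.5 by default. Full
  known/semi-novel/novel triage additionally needs biological context and
  is left to the user.

## The synthetic-data generator

Every statistic is validated against generated data with exact ground
truth. Proteomes are i.i.d. residues (default uniform over the 20 canonical
amino acids) with normal lengths (mean 400, sd 80, floor 20 — twice the
largest supported width). Planting *overwrites* sequence content at a drawn
start rather than inserting, so lengths, coordinates, and truth records stay
exact. Carriers are drawn per target-class protein with the stated
penetrance; the default recovery scenario (2,000 proteins, a 250-protein
target class, `SP.[RK]` at penetrance 0.7) mirrors a kinase-interactor
profile in which the motif is carried by ~70% of the target class. Chance
matches of the planted pattern in other proteins are recorded as
"incidental" carriers, so recovery can be scored against either the strict
(planted-only) or lenient (all-match) carrier set; with uniform 400-residue
sequences the lenient set is the correct reference, since the pattern's
background match rate (~9%) is part of what any scanner must report.

What the generator does **not** emulate: real residue composition,
homologous repeats, domain architecture, or disorder-aware placement.
Passing tests therefore demonstrate the statistics' correctness and
calibration, not performance on real proteomes, where background motif
frequencies are higher and carrier classes noisier.

## Numerical and design choices

* All randomness derives from one master seed via
  `derive_seed(master, component, index)`; identical configurations give
  byte-identical outputs.
* Permutation inner loops are compiled (Rcpp) and use R's RNG, so C++ speed
  does not break seed reproducibility. For binary presence profiles the
  permutation null is sampled by drawing the smaller presence side's labels
  without replacement — distributionally identical to a full shuffle at a
  fraction of the cost.
* Non-canonical residues (X, U, B, Z, `*`) are retained in sequences but
  match no motif position, including the wildcard: ambiguity codes should
  never create instances.
* Coordinates are 0-based half-open everywhere; instance starts satisfy
  `0 <= s <= L - w`.
* Empty behavior classes, all-zero profiles, zero-instance PWMs and
  zero-variance nulls are all explicit: the first is an error, the others
  abstain or degrade (z = 0) rather than emitting NaN.
* Problem sizes in the test suite (e.g., 2,000 x 400-residue proteomes for
  recovery and specificity, 1,000-observation calibration runs with 999
  shuffles and 2,000 repeats) were chosen as the smallest sizes at which
  the binomial/KS tolerances of the checks are meaningful.

## Known limitations

* Greedy refinement maximizes in-sample MI and will overfit a marginally
  significant seed; the strict re-test and jackknife cannot fully undo
  seed-selection bias, which is why the `n_rand >= number of seeds`
  guidance above matters.
* The conditional-information redundancy rule compares candidates to
  accepted motifs one at a time; a candidate jointly explained by two
  accepted motifs but not by either alone can slip through.
* Degeneracy per position is capped (default 5, wildcard exempt) to bound
  the search; genuinely broader biochemical classes (e.g., "any
  hydrophobic") are reachable only via the wildcard or a larger cap.
* The domain overlap null assumes instances are placed independently and
  uniformly across valid starts; clustered instances (tandem repeats)
  inflate |z|.
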