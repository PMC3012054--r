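# Post-discovery annotation of motifs: positional bias along the normalized
# sequence, motif-motif co-occurrence and co-localization, domain
# co-occurrence and overlap z-scores, flat term enrichment, disorder scoring,
# and similarity to known-motif catalogs.

instance_table <- function(profile, prot) {
  n_i <- lengths(profile$instances)
  data.frame(protein_id = rep(profile$ids, n_i),
             start = unlist(profile$instances, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Positional bias of motif instances along the normalized sequence
#'
#' Each instance's position is normalized to the number of valid starts,
#' `s / (L - w + 1)`, binned into `n_pos_bins` equal-width bins covering
#' `[0, 1]`, and the mutual information between the instance's bin and its
#' host protein's behavior class is tested against a null that shuffles
#' host-class labels across instances. The returned histograms split
#' instances into "targets" (instances in proteins of classes where the
#' motif is significantly over-represented) versus all others. With fewer
#' than 20 instances the statistic abstains (`insufficient = TRUE`).
#'
#' @param profile A `slim_profile` aligned with `behavior`.
#' @param behavior A `slim_behavior`.
#' @param prot A [proteome()].
#' @param n_pos_bins Number of position bins (default 10).
#' @param n_rand Label permutations (default 10000).
#' @param seed Integer seed.
#' @return A `slim_positional_bias`: list with `mi_bits`, `empirical_p`,
#'   `z_score`, `insufficient`, `n_instances`, `histogram_targets`,
#'   `histogram_others`, `bin_edges`.
#' @export
positional_bias <- function(profile, behavior, prot, n_pos_bins = 10L,
                            n_rand = 10000L, seed = 1L) {
  stopifnot(identical(profile$ids, behavior$ids))
  w <- profile$motif$width
  inst <- instance_table(profile, prot)
  empty <- structure(list(mi_bits = NA_real_, empirical_p = NA_real_,
                          z_score = NA_real_, insufficient = TRUE,
                          n_instances = nrow(inst),
                          histogram_targets = rep(0L, n_pos_bins),
                          histogram_others = rep(0L, n_pos_bins),
                          bin_edges = seq(0, 1, length.out = n_pos_bins + 1)),
                     class = "slim_positional_bias")
  if (nrow(inst) < 20) return(empty)
  L <- nchar(unclass(prot))[inst$protein_id]
  norm_pos <- inst$start / (L - w + 1)
  bins <- pmin(floor(norm_pos * n_pos_bins), n_pos_bins - 1L)
  cls <- behavior$class[match(inst$protein_id, behavior$ids)]
  st <- shuffle_test_discrete(bins, cls, n_rand, seed)
  enr <- class_enrichment(profile, behavior)
  target_classes <- enr$class_index[enr$significant & enr$signed_score > 0]
  is_target <- cls %in% target_classes
  structure(list(mi_bits = st$observed_mi, empirical_p = st$empirical_p,
                 z_score = st$z_score, insufficient = FALSE,
                 n_instances = nrow(inst),
                 histogram_targets = tabulate(bins[is_target] + 1L, n_pos_bins),
                 histogram_others = tabulate(bins[!is_target] + 1L, n_pos_bins),
                 bin_edges = seq(0, 1, length.out = n_pos_bins + 1)),
            class = "slim_positional_bias")
}

# permutation MI test for two general discrete vectors
shuffle_test_discrete <- function(x, y, n_rand, seed) {
  cx <- as_code(x)
  cy <- as_code(y)
  obs <- .cpp_mi_disc(cx$code, cy$code, cx$K, cy$K)
  set.seed(seed)
  null <- .cpp_perm_mi_null(cx$code, cy$code, cx$K, cy$K, as.integer(n_rand))
  new_shuffle_test(obs, null, as.integer(n_rand), seed)
}

#' Co-occurrence of two motifs across proteins
#'
#' Mutual information between the two binary presence profiles, with a
#' permutation null on the second profile. Direction is `"co-occur"` when
#' the observed joint-presence count exceeds its independence expectation,
#' `"co-avoid"` otherwise.
#'
#' @param profile_a,profile_b `slim_profile`s over the same universe.
#' @param n_rand Permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `mi_bits`, `empirical_p`, `z_score`, `passed`,
#'   `direction`, `n_joint`, `expected_joint`.
#' @export
motif_cooccurrence <- function(profile_a, profile_b, n_rand = 10000L,
                               seed = 1L) {
  stopifnot(identical(profile_a$ids, profile_b$ids))
  a <- profile_a$present
  b <- profile_b$present
  st <- shuffle_test(a, b, n_rand = n_rand, seed = seed)
  n_joint <- sum(a & b)
  expected <- sum(a) * sum(b) / length(a)
  list(mi_bits = st$observed_mi, empirical_p = st$empirical_p,
       z_score = st$z_score, passed = st$passed,
       direction = if (n_joint > expected) "co-occur" else "co-avoid",
       n_joint = n_joint, expected_joint = expected)
}

#' Co-localization: is the motif-motif distance informative of behavior?
#'
#' For each protein carrying both motifs, the distance is the minimum
#' `|start_a - start_b|` over instance pairs; distances are split into
#' `n_dist_bins` equally populated bins ([discretize_equal()]) and the MI
#' with the host protein's class is tested by shuffling class labels among
#' co-carrying proteins. Abstains with fewer than 20 co-carriers.
#'
#' @param profile_a,profile_b `slim_profile`s over the same universe.
#' @param behavior A `slim_behavior` on the same universe.
#' @param n_dist_bins Distance bins (default 3).
#' @param n_rand Permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `mi_bits`, `empirical_p`, `z_score`, `passed`,
#'   `insufficient`, `n_cocarriers`.
#' @export
motif_colocalization <- function(profile_a, profile_b, behavior,
                                 n_dist_bins = 3L, n_rand = 10000L,
                                 seed = 1L) {
  stopifnot(identical(profile_a$ids, profile_b$ids),
            identical(profile_a$ids, behavior$ids))
  both <- which(profile_a$present & profile_b$present)
  if (length(both) < 20)
    return(list(mi_bits = NA_real_, empirical_p = NA_real_,
                z_score = NA_real_, passed = FALSE, insufficient = TRUE,
                n_cocarriers = length(both)))
  dist <- vapply(both, function(i) {
    min(abs(outer(profile_a$instances[[i]], profile_b$instances[[i]], `-`)))
  }, 0)
  bins <- discretize_equal(dist, n_dist_bins)
  st <- shuffle_test_discrete(bins, behavior$class[both], n_rand, seed)
  list(mi_bits = st$observed_mi, empirical_p = st$empirical_p,
       z_score = st$z_score, passed = st$passed, insufficient = FALSE,
       n_cocarriers = length(both))
}

# number of start offsets in 0..L-w whose window [s, s+w) intersects any of
# the given (merged) intervals
overlap_start_count <- function(starts_max, w, ivs) {
  if (nrow(ivs) == 0) return(0L)
  lo <- pmax(ivs$start - w + 1L, 0L)
  hi <- pmin(ivs$end - 1L, starts_max)
  keep <- lo <= hi
  if (!any(keep)) return(0L)
  lo <- lo[keep]; hi <- hi[keep]
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  total <- 0L; cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      if (lo[i] <= cur_hi + 1L) cur_hi <- max(cur_hi, hi[i])
      else { total <- total + cur_hi - cur_lo + 1L; cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
  }
  total + cur_hi - cur_lo + 1L
}

#' Domain co-occurrence and overlap z-score per domain
#'
#' For each domain name: the co-occurrence p-value is the upper
#' hypergeometric tail of the overlap between motif carriers and
#' domain-bearing proteins; the overlap z-score compares, over all motif
#' instances in domain-bearing proteins, the number of instances whose
#' window `[s, s + w)` intersects a domain interval against a null of
#' uniform placement (each instance contributes success probability
#' `p_i` = intersecting starts / valid starts;
#' `z = (sum O_i - sum p_i) / sqrt(sum p_i (1 - p_i))`). Positive z marks a
#' domain signature (the motif is part of the domain); negative z marks a
#' motif lying away from the domain.
#'
#' @param profile A `slim_profile`.
#' @param domains A `slim_domains` annotation.
#' @param prot A [proteome()].
#' @return Data frame ranked by co-occurrence p ascending: `domain_name`,
#'   `n_domain_proteins`, `n_joint`, `cooccurrence_p`, `overlap_z` (NA when
#'   undefined), `n_instances_in_domain_proteins`.
#' @export
domain_report <- function(profile, domains, prot) {
  ids <- profile$ids
  N <- length(ids)
  K <- sum(profile$present)
  carriers <- ids[profile$present]
  lens <- nchar(unclass(prot))
  w <- profile$motif$width
  doms <- domains[domains$protein_id %in% ids, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(doms)), doms$name), function(rows) {
    d <- doms[rows, , drop = FALSE]
    dom_ids <- unique(d$protein_id)
    n_joint <- length(intersect(carriers, dom_ids))
    p_co <- hypergeom_tail(n_joint, K, length(dom_ids), N, "upper")
    O <- numeric(0); P <- numeric(0); n_inst <- 0L
    for (pid in intersect(dom_ids, carriers)) {
      starts <- profile$instances[[match(pid, ids)]]
      if (!length(starts)) next
      ivs <- d[d$protein_id == pid, , drop = FALSE]
      smax <- lens[pid] - w
      hit_s <- overlap_start_count(smax, w, ivs)
      p_i <- hit_s / (smax + 1)
      hit <- vapply(starts, function(s)
        any(s < ivs$end & s + w > ivs$start), TRUE)
      O <- c(O, as.numeric(hit))
      P <- c(P, rep(p_i, length(starts)))
      n_inst <- n_inst + length(starts)
    }
    denom <- sqrt(sum(P * (1 - P)))
    z <- if (length(O) == 0 || denom == 0) NA_real_
         else (sum(O) - sum(P)) / denom
    data.frame(domain_name = d$name[1], n_domain_proteins = length(dom_ids),
               n_joint = n_joint, cooccurrence_p = p_co, overlap_z = z,
               n_instances_in_domain_proteins = n_inst,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(domain_name = character(0), n_domain_proteins = integer(0),
               n_joint = integer(0), cooccurrence_p = numeric(0),
               overlap_z = numeric(0),
               n_instances_in_domain_proteins = integer(0))
  res <- res[order(res$cooccurrence_p, res$domain_name), ]
  rownames(res) <- NULL
  res
}

#' Flat term enrichment of a carrier set
#'
#' Upper hypergeometric tail per term with Bonferroni correction over the
#' number of terms tested, ranked by raw p ascending.
#'
#' @param carriers Character vector of protein ids (subset of `universe`).
#' @param terms A `slim_terms` map.
#' @param universe Character vector of protein ids defining the universe.
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame: `term_id`, `term_name`, `n_term`, `n_overlap`, `p`,
#'   `corrected_p`, `significant`.
#' @export
term_enrichment <- function(carriers, terms, universe, alpha = 0.05) {
  stopifnot(all(carriers %in% universe))
  N <- length(universe)
  K <- length(carriers)
  tn <- attr(terms, "term_names")
  rows <- lapply(names(terms), function(t) {
    members <- intersect(terms[[t]], universe)
    k <- length(intersect(members, carriers))
    p <- if (length(members) == 0) 1 else
      hypergeom_tail(k, K, length(members), N, "upper")
    data.frame(term_id = t,
               term_name = if (!is.null(tn) && t %in% names(tn)) tn[[t]] else t,
               n_term = length(members), n_overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$corrected_p <- pmin(res$p * length(terms), 1)
  res$significant <- res$corrected_p < alpha
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}

instance_disorder_flags <- function(inst, w, mask) {
  if (nrow(inst) == 0) return(logical(0))
  vapply(seq_len(nrow(inst)), function(i) {
    ivs <- mask[mask$protein_id == inst$protein_id[i], , drop = FALSE]
    if (nrow(ivs) == 0) return(FALSE)
    s <- inst$start[i]
    cov <- sum(pmax(0, pmin(ivs$end, s + w) - pmax(ivs$start, s)))
    cov > w / 2
  }, TRUE)
}

#' Disorder score of a motif
#'
#' The fraction of motif instances that lie in disordered regions, where an
#' instance counts as disordered when more than half of its residues fall
#' inside disorder intervals.
#'
#' @param profile A `slim_profile` with at least one instance.
#' @param mask A `slim_disorder` mask.
#' @param prot A [proteome()].
#' @return Fraction in `[0, 1]`.
#' @export
disorder_score <- function(profile, mask, prot) {
  inst <- instance_table(profile, prot)
  if (nrow(inst) == 0) stop("no motif instances; disorder score undefined")
  mean(instance_disorder_flags(inst, profile$motif$width, mask))
}

#' Percentile of a motif's disorder score among all same-width k-mers
#'
#' Computes the disorder score of every exact k-mer of the motif's width in
#' the proteome (canonical k-mers only) and returns the percentage of k-mers
#' whose score is strictly below the motif's.
#'
#' @param profile A `slim_profile` with at least one instance.
#' @param mask A `slim_disorder` mask.
#' @param prot A [proteome()].
#' @return List with `percentile` (0-100), `motif_score`, `n_kmers`.
#' @export
kmer_disorder_percentile <- function(profile, mask, prot) {
  w <- profile$motif$width
  ms <- disorder_score(profile, mask, prot)
  seqs <- unclass(prot)
  ids <- names(seqs)
  noncanon <- paste0("[^", paste(AA_CANON, collapse = ""), "]")
  per <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) character(0)
    else substring(s, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
  })
  kk <- unlist(per, use.names = FALSE)
  inst <- data.frame(
    protein_id = rep(ids, lengths(per)),
    start = unlist(lapply(lengths(per), function(m) seq_len(m) - 1L),
                   use.names = FALSE),
    stringsAsFactors = FALSE)
  ok <- !grepl(noncanon, kk)
  kk <- kk[ok]
  inst <- inst[ok, , drop = FALSE]
  flags <- instance_disorder_flags(inst, w, mask)
  scores <- tapply(flags, kk, mean)
  list(percentile = 100 * mean(scores < ms), motif_score = ms,
       n_kmers = length(scores))
}

#' Similarity between two degenerate motifs
#'
#' Over all ungapped relative offsets with at least two aligned positions,
#' the score is the maximum over offsets of the mean per-aligned-position
#' set similarity: the Jaccard index `|A n B| / |A u B|` of the allowed
#' sets, except that any aligned position involving a full wildcard
#' contributes a fixed 0.05 (so all-wildcard stretches cannot inflate the
#' score). Symmetric; equals 1 only for set-identical aligned patterns
#' without wildcards.
#'
#' @param motif_a,motif_b `slim_motif`s or pattern strings.
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' motif_similarity("SP.[RK]", "[ST]P.[RK]")
motif_similarity <- function(motif_a, motif_b) {
  if (is.character(motif_a)) motif_a <- parse_motif(motif_a)
  if (is.character(motif_b)) motif_b <- parse_motif(motif_b)
  wa <- motif_a$width
  wb <- motif_b$width
  best <- 0
  for (off in seq.int(-(wb - 2L), wa - 2L)) {
    ja <- max(1L, 1L + off):min(wa, wb + off)
    if (length(ja) < 2) next
    sims <- vapply(ja, function(a) {
      A <- motif_a$sets[[a]]
      B <- motif_b$sets[[a - off]]
      if (length(A) == 20L || length(B) == 20L) 0.05
      else length(intersect(A, B)) / length(union(A, B))
    }, 0)
    best <- max(best, mean(sims))
  }
  best
}

#' Best match of a motif in a known-motif catalog
#'
#' @param m A `slim_motif` or pattern string.
#' @param catalog A `slim_catalog` from [read_motif_catalog()] (or a data
#'   frame with `name`/`pattern` columns).
#' @param threshold Minimum similarity to call a match (default 0.5).
#' @return List with `name`, `pattern`, `context`, `score`, or `NULL` when
#'   nothing reaches the threshold.
#' @export
best_known_match <- function(m, catalog, threshold = 0.5) {
  if (is.character(m)) m <- parse_motif(m)
  if (nrow(catalog) == 0) return(NULL)
  motifs <- attr(catalog, "motifs")
  if (is.null(motifs)) motifs <- lapply(catalog$pattern, parse_motif)
  scores <- vapply(motifs, function(b) motif_similarity(m, b), 0)
  i <- which.max(scores)
  if (scores[i] < threshold) return(NULL)
  list(name = catalog$name[i], pattern = catalog$pattern[i],
       context = if ("context" %in% names(catalog)) catalog$context[i] else "",
       score = scores[i])
}
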