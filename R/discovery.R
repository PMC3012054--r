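# Two-step motif discovery: every abundant exact k-mer is scored by mutual
# information against the behavior profile, then informative seeds are
# greedily refined into degenerate motifs (single-residue set edits plus
# interior wildcards), with a strict permutation gate before and after
# refinement, a jackknife robustness score, and a conditional-information
# redundancy filter.

#' Discovery configuration
#'
#' @param k_values Seed widths to enumerate (subset of 2..10; default 3:5).
#' @param min_carrier_proteins A k-mer is "abundant" (and scored as a seed)
#'   only if it occurs in at least this many distinct proteins (default 10).
#' @param n_rand Permutations for the strict significance gate (default
#'   10000; a motif must beat every draw).
#' @param seed Master seed; all randomness derives from it via
#'   [derive_seed()].
#' @param max_refine_passes Maximum full passes of the greedy refinement.
#' @param max_degeneracy_per_position Largest non-wildcard allowed-set size a
#'   refinement proposal may create (default 5; the full wildcard is exempt).
#' @param max_motifs Stop after this many accepted motifs (default 50).
#' @param redundancy_n_rand Permutations for the conditional redundancy test.
#' @param robustness_trials,robustness_keep,robustness_n_rand Jackknife
#'   robustness parameters (defaults 10 trials, keep 2/3, 1000 permutations).
#' @param robust_floor Motifs with robustness below this (default 6/10) are
#'   excluded from the main result list and reported in
#'   `attr(result, "below_floor")` instead of being silently dropped.
#' @return A `slim_config` list.
#' @export
discovery_config <- function(k_values = 3:5, min_carrier_proteins = 10L,
                             n_rand = 10000L, seed = 1L,
                             max_refine_passes = 10L,
                             max_degeneracy_per_position = 5L,
                             max_motifs = 50L, redundancy_n_rand = 1000L,
                             robustness_trials = 10L, robustness_keep = 2 / 3,
                             robustness_n_rand = 1000L, robust_floor = 6L) {
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 2 | k_values > 10))
    stop("k_values must lie in 2..10")
  cfg <- list(k_values = k_values,
              min_carrier_proteins = as.integer(min_carrier_proteins),
              n_rand = as.integer(n_rand), seed = as.integer(seed),
              max_refine_passes = as.integer(max_refine_passes),
              max_degeneracy_per_position = as.integer(max_degeneracy_per_position),
              max_motifs = as.integer(max_motifs),
              redundancy_n_rand = as.integer(redundancy_n_rand),
              robustness_trials = as.integer(robustness_trials),
              robustness_keep = robustness_keep,
              robustness_n_rand = as.integer(robustness_n_rand),
              robust_floor = as.integer(robust_floor))
  if (any(vapply(cfg[-which(names(cfg) == "k_values")], function(v)
    any(!is.finite(as.numeric(v)) | as.numeric(v) < 0), TRUE)))
    stop("all configuration values must be non-negative and finite")
  structure(cfg, class = "slim_config")
}

# MI of many binary presence profiles against one class vector, vectorized:
# M is kmer x class carrier-count matrix, n_c the class sizes.
mi_presence_counts <- function(M, n_c, N) {
  m <- rowSums(M)
  p1 <- M / N
  p0 <- sweep(-M, 2, n_c, `+`) / N
  py <- n_c / N
  e1 <- outer(m / N, py)
  e0 <- outer(1 - m / N, py)
  term <- function(p, e) {
    t <- p * log2(p / e)
    t[p == 0] <- 0
    t
  }
  pmax(rowSums(term(p1, e1)) + rowSums(term(p0, e0)), 0)
}

#' Enumerate and score abundant k-mer seeds
#'
#' Every exact k-mer (canonical residues only) occurring in at least
#' `min_carrier_proteins` distinct proteins of the analysis universe is
#' scored by the mutual information between its presence profile and the
#' behavior profile.
#'
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior`.
#' @param config A [discovery_config()].
#' @return Data frame (`kmer`, `width`, `n_carriers`, `mi`) sorted by MI
#'   descending, ties broken lexicographically.
#' @export
enumerate_seeds <- function(prot, behavior, config = discovery_config()) {
  seqs <- unclass(prot)[behavior$ids]
  y <- behavior$class
  C <- length(behavior$labels)
  N <- length(seqs)
  n_c <- tabulate(y + 1L, C)
  noncanon <- paste0("[^", paste(AA_CANON, collapse = ""), "]")
  out <- list()
  for (k in config$k_values) {
    per <- lapply(seqs, function(s) {
      L <- nchar(s)
      if (L < k) character(0)
      else unique(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
    })
    kk <- unlist(per, use.names = FALSE)
    if (!length(kk)) next
    pi_ <- rep.int(seq_len(N), lengths(per))
    u <- unique(kk)
    ki <- match(kk, u)
    tot <- tabulate(ki, length(u))
    ok <- tot >= config$min_carrier_proteins & !grepl(noncanon, u)
    if (!any(ok)) next
    counts <- matrix(tabulate((ki - 1L) * C + y[pi_] + 1L, length(u) * C),
                     ncol = C, byrow = TRUE)
    mi <- mi_presence_counts(counts[ok, , drop = FALSE], n_c, N)
    out[[as.character(k)]] <- data.frame(
      kmer = u[ok], width = k, n_carriers = tot[ok], mi = mi,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(kmer = character(0), width = integer(0),
               n_carriers = integer(0), mi = numeric(0))
  res <- res[order(-res$mi, res$kmer), ]
  rownames(res) <- NULL
  res
}

#' Greedy degenerate refinement of a seed motif
#'
#' Repeats up to `max_refine_passes` full passes; at each position (left to
#' right) it proposes (a) adding any single residue to the allowed-set while
#' the resulting size stays within `max_degeneracy_per_position`, (b)
#' removing any residue from a set of size >= 2, and (c) replacing an
#' interior position's set with the full wildcard; the proposal with the
#' largest strict MI increase (> 1e-12) at that position is accepted.
#' Terminal positions never become wildcards. The MI of the returned motif
#' is therefore never below the seed's.
#'
#' @param seed A `slim_motif` or pattern string.
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior`.
#' @param config A [discovery_config()].
#' @param cache Internal presence-profile cache (an environment); a shared
#'   cache may be passed across calls on the same universe.
#' @return Refined `slim_motif`, with the accepted-MI trajectory (seed MI
#'   first) in `attr(, "mi_trajectory")`.
#' @export
refine_motif <- function(seed, prot, behavior, config = discovery_config(),
                         cache = new.env(parent = emptyenv())) {
  if (is.character(seed)) seed <- parse_motif(seed)
  seqs <- unclass(prot)[behavior$ids]
  y <- behavior$class
  C <- length(behavior$labels)
  n <- length(y)
  eps <- 1e-12
  mi_of <- function(pres) .cpp_mi_disc(as.integer(pres), y, 2L, C)
  cur <- seed
  cur_pres <- present_many(seqs, cur)
  cur_mi <- mi_of(cur_pres)
  traj <- cur_mi
  w <- cur$width
  for (pass in seq_len(config$max_refine_passes)) {
    changed <- FALSE
    for (j in seq_len(w)) {
      Sj <- cur$sets[[j]]
      if (length(Sj) == 20L) next
      props <- list()
      if (length(Sj) < config$max_degeneracy_per_position)
        for (aa in setdiff(AA_CANON, Sj)) props <- c(props, list(sort(c(Sj, aa))))
      if (length(Sj) >= 2)
        for (aa in Sj) props <- c(props, list(setdiff(Sj, aa)))
      if (j > 1 && j < w) props <- c(props, list(AA_CANON))
      if (!length(props)) next
      sup <- cur
      sup$sets[[j]] <- AA_CANON
      sup_key <- format(sup)
      sup_pres <- cache[[sup_key]]
      if (is.null(sup_pres)) {
        sup_pres <- present_many(seqs, sup)
        cache[[sup_key]] <- sup_pres
      }
      sup_idx <- which(sup_pres)
      sup_seqs <- seqs[sup_idx]
      best_mi <- cur_mi + eps
      best <- NULL
      best_pres <- NULL
      for (pset in props) {
        cand <- cur
        cand$sets[[j]] <- pset
        pres <- logical(n)
        if (length(sup_idx))
          pres[sup_idx] <- grepl(motif_regex(cand), sup_seqs, perl = TRUE)
        mi_p <- mi_of(pres)
        if (mi_p > best_mi) {
          best_mi <- mi_p
          best <- cand
          best_pres <- pres
        }
      }
      if (!is.null(best)) {
        cur <- best
        cur_pres <- best_pres
        cur_mi <- best_mi
        traj <- c(traj, cur_mi)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(cur, "mi_trajectory") <- traj
  cur
}

#' Redundancy decision for a candidate motif
#'
#' A candidate is kept only if, for every already-accepted motif, the
#' conditional-information test ([conditional_mi_test()]) passes: the
#' candidate must still be informative about the behavior within the strata
#' defined by the accepted motif's presence. Evaluated in accepted order with
#' short-circuit on the first failure.
#'
#' @param accepted List of accepted motif results (each with `$profile`).
#' @param candidate_present Logical presence profile of the candidate.
#' @param behavior A `slim_behavior`.
#' @param config A [discovery_config()].
#' @param seed Integer seed.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_redundant <- function(accepted, candidate_present, behavior,
                             config = discovery_config(), seed = config$seed) {
  for (i in seq_along(accepted)) {
    ct <- conditional_mi_test(candidate_present, behavior$class,
                              accepted[[i]]$profile$present,
                              n_rand = config$redundancy_n_rand,
                              seed = derive_seed(seed, "redundancy", i))
    if (!ct$passed) return(FALSE)
  }
  TRUE
}

#' Discover informative motifs in a proteome
#'
#' Full pipeline: [enumerate_seeds()], then seeds in rank order are gated by
#' the strict [shuffle_test()], refined ([refine_motif()]), re-tested against
#' a fresh null, scored for jackknife robustness, and passed through the
#' conditional-information redundancy filter, until `max_motifs` are accepted
#' or seeds are exhausted. Motifs whose robustness falls below
#' `robust_floor` are reported in `attr(, "below_floor")` rather than in the
#' main list. Results are sorted by MI descending and are deterministic given
#' the configuration (including its master seed).
#'
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior`.
#' @param config A [discovery_config()].
#' @return A `slim_result_set`: list of `slim_motif_result` (fields `motif`,
#'   `mi`, `test`, `robustness`, `enrichment`, `profile`, `pwm`,
#'   `seed_kmer`), with attributes `config`, `log` (gate counts), and
#'   `below_floor`.
#' @export
discover_motifs <- function(prot, behavior, config = discovery_config()) {
  seeds <- enumerate_seeds(prot, behavior, config)
  seqs <- unclass(prot)[behavior$ids]
  y <- behavior$class
  cache <- new.env(parent = emptyenv())
  accepted <- list()
  below <- list()
  log <- c(n_seeds = nrow(seeds), n_gate_passed = 0L, n_retest_passed = 0L,
           n_redundant_dropped = 0L, n_below_floor = 0L)
  master <- config$seed
  for (i in seq_len(nrow(seeds))) {
    if (length(accepted) >= config$max_motifs) break
    km <- seeds$kmer[i]
    pres0 <- grepl(km, seqs, fixed = TRUE)
    st0 <- shuffle_test(pres0, y, n_rand = config$n_rand,
                        seed = derive_seed(master, "seed_gate", i))
    if (!st0$passed) next
    log["n_gate_passed"] <- log["n_gate_passed"] + 1L
    mref <- refine_motif(km, prot, behavior, config, cache)
    prof <- build_profile(prot, mref, behavior$ids)
    st <- shuffle_test(prof$present, y, n_rand = config$n_rand,
                       seed = derive_seed(master, "refined_test", i))
    if (!st$passed) next
    log["n_retest_passed"] <- log["n_retest_passed"] + 1L
    rob <- robustness_score(mref, prot, behavior,
                            n_trials = config$robustness_trials,
                            keep_fraction = config$robustness_keep,
                            n_rand = config$robustness_n_rand,
                            seed = derive_seed(master, "robustness", i),
                            profile = prof)
    if (!filter_redundant(accepted, prof$present, behavior, config,
                          seed = derive_seed(master, "redundancy_set", i))) {
      log["n_redundant_dropped"] <- log["n_redundant_dropped"] + 1L
      next
    }
    res <- structure(list(motif = mref, mi = st$observed_mi, test = st,
                          robustness = rob,
                          enrichment = class_enrichment(prof, behavior),
                          profile = prof,
                          pwm = if (any(prof$present))
                            pwm_from_instances(prof, prot),
                          seed_kmer = km),
                     class = "slim_motif_result")
    if (rob >= config$robust_floor) {
      accepted <- c(accepted, list(res))
    } else {
      log["n_below_floor"] <- log["n_below_floor"] + 1L
      below <- c(below, list(res))
    }
  }
  ord <- order(-vapply(accepted, `[[`, 0, "mi"))
  structure(accepted[ord], class = "slim_result_set",
            config = config, log = log, below_floor = below)
}

#' @export
print.slim_result_set <- function(x, ...) {
  cat("<slim_result_set> ", length(x), " motif(s)\n", sep = "")
  for (r in x)
    cat(sprintf("  %-14s MI = %.4f  z = %6.1f  p = %.4g  robustness = %d/%d  carriers = %d\n",
                format(r$motif), r$mi, r$test$z_score, r$test$empirical_p,
                r$robustness, attr(x, "config")$robustness_trials,
                sum(r$profile$present)))
  bf <- attr(x, "below_floor")
  if (length(bf))
    cat("  (", length(bf), " motif(s) below the robustness floor; see attr 'below_floor')\n",
        sep = "")
  invisible(x)
}

#' @export
print.slim_motif_result <- function(x, ...) {
  cat(sprintf("<slim_motif_result> %s  MI = %.4f bits, z = %.1f, p = %.4g, robustness = %d, seed k-mer %s\n",
              format(x$motif), x$mi, x$test$z_score, x$test$empirical_p,
              x$robustness, x$seed_kmer))
  invisible(x)
}
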