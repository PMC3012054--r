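# Shared statistics: maximum-entropy discretization, plug-in mutual
# information, strict permutation significance (a motif passes only if its
# observed MI beats every null draw), jackknife robustness, and exact
# hypergeometric enrichment.

#' Equal-population (maximum-entropy) discretization
#'
#' Values are sorted ascending (ties keep input order) and split into
#' `n_bins` contiguous bins whose sizes differ by at most one, larger bins
#' first; class 0 holds the smallest values. Making bins equally populated
#' imposes no assumption on the distribution of the measurements.
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins, at most `length(values)`.
#' @return Integer vector of 0-based class indices aligned with `values`.
#' @export
#' @examples
#' discretize_equal(c(5, 1, 9, 3, 7, 2, 8), 3) # sizes 3, 2, 2
discretize_equal <- function(values, n_bins) {
  n <- length(values)
  if (any(!is.finite(values))) stop("non-finite value(s) in discretize input")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1 || n_bins > n)
    stop("n_bins must be in 1..", n, ", got ", n_bins)
  ord <- order(values)                     # stable for ties
  q <- n %/% n_bins
  r <- n %% n_bins
  sizes <- q + as.integer(seq_len(n_bins) <= r)
  cls <- integer(n)
  cls[ord] <- rep.int(seq_len(n_bins) - 1L, sizes)
  cls
}

as_code <- function(x) {
  if (is.logical(x)) return(list(code = as.integer(x), K = 2L))
  if (is.factor(x)) return(list(code = as.integer(x) - 1L, K = nlevels(x)))
  u <- sort(unique(x))
  list(code = match(x, u) - 1L, K = length(u))
}

#' Plug-in mutual information between two discrete vectors
#'
#' `sum p(a,b) log2(p(a,b) / (p(a) p(b)))` in bits, with zero-count terms
#' contributing zero. Symmetric and non-negative.
#'
#' @param x,y Equal-length discrete vectors (logical, integer, factor, or
#'   character).
#' @return MI in bits.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)) # 1 bit
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) == 0) stop("empty input")
  cx <- as_code(x); cy <- as_code(y)
  .cpp_mi_disc(cx$code, cy$code, cx$K, cy$K)
}

new_shuffle_test <- function(obs, null, n_rand, seed) {
  m <- mean(null); s <- stats::sd(null)
  structure(list(
    observed_mi = obs,
    z_score = if (is.na(s) || s == 0) 0 else (obs - m) / s,
    empirical_p = (1 + sum(null >= obs)) / (1 + n_rand),
    passed = obs > max(null),
    n_rand = n_rand, seed = seed,
    null_mean = m, null_sd = if (is.na(s)) 0 else s),
    class = "slim_shuffle_test")
}

#' @export
print.slim_shuffle_test <- function(x, ...) {
  cat(sprintf("<shuffle_test> MI = %.5f bits, z = %.2f, p = %.4g (%s, n_rand = %d)\n",
              x$observed_mi, x$z_score, x$empirical_p,
              if (x$passed) "passed" else "not passed", x$n_rand))
  invisible(x)
}

#' Strict randomization test of motif-behavior mutual information
#'
#' The behavior profile is shuffled `n_rand` times (independent uniform
#' permutations) and the MI with the fixed presence profile recomputed; the
#' motif is deemed significant (`passed`) only if the observed MI is greater
#' than all `n_rand` randomized values. The empirical p-value uses the
#' add-one estimator `(1 + #null >= observed) / (1 + n_rand)` so it is never
#' zero, and the z-score is taken from the same null sample.
#'
#' @param present Logical (or 0/1) motif presence per protein.
#' @param classes Behavior class per protein (any discrete coding).
#' @param n_rand Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return A `slim_shuffle_test` with fields `observed_mi`, `z_score`,
#'   `empirical_p`, `passed`, `n_rand`, `seed`, `null_mean`, `null_sd`.
#' @export
shuffle_test <- function(present, classes, n_rand = 10000L, seed = 1L) {
  if (length(present) != length(classes))
    stop("length mismatch: ", length(present), " vs ", length(classes))
  n_rand <- as.integer(n_rand)
  stopifnot(n_rand >= 1)
  cx <- as_code(as.logical(present)); cy <- as_code(classes)
  obs <- .cpp_mi_disc(cx$code, cy$code, cx$K, cy$K)
  set.seed(seed)
  # drawing class labels for the smaller presence side without replacement
  # is the exact permutation null (MI is invariant to swapping the binary
  # labels) at O(m) per draw instead of O(n)
  m <- sum(cx$code == 1L)
  null <- .cpp_perm_mi_null_binary(cy$code, min(m, length(cx$code) - m),
                                   cy$K, n_rand)
  new_shuffle_test(obs, null, n_rand, seed)
}

#' Conditional-information test of a candidate motif given an accepted one
#'
#' Tests whether `candidate` still carries information about the behavior
#' once an already-accepted presence profile is known: the observed statistic
#' is `sum_g p(g) MI(candidate; behavior | given = g)` and the null permutes
#' behavior labels independently within each stratum of `given`. The pass
#' rule is the same strict beat-all-draws rule as [shuffle_test()].
#'
#' @param candidate Logical presence profile under test.
#' @param classes Behavior class per protein.
#' @param given Logical presence profile of the accepted motif.
#' @param n_rand Number of stratified permutations.
#' @param seed Integer seed.
#' @return A `slim_shuffle_test` (observed_mi holds the conditional MI).
#' @export
conditional_mi_test <- function(candidate, classes, given,
                                n_rand = 1000L, seed = 1L) {
  n <- length(candidate)
  if (length(classes) != n || length(given) != n) stop("length mismatch")
  n_rand <- as.integer(n_rand)
  cx <- as_code(as.logical(candidate))
  cy <- as_code(classes)
  cg <- as_code(as.logical(given))
  obs <- .cpp_cond_mi(cx$code, cy$code, cg$code, cx$K, cy$K, cg$K)
  set.seed(seed)
  null <- .cpp_cond_perm_null(cx$code, cy$code, cg$code, cx$K, cy$K, cg$K,
                              n_rand)
  new_shuffle_test(obs, null, n_rand, seed)
}

#' Jackknife robustness score of a motif (0-10)
#'
#' For each of `n_trials` trials, a fraction `keep_fraction` of the analysis
#' universe is sampled without replacement, the motif profile restricted to
#' the subset, and the strict [shuffle_test()] re-run with `n_rand`
#' permutations; the score is the number of passing trials. A subsample that
#' empties a behavior class is redrawn (up to 100 attempts, then the trial
#' counts as a failure).
#'
#' @param m A `slim_motif` or pattern string.
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior`.
#' @param n_trials Number of jackknife trials (default 10).
#' @param keep_fraction Fraction kept per trial (default 2/3).
#' @param n_rand Permutations per inner test (default 1000).
#' @param seed Integer seed.
#' @param profile Optional prebuilt `slim_profile` on `behavior$ids` (avoids
#'   rescanning).
#' @return Integer score in `0..n_trials`.
#' @export
robustness_score <- function(m, prot, behavior, n_trials = 10L,
                             keep_fraction = 2 / 3, n_rand = 1000L,
                             seed = 1L, profile = NULL) {
  stopifnot(keep_fraction > 0, keep_fraction < 1)
  if (is.null(profile)) profile <- build_profile(prot, m, behavior$ids)
  stopifnot(identical(profile$ids, behavior$ids))
  n <- length(behavior$ids)
  keep <- floor(keep_fraction * n)
  C <- length(behavior$labels)
  score <- 0L
  for (t in seq_len(n_trials)) {
    set.seed(derive_seed(seed, "robustness_subset", t))
    idx <- NULL
    for (attempt in 1:100) {
      cand <- sample.int(n, keep)
      if (all(tabulate(behavior$class[cand] + 1L, C) > 0)) { idx <- cand; break }
    }
    if (is.null(idx)) next
    st <- shuffle_test(profile$present[idx], behavior$class[idx],
                       n_rand = n_rand,
                       seed = derive_seed(seed, "robustness_test", t))
    if (st$passed) score <- score + 1L
  }
  score
}

#' Exact hypergeometric tail probability
#'
#' Drawing `n` from a universe of `N` containing `K` successes, the upper
#' tail is `P(X >= k)` and the lower tail `P(X <= k)`.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @param tail `"upper"` or `"lower"`.
#' @return Probability.
#' @export
#' @examples
#' hypergeom_tail(4, 5, 4, 10, "upper") # 5/210
hypergeom_tail <- function(k, K, n, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (k < 0 || K < 0 || n < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: k=", k, " K=", K,
         " n=", n, " N=", N)
  if (tail == "upper") stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else stats::phyper(k, K, N - K, n)
}

#' Per-class hypergeometric enrichment of a motif profile
#'
#' For each behavior class: `k` carriers inside the class, `K` carriers
#' total, `n` class size, `N` universe size. Both tails are computed; the
#' signed score is `-log10(p_over)` (positive) when over-representation is
#' the smaller tail and `+log10(p_under)` (negative) otherwise, with p-values
#' floored at 1e-300. Significance is Bonferroni-corrected over
#' `classes x 2` tails per motif.
#'
#' @param profile A `slim_profile` aligned with `behavior`.
#' @param behavior A `slim_behavior`.
#' @param alpha Family-wise level (default 0.05).
#' @return Data frame with one row per class: `class_index`, `class_label`,
#'   `n_class`, `k_carriers`, `p_over`, `p_under`, `signed_score`,
#'   `significant`.
#' @export
class_enrichment <- function(profile, behavior, alpha = 0.05) {
  stopifnot(identical(profile$ids, behavior$ids))
  C <- length(behavior$labels)
  N <- length(behavior$ids)
  K <- sum(profile$present)
  n_c <- tabulate(behavior$class + 1L, C)
  k_c <- vapply(seq_len(C) - 1L, function(c)
    sum(profile$present & behavior$class == c), 0L)
  p_over <- mapply(function(k, n) hypergeom_tail(k, K, n, N, "upper"),
                   k_c, n_c)
  p_under <- mapply(function(k, n) hypergeom_tail(k, K, n, N, "lower"),
                    k_c, n_c)
  p_over <- pmax(p_over, 1e-300)
  p_under <- pmax(p_under, 1e-300)
  signed <- ifelse(p_over <= p_under, -log10(p_over), log10(p_under))
  bonf <- 2 * C
  sig <- pmin(p_over, p_under) * bonf < alpha
  data.frame(class_index = seq_len(C) - 1L,
             class_label = behavior$labels,
             n_class = n_c, k_carriers = k_c,
             p_over = p_over, p_under = p_under,
             signed_score = signed, significant = sig,
             stringsAsFactors = FALSE)
}
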