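# Seeded generators for proteomes, planted motifs/pairs/domains, and
# quantitative behaviors with full ground-truth records, so every statistic
# in the package can be validated end to end without external data.
#
# Planting overwrites sequence content in place (it never inserts), keeping
# lengths fixed so positional statistics and truth records stay exact.
# Chance matches of the planted pattern in non-carriers are recorded as
# "incidental" carriers, letting recovery metrics use either the strict
# (planted-only) or lenient (all-match) carrier set.

#' Generate a random proteome
#'
#' Sequences are i.i.d. residues drawn from `residue_freqs`; lengths are
#' normal with mean `length_mean`, sd `length_sd`, truncated below at
#' `min_length` (default 20, twice the maximum supported motif width).
#'
#' @param n Number of proteins.
#' @param length_mean,length_sd Length distribution parameters.
#' @param residue_freqs 20 probabilities in [aa_alphabet()] order, summing to
#'   1 (default uniform).
#' @param seed Integer seed.
#' @param min_length Lower truncation for lengths.
#' @return A [proteome()] with ids `P0001`, `P0002`, ...
#' @export
random_proteome <- function(n, length_mean = 400L, length_sd = 100L,
                            residue_freqs = rep(1 / 20, 20), seed = 1L,
                            min_length = 20L) {
  stopifnot(n >= 1)
  if (length(residue_freqs) != 20 || any(residue_freqs < 0) ||
      abs(sum(residue_freqs) - 1) > 1e-9)
    stop("residue_freqs must be 20 non-negative values summing to 1")
  set.seed(seed)
  lens <- pmax(round(stats::rnorm(n, length_mean, length_sd)),
               as.integer(min_length))
  seqs <- vapply(lens, function(L)
    paste(sample(AA_CANON, L, replace = TRUE, prob = residue_freqs),
          collapse = ""), character(1))
  names(seqs) <- sprintf("P%04d", seq_len(n))
  proteome(seqs)
}

sample_instance <- function(m) {
  paste(vapply(m$sets, function(s) s[sample.int(length(s), 1L)],
               character(1)), collapse = "")
}

draw_start <- function(n_starts, mode) {
  switch(mode,
         uniform = sample.int(n_starts, 1L) - 1L,
         nterm = sample.int(max(1L, ceiling(0.1 * n_starts)), 1L) - 1L,
         cterm = n_starts - sample.int(max(1L, ceiling(0.1 * n_starts)), 1L),
         stop("unknown position mode: ", mode))
}

overwrite_at <- function(seqs, id, start, word) {
  s <- seqs[[id]]
  paste0(substring(s, 1, start), word,
         substring(s, start + nchar(word) + 1, nchar(s)))
}

#' Plant a motif into target-class proteins
#'
#' Each protein of the target class independently becomes a carrier with
#' probability `penetrance`; a concrete instance (one residue sampled
#' uniformly from each allowed-set, wildcards from the full canonical
#' alphabet) overwrites the sequence at a start drawn by `position_mode`
#' (`"nterm"`/`"cterm"` use the first/last 10% of valid starts). Proteins
#' too short for the motif are skipped with a message.
#'
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior` over (a subset of) `prot`.
#' @param m A `slim_motif` or pattern string.
#' @param target_class 0-based class index receiving the plant.
#' @param penetrance Carrier probability in (0, 1].
#' @param position_mode `"uniform"`, `"nterm"`, or `"cterm"`.
#' @param seed Integer seed.
#' @return List `proteome` (modified) and `truth` (a `slim_truth`: `motif`,
#'   `target_class`, `penetrance`, `planted` data frame of id/start,
#'   `carrier_ids`, `incidental_ids`, `all_carrier_ids`).
#' @export
plant_motif <- function(prot, behavior, m, target_class, penetrance,
                        position_mode = "uniform", seed = 1L) {
  if (is.character(m)) m <- parse_motif(m)
  stopifnot(penetrance > 0, penetrance <= 1)
  w <- m$width
  set.seed(seed)
  seqs <- unclass(prot)
  targets <- behavior$ids[behavior$class == target_class]
  planted_id <- character(0)
  planted_start <- integer(0)
  skipped <- 0L
  for (id in targets) {
    if (stats::runif(1) > penetrance) next
    n_starts <- nchar(seqs[[id]]) - w + 1L
    if (n_starts < 1L) { skipped <- skipped + 1L; next }
    s <- draw_start(n_starts, position_mode)
    seqs[[id]] <- overwrite_at(seqs, id, s, sample_instance(m))
    planted_id <- c(planted_id, id)
    planted_start <- c(planted_start, s)
  }
  if (skipped) message("plant_motif: skipped ", skipped, " too-short protein(s)")
  newprot <- proteome(seqs)
  all_carriers <- behavior$ids[present_many(seqs[behavior$ids], m)]
  truth <- structure(list(
    motif = m, target_class = target_class, penetrance = penetrance,
    position_mode = position_mode,
    planted = data.frame(protein_id = planted_id, start = planted_start,
                         stringsAsFactors = FALSE),
    carrier_ids = planted_id,
    incidental_ids = setdiff(all_carriers, planted_id),
    all_carrier_ids = all_carriers), class = "slim_truth")
  list(proteome = newprot, truth = truth)
}

#' Plant a co-occurring, co-localized motif pair
#'
#' Carriers (target-class proteins, probability `penetrance`) receive one
#' instance of each motif with `start_b - start_a = spacing + U(-jitter,
#' jitter)`; `spacing - jitter` must be at least the width of the first
#' motif so the second plant cannot clobber the first.
#'
#' @param prot A [proteome()].
#' @param behavior A `slim_behavior`.
#' @param motif_a,motif_b `slim_motif`s or pattern strings.
#' @param target_class 0-based class index.
#' @param spacing Nominal start-to-start distance.
#' @param jitter Maximum uniform deviation from `spacing` (default 0).
#' @param penetrance Carrier probability.
#' @param seed Integer seed.
#' @return List `proteome` and `truth` (with `pairs` data frame: protein_id,
#'   start_a, start_b, distance).
#' @export
plant_pair <- function(prot, behavior, motif_a, motif_b, target_class,
                       spacing, jitter = 0L, penetrance = 1, seed = 1L) {
  if (is.character(motif_a)) motif_a <- parse_motif(motif_a)
  if (is.character(motif_b)) motif_b <- parse_motif(motif_b)
  stopifnot(penetrance >= 0, penetrance <= 1)
  if (spacing - jitter < motif_a$width)
    stop("spacing - jitter must be >= width of motif_a")
  set.seed(seed)
  seqs <- unclass(prot)
  targets <- behavior$ids[behavior$class == target_class]
  rows <- list()
  skipped <- 0L
  for (id in targets) {
    if (stats::runif(1) > penetrance) next
    d <- spacing + if (jitter > 0) sample.int(2L * jitter + 1L, 1L) - jitter - 1L else 0L
    span <- d + motif_b$width
    n_starts <- nchar(seqs[[id]]) - span + 1L
    if (n_starts < 1L) { skipped <- skipped + 1L; next }
    sa <- sample.int(n_starts, 1L) - 1L
    seqs[[id]] <- overwrite_at(seqs, id, sa, sample_instance(motif_a))
    seqs[[id]] <- overwrite_at(seqs, id, sa + d, sample_instance(motif_b))
    rows <- c(rows, list(data.frame(protein_id = id, start_a = sa,
                                    start_b = sa + d, distance = d,
                                    stringsAsFactors = FALSE)))
  }
  if (skipped) message("plant_pair: skipped ", skipped, " too-short protein(s)")
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), start_a = integer(0),
               start_b = integer(0), distance = integer(0))
  newprot <- proteome(seqs)
  truth <- structure(list(motif_a = motif_a, motif_b = motif_b,
                          target_class = target_class,
                          penetrance = penetrance, spacing = spacing,
                          jitter = jitter, pairs = pairs,
                          carrier_ids = pairs$protein_id),
                     class = "slim_truth")
  list(proteome = newprot, truth = truth)
}

#' Plant one synthetic domain interval per carrier protein
#'
#' Each carrier receives a single interval named `"SynDom"` of length
#' `floor(coverage * L)` at a uniform offset.
#'
#' @param prot A [proteome()].
#' @param carrier_ids Protein ids receiving a domain.
#' @param coverage Fraction of sequence length covered, in (0, 1).
#' @param seed Integer seed.
#' @return A `slim_domains` annotation.
#' @export
plant_domains <- function(prot, carrier_ids, coverage, seed = 1L) {
  stopifnot(coverage > 0, coverage < 1)
  set.seed(seed)
  lens <- nchar(unclass(prot))[carrier_ids]
  dl <- pmax(1L, as.integer(floor(coverage * lens)))
  start <- vapply(lens - dl, function(m) sample.int(m + 1L, 1L) - 1L, 0L)
  domain_annotations(
    data.frame(protein_id = carrier_ids, name = "SynDom",
               start = start, end = start + dl, stringsAsFactors = FALSE),
    prot)
}

#' Couple a quantitative value to motif carriage
#'
#' Per-protein value = 0 - `effect` x carrier + Gaussian noise, so carriers
#' concentrate in the low bins after equal-population discretization.
#'
#' @param behavior A `slim_behavior` defining the universe and order.
#' @param carrier_ids Ids of carrier proteins.
#' @param effect Effect size subtracted for carriers.
#' @param noise_sd Gaussian noise sd (> 0).
#' @param seed Integer seed.
#' @return Named numeric vector over `behavior$ids`.
#' @export
make_quantitative <- function(behavior, carrier_ids, effect, noise_sd,
                              seed = 1L) {
  stopifnot(noise_sd > 0)
  set.seed(seed)
  vals <- -effect * (behavior$ids %in% carrier_ids) +
    stats::rnorm(length(behavior$ids), 0, noise_sd)
  stats::setNames(vals, behavior$ids)
}
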