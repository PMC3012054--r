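test_that("positional bias abstains under 20 instances and detects terminal planting", {
  prot <- toy_proteome()
  bp <- behavior_discrete(names(prot), c("x", "y", "x", "y", "x"), prot)
  prof <- build_profile(prot, "SP.[RK]", bp$ids)
  pb <- positional_bias(prof, bp, prot, n_rand = 99, seed = 1)
  expect_true(pb$insufficient)
  expect_true(is.na(pb$empirical_p))

  ds <- planted_dataset(55, n = 500, n_target = 120, length_mean = 250,
                        length_sd = 30, pattern = "SP[AG][RK]",
                        penetrance = 0.9, position_mode = "nterm",
                        background_rate = 0.3)
  prof2 <- build_profile(ds$proteome, "SP[AG][RK]", ds$behavior$ids)
  pb2 <- positional_bias(prof2, ds$behavior, ds$proteome, n_rand = 999,
                         seed = 2)
  expect_false(pb2$insufficient)
  expect_lt(pb2$empirical_p, 0.01)
  # histograms conserve instances and N-terminal bin dominates targets
  expect_identical(sum(pb2$histogram_targets) + sum(pb2$histogram_others),
                   pb2$n_instances)
  expect_identical(which.max(pb2$histogram_targets), 1L)
})

test_that("co-occurrence direction and significance follow the presence overlap", {
  ds <- planted_dataset(56, n = 400, n_target = 100, length_mean = 200,
                        length_sd = 20, pattern = "SP[AG][RK]",
                        penetrance = 0.9)
  prof <- build_profile(ds$proteome, "SP[AG][RK]", ds$behavior$ids)
  co <- motif_cooccurrence(prof, prof, n_rand = 499, seed = 3)
  expect_identical(co$direction, "co-occur")
  expect_true(co$passed)
  expect_equal(co$empirical_p, 1 / 500)

  # forced disjoint profiles larger than expected overlap co-avoid
  n <- length(prof$present)
  a <- prof
  b <- prof
  a$present <- seq_len(n) <= n / 2
  b$present <- seq_len(n) > n / 2
  expect_identical(motif_cooccurrence(a, b, n_rand = 99, seed = 1)$direction,
                   "co-avoid")
})

test_that("co-localization abstains with few co-carriers and detects planted spacing", {
  prot <- toy_proteome()
  bp <- behavior_discrete(names(prot), c("x", "y", "x", "y", "x"), prot)
  pa <- build_profile(prot, "SP.[RK]", bp$ids)
  cl0 <- motif_colocalization(pa, pa, bp, n_rand = 99, seed = 1)
  expect_true(cl0$insufficient)

  prot2 <- random_proteome(300, 220, 20, seed = 61)
  set.seed(62)
  tids <- sample(names(prot2), 90)
  bp2 <- behavior_discrete(names(prot2),
                           ifelse(names(prot2) %in% tids, "t", "b"), prot2)
  tc <- match("t", bp2$labels) - 1L
  bc <- match("b", bp2$labels) - 1L
  pp <- plant_pair(prot2, bp2, "WADAW", "CYKYC", tc, spacing = 8,
                   jitter = 0, penetrance = 0.9, seed = 63)
  # background co-carriers at wide random spacings make distance informative
  pp2 <- plant_pair(pp$proteome, bp2, "WADAW", "CYKYC", bc, spacing = 60,
                    jitter = 30, penetrance = 0.25, seed = 64)
  pa2 <- build_profile(pp2$proteome, "WADAW", bp2$ids)
  pb2 <- build_profile(pp2$proteome, "CYKYC", bp2$ids)
  cl <- motif_colocalization(pa2, pb2, bp2, n_rand = 999, seed = 65)
  expect_false(cl$insufficient)
  expect_lt(cl$empirical_p, 0.01)
})

test_that("domain overlap z-scores carry the planted sign", {
  set.seed(71)
  prot <- random_proteome(80, 200, 10, seed = 71)
  carriers <- names(prot)[1:40]
  dom <- plant_domains(prot, carriers, coverage = 0.4, seed = 72)
  seqs <- unclass(prot)
  word <- "WCDCW"
  inside <- seqs
  outside <- seqs
  for (id in carriers) {
    iv <- dom[dom$protein_id == id, ]
    L <- nchar(seqs[[id]])
    s_in <- iv$start + 2L
    s_out <- if (iv$start >= 10) 0L else iv$end + 2L
    inside[[id]] <- paste0(substring(inside[[id]], 1, s_in), word,
                           substring(inside[[id]], s_in + 6, L))
    outside[[id]] <- paste0(substring(outside[[id]], 1, s_out), word,
                            substring(outside[[id]], s_out + 6, L))
  }
  prof_in <- build_profile(proteome(inside), word)
  prof_out <- build_profile(proteome(outside), word)
  rep_in <- domain_report(prof_in, dom, proteome(inside))
  rep_out <- domain_report(prof_out, dom, proteome(outside))
  expect_gt(rep_in$overlap_z[rep_in$domain_name == "SynDom"], 0)
  expect_lt(rep_out$overlap_z[rep_out$domain_name == "SynDom"], 0)
  # carriers and domain-bearers coincide, so co-occurrence is enriched
  expect_lt(rep_in$cooccurrence_p[1], 0.01)
})

test_that("term enrichment ranks the matching term first and handles zero overlap", {
  prot <- random_proteome(200, 80, 10, seed = 81)
  ids <- names(prot)
  terms <- term_map(stats::setNames(
    c(ids[1:20], ids[30:60], ids[100:110]),
    rep(c("T_match", "T_big", "T_none"), c(20, 31, 11))), prot)
  te <- term_enrichment(ids[1:20], terms, ids)
  expect_identical(te$term_id[1], "T_match")
  expect_true(te$significant[1])
  expect_equal(te$p[te$term_id == "T_none"], 1)
})

test_that("disorder scoring counts instances by majority residue coverage", {
  prot <- proteome(c(A = strrep("W", 20), B = strrep("W", 20)))
  prof <- build_profile(prot, "WWWW")
  prof$instances <- list(c(0L, 8L), c(0L, 10L))
  prof$present <- c(TRUE, TRUE)
  mask_all <- disorder_mask(data.frame(protein_id = c("A", "B"),
                                       start = c(0L, 0L), end = c(20L, 20L)),
                            prot)
  expect_equal(disorder_score(prof, mask_all, prot), 1.0)
  mask_none <- disorder_mask(data.frame(protein_id = "A", start = 0L,
                                        end = 1L), prot)
  expect_equal(disorder_score(prof, mask_none, prot), 0.0)
  # 3 of 4 instances covered: A fully disordered, B only the first half
  mask_part <- disorder_mask(data.frame(protein_id = c("A", "B"),
                                        start = c(0L, 0L), end = c(20L, 9L)),
                             prot)
  expect_equal(disorder_score(prof, mask_part, prot), 0.75)
})

test_that("k-mer disorder percentile places a disorder-planted motif high", {
  set.seed(91)
  prot <- random_proteome(60, 150, 10, seed = 91)
  seqs <- unclass(prot)
  # disorder = first 30 residues of each protein; plant CDC there
  for (id in names(seqs)[1:40])
    seqs[[id]] <- paste0(substring(seqs[[id]], 1, 5), "CDC",
                         substring(seqs[[id]], 9, nchar(seqs[[id]])))
  prot2 <- proteome(seqs)
  mask <- disorder_mask(data.frame(protein_id = names(prot2), start = 0L,
                                   end = 30L), prot2)
  prof <- build_profile(prot2, "CDC")
  kp <- kmer_disorder_percentile(prof, mask, prot2)
  expect_gt(kp$motif_score, 0.5)
  expect_gt(kp$percentile, 50)
  expect_gt(kp$n_kmers, 100)
})

test_that("motif similarity is symmetric, maximal for identity, and finds catalog matches", {
  expect_equal(motif_similarity("SPAR", "SPAR"), 1.0)
  expect_lt(motif_similarity("SP.[RK]", "SP.[RK]"), 1.0)  # wildcard penalty
  expect_gt(motif_similarity("SP.[RK]", "SP.[RK]"), 0.7)
  expect_lte(motif_similarity("ACAC", "WYWY"), 0.05)
  set.seed(95)
  for (i in 1:30) {
    a <- random_motif()
    b <- random_motif()
    expect_equal(motif_similarity(a, b), motif_similarity(b, a))
  }

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CDK_substrate\t[ST]P.[RK]\tkinase",
               "NLS\tK[KR].K\tlocalization",
               "SH3\tP..P\tbinding"), tsv)
  cat <- read_motif_catalog(tsv)
  bm <- best_known_match("SP.[RK]", cat)
  expect_identical(bm$name, "CDK_substrate")
  expect_gte(bm$score, 0.5)
  expect_null(best_known_match("WWWW", cat))
})
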