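test_that("FASTA reading parses, normalizes, and validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A some description", "MSP", "ARK", ">B", "kkrk"), fa)
  p <- read_fasta(fa)
  expect_s3_class(p, "slim_proteome")
  expect_identical(names(p), c("A", "B"))
  expect_identical(unname(nchar(p)), c(6L, 4L))
  expect_identical(unname(unclass(p)["B"]), "KKRK")  # lowercase uppercased

  writeLines(c(">A", "MSP", ">A", "KKK"), fa)
  expect_error(read_fasta(fa), "duplicate.*A")

  writeLines(c(">A", "", ">B", "KK"), fa)
  expect_error(read_fasta(fa), "empty")

  writeLines(c(">A", "MS1P"), fa)
  expect_error(read_fasta(fa), "non-letter")

  # '*' is a retained non-canonical residue, not an error
  writeLines(c(">A", "MSP*K", ">B", "KXUK"), fa)
  p <- read_fasta(fa)
  expect_identical(unname(unclass(p)["A"]), "MSP*K")
})

test_that("FASTA round-trips and record order only permutes rows", {
  prot <- random_proteome(30, 80, 10, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(prot, fa)
  back <- read_fasta(fa)
  expect_identical(unclass(back), unclass(prot))

  # permuting record order changes no statistic, only row order
  bp <- behavior_discrete(names(prot),
                          rep(c("a", "b"), length.out = 30), prot)
  prof <- build_profile(prot, "AC", bp$ids)
  mi1 <- mutual_information(prof$present, bp$class)
  perm <- proteome(unclass(prot)[sample(seq_len(30))])
  bp2 <- behavior_discrete(names(prot),
                           rep(c("a", "b"), length.out = 30), perm)
  prof2 <- build_profile(perm, "AC", bp2$ids)
  expect_equal(mutual_information(prof2$present, bp2$class), mi1)
  expect_setequal(prof2$ids[prof2$present], prof$ids[prof$present])
})

test_that("behavior profiles map labels, bin values, and drop unknown ids", {
  prot <- proteome(c(A = "MSPARK", B = "KKRKAA", C = "MSPGRW"))
  bp <- behavior_discrete(c("A", "B", "C"),
                          c("nucleus", "mito", "nucleus"), prot)
  expect_identical(bp$labels, c("nucleus", "mito"))
  expect_identical(bp$class, c(0L, 1L, 0L))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A\tnucleus", "B\tmito", "C\tnucleus",
               "ZZZ\tmito"), tsv)
  expect_message(bp2 <- read_behavior(tsv, prot), "dropped 1")
  expect_identical(bp2$class, bp$class)

  # 20 values into 10 bins -> classes of size 2, ordered by value
  prot20 <- random_proteome(20, 50, 5, seed = 2)
  vals <- seq(20, 1)
  bq <- behavior_quantize(names(prot20), vals, 10, prot20)
  expect_identical(unname(tabulate(bq$class + 1L, 10)), rep(2L, 10))
  expect_identical(bq$class[order(vals[match(bq$ids, names(prot20))])],
                   rep(0:9, each = 2))

  writeLines(c("A\tsame", "B\tsame", "C\tsame"), tsv)
  expect_error(read_behavior(tsv, prot), "2 distinct")
  expect_error(behavior_quantize(c("A", "B"), c(1, 2), 5, prot), "n_bins")
})

test_that("interval annotations validate bounds and merge disorder", {
  prot <- proteome(c(A = strrep("M", 100), B = strrep("K", 50)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tPkinase\t10\t60"), tsv)
  dom <- read_intervals(tsv, prot, "domain")
  expect_identical(dom$start, 10L)
  expect_identical(dom$end, 60L)

  writeLines(c("A\t\t0\t10", "A\t\t5\t20", "A\t\t30\t40"), tsv)
  dis <- read_intervals(tsv, prot, "disorder")
  expect_identical(dis$start, c(0L, 30L))
  expect_identical(dis$end, c(20L, 40L))

  writeLines(c("A\tPkinase\t90\t101"), tsv)
  expect_error(read_intervals(tsv, prot, "domain"), "out-of-bounds.*A")
})

test_that("term maps and motif catalogs load and validate", {
  prot <- proteome(c(A = "MSPARK", B = "KKRKAA", C = "MSPGRW"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GO:1\tA", "GO:1\tB", "GO:2\tC"), tsv)
  tm <- read_term_map(tsv, prot)
  expect_setequal(tm[["GO:1"]], c("A", "B"))
  writeLines(c("GO:1\tA", "GO:1\tZZ"), tsv)
  expect_error(read_term_map(tsv, prot), "unknown protein")

  writeLines(c("CDK\tSP.[RK]\tkinase", "BAD\tS[]P\tx"), tsv)
  expect_error(read_motif_catalog(tsv), "line 2")
  writeLines(c("CDK\tSP.[RK]\tkinase"), tsv)
  cat <- read_motif_catalog(tsv)
  expect_identical(cat$name, "CDK")
  expect_identical(format(attr(cat, "motifs")[[1]]), "SP.[KR]")
})

test_that("write_results emits deterministic, complete tables", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_results(list(), out1)
  expect_identical(readLines(file.path(out1, "motifs.tsv")),
                   "motif\tmi_bits\tz_score\tempirical_p\trobustness\tn_carriers\tseed_kmer")

  prot <- toy_proteome()
  bp <- behavior_discrete(names(prot), c("x", "y", "x", "y", "x"), prot)
  prof <- build_profile(prot, "SP.[RK]", bp$ids)
  res <- structure(list(
    motif = prof$motif, mi = mutual_information(prof$present, bp$class),
    test = shuffle_test(prof$present, bp$class, 99, 3),
    robustness = 7L, enrichment = class_enrichment(prof, bp),
    profile = prof, pwm = pwm_from_instances(prof, prot),
    seed_kmer = "SPAR"), class = "slim_motif_result")
  write_results(list(res), out1)
  write_results(list(res), out2)
  for (f in c("motifs.tsv", "heatmap.tsv", "instances.tsv",
              file.path("pwm", "SP.[KR].tsv")))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  hm <- read.delim(file.path(out1, "heatmap.tsv"), check.names = FALSE)
  expect_identical(nrow(hm), 1L)
  expect_identical(sum(startsWith(names(hm), "score_")), 2L)
  inst <- read.delim(file.path(out1, "instances.tsv"))
  expect_identical(nrow(inst), 4L)  # two in A, one each in C and E
})
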