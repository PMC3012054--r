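test_that("equal-population discretization follows the contract", {
  expect_identical(unname(tabulate(discretize_equal(rnorm(10), 5) + 1L, 5)),
                   rep(2L, 5))
  expect_identical(unname(tabulate(discretize_equal(rnorm(7), 3) + 1L, 3)),
                   c(3L, 2L, 2L))
  # all-tied values: first ceiling(n/2) input positions take class 0
  expect_identical(discretize_equal(rep(1, 5), 2), c(0L, 0L, 0L, 1L, 1L))
  v <- c(5, 1, 9, 3, 7, 2, 8)
  expect_identical(discretize_equal(v, 3), c(1L, 0L, 2L, 0L, 1L, 0L, 2L))
  expect_error(discretize_equal(c(1, NA), 2), "non-finite")
  expect_error(discretize_equal(c(1, 2), 5), "n_bins")
})

test_that("mutual information matches hand-computed and oracle values", {
  y <- rep(0:1, each = 50)
  expect_equal(mutual_information(y, y), 1.0)
  expect_equal(mutual_information(rep(1, 40), rep(0:1, each = 20)), 0.0)
  # joint counts {(0,0):30,(0,1):10,(1,0):10,(1,1):30}
  x <- rep(c(0, 0, 1, 1), c(30, 10, 10, 30))
  z <- rep(c(0, 1, 0, 1), c(30, 10, 10, 30))
  expect_equal(mutual_information(x, z), 0.188721875540867, tolerance = 1e-13)
  expect_equal(mutual_information(x, z), mutual_information(z, x))
  expect_error(mutual_information(1:3, 1:4), "mismatch")
})

test_that("MI is bounded by the marginal entropies", {
  set.seed(3)
  ent <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  for (i in 1:50) {
    n <- sample(20:200, 1)
    x <- sample.int(sample(2:6, 1), n, replace = TRUE)
    y <- sample.int(sample(2:6, 1), n, replace = TRUE)
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, min(ent(x), ent(y)) + 1e-12)
  }
})

test_that("shuffle test applies the strict beat-all-draws rule", {
  n <- 1000
  x <- rep(c(TRUE, FALSE), each = n / 2)
  y <- rep(0:1, each = n / 2)
  st <- shuffle_test(x, y, n_rand = 999, seed = 11)
  expect_true(st$passed)
  expect_equal(st$empirical_p, 1 / 1000)
  expect_equal(st$observed_mi, 1.0)
  expect_gt(st$z_score, 10)

  st0 <- shuffle_test(rep(TRUE, n), y, n_rand = 99, seed = 1)
  expect_equal(st0$observed_mi, 0)
  expect_false(st0$passed)
  expect_equal(st0$z_score, 0)  # degenerate null

  st1 <- shuffle_test(x, y, n_rand = 200, seed = 5)
  st2 <- shuffle_test(x, y, n_rand = 200, seed = 5)
  expect_identical(st1, st2)
})

test_that("conditional MI test detects stratum-specific signal only", {
  n <- 600
  g <- rep(c(TRUE, FALSE), each = n / 2)
  set.seed(21)
  y <- sample(0:1, n, replace = TRUE)
  cand <- g  # candidate identical to conditioning profile
  ct <- conditional_mi_test(cand, y, g, n_rand = 199, seed = 2)
  expect_equal(ct$observed_mi, 0)
  expect_false(ct$passed)

  # candidate informative only where g is FALSE
  cand2 <- ifelse(g, sample(c(TRUE, FALSE), n, replace = TRUE),
                  y == 1)
  ct2 <- conditional_mi_test(cand2, y, g, n_rand = 199, seed = 3)
  expect_true(ct2$passed)
})

test_that("robustness is high for planted signal, low for noise", {
  ds <- planted_dataset(77, n = 400, n_target = 80, length_mean = 250,
                        length_sd = 40, pattern = "SP[AG][RK]",
                        penetrance = 0.9)
  r <- robustness_score("SP[AG][RK]", ds$proteome, ds$behavior,
                        n_rand = 499, seed = 9)
  expect_equal(r, 10L)
  expect_identical(robustness_score("SP[AG][RK]", ds$proteome, ds$behavior,
                                    n_rand = 499, seed = 9), r)

  shuf <- shuffled_labels(ds, 15)
  low <- vapply(1:5, function(i)
    robustness_score("SP[AG][RK]", ds$proteome, shuf, n_rand = 499,
                     seed = 100 + i), 0L)
  expect_gte(sum(low <= 1), 4)
})

test_that("hypergeometric tails are exact", {
  expect_equal(hypergeom_tail(0, 5, 4, 10, "upper"), 1.0)
  expect_equal(hypergeom_tail(4, 5, 4, 10, "upper"), 5 / 210)
  set.seed(8)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N, "upper") +
                   hypergeom_tail(k, K, n, N, "lower") -
                   dhyper(k, K, N - K, n), 1, tolerance = 1e-12)
  }
  expect_error(hypergeom_tail(6, 5, 4, 10), "inconsistent")
})

test_that("class enrichment flags the carrier class and matches interaction-scale p-values", {
  prot <- random_proteome(60, 60, 5, seed = 4)
  bp <- behavior_discrete(names(prot), rep(c("in", "out"), each = 30), prot)
  prof <- build_profile(prot, "AC", bp$ids)
  prof$present <- bp$class == 0          # carriers exactly the first class
  enr <- class_enrichment(prof, bp)
  expect_true(enr$significant[1])
  expect_gt(enr$signed_score[1], 0)
  expect_lt(enr$signed_score[2], 0)

  # 72% of a 225-protein class vs 11% of 5500 others is astronomically
  # over-represented
  k <- round(0.72 * 225)
  K <- k + round(0.11 * 5500)
  p <- hypergeom_tail(k, K, 225, 5725, "upper")
  expect_lt(p, 1e-15)
})
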