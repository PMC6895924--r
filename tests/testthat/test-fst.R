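# Tail partition and Nei FST scan.

test_that("tail partition hits exact counts on distinct phenotypes", {
  set.seed(1)
  y <- setNames(sample(seq_len(100)), sprintf("i%03d", 1:100))
  sp <- partition_tails(y, q_low = 0.05, q_high = 0.95)
  expect_length(sp$s1_ids, 5)
  expect_length(sp$s2_ids, 5)
  # partition property
  expect_setequal(c(sp$s1_ids, sp$s0_ids, sp$s2_ids), names(y))
  expect_length(intersect(sp$s1_ids, sp$s2_ids), 0)
  # the tails really are the extremes
  expect_setequal(sp$s1_ids, names(sort(y)[1:5]))
  expect_setequal(sp$s2_ids, names(sort(y, decreasing = TRUE)[1:5]))
})

test_that("boundary ties are resolved by ascending id order", {
  y <- setNames(c(0, 1, 1, 1, 2, 3, 4, 5, 6, 7,
                  8, 9, 10, 11, 12, 13, 14, 15, 16, 17),
                sprintf("i%02d", 1:20))
  sp <- partition_tails(y, q_low = 0.10, q_high = 0.90)
  expect_identical(sp$s1_ids, c("i01", "i02"))  # tie among i02/i03/i04 at 1
  expect_identical(sp$s2_ids, c("i19", "i20"))
})

test_that("degenerate and undersized phenotype sets are rejected", {
  expect_error(partition_tails(rep(1, 100), sprintf("i%d", 1:100)),
               "degenerate")
  expect_error(partition_tails(rnorm(20), sprintf("i%d", 1:20),
                               q_low = 0.05, q_high = 0.95),
               "fewer than 2")
  expect_error(partition_tails(rnorm(100), sprintf("i%d", 1:100),
                               q_low = 0.95, q_high = 0.05), "q_low")
})

test_that("subpopulation frequencies equal mean dosage over two", {
  g <- make_test_geno(3, 4, seed = 2)
  g$dosages[, 1] <- c(0L, 1L, 2L)
  g$dosages[, 2] <- c(2L, 2L, 2L)
  f <- subpop_freqs(g, rownames(g$dosages))
  expect_equal(unname(f[1]), 0.5)
  expect_equal(unname(f[2]), 1)
  expect_error(subpop_freqs(g, character(0)), "empty")
  expect_error(subpop_freqs(g, "nobody"), "absent")
})

test_that("subpopulation frequencies match brute-force allele counting", {
  g <- make_test_geno(50, 20, seed = 3)
  ids <- sample(rownames(g$dosages), 23)
  f <- subpop_freqs(g, ids)
  oracle <- apply(g$dosages[ids, ], 2, function(col) sum(col) / (2 * length(ids)))
  expect_equal(unname(f), unname(oracle), tolerance = 1e-15)
})

test_that("FST hand-computed cases are exact", {
  split <- make_split(sprintf("s1_%d", 1:5), sprintf("s2_%d", 1:5),
                      character(0))

  # equal frequencies: no differentiation
  sc <- fst_scores(two_group_geno(0.3, 0.3), split)
  expect_equal(sc$fst, 0, tolerance = 1e-12)

  # fixed alternative alleles: complete differentiation
  sc <- fst_scores(two_group_geno(1, 0), split)
  expect_equal(sc$p, 0.5, tolerance = 1e-12)
  expect_equal(sc$h_t, 0.5, tolerance = 1e-12)
  expect_equal(sc$h_s, 0, tolerance = 1e-12)
  expect_equal(sc$fst, 1, tolerance = 1e-12)

  # intermediate case: p1 = 0.8, p2 = 0.4, equal sizes
  sc <- fst_scores(two_group_geno(0.8, 0.4), split)
  expect_equal(sc$p, 0.6, tolerance = 1e-12)
  expect_equal(sc$h_t, 0.48, tolerance = 1e-12)
  expect_equal(sc$h_s, 0.40, tolerance = 1e-12)
  expect_equal(sc$fst, 1 / 6, tolerance = 1e-12)
})

test_that("FST lies in [0,1], is zero at monomorphic loci, and H_S <= H_T", {
  g <- make_test_geno(80, 500, seed = 4, maf_min = 0)
  g$dosages[, 1] <- 0L  # force a monomorphic locus
  y <- setNames(rnorm(80), rownames(g$dosages))
  sp <- partition_tails(y, q_low = 0.2, q_high = 0.8)
  sc <- fst_scores(g, sp)
  expect_true(all(sc$fst >= 0 & sc$fst <= 1))
  expect_true(all(sc$h_s <= sc$h_t + 1e-12))
  expect_equal(sc$fst[1], 0)
})

test_that("FST is invariant to permuting individuals and swapping tail labels", {
  g <- make_test_geno(60, 100, seed = 5)
  y <- setNames(rnorm(60), rownames(g$dosages))
  sp <- partition_tails(y, q_low = 0.15, q_high = 0.85)
  sc <- fst_scores(g, sp)

  perm <- sample(nrow(g$dosages))
  gp <- geno_matrix(g$dosages[perm, ], g$map)
  expect_equal(fst_scores(gp, sp)$fst, sc$fst, tolerance = 1e-12)

  swapped <- sp
  swapped$s1_ids <- sp$s2_ids
  swapped$s2_ids <- sp$s1_ids
  expect_equal(fst_scores(g, swapped)$fst, sc$fst, tolerance = 1e-12)
})

test_that("under no selection mean FST shrinks as the tails grow", {
  # phenotype independent of genotype: FST is pure sampling noise ~ 1/(2n)
  g <- make_test_geno(400, 200, seed = 6)
  y <- setNames(rnorm(400), rownames(g$dosages))
  m <- sapply(c(0.05, 0.25), function(q) {
    sp <- partition_tails(y, q_low = q, q_high = 1 - q)
    mean(fst_scores(g, sp)$fst)
  })
  expect_lt(m[2], m[1])
  expect_lt(m[1], 0.1)
})

test_that("top-k selection matches a full-sort oracle and breaks ties by position", {
  sc <- data.frame(locus = c("a", "b", "c"), chrom = 1L, pos_cM = 1:3,
                   fst = c(0.1, 0.9, 0.5))
  expect_setequal(fst_top_k(sc, 2), c("b", "c"))
  expect_setequal(fst_top_k(sc, 3), sc$locus)
  expect_error(fst_top_k(sc, 0), "positive")
  expect_error(fst_top_k(sc, 4), "exceeds")

  set.seed(7)
  big <- data.frame(locus = sprintf("L%04d", 1:1000), chrom = 1L,
                    pos_cM = 1:1000,
                    fst = round(runif(1000), 2))  # rounding forces ties
  got <- fst_top_k(big, 50)
  cutoff <- sort(big$fst, decreasing = TRUE)[50]
  oracle_above <- big$locus[big$fst > cutoff]
  expect_true(all(oracle_above %in% got))
  # remaining slots filled from the tied score, lowest positions first
  tied <- big$locus[big$fst == cutoff]
  expect_identical(setdiff(got, oracle_above),
                   tied[seq_len(50 - length(oracle_above))])
})
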