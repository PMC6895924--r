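# Forward-in-time simulator: drift-free expectations, determinism, additive
# genetics bookkeeping, Mendelian transmission, selection response.

test_that("one drift-free historical generation keeps allele frequencies near 0.5", {
  cfg <- sim_config(n_snp = 2000, n_qtl = 0, n_hist_generations = 1,
                    hist_pop_size = 200, hist_expansion = 200,
                    n_founder_males = 50, n_founder_females = 150,
                    mutation_rate = 0, seed = 3)
  f <- simulate_history(cfg)
  p <- allele_freq(f)
  # founding draw is Binomial(2N, 0.5) per locus; the mean over 2000 loci
  # has SE ~ sqrt(0.25 / (2 * 200)) / sqrt(2000) ~ 0.0006
  expect_lt(abs(mean(p) - 0.5), 0.005)
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- tiny_config()
  s1 <- simulate_population(cfg, keep_genotypes = c(2, 3))
  s2 <- simulate_population(cfg, keep_genotypes = c(2, 3))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$geno$G3$dosages, s2$geno$G3$dosages)
  expect_identical(s1$qtl$effect, s2$qtl$effect)
  # standalone history under the same seed matches the wrapper's founders
  f <- simulate_history(cfg)
  expect_identical(allele_freq(f), s1$founder_freq)
})

test_that("QTL effect magnitudes follow the configured Gamma distribution", {
  cfg <- sim_config(n_snp = 5, n_qtl = 100000, n_hist_generations = 1,
                    hist_pop_size = 20, hist_expansion = 25,
                    n_founder_males = 5, n_founder_females = 15, seed = 9)
  f <- simulate_history(cfg)
  qtl <- sample_qtl(cfg, f)
  expect_equal(nrow(qtl), 100000)
  # Gamma(0.4, scale 0.15) mean = 0.06, SE of the mean over 1e5 draws ~ 3e-4
  expect_lt(abs(mean(qtl$magnitude) - 0.4 * 0.15), 0.002)
  # signs are balanced
  expect_lt(abs(mean(sign(qtl$effect))), 0.02)
  # QTL never collide with the SNP panel: each locus index used once
  expect_false(any(duplicated(attr(qtl, "idx"))))
})

test_that("sample_qtl with zero QTL yields identically zero breeding values", {
  cfg <- tiny_config(n_qtl = 0)
  sim <- simulate_population(cfg, keep_genotypes = integer(0))
  expect_true(all(sim$records$tbv == 0))
})

test_that("residual scaling hits the heritability and variance targets", {
  cfg <- tiny_config()
  f <- simulate_history(cfg)
  qtl <- sample_qtl(cfg, f)
  sc <- scale_residual(cfg, qtl, f)
  # after rescaling, founder TBV variance is exactly h2 * Vp
  g <- rowSums(sweep(
    as_geno_matrix(f)$dosages[, attr(qtl, "idx"), drop = FALSE], 2,
    sc$qtl$effect, `*`))
  expect_equal(var(g), cfg$h2_target * cfg$vp_target, tolerance = 1e-12)
  expect_equal(sc$sigma_e, sqrt(cfg$vp_target * (1 - cfg$h2_target)),
               tolerance = 1e-12)
  # algebraic identity: h2 = 0.3 and Vp = 1 imply sigma_e = sqrt(0.7)
  expect_equal(sc$sigma_e, sqrt(0.7), tolerance = 1e-12)
})

test_that("heritability one gives zero residual and phenotype equal to TBV", {
  cfg <- tiny_config(h2_target = 1, trait_mean = 5)
  sim <- simulate_population(cfg, keep_genotypes = integer(0))
  rec <- sim$records[sim$records$generation >= 0, ]
  expect_equal(sim$sigma_e, 0)
  expect_equal(rec$phenotype, rec$tbv + 5, tolerance = 1e-12)
})

test_that("TBV is exactly additive in QTL dosages", {
  cfg <- tiny_config()
  sim <- simulate_population(cfg, keep_genotypes = c(2, 3))
  for (gen in c("G2", "G3")) {
    g <- sim$geno[[gen]]
    qidx <- match(sim$qtl$locus, g$map$locus)
    raw <- drop(g$dosages[, qidx, drop = FALSE] %*% sim$qtl$effect)
    rec <- sim$records[match(rownames(g$dosages), sim$records$id), ]
    centering <- raw - rec$tbv
    # the same centering constant for every individual
    expect_lt(diff(range(centering)), 1e-10)
  }
})

test_that("offspring dosages are Mendelian-consistent with their parents", {
  cfg <- tiny_config(male_replacement = 1, female_replacement = 1)
  sim <- simulate_population(cfg, keep_genotypes = "all")
  rec <- sim$records
  # with full replacement every parent of G_g belongs to G_{g-1}
  for (g in 2:3) {
    child <- sim$geno[[paste0("G", g)]]$dosages
    parent <- sim$geno[[paste0("G", g - 1)]]$dosages
    kids <- rec[rec$generation == g, ]
    pick <- sample(nrow(kids), 25)  # spot-check
    for (i in pick) {
      s <- parent[kids$sire[i], ]
      d <- parent[kids$dam[i], ]
      o <- child[kids$id[i], ]
      # brute-force gamete bounds: a parent with dosage 0/2 transmits 0/1,
      # a heterozygote transmits either allele
      lo <- (s == 2L) + (d == 2L)
      hi <- (s > 0L) + (d > 0L)
      expect_true(all(o >= lo & o <= hi))
    }
  }
})

test_that("selection raises mean TBV while random replacement does not", {
  gain <- function(selection, seed) {
    cfg <- tiny_config(selection = selection, seed = seed)
    sim <- simulate_population(cfg, keep_genotypes = integer(0))
    rec <- sim$records
    mean(rec$tbv[rec$generation == 3]) - mean(rec$tbv[rec$generation == 0])
  }
  sel <- vapply(1:4, function(s) gain("ebv", s), numeric(1))
  rnd <- vapply(1:4, function(s) gain("random", s), numeric(1))
  expect_gt(mean(sel), 0)
  expect_gt(mean(sel), mean(rnd) + 0.1)
  # no directional trend without ranking: drift stays near zero
  expect_lt(abs(mean(rnd)), 0.2)
})

test_that("mean TBV is non-decreasing across selected generations", {
  means <- sapply(1:3, function(s) {
    cfg <- tiny_config(seed = s + 100)
    sim <- simulate_population(cfg, keep_genotypes = integer(0))
    tapply(sim$records$tbv[sim$records$generation >= 0],
           sim$records$generation[sim$records$generation >= 0], mean)
  })
  trend <- rowMeans(matrix(apply(means, 2, diff), nrow = nrow(means) - 1))
  expect_true(all(trend > -0.02))
  expect_gt(sum(trend), 0)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_chromosomes = 0), "positive")
  expect_error(sim_config(n_snp = 0), "positive")
  expect_error(sim_config(h2_target = 0), "h2_target")
  expect_error(sim_config(male_replacement = 1.2), "fraction")
  expect_error(sim_config(hist_expansion = 10), "founder set")
})
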