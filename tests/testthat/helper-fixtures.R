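# Shared fixtures: everything is generated in code at test time.

# A small, fast simulation configuration used across module tests.
tiny_config <- function(...) {
  args <- list(
    n_snp = 400, n_qtl = 20,
    n_hist_generations = 12, hist_pop_size = 40, hist_expansion = 80,
    n_founder_males = 10, n_founder_females = 50,
    offspring_per_generation = 120, n_offspring_generations = 3,
    n_chromosomes = 2, chrom_length_cM = 100,
    seed = 42
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Random genotype matrix with a simple one-or-two-chromosome map.
make_test_geno <- function(n, L, seed = 1, n_chrom = 1L, maf_min = 0.1) {
  set.seed(seed)
  p <- runif(L, maf_min, 1 - maf_min)
  d <- matrix(rbinom(n * L, 2L, rep(p, each = n)), n, L)
  rownames(d) <- sprintf("id%04d", seq_len(n))
  map <- data.frame(
    locus = sprintf("L%06d", seq_len(L)),
    chrom = rep(seq_len(n_chrom), length.out = L),
    pos_cM = rep(seq_len(ceiling(L / n_chrom)), n_chrom)[seq_len(L)],
    is_qtl = FALSE, stringsAsFactors = FALSE
  )
  map <- map[order(map$chrom, map$pos_cM), ]
  map$locus <- sprintf("L%06d", seq_len(L))
  geno_matrix(d, map)
}

# Build a tail split for explicitly chosen member sets by crafting
# phenotypes: S1 ids get the lowest values, S2 the highest. The middle set
# may be filler ids without genotypes (S0 never enters score computation).
make_split <- function(s1, s2, s0 = c("mid_1", "mid_2")) {
  if (length(s0) == 0L) s0 <- c("mid_1", "mid_2")
  ids <- c(s1, s0, s2)
  phen <- c(seq(-10, -9, length.out = length(s1)),
            seq(-1, 1, length.out = length(s0)),
            seq(9, 10, length.out = length(s2)))
  partition_tails(phen, ids,
                  q_low = length(s1) / length(ids) + 1e-9,
                  q_high = 1 - length(s2) / length(ids) - 1e-9)
}

# Genotype matrix realizing exact target allele frequencies in two groups of
# 5 individuals each (frequencies must be multiples of 0.1).
two_group_geno <- function(p1, p2) {
  dose_for <- function(p) {
    alleles <- round(10 * p)
    d <- integer(5)
    d[seq_len(alleles %/% 2)] <- 2L
    if (alleles %% 2 == 1L) d[alleles %/% 2 + 1L] <- 1L
    d
  }
  d <- matrix(c(dose_for(p1), dose_for(p2)), ncol = 1)
  rownames(d) <- c(sprintf("s1_%d", 1:5), sprintf("s2_%d", 1:5))
  map <- data.frame(locus = "L000001", chrom = 1L, pos_cM = 1,
                    is_qtl = FALSE, stringsAsFactors = FALSE)
  geno_matrix(d, map)
}
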