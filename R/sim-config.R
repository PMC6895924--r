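#' Configuration for the forward-in-time breeding simulation
#'
#' Builds a validated configuration object for [simulate_population()] and the
#' lower-level simulation steps. The defaults describe a desk-scale breeding
#' population: a randomly mated historical population that accumulates linkage
#' disequilibrium by drift, a base population founded from the last historical
#' generation, and seven discrete offspring generations bred by truncation
#' selection on estimated breeding values. The trait is fully additive with
#' `n_qtl` biallelic QTL whose effect magnitudes are Gamma-distributed; QTL are
#' carried on the genome alongside the SNP panel but are never genotyped.
#'
#' The default sizes are a reduced shadow of a large livestock simulation
#' (2 chromosomes of 100 cM carrying 20,000 SNPs and 100 QTL, 3,000 animals
#' per generation) that preserves the marker:QTL ratio and the sampling
#' fractions of the full-scale design while running on a single CPU in
#' minutes. Heritability and phenotypic variance are held at 0.3 and 1 by
#' rescaling QTL effects and the residual standard deviation (see
#' [scale_residual()]).
#'
#' @param n_hist_generations Number of constant-size historical generations of
#'   random mating used to build up linkage disequilibrium.
#' @param hist_pop_size Population size during the constant phase of the
#'   historical population.
#' @param hist_expansion Vector of population sizes for the expansion
#'   generations appended after the constant phase. The last entry must be at
#'   least `n_founder_males + n_founder_females`.
#' @param n_founder_males,n_founder_females Number of male and female founders
#'   drawn from the final historical generation to found the base population.
#' @param n_offspring_generations Number of selected offspring generations
#'   (G1..G7 by default) bred after the randomly mated base generation G0.
#' @param offspring_per_generation Number of progeny born in G0 and in each
#'   selected generation (one progeny per mating).
#' @param male_replacement,female_replacement Fraction of the sire and dam
#'   pools replaced each generation by the top-ranking candidates of the most
#'   recent generation.
#' @param sex_ratio Probability that a newborn is male.
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length_cM Length of each chromosome in centimorgans.
#' @param n_snp Total number of SNP markers, spread evenly over chromosomes.
#' @param n_qtl Number of QTL. QTL occupy their own positions on the same
#'   equidistant locus grid, so they never coincide with a SNP.
#' @param qtl_gamma_shape,qtl_gamma_scale Shape and scale of the Gamma
#'   distribution of QTL effect magnitudes.
#' @param h2_target Narrow-sense heritability of the simulated trait in the
#'   base generation, in (0, 1].
#' @param vp_target Phenotypic variance of the simulated trait.
#' @param trait_mean Overall mean added to every phenotype.
#' @param mutation_rate Per-locus, per-gamete probability of a recurrent
#'   biallelic mutation. Applied during the historical phase only.
#' @param selection Ranking rule used to pick replacement parents:
#'   `"ebv"` (default) ranks candidates on a pedigree-index EBV
#'   `h2 * (phenotype - generation mean) + 0.5 * (sire EBV + dam EBV)`,
#'   `"phenotype"` ranks on raw phenotype, `"random"` disables ranking
#'   (random replacement, i.e. no directional selection).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `"sim_config"` (a named list with the fields
#'   above plus `n_loci`, the total locus count).
#' @seealso [simulate_population()], [simulate_history()], [breed()]
#' @examples
#' cfg <- sim_config(n_snp = 200, n_qtl = 10, offspring_per_generation = 60,
#'                   n_founder_males = 5, n_founder_females = 25,
#'                   hist_expansion = c(40, 40), n_hist_generations = 10,
#'                   hist_pop_size = 30, seed = 1)
#' cfg
#' @export
sim_config <- function(n_hist_generations = 120L,
                       hist_pop_size = 200L,
                       hist_expansion = c(400L, 800L, 1600L),
                       n_founder_males = 100L,
                       n_founder_females = 1500L,
                       n_offspring_generations = 7L,
                       offspring_per_generation = 3000L,
                       male_replacement = 0.5,
                       female_replacement = 0.2,
                       sex_ratio = 0.5,
                       n_chromosomes = 2L,
                       chrom_length_cM = 100,
                       n_snp = 20000L,
                       n_qtl = 100L,
                       qtl_gamma_shape = 0.4,
                       qtl_gamma_scale = 0.15,
                       h2_target = 0.3,
                       vp_target = 1,
                       trait_mean = 0,
                       mutation_rate = 1e-5,
                       selection = c("ebv", "phenotype", "random"),
                       seed = NULL) {
  selection <- match.arg(selection)
  cfg <- list(
    n_hist_generations = as.integer(n_hist_generations),
    hist_pop_size = as.integer(hist_pop_size),
    hist_expansion = as.integer(hist_expansion),
    n_founder_males = as.integer(n_founder_males),
    n_founder_females = as.integer(n_founder_females),
    n_offspring_generations = as.integer(n_offspring_generations),
    offspring_per_generation = as.integer(offspring_per_generation),
    male_replacement = male_replacement,
    female_replacement = female_replacement,
    sex_ratio = sex_ratio,
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = chrom_length_cM,
    n_snp = as.integer(n_snp),
    n_qtl = as.integer(n_qtl),
    qtl_gamma_shape = qtl_gamma_shape,
    qtl_gamma_scale = qtl_gamma_scale,
    h2_target = h2_target,
    vp_target = vp_target,
    trait_mean = trait_mean,
    mutation_rate = mutation_rate,
    selection = selection,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  cfg$n_loci <- cfg$n_snp + cfg$n_qtl
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_hist_generations", "hist_pop_size", "n_founder_males",
              "n_founder_females", "offspring_per_generation",
              "n_chromosomes", "n_snp")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop(sprintf("'%s' must be a single positive count", f), call. = FALSE)
  }
  if (cfg$n_offspring_generations < 0L)
    stop("'n_offspring_generations' must be >= 0", call. = FALSE)
  if (cfg$n_qtl < 0L)
    stop("'n_qtl' must be >= 0", call. = FALSE)
  if (any(cfg$hist_expansion <= 0L))
    stop("'hist_expansion' sizes must be positive", call. = FALSE)
  for (f in c("male_replacement", "female_replacement", "sex_ratio")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in (0, 1]", f), call. = FALSE)
  }
  if (cfg$h2_target <= 0 || cfg$h2_target > 1)
    stop("'h2_target' must lie in (0, 1]", call. = FALSE)
  if (cfg$vp_target <= 0) stop("'vp_target' must be positive", call. = FALSE)
  if (cfg$chrom_length_cM <= 0)
    stop("'chrom_length_cM' must be positive", call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate >= 1)
    stop("'mutation_rate' must lie in [0, 1)", call. = FALSE)
  n_founders <- cfg$n_founder_males + cfg$n_founder_females
  final_hist <- utils::tail(c(cfg$hist_pop_size, cfg$hist_expansion), 1L)
  if (final_hist < n_founders)
    stop("final historical generation is smaller than the founder set; ",
         "increase 'hist_expansion'", call. = FALSE)
  if (cfg$n_loci < cfg$n_chromosomes)
    stop("need at least one locus per chromosome", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding simulation configuration\n")
  cat(sprintf("  genome: %d chromosomes x %g cM, %d SNPs + %d QTL\n",
              x$n_chromosomes, x$chrom_length_cM, x$n_snp, x$n_qtl))
  cat(sprintf("  history: %d generations of %d, expansion %s, mutation %g\n",
              x$n_hist_generations, x$hist_pop_size,
              paste(x$hist_expansion, collapse = "/"), x$mutation_rate))
  cat(sprintf("  founders: %d males + %d females; %d offspring/generation x %d generations\n",
              x$n_founder_males, x$n_founder_females,
              x$offspring_per_generation, x$n_offspring_generations))
  cat(sprintf("  selection: %s (replacement M %.0f%% / F %.0f%%), sex ratio %.2f\n",
              x$selection, 100 * x$male_replacement, 100 * x$female_replacement,
              x$sex_ratio))
  cat(sprintf("  trait: h2 = %.2f, Vp = %g, QTL effects ~ Gamma(%g, scale %g)\n",
              x$h2_target, x$vp_target, x$qtl_gamma_shape, x$qtl_gamma_scale))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Locus map: loci equidistant within each chromosome; loci are numbered
# genome-wide in (chromosome, position) order.
locus_map <- function(cfg) {
  per_chrom <- diff(round(seq(0, cfg$n_loci, length.out = cfg$n_chromosomes + 1L)))
  chrom <- rep(seq_len(cfg$n_chromosomes), per_chrom)
  pos <- unlist(lapply(per_chrom, function(m)
    (seq_len(m) - 0.5) * cfg$chrom_length_cM / m), use.names = FALSE)
  data.frame(
    locus = sprintf("L%06d", seq_len(cfg$n_loci)),
    chrom = chrom,
    pos_cM = pos,
    is_qtl = FALSE,
    stringsAsFactors = FALSE
  )
}
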