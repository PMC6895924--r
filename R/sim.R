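# Forward-in-time simulator. Haplotypes are stored as an L x 2N matrix of
# 0/1 alleles in raw (one-byte) storage to bound memory; individual i owns
# columns 2i-1 and 2i. Loci sit on an equidistant grid per chromosome, so
# crossover positions map directly to locus indices and a gamete is
# assembled from run-length parity segments.

.map_info <- function(cfg, map) {
  m_c <- as.integer(table(factor(map$chrom, levels = seq_len(cfg$n_chromosomes))))
  list(first = cumsum(c(1L, m_c[-length(m_c)])),
       m = m_c,
       len_M = rep(cfg$chrom_length_cM / 100, cfg$n_chromosomes))
}

# One gamete from individual `ind` of haplotype store H. Crossover counts are
# Poisson with mean equal to the chromosome map length in Morgans, placed
# uniformly, no interference; chromosomes assort independently.
.gamete <- function(H, ind, minfo) {
  h1 <- H[, 2L * ind - 1L]
  g <- h1
  h2 <- H[, 2L * ind]
  for (c in seq_along(minfo$m)) {
    m <- minfo$m[c]
    a <- minfo$first[c]
    k <- stats::rpois(1L, minfo$len_M[c])
    start <- if (stats::runif(1L) < 0.5) 0L else 1L
    if (k > 0L) {
      bp <- unique(sort(ceiling(stats::runif(k) * m)))
      bp <- bp[bp > 0L & bp < m]
    } else bp <- integer(0L)
    if (length(bp) == 0L) {
      if (start == 1L) {
        idx <- a:(a + m - 1L)
        g[idx] <- h2[idx]
      }
      next
    }
    lens <- diff(c(0L, bp, m))
    par <- rep((start + seq_along(lens) - 1L) %% 2L, lens)
    sw <- which(par == 1L) + (a - 1L)
    g[sw] <- h2[sw]
  }
  g
}

.make_generation <- function(Hs, s_pick, Hd, d_pick, minfo, L) {
  n <- length(s_pick)
  out <- matrix(as.raw(0L), L, 2L * n)
  for (j in seq_len(n)) {
    out[, 2L * j - 1L] <- .gamete(Hs, s_pick[j], minfo)
    out[, 2L * j] <- .gamete(Hd, d_pick[j], minfo)
  }
  out
}

.mutate <- function(H, rate) {
  if (rate <= 0) return(H)
  n_mut <- stats::rbinom(1L, length(H), rate)
  if (n_mut > 0L) {
    idx <- sample.int(length(H), n_mut)
    H[idx] <- xor(H[idx], as.raw(1L))
  }
  H
}

# Individuals x loci dosage matrix from a raw haplotype store, built row by
# row to avoid a transposed temporary.
.dosages_from_hap <- function(H) {
  n <- ncol(H) %/% 2L
  D <- matrix(0L, n, nrow(H))
  for (j in seq_len(n))
    D[j, ] <- as.integer(H[, 2L * j - 1L]) + as.integer(H[, 2L * j])
  D
}

#' Simulate the randomly mated historical population and draw founders
#'
#' Initializes every locus at allele frequency 0.5 and runs the configured
#' number of constant-size historical generations of random mating (with
#' recurrent mutation), followed by the expansion generations, so that
#' linkage disequilibrium between nearby markers builds up by drift. Founders
#' of the breeding population are then sampled from the final historical
#' generation and assigned sexes.
#'
#' Monomorphic loci can arise by drift; they are retained (and visible as
#' allele frequencies of 0 or 1) rather than dropped.
#'
#' @param config A [sim_config()].
#' @return An object of class `"founder_pop"`: haplotypes of the founder set,
#'   locus map, founder ids and sexes.
#' @examples
#' cfg <- sim_config(n_snp = 100, n_qtl = 5, n_hist_generations = 5,
#'                   hist_pop_size = 30, hist_expansion = 40,
#'                   n_founder_males = 5, n_founder_females = 20, seed = 7)
#' f <- simulate_history(cfg)
#' mean(allele_freq(f))
#' @export
simulate_history <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  .simulate_history_impl(config)
}

.simulate_history_impl <- function(cfg) {
  map <- locus_map(cfg)
  L <- cfg$n_loci
  minfo <- .map_info(cfg, map)
  sizes <- c(rep(cfg$hist_pop_size, cfg$n_hist_generations), cfg$hist_expansion)
  N <- sizes[1L]
  H <- matrix(as.raw(stats::rbinom(L * 2L * N, 1L, 0.5)), nrow = L)
  for (g in seq_along(sizes)[-1L]) {
    N_next <- sizes[g]
    # monoecious random mating with two distinct parents per offspring
    p1 <- sample.int(N, N_next, replace = TRUE)
    p2 <- sample.int(N, N_next, replace = TRUE)
    clash <- p1 == p2
    while (any(clash)) {
      p2[clash] <- sample.int(N, sum(clash), replace = TRUE)
      clash <- p1 == p2
    }
    H <- .make_generation(H, p1, H, p2, minfo, L)
    H <- .mutate(H, cfg$mutation_rate)
    N <- N_next
  }
  n_f <- cfg$n_founder_males + cfg$n_founder_females
  pick <- sample.int(N, n_f)
  cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  founders <- structure(list(
    haplotypes = H[, cols, drop = FALSE],
    map = map,
    ids = sprintf("F_%05d", seq_len(n_f)),
    sex = rep(c("M", "F"), c(cfg$n_founder_males, cfg$n_founder_females)),
    n = n_f
  ), class = "founder_pop")
  founders
}

#' @export
print.founder_pop <- function(x, ...) {
  p <- allele_freq(x)
  cat(sprintf("Founder population: %d individuals (%d M / %d F), %d loci\n",
              x$n, sum(x$sex == "M"), sum(x$sex == "F"), nrow(x$map)))
  cat(sprintf("  monomorphic loci: %d (%.1f%%)\n",
              sum(p == 0 | p == 1), 100 * mean(p == 0 | p == 1)))
  invisible(x)
}

#' @export
allele_freq.founder_pop <- function(x, ids = NULL) {
  H <- x$haplotypes
  if (!is.null(ids)) {
    j <- match(ids, x$ids)
    if (anyNA(j)) stop("unknown founder ids", call. = FALSE)
    cols <- as.vector(rbind(2L * j - 1L, 2L * j))
    H <- H[, cols, drop = FALSE]
  }
  # raw storage: accumulate row sums in column chunks
  s <- numeric(nrow(H))
  chunks <- split(seq_len(ncol(H)), ceiling(seq_len(ncol(H)) / 512))
  for (ch in chunks)
    s <- s + rowSums(matrix(as.integer(H[, ch, drop = FALSE]), nrow(H)))
  stats::setNames(s / ncol(H), x$map$locus)
}

#' Convert a founder population to a genotype matrix
#'
#' @param x A `"founder_pop"` from [simulate_history()].
#' @return A [geno_matrix()] of founder dosages.
#' @export
as_geno_matrix <- function(x) {
  stopifnot(inherits(x, "founder_pop"))
  d <- .dosages_from_hap(x$haplotypes)
  rownames(d) <- x$ids
  geno_matrix(d, x$map)
}

#' Sample QTL positions and effects
#'
#' Picks `n_qtl` loci uniformly from the locus grid and flags them as QTL;
#' the remaining loci form the SNP panel, so QTL and SNP positions never
#' coincide and QTL are excluded from every marker panel downstream. Effect
#' magnitudes are i.i.d. Gamma(`qtl_gamma_shape`, scale `qtl_gamma_scale`);
#' each sign is +1 or -1 with probability one half.
#'
#' @param config A [sim_config()].
#' @param founders A `"founder_pop"` from [simulate_history()].
#' @return An object of class `"qtl_set"`: data frame of QTL (locus, position,
#'   signed effect) with the locus indices as attribute `idx`.
#' @export
sample_qtl <- function(config, founders) {
  validate_sim_config(config)
  stopifnot(inherits(founders, "founder_pop"))
  L <- nrow(founders$map)
  if (config$n_qtl > L)
    stop("cannot place ", config$n_qtl, " QTL on ", L,
         " loci without overlapping the SNP panel", call. = FALSE)
  if (config$n_qtl == 0L) {
    qtl <- data.frame(locus = character(0L), chrom = integer(0L),
                      pos_cM = numeric(0L), effect = numeric(0L),
                      magnitude = numeric(0L))
    attr(qtl, "idx") <- integer(0L)
    class(qtl) <- c("qtl_set", "data.frame")
    return(qtl)
  }
  idx <- sort(sample.int(L, config$n_qtl))
  magnitude <- stats::rgamma(config$n_qtl, shape = config$qtl_gamma_shape,
                             scale = config$qtl_gamma_scale)
  sign <- sample(c(-1, 1), config$n_qtl, replace = TRUE)
  qtl <- data.frame(
    locus = founders$map$locus[idx],
    chrom = founders$map$chrom[idx],
    pos_cM = founders$map$pos_cM[idx],
    effect = sign * magnitude,
    magnitude = magnitude,
    stringsAsFactors = FALSE
  )
  attr(qtl, "idx") <- idx
  class(qtl) <- c("qtl_set", "data.frame")
  qtl
}

# Raw (uncentered) true breeding values of the individuals in haplotype store H.
.raw_tbv <- function(H, qtl) {
  idx <- attr(qtl, "idx")
  if (length(idx) == 0L) return(rep(0, ncol(H) / 2L))
  Hq <- matrix(as.integer(H[idx, , drop = FALSE]), nrow = length(idx))
  odd <- seq.int(1L, ncol(Hq), by = 2L)
  Dq <- Hq[, odd, drop = FALSE] + Hq[, odd + 1L, drop = FALSE]
  drop(crossprod(Dq, qtl$effect))
}

#' Scale QTL effects and the residual to the target heritability
#'
#' The trait is constrained to a fixed heritability and phenotypic variance
#' (defaults 0.3 and 1). Because the genetic variance realized by a finite
#' QTL sample is random, all QTL effects are rescaled by a common factor so
#' that the empirical variance of founder breeding values equals
#' `h2_target * vp_target` exactly, and the residual standard deviation is
#' then `sqrt(vp_target * (1 - h2_target))`. This keeps both targets exact in
#' expectation for the randomly mated base generation.
#'
#' @param config A [sim_config()].
#' @param qtl A `"qtl_set"` from [sample_qtl()].
#' @param founders A `"founder_pop"` from [simulate_history()].
#' @return An object of class `"resid_scale"`: list with `sigma_e` (residual
#'   SD), `qtl` (the rescaled QTL set), `scale_factor`, `sigma_g2_raw` (the
#'   pre-scaling genetic variance) and `tbv_center` (centering constant so
#'   breeding values average zero in the founders).
#' @export
scale_residual <- function(config, qtl, founders) {
  validate_sim_config(config)
  stopifnot(inherits(founders, "founder_pop"))
  g <- .raw_tbv(founders$haplotypes, qtl)
  sigma_g2 <- stats::var(g)
  if (sigma_g2 == 0 && config$h2_target > 0)
    stop("founder genetic variance is zero; cannot reach a positive ",
         "heritability (no segregating QTL?)", call. = FALSE)
  target <- config$h2_target * config$vp_target
  fac <- sqrt(target / sigma_g2)
  qtl$effect <- qtl$effect * fac
  qtl$magnitude <- qtl$magnitude * fac
  sigma_e <- sqrt(config$vp_target * (1 - config$h2_target))
  structure(list(
    sigma_e = sigma_e,
    qtl = qtl,
    scale_factor = fac,
    sigma_g2_raw = sigma_g2,
    tbv_center = mean(g) * fac
  ), class = "resid_scale")
}

#' Breed the base and selected generations
#'
#' Produces generation G0 (random mating among the founders) and then
#' `n_offspring_generations` further generations (G1..G7 by default) in which
#' the parents are drawn from sire and dam pools under truncation selection.
#' After each generation a fraction `male_replacement` of the sire pool and
#' `female_replacement` of the dam pool is replaced by the top-ranking
#' candidates of that generation; ranking uses the rule in
#' `config$selection`. Matings are random within the pools, one progeny per
#' mating, and offspring sex is male with probability `sex_ratio`.
#'
#' Phenotypes are `trait_mean + TBV + N(0, sigma_e^2)`; the pedigree-index
#' EBV used for ranking is `h2 * (phenotype - generation mean) + 0.5 *
#' (sire EBV + dam EBV)` (founders start at EBV 0).
#'
#' @param config A [sim_config()].
#' @param founders A `"founder_pop"`.
#' @param qtl A (scaled) `"qtl_set"`; see [scale_residual()].
#' @param sigma_e Residual standard deviation.
#' @param keep_genotypes Integer vector of generation numbers whose genotype
#'   matrices are retained (genotypes of other generations are discarded to
#'   bound memory), or `"all"`.
#' @param tbv_center Centering constant for breeding values; defaults to the
#'   founder mean raw breeding value.
#' @return An object of class `"bred_pop"`: `records` (one row per animal:
#'   id, sire, dam, sex, generation, tbv, phenotype, ebv; founders appear as
#'   generation -1 with missing phenotype) and `geno`, a named list of
#'   [geno_matrix()] objects (`"G0"`, `"G6"`, ...) for the kept generations.
#' @export
breed <- function(config, founders, qtl, sigma_e,
                  keep_genotypes = c(6L, 7L), tbv_center = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(founders, "founder_pop"))
  if (sigma_e < 0) stop("'sigma_e' must be >= 0", call. = FALSE)
  cfg <- config
  L <- nrow(founders$map)
  minfo <- .map_info(cfg, founders$map)
  map <- founders$map
  map$is_qtl[attr(qtl, "idx")] <- TRUE
  if (is.null(tbv_center)) tbv_center <- mean(.raw_tbv(founders$haplotypes, qtl))
  keep_all <- identical(keep_genotypes, "all")
  if (keep_all) keep_genotypes <- 0:cfg$n_offspring_generations

  m_idx <- which(founders$sex == "M")
  f_idx <- which(founders$sex == "F")
  if (length(m_idx) == 0L || length(f_idx) == 0L)
    stop("selected parent pool is empty", call. = FALSE)
  hap_cols <- function(j) as.vector(rbind(2L * j - 1L, 2L * j))
  SH <- founders$haplotypes[, hap_cols(m_idx), drop = FALSE]
  DH <- founders$haplotypes[, hap_cols(f_idx), drop = FALSE]
  s_ids <- founders$ids[m_idx]; d_ids <- founders$ids[f_idx]
  s_ebv <- numeric(length(m_idx)); d_ebv <- numeric(length(f_idx))
  nm <- length(m_idx); nf <- length(f_idx)

  records <- list(data.frame(
    id = founders$ids, sire = NA_character_, dam = NA_character_,
    sex = founders$sex, generation = -1L,
    tbv = .raw_tbv(founders$haplotypes, qtl) - tbv_center,
    phenotype = NA_real_, ebv = 0, stringsAsFactors = FALSE))
  geno <- list()

  for (g in 0:cfg$n_offspring_generations) {
    n_off <- cfg$offspring_per_generation
    s_pick <- sample.int(nm, n_off, replace = TRUE)
    d_pick <- sample.int(nf, n_off, replace = TRUE)
    H <- .make_generation(SH, s_pick, DH, d_pick, minfo, L)
    sex <- ifelse(stats::runif(n_off) < cfg$sex_ratio, "M", "F")
    tbv <- .raw_tbv(H, qtl) - tbv_center
    phen <- cfg$trait_mean + tbv +
      if (sigma_e > 0) stats::rnorm(n_off, 0, sigma_e) else 0
    ebv <- switch(cfg$selection,
      ebv = cfg$h2_target * (phen - mean(phen)) +
        0.5 * (s_ebv[s_pick] + d_ebv[d_pick]),
      phenotype = phen,
      random = numeric(n_off))
    ids <- sprintf("G%d_%05d", g, seq_len(n_off))
    records[[length(records) + 1L]] <- data.frame(
      id = ids, sire = s_ids[s_pick], dam = d_ids[d_pick], sex = sex,
      generation = g, tbv = tbv, phenotype = phen, ebv = ebv,
      stringsAsFactors = FALSE)
    if (g %in% keep_genotypes) {
      d <- .dosages_from_hap(H)
      rownames(d) <- ids
      geno[[paste0("G", g)]] <- geno_matrix(d, map)
    }
    if (g < cfg$n_offspring_generations) {
      upd <- .update_pool(SH, s_ids, s_ebv, H, ids, ebv, sex == "M",
                          cfg$male_replacement, cfg$selection, hap_cols)
      SH <- upd$H; s_ids <- upd$ids; s_ebv <- upd$ebv; nm <- length(s_ids)
      upd <- .update_pool(DH, d_ids, d_ebv, H, ids, ebv, sex == "F",
                          cfg$female_replacement, cfg$selection, hap_cols)
      DH <- upd$H; d_ids <- upd$ids; d_ebv <- upd$ebv; nf <- length(d_ids)
    }
  }
  structure(list(records = do.call(rbind, records), geno = geno, map = map),
            class = "bred_pop")
}

# Replace a fraction of a parent pool with the top-ranking candidates of the
# newest generation. Ties and "random" selection resolve by candidate order.
.update_pool <- function(PH, p_ids, p_ebv, H, ids, ebv, is_cand, frac,
                         selection, hap_cols) {
  cand <- which(is_cand)
  if (length(cand) == 0L)
    stop("selected parent pool is empty: no replacement candidates of the ",
         "required sex", call. = FALSE)
  n_pool <- length(p_ids)
  n_new <- min(round(frac * n_pool), length(cand))
  if (n_new == 0L) return(list(H = PH, ids = p_ids, ebv = p_ebv))
  take <- if (selection == "random") sample(cand, n_new)
          else cand[order(-ebv[cand])][seq_len(n_new)]
  keep <- order(-p_ebv)[seq_len(n_pool - n_new)]
  list(H = cbind(PH[, hap_cols(keep), drop = FALSE],
                 H[, hap_cols(take), drop = FALSE]),
       ids = c(p_ids[keep], ids[take]),
       ebv = c(p_ebv[keep], ebv[take]))
}

#' Run the full simulation: history, QTL, scaling, breeding
#'
#' Convenience wrapper chaining [simulate_history()], [sample_qtl()],
#' [scale_residual()] and [breed()] under a single seed.
#'
#' @param config A [sim_config()].
#' @param keep_genotypes Generations whose genotype matrices to keep
#'   (default G6 and G7, the training and validation generations), or
#'   `"all"`.
#' @return An object of class `"gs_sim"`: the configuration, pedigree and
#'   phenotype `records`, kept genotype matrices (`geno`), the scaled QTL
#'   set, residual SD, locus map, founder allele frequencies, and the mean
#'   adjacent-marker r-squared among founders (`r2_adjacent`).
#' @examples
#' cfg <- sim_config(n_snp = 300, n_qtl = 20, n_hist_generations = 10,
#'                   hist_pop_size = 40, hist_expansion = 60,
#'                   n_founder_males = 8, n_founder_females = 40,
#'                   offspring_per_generation = 100,
#'                   n_offspring_generations = 3, seed = 11)
#' sim <- simulate_population(cfg, keep_genotypes = c(2, 3))
#' summary(sim)
#' @export
simulate_population <- function(config, keep_genotypes = c(6L, 7L)) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  founders <- .simulate_history_impl(config)
  qtl <- sample_qtl(config, founders)
  if (config$n_qtl > 0L) {
    sc <- scale_residual(config, qtl, founders)
  } else {
    sc <- list(sigma_e = sqrt(config$vp_target), qtl = qtl,
               scale_factor = 1, sigma_g2_raw = 0, tbv_center = 0)
  }
  fg <- as_geno_matrix(founders)
  fg$map$is_qtl[attr(qtl, "idx")] <- TRUE
  r2 <- adjacent_r2(fg)
  founder_freq <- allele_freq(founders)
  pop <- breed(config, founders, sc$qtl, sc$sigma_e, keep_genotypes,
               sc$tbv_center)
  structure(list(
    config = config, records = pop$records, geno = pop$geno,
    qtl = sc$qtl, sigma_e = sc$sigma_e, scale_factor = sc$scale_factor,
    map = pop$map, founder_freq = founder_freq, r2_adjacent = r2
  ), class = "gs_sim")
}

#' @export
print.gs_sim <- function(x, ...) {
  gens <- sort(unique(x$records$generation))
  cat(sprintf("Simulated breeding population: %d animals over generations %s\n",
              nrow(x$records), paste(range(gens), collapse = "..")))
  cat(sprintf("  %d SNPs + %d QTL; genotypes kept for: %s\n",
              sum(!x$map$is_qtl), sum(x$map$is_qtl),
              paste(names(x$geno), collapse = ", ")))
  cat(sprintf("  residual SD %.3f; founder adjacent-marker r2 %.3f\n",
              x$sigma_e, x$r2_adjacent))
  invisible(x)
}

#' @export
summary.gs_sim <- function(object, ...) {
  rec <- object$records[object$records$generation >= 0L, ]
  agg <- do.call(rbind, lapply(split(rec, rec$generation), function(d) {
    data.frame(generation = d$generation[1L], n = nrow(d),
               mean_tbv = mean(d$tbv), var_tbv = stats::var(d$tbv),
               var_phen = stats::var(d$phenotype),
               realized_h2 = stats::var(d$tbv) / stats::var(d$phenotype))
  }))
  rownames(agg) <- NULL
  structure(list(by_generation = agg, r2_adjacent = object$r2_adjacent,
                 sigma_e = object$sigma_e), class = "summary.gs_sim")
}

#' @export
print.summary.gs_sim <- function(x, ...) {
  cat("Per-generation trait summary:\n")
  print(x$by_generation, digits = 3)
  cat(sprintf("founder adjacent-marker r2: %.3f; residual SD: %.3f\n",
              x$r2_adjacent, x$sigma_e))
  invisible(x)
}
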