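# Nei fixation-index scan contrasting the phenotypic tails of the training
# generation. Per locus, with subpopulation frequencies p_S1 and p_S2 and the
# pooled-tail frequency p:
#   H_T = 2 p q,   H_S = (n1 H_S1 + n2 H_S2) / (n1 + n2),  H_Si = 2 p_Si q_Si
#   FST = (H_T - H_S) / H_T           (0 when the pooled locus is monomorphic)

#' Split individuals into phenotypic tail subpopulations
#'
#' Ranks phenotypes and assigns the lowest `floor(q_low * n)` individuals to
#' the low tail S1 and the highest `floor((1 - q_high) * n)` to the high tail
#' S2; everyone else is S0. Ties at a quantile boundary are resolved by
#' ascending id order so the tail counts are exact and the split is
#' reproducible.
#'
#' @param phenotypes Numeric vector of phenotypes, without missing values.
#' @param ids Individual ids, parallel to `phenotypes` (default
#'   `names(phenotypes)`).
#' @param q_low,q_high Quantile cut points, `0 < q_low < q_high < 1`
#'   (defaults 0.05 and 0.95).
#' @return An object of class `"subpop_split"`: `s1_ids`, `s2_ids`, `s0_ids`,
#'   the quantiles, and `n`.
#' @examples
#' set.seed(1)
#' y <- stats::setNames(rnorm(100), sprintf("id%03d", 1:100))
#' sp <- partition_tails(y)
#' lengths(sp[c("s1_ids", "s2_ids")])
#' @export
partition_tails <- function(phenotypes, ids = names(phenotypes),
                            q_low = 0.05, q_high = 0.95) {
  if (anyNA(phenotypes)) stop("phenotypes contain missing values", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(phenotypes))
  if (length(ids) != length(phenotypes))
    stop("'ids' and 'phenotypes' lengths differ", call. = FALSE)
  if (!(q_low > 0 && q_low < q_high && q_high < 1))
    stop("need 0 < q_low < q_high < 1", call. = FALSE)
  n <- length(phenotypes)
  n1 <- floor(q_low * n + 1e-9)       # guard floating-point dust in q * n
  n2 <- floor((1 - q_high) * n + 1e-9)
  if (n1 < 2L || n2 < 2L)
    stop("fewer than 2 individuals per tail; enlarge the sample or the tails",
         call. = FALSE)
  if (stats::var(phenotypes) == 0)
    stop("degenerate phenotypes: all values identical, tails are undefined",
         call. = FALSE)
  ord <- order(phenotypes, ids)
  s1 <- ids[ord[seq_len(n1)]]
  s2 <- ids[ord[seq.int(n - n2 + 1L, n)]]
  structure(list(
    s1_ids = s1, s2_ids = s2,
    s0_ids = ids[ord[seq.int(n1 + 1L, n - n2)]],
    q_low = q_low, q_high = q_high, n = n
  ), class = "subpop_split")
}

#' @export
print.subpop_split <- function(x, ...) {
  cat(sprintf("Tail split at (%.2f, %.2f) quantiles of %d phenotypes:\n",
              x$q_low, x$q_high, x$n))
  cat(sprintf("  S1 (low) %d, S0 %d, S2 (high) %d\n",
              length(x$s1_ids), length(x$s0_ids), length(x$s2_ids)))
  invisible(x)
}

#' Allele frequencies within a subpopulation
#'
#' @param geno A [geno_matrix()].
#' @param ids Ids of the subpopulation members.
#' @return Named vector of per-locus frequencies (mean dosage / 2).
#' @export
subpop_freqs <- function(geno, ids) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(ids) == 0L) stop("empty id set", call. = FALSE)
  allele_freq(geno, ids = ids)
}

#' Per-locus fixation-index scores between phenotypic tails
#'
#' Computes the Nei FST at every locus of `geno` from the two tail
#' subpopulations of `split`. The total-population frequency entering H_T is
#' the pooled S1-union-S2 frequency, i.e. the size-weighted mean of the tail
#' frequencies; the middle subpopulation S0 does not contribute. Loci that
#' are monomorphic in the pooled tails carry no differentiation information
#' and get FST = 0.
#'
#' @param geno A [geno_matrix()] holding at least the individuals of both
#'   tails (typically the SNP panel of the training generation, see
#'   [snp_panel()]).
#' @param split A [partition_tails()] result.
#' @return An object of class `"fst_scores"`: a data frame with one row per
#'   locus (`locus`, `chrom`, `pos_cM`, `p_s1`, `p_s2`, `p`, `h_t`, `h_s`,
#'   `fst`) and attributes `n_s1`, `n_s2`.
#' @export
fst_scores <- function(geno, split) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(split, "subpop_split"))
  if (length(split$s1_ids) == 0L || length(split$s2_ids) == 0L)
    stop("both tails must be nonempty", call. = FALSE)
  n1 <- length(split$s1_ids)
  n2 <- length(split$s2_ids)
  p1 <- subpop_freqs(geno, split$s1_ids)
  p2 <- subpop_freqs(geno, split$s2_ids)
  p <- (n1 * p1 + n2 * p2) / (n1 + n2)
  h_t <- 2 * p * (1 - p)
  h_s <- (n1 * 2 * p1 * (1 - p1) + n2 * 2 * p2 * (1 - p2)) / (n1 + n2)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, 0)
  fst <- pmin(pmax(fst, 0), 1)  # guard floating-point dust at the bounds
  out <- data.frame(
    locus = geno$map$locus, chrom = geno$map$chrom, pos_cM = geno$map$pos_cM,
    p_s1 = unname(p1), p_s2 = unname(p2), p = unname(p),
    h_t = unname(h_t), h_s = unname(h_s), fst = unname(fst),
    stringsAsFactors = FALSE
  )
  attr(out, "n_s1") <- n1
  attr(out, "n_s2") <- n2
  class(out) <- c("fst_scores", "data.frame")
  out
}

#' Top-k loci by fixation-index score
#'
#' @param scores An `"fst_scores"` data frame (or any data frame with
#'   `locus`, `chrom`, `pos_cM` and `fst` columns).
#' @param k Number of loci to select, `1 <= k <= nrow(scores)`.
#' @return Character vector of the k locus ids with the largest FST, in
#'   genome order; ties at the score cutoff are broken by genome position
#'   for determinism.
#' @export
fst_top_k <- function(scores, k) {
  if (length(k) != 1L || is.na(k) || k <= 0)
    stop("'k' must be a positive count", call. = FALSE)
  if (k > nrow(scores))
    stop("'k' exceeds the number of scored loci", call. = FALSE)
  ord <- order(-scores$fst, scores$chrom, scores$pos_cM)
  sel <- sort(ord[seq_len(k)])
  scores$locus[sel]
}
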