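#' Genotype matrix container
#'
#' A light container pairing an individuals-by-loci allele-dosage matrix with
#' its locus map. Dosages count copies of the reference allele (0, 1 or 2).
#'
#' @param dosages Integer matrix, individuals in rows (rownames are ids),
#'   loci in columns (colnames are locus ids).
#' @param map Data frame with one row per locus: columns `locus`, `chrom`,
#'   `pos_cM`, `is_qtl`, aligned with the columns of `dosages`.
#' @return An object of class `"geno_matrix"`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 2L), 2, 2,
#'             dimnames = list(c("a", "b"), c("L1", "L2")))
#' m <- data.frame(locus = c("L1", "L2"), chrom = 1L, pos_cM = c(1, 2),
#'                 is_qtl = FALSE)
#' g <- geno_matrix(d, m)
#' allele_freq(g)
#' @export
geno_matrix <- function(dosages, map) {
  if (!is.matrix(dosages)) stop("'dosages' must be a matrix", call. = FALSE)
  storage.mode(dosages) <- "integer"
  if (nrow(map) != ncol(dosages))
    stop("locus map does not match genotype columns", call. = FALSE)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%04d", seq_len(nrow(dosages)))
  colnames(dosages) <- map$locus
  rng <- range(dosages)
  if (rng[1L] < 0L || rng[2L] > 2L)
    stop("dosages must lie in {0, 1, 2}", call. = FALSE)
  structure(list(dosages = dosages, map = map), class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci (%d QTL, %d SNP)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$map$is_qtl),
              sum(!x$map$is_qtl)))
  p <- allele_freq(x)
  cat(sprintf("  monomorphic loci: %d; mean allele frequency %.3f\n",
              sum(p == 0 | p == 1), mean(p)))
  invisible(x)
}

#' Per-locus reference allele frequencies
#'
#' Frequencies are half the column means of the dosage matrix.
#'
#' @param x A [geno_matrix()] or an object with a dosage accessor.
#' @param ids Optional subset of individual ids to compute frequencies over.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_freq <- function(x, ids = NULL) UseMethod("allele_freq")

#' @export
allele_freq.geno_matrix <- function(x, ids = NULL) {
  d <- x$dosages
  if (!is.null(ids)) {
    if (!all(ids %in% rownames(d)))
      stop("some ids are absent from the genotype matrix", call. = FALSE)
    if (length(ids) == 0L) stop("empty id set", call. = FALSE)
    d <- d[ids, , drop = FALSE]
  }
  colMeans(d) / 2
}

#' @export
allele_freq.default <- function(x, ids = NULL) {
  if (!is.matrix(x)) stop("cannot compute allele frequencies", call. = FALSE)
  colMeans(x) / 2
}

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param ids Individual ids to keep (default all).
#' @param loci Locus ids or column indices to keep (default all).
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(x, ids = NULL, loci = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  d <- x$dosages
  map <- x$map
  if (!is.null(ids)) {
    if (!all(ids %in% rownames(d)))
      stop("some ids are absent from the genotype matrix", call. = FALSE)
    d <- d[ids, , drop = FALSE]
  }
  if (!is.null(loci)) {
    j <- if (is.character(loci)) match(loci, map$locus) else as.integer(loci)
    if (anyNA(j)) stop("unknown loci requested", call. = FALSE)
    d <- d[, j, drop = FALSE]
    map <- map[j, , drop = FALSE]
  }
  geno_matrix(d, map)
}

#' SNP panel of a genotype matrix
#'
#' Drops QTL columns: QTL are simulated as causal but not genotyped, so every
#' marker-based computation (FST scan, relationship matrix) operates on the
#' SNP panel only.
#'
#' @param x A [geno_matrix()].
#' @return A [geno_matrix()] restricted to loci with `is_qtl == FALSE`.
#' @export
snp_panel <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  subset_geno(x, loci = which(!x$map$is_qtl))
}

#' Squared correlation between adjacent SNP pairs
#'
#' Summarizes linkage disequilibrium as the mean r-squared between dosages of
#' adjacent SNPs on the same chromosome. Monomorphic loci are skipped.
#'
#' @param x A [geno_matrix()].
#' @param max_pairs Cap on the number of adjacent pairs sampled.
#' @return Mean adjacent-pair r-squared (scalar).
#' @export
adjacent_r2 <- function(x, max_pairs = 2000L) {
  stopifnot(inherits(x, "geno_matrix"))
  snp <- which(!x$map$is_qtl)
  p <- allele_freq(x)
  poly <- p > 0 & p < 1
  snp <- snp[poly[snp]]
  if (length(snp) < 2L) return(NA_real_)
  same_chrom <- x$map$chrom[snp[-length(snp)]] == x$map$chrom[snp[-1L]]
  i1 <- snp[-length(snp)][same_chrom]
  i2 <- snp[-1L][same_chrom]
  if (length(i1) > max_pairs) {
    keep <- round(seq(1L, length(i1), length.out = max_pairs))
    i1 <- i1[keep]; i2 <- i2[keep]
  }
  r2 <- vapply(seq_along(i1), function(k)
    stats::cor(x$dosages[, i1[k]], x$dosages[, i2[k]])^2, numeric(1))
  mean(r2)
}
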