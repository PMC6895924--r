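# Z diag(w) Z' accumulated over column chunks, so the weighted copy of Z
# never exists in full.
.weighted_gram <- function(Z, w = NULL, chunk = 2048L) {
  n <- nrow(Z)
  idx <- seq_len(ncol(Z))
  K <- matrix(0, n, n)
  for (ch in unname(split(idx, ceiling(idx / chunk)))) {
    Zc <- Z[, ch, drop = FALSE]
    if (!is.null(w)) Zc <- Zc * rep(sqrt(w[ch]), each = n)
    K <- K + tcrossprod(Zc)
  }
  K
}

# Weighted VanRaden genomic relationship matrix:
#   Z = M - 2P  (dosages centered by twice the reference allele frequency)
#   G = Z diag(w) Z' / (2 * sum_i w_i p_i q_i)
# With all weights 1 this is VanRaden's first method. The weighted
# normalization keeps the expected diagonal near 1 under any weight budget
# and makes G invariant to rescaling all weights by a positive constant.

#' Build a (weighted) VanRaden genomic relationship matrix
#'
#' @param geno A [geno_matrix()] over the individuals entering the matrix
#'   (typically training plus validation animals, SNP panel only).
#' @param loci Panel locus ids or indices (default: all loci of `geno`).
#' @param weights Per-locus nonnegative relative weights aligned with the
#'   panel (named vectors are matched by locus id); `NULL` means equal
#'   weights.
#' @param freqs Reference allele frequencies used for centering and
#'   normalization: `NULL` (computed from the individuals of `geno`) or a
#'   named vector, e.g. base-generation frequencies.
#' @param blend Weight of the identity added for numerical stability:
#'   `G* = (1 - blend) G + blend I`. Default 0 (no blending); model fitting
#'   blends at inversion time instead, see [gblup()].
#' @return An object of class `"grm"`: `values` (symmetric n x n matrix with
#'   id dimnames), `ids`, and `meta` (panel size, monomorphic loci dropped,
#'   normalization constant, blend).
#' @examples
#' d <- matrix(c(2L, 0L), 2, 1, dimnames = list(c("a", "b"), "L1"))
#' m <- data.frame(locus = "L1", chrom = 1L, pos_cM = 1, is_qtl = FALSE)
#' build_grm(geno_matrix(d, m))$values  # [[2,-2],[-2,2]]
#' @export
build_grm <- function(geno, loci = NULL, weights = NULL, freqs = NULL,
                      blend = 0) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (blend < 0 || blend >= 1) stop("'blend' must lie in [0, 1)", call. = FALSE)
  g <- if (is.null(loci)) geno else subset_geno(geno, loci = loci)
  M <- g$dosages
  panel <- colnames(M)
  n <- nrow(M)

  if (is.null(freqs)) {
    p <- colMeans(M) / 2
  } else {
    if (is.null(names(freqs)))
      stop("'freqs' must be named by locus", call. = FALSE)
    if (!all(panel %in% names(freqs)))
      stop("'freqs' does not cover the panel", call. = FALSE)
    p <- freqs[panel]
  }
  if (is.null(weights)) {
    w <- rep(1, length(panel))
  } else {
    if (!is.null(names(weights))) {
      if (!all(panel %in% names(weights)))
        stop("'weights' does not cover the panel", call. = FALSE)
      w <- as.numeric(weights[panel])
    } else {
      if (length(weights) != length(panel))
        stop("'weights' length does not match the panel", call. = FALSE)
      w <- as.numeric(weights)
    }
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)

  poly <- p > 0 & p < 1
  dropped <- sum(!poly)
  if (dropped > 0L) {
    message(dropped, " monomorphic loci dropped from the relationship panel")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]; w <- w[poly]; panel <- panel[poly]
  }
  if (length(panel) == 0L) stop("no polymorphic loci in the panel", call. = FALSE)

  denom <- 2 * sum(w * p * (1 - p))
  if (denom <= 0)
    stop("normalization constant is not positive (all weight on ",
         "monomorphic loci?)", call. = FALSE)
  Z <- M - matrix(2 * p, n, length(p), byrow = TRUE)
  G <- .weighted_gram(Z, w) / denom
  if (blend > 0) G <- (1 - blend) * G + blend * diag(n)
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(values = G, ids = rownames(M),
                 meta = list(n_loci = length(panel), dropped = dropped,
                             denom = denom, blend = blend)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$ids)
  od <- x$values[upper.tri(x$values)]
  cat(sprintf("Genomic relationship matrix: %d individuals, %d loci\n",
              n, x$meta$n_loci))
  cat(sprintf("  mean diagonal %.3f; off-diagonal mean %.4f, range [%.3f, %.3f]\n",
              mean(diag(x$values)), mean(od), min(od), max(od)))
  if (!is.na(x$meta$blend) && x$meta$blend > 0)
    cat(sprintf("  blended with %.2f * I\n", x$meta$blend))
  invisible(x)
}

#' @export
dim.grm <- function(x) dim(x$values)

#' Histogram of training-by-validation relationships
#'
#' Bins the rectangle of relationship coefficients between two disjoint id
#' sets (training rows, validation columns) into intervals defined by the
#' ordered thresholds, and reports the percentage of entries per bin. Bins
#' are left-open, right-closed: `(-Inf, t1], (t1, t2], ..., (tK, Inf)`.
#'
#' @param grm A `"grm"` object (or bare symmetric matrix with id dimnames).
#' @param row_ids,col_ids Disjoint id sets (e.g. training and validation).
#' @param thresholds Ordered cut points; the default reproduces the
#'   conventional summary at -0.05, -0.03, -0.01, 0.01, 0.03, 0.05.
#' @return An object of class `"offdiag_hist"`: data frame with `bin` labels
#'   and `percent` per bin (summing to 100), plus a `mass_above` attribute
#'   giving the percentage of entries above the largest threshold below
#'   which similarity is conventionally judged (0.03).
#' @export
offdiag_histogram <- function(grm, row_ids, col_ids,
                              thresholds = c(-0.05, -0.03, -0.01,
                                             0.01, 0.03, 0.05)) {
  G <- if (inherits(grm, "grm")) grm$values else grm
  if (length(row_ids) == 0L || length(col_ids) == 0L)
    stop("empty id set", call. = FALSE)
  if (length(intersect(row_ids, col_ids)) > 0L)
    stop("row and column id sets must be disjoint", call. = FALSE)
  if (!all(c(row_ids, col_ids) %in% rownames(G)))
    stop("some ids are absent from the relationship matrix", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing", call. = FALSE)
  v <- as.vector(G[row_ids, col_ids, drop = FALSE])
  breaks <- c(-Inf, thresholds, Inf)
  counts <- table(cut(v, breaks = breaks, right = TRUE))
  labels <- c(sprintf("OD <= %g", thresholds[1L]),
              sprintf("(%g, %g]", thresholds[-length(thresholds)],
                      thresholds[-1L]),
              sprintf("OD > %g", thresholds[length(thresholds)]))
  out <- data.frame(bin = labels, percent = 100 * as.vector(counts) / length(v),
                    stringsAsFactors = FALSE)
  attr(out, "mass_above") <- 100 * mean(v > 0.03)
  class(out) <- c("offdiag_hist", "data.frame")
  out
}
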