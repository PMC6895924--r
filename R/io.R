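# Plain-text interchange formats: PLINK-raw-style dosages, phenotype and
# locus-map CSVs, and long-format relationship matrices.

#' Write genotypes as PLINK-raw-style dosage text
#'
#' One header row (`FID IID` then locus ids), then one row per individual
#' with family id, individual id and the 0/1/2 dosage at each locus.
#'
#' @param geno A [geno_matrix()].
#' @param file Output path.
#' @param fid Family id written in the first column.
#' @return `file`, invisibly.
#' @export
write_plink_raw <- function(geno, file, fid = "FAM1") {
  stopifnot(inherits(geno, "geno_matrix"))
  d <- geno$dosages
  df <- data.frame(FID = fid, IID = rownames(d), d, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, quote = FALSE, sep = " ", row.names = FALSE)
  invisible(file)
}

#' Read PLINK-raw-style dosage text
#'
#' @param file Path written by [write_plink_raw()] (or any whitespace table
#'   with FID/IID columns followed by per-locus dosages).
#' @param map Optional locus map; reconstructed as a single pseudo-chromosome
#'   with unit spacing when absent.
#' @return A [geno_matrix()].
#' @export
read_plink_raw <- function(file, map = NULL) {
  if (!file.exists(file)) stop("cannot read genotype file: ", file, call. = FALSE)
  df <- utils::read.table(file, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("FID", "IID") %in% names(df)[1:2]))
    stop("not a PLINK-raw-style file (missing FID/IID header): ", file,
         call. = FALSE)
  d <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(d) <- df$IID
  if (is.null(map))
    map <- data.frame(locus = colnames(d), chrom = 1L,
                      pos_cM = seq_len(ncol(d)), is_qtl = FALSE,
                      stringsAsFactors = FALSE)
  geno_matrix(d, map)
}

#' Write the phenotype/pedigree table of a simulation
#'
#' @param records Data frame of population records (id, sire, dam, sex,
#'   generation, phenotype, tbv, ...).
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_phenotypes <- function(records, file) {
  cols <- intersect(c("id", "sire", "dam", "sex", "generation", "phenotype",
                      "tbv", "ebv"), names(records))
  utils::write.csv(records[, cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a phenotype/pedigree CSV
#'
#' @param file CSV path with at least columns `id` and `phenotype`.
#' @return Data frame.
#' @export
read_phenotypes <- function(file) {
  if (!file.exists(file)) stop("cannot read phenotype file: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("phenotype file must have 'id' and 'phenotype' columns: ", file,
         call. = FALSE)
  df
}

#' Write the locus map as CSV
#'
#' @param map Locus map data frame (`locus`, `chrom`, `pos_cM`, `is_qtl`).
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_locus_map <- function(map, file) {
  utils::write.csv(map, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export simulated generations to plain-text files
#'
#' Writes, per kept generation, a PLINK-raw-style genotype file
#' (`geno_G<g>.raw`) containing the SNP panel only — QTL are simulated as
#' non-genotyped, so their dosages never leave the simulation; their
#' positions are still recorded in the locus map. Also writes one phenotype
#' CSV (`phenotypes.csv`) and one locus map CSV (`locus_map.csv`) for the
#' whole population. Files round-trip losslessly through
#' [read_plink_raw()] and [read_phenotypes()].
#'
#' @param sim A `"gs_sim"` from [simulate_population()].
#' @param dir Output directory (created if needed).
#' @param generations Generations to export; defaults to the kept ones.
#'   Generations without stored genotypes trigger a warning and no file.
#' @return Character vector of written paths, invisibly.
#' @export
export_population <- function(sim, dir, generations = NULL) {
  stopifnot(inherits(sim, "gs_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kept <- as.integer(sub("^G", "", names(sim$geno)))
  if (is.null(generations)) generations <- kept
  generations <- as.integer(generations)
  missing <- setdiff(generations, kept)
  if (length(missing)) {
    warning("no stored genotypes for generation(s) ",
            paste(missing, collapse = ", "), "; skipped")
    generations <- intersect(generations, kept)
    if (length(generations) == 0L) return(invisible(character(0L)))
  }
  paths <- character(0L)
  if (length(generations) == 0L) {
    warning("empty generation set: no genotype files written")
  } else {
    for (g in generations) {
      p <- file.path(dir, sprintf("geno_G%d.raw", g))
      write_plink_raw(snp_panel(sim$geno[[paste0("G", g)]]), p)
      paths <- c(paths, p)
    }
    p <- file.path(dir, "phenotypes.csv")
    write_phenotypes(sim$records, p)
    paths <- c(paths, p)
    p <- file.path(dir, "locus_map.csv")
    write_locus_map(sim$map, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a relationship matrix as long-format text
#'
#' Lower triangle including the diagonal, one `id1,id2,value` row per pair.
#'
#' @param grm A [build_grm()] result.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_grm <- function(grm, file) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$values
  ids <- grm$ids
  lt <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id1 = ids[lt[, 1L]], id2 = ids[lt[, 2L]],
                   value = G[lt], stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a long-format relationship matrix
#'
#' @param file CSV written by [write_grm()].
#' @return A `"grm"` object.
#' @export
read_grm <- function(file) {
  if (!file.exists(file)) stop("cannot read GRM file: ", file, call. = FALSE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  ids <- unique(c(df$id1, df$id2))
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$value
  G[upper.tri(G)] <- t(G)[upper.tri(G)]
  structure(list(values = G, ids = ids,
                 meta = list(n_loci = NA_integer_, denom = NA_real_,
                             blend = NA_real_, dropped = NA_integer_)),
            class = "grm")
}
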