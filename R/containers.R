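#' Genotype container
#'
#' Bundles a dosage matrix (individuals x SNPs, values 0/1/2 counting copies
#' of allele 1, \code{NA} for missing) with its SNP map and sample ids.
#'
#' @param dosage numeric/integer matrix, individuals in rows, SNPs in columns.
#' @param map data.frame with columns \code{snp}, \code{chr}, \code{bp}
#'   (1-based position), \code{a1}, \code{a2}. Must be sorted by
#'   (\code{chr}, \code{bp}) within chromosome blocks.
#' @param ids character vector of sample ids, one per dosage row.
#' @return An object of class \code{genotype_set}.
#' @export
genotype_set <- function(dosage, map, ids) {
  dosage <- as.matrix(dosage)
  ids <- as.character(ids)
  req <- c("snp", "chr", "bp", "a1", "a2")
  if (!all(req %in% names(map)))
    stop("map must have columns: ", paste(req, collapse = ", "))
  if (nrow(dosage) != length(ids))
    stop("dosage has ", nrow(dosage), " rows but ", length(ids), " ids")
  if (ncol(dosage) != nrow(map))
    stop("dosage has ", ncol(dosage), " columns but map has ", nrow(map), " SNPs")
  if (any(map$bp <= 0)) stop("bp positions must be positive")
  map$snp <- as.character(map$snp)
  map$chr <- as.character(map$chr)
  map$bp <- as.integer(map$bp)
  # positions must be non-decreasing within each chromosome block
  for (ch in unique(map$chr)) {
    b <- map$bp[map$chr == ch]
    if (is.unsorted(b)) stop("bp not sorted within chromosome ", ch)
  }
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok)) stop("dosage values must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(ids, map$snp)
  structure(list(dosage = dosage, map = map, ids = ids),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$ids), "individuals x", nrow(x$map), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$dosage))
  if (nmiss > 0) cat("  missing dosages:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.genotype_set <- function(x) dim(x$dosage)

#' Subset a genotype set by SNPs and/or individuals
#'
#' @param x a \code{genotype_set}.
#' @param snps SNP ids or column indices (default all).
#' @param ids sample ids or row indices (default all).
#' @return A \code{genotype_set} restricted to the selection.
#' @export
subset_snps <- function(x, snps = NULL, ids = NULL) {
  stopifnot(inherits(x, "genotype_set"))
  jj <- if (is.null(snps)) seq_len(nrow(x$map)) else
    if (is.character(snps)) match(snps, x$map$snp) else snps
  if (anyNA(jj)) stop("unknown SNP id(s): ",
                      paste(snps[is.na(jj)], collapse = ", "))
  ii <- if (is.null(ids)) seq_along(x$ids) else
    if (is.character(ids)) match(ids, x$ids) else ids
  if (anyNA(ii)) stop("unknown sample id(s)")
  genotype_set(x$dosage[ii, jj, drop = FALSE], x$map[jj, , drop = FALSE],
               x$ids[ii])
}

#' Phased haplotype panel
#'
#' Stores two haplotypes per sample over a SNP subset, with a population
#' label per sample. Haplotype alleles are coded 0/1 where 1 is allele 1 of
#' the SNP map, so the two haplotype rows of a sample sum to its dosage.
#' Sample i occupies rows 2i-1 and 2i of \code{haps}.
#'
#' @param haps integer matrix of 0/1, (2 x n samples) rows x SNPs columns.
#' @param map SNP map as in \code{\link{genotype_set}}.
#' @param ids character vector of sample ids (half the number of hap rows).
#' @param pop population label per sample (recycled if length 1).
#' @return An object of class \code{phased_panel}.
#' @export
phased_panel <- function(haps, map, ids, pop = "focal") {
  haps <- as.matrix(haps)
  ids <- as.character(ids)
  if (nrow(haps) != 2L * length(ids))
    stop("haps must have exactly two rows per sample")
  if (ncol(haps) != nrow(map)) stop("haps/map dimension mismatch")
  if (!all(haps %in% 0:1)) stop("haplotype alleles must be 0/1")
  map$snp <- as.character(map$snp)
  map$chr <- as.character(map$chr)
  map$bp <- as.integer(map$bp)
  pop <- rep_len(as.character(pop), length(ids))
  rownames(haps) <- paste0(rep(ids, each = 2), c("_1", "_2"))
  structure(list(haps = haps, map = map, ids = ids, pop = pop),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat("phased_panel:", length(x$ids), "samples (",
      nrow(x$haps), "haplotypes ) x", nrow(x$map), "SNPs;",
      "populations:", paste(unique(x$pop), collapse = ", "), "\n")
  invisible(x)
}

#' Dosages from a phased panel
#' @param panel a \code{phased_panel}.
#' @return A \code{genotype_set} with dosage = sum of the two haplotypes.
#' @export
panel_dosage <- function(panel) {
  stopifnot(inherits(panel, "phased_panel"))
  n <- length(panel$ids)
  d <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
       panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  genotype_set(d, panel$map, panel$ids)
}

#' Genomic relatedness matrix container
#'
#' @param mat symmetric relatedness matrix.
#' @param ids sample ids matching rows/columns.
#' @param m number of SNPs used to build the matrix.
#' @param freq_source tag recording where allele frequencies came from.
#' @return An object of class \code{grm}.
#' @export
new_grm <- function(mat, ids, m, freq_source = "sample") {
  mat <- as.matrix(mat)
  ids <- as.character(ids)
  if (nrow(mat) != ncol(mat) || nrow(mat) != length(ids))
    stop("GRM dimensions must match id count")
  if (any(!is.finite(mat))) stop("GRM entries must be finite")
  if (max(abs(mat - t(mat))) > 1e-8) stop("GRM must be symmetric")
  mat <- (mat + t(mat)) / 2
  if (m < 1) stop("m (SNP count) must be >= 1")
  dimnames(mat) <- list(ids, ids)
  structure(list(mat = mat, ids = ids, m = as.integer(m),
                 freq_source = freq_source), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "individuals, built from", x$m,
      "SNPs (frequencies:", x$freq_source, ")\n")
  od <- x$mat[lower.tri(x$mat)]
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.5f\n",
              mean(diag(x$mat)), mean(od)))
  invisible(x)
}

#' Pedigree constructor with validation
#'
#' @param id,sire,dam individual and parent ids (\code{NA} for unknown).
#' @param sex "F"/"M" per individual.
#' @param birth_year integer birth year per individual.
#' @return A data.frame of class \code{pedigree}.
#' @export
pedigree <- function(id, sire = NA, dam = NA, sex, birth_year) {
  ped <- data.frame(id = as.character(id), sire = as.character(sire),
                    dam = as.character(dam), sex = as.character(sex),
                    birth_year = as.integer(birth_year),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicated individual ids in pedigree")
  validate_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  by <- setNames(ped$birth_year, ped$id)
  sx <- setNames(ped$sex, ped$id)
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    bad <- known & !(p %in% ped$id)
    if (any(bad))
      stop("pedigree references unknown ", col, " id(s): ",
           paste(unique(p[bad]), collapse = ", "))
    if (any(known & by[p] >= ped$birth_year, na.rm = TRUE))
      stop(col, " born in the same year as or after offspring")
    want <- if (col == "sire") "M" else "F"
    if (any(known & sx[p] != want, na.rm = TRUE))
      stop("sex of ", col, " inconsistent with parental role")
  }
  invisible(ped)
}
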