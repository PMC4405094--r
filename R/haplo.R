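# Linkage disequilibrium, haplotype enumeration around focal SNPs, core
# haplotypes, and the haplotype-sharing (HS) length statistic across breed
# panels used to trace trait alleles to an admixture source.

#' Pairwise LD (r-squared) matrix
#'
#' r^2 is the squared Pearson correlation of allele indicators computed on
#' phased haplotypes when a \code{\link{phased_panel}} is given, otherwise
#' of dosages from a \code{\link{genotype_set}}. Monomorphic SNPs get NA
#' rows/columns.
#'
#' @param x a \code{phased_panel} or \code{genotype_set}.
#' @param snps SNP ids or column indices (default: all).
#' @return symmetric r^2 matrix with unit diagonal for polymorphic SNPs.
#' @export
ld_r2_matrix <- function(x, snps = NULL) {
  if (inherits(x, "phased_panel")) {
    M <- x$haps
    map <- x$map
  } else if (inherits(x, "genotype_set")) {
    M <- x$dosage
    map <- x$map
  } else stop("x must be a phased_panel or genotype_set")
  j <- if (is.null(snps)) seq_len(nrow(map)) else
    if (is.character(snps)) match(snps, map$snp) else snps
  if (anyNA(j)) stop("unknown SNP id(s)")
  if (length(j) < 2) stop("need >= 2 SNPs")
  M <- M[, j, drop = FALSE]
  v <- apply(M, 2, stats::var)
  mono <- is.na(v) | v == 0
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s): NA rows in the r^2 matrix")
  r2 <- matrix(NA_real_, length(j), length(j),
               dimnames = list(map$snp[j], map$snp[j]))
  ok <- which(!mono)
  if (length(ok) >= 2)
    r2[ok, ok] <- suppressWarnings(stats::cor(M[, ok, drop = FALSE]))^2
  diag(r2)[!mono] <- 1
  r2
}

#' Enumerate haplotypes over a region
#'
#' Counts distinct allele strings across all chromosomes of the panel over
#' the given SNPs; extremely rare haplotypes (count below \code{min_count})
#' are dropped.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @param snps SNP ids or indices spanning the region.
#' @param min_count retention threshold (default 5: haplotypes observed
#'   fewer than 5 times are dropped).
#' @return data.frame(haplotype, count) sorted by descending count;
#'   attribute \code{"n_chromosomes"} records the pre-filter total.
#' @export
enumerate_haplotypes <- function(panel, snps = NULL, min_count = 5L) {
  stopifnot(inherits(panel, "phased_panel"))
  j <- if (is.null(snps)) seq_len(nrow(panel$map)) else
    if (is.character(snps)) match(snps, panel$map$snp) else snps
  if (length(j) == 0 || anyNA(j)) stop("empty or unknown SNP region")
  H <- panel$haps[, j, drop = FALSE]
  strs <- apply(H, 1, paste, collapse = "")
  tab <- sort(table(strs), decreasing = TRUE)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  keep <- out$count >= min_count
  if (!any(keep))
    warning("no haplotype reaches the retention threshold of ", min_count)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_chromosomes") <- nrow(H)
  attr(res, "pre_filter") <- out
  res
}

# member SNP columns of a core: 3 upstream + focal + 2 downstream (the
# "six SNPs" arithmetic includes the focal SNP itself)
core_member_cols <- function(map, focal_snp, upstream = 3L, downstream = 2L) {
  jf <- match(focal_snp, map$snp)
  if (is.na(jf)) stop("unknown focal SNP: ", focal_snp)
  ch <- map$chr[jf]
  jc <- which(map$chr == ch)
  pos <- match(jf, jc)
  if (pos - upstream < 1 || pos + downstream > length(jc))
    stop("focal SNP too close to the chromosome end: ", pos - 1,
         " SNP(s) upstream and ", length(jc) - pos,
         " downstream available, need ", upstream, "+", downstream)
  jc[(pos - upstream):(pos + downstream)]
}

#' Extract core haplotypes around a focal SNP
#'
#' A core haplotype is the allele string over the focal SNP and its flanks
#' (by default 3 SNPs upstream and 2 downstream, i.e. six SNPs in total
#' including the focal SNP). Distinct strings observed at least
#' \code{min_count} times in the panel are retained and labelled by their
#' allele at the focal SNP.
#'
#' @param panel a \code{\link{phased_panel}} (typically the focal
#'   population).
#' @param focal_snp SNP id.
#' @param upstream,downstream flank sizes in SNPs.
#' @param min_count retention threshold (default 5).
#' @param pop restrict counting to these population labels (default: all).
#' @return data.frame of class \code{core_haplotypes}: core (index),
#'   haplotype (allele string), focal_allele (0/1), count, bp_start, bp_end;
#'   attributes \code{"snps"} (member SNP ids) and \code{"focal_snp"}.
#' @export
extract_core_haplotypes <- function(panel, focal_snp, upstream = 3L,
                                    downstream = 2L, min_count = 5L,
                                    pop = NULL) {
  stopifnot(inherits(panel, "phased_panel"))
  j <- core_member_cols(panel$map, focal_snp, upstream, downstream)
  rows <- if (is.null(pop)) seq_len(nrow(panel$haps)) else
    which(rep(panel$pop, each = 2) %in% pop)
  H <- panel$haps[rows, j, drop = FALSE]
  strs <- apply(H, 1, paste, collapse = "")
  tab <- sort(table(strs), decreasing = TRUE)
  keep <- as.integer(tab) >= min_count
  strs_k <- names(tab)[keep]
  fa <- substr(strs_k, upstream + 1L, upstream + 1L)
  out <- data.frame(core = seq_along(strs_k), haplotype = strs_k,
                    focal_allele = as.integer(fa),
                    count = as.integer(tab)[keep],
                    bp_start = rep(panel$map$bp[j[1]], length(strs_k)),
                    bp_end = rep(panel$map$bp[j[length(j)]], length(strs_k)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "snps") <- panel$map$snp[j]
  attr(out, "focal_snp") <- focal_snp
  class(out) <- c("core_haplotypes", "data.frame")
  out
}

# first TRUE index per row of a logical matrix; 0 if none
first_true <- function(M) {
  if (ncol(M) == 0) return(rep(0L, nrow(M)))
  w <- max.col(sweep(M * 1, 2, rev(seq_len(ncol(M))), `*`),
               ties.method = "first")
  has <- rowSums(M) > 0
  ifelse(has, w, 0L)
}

#' Haplotype-sharing lengths around a core haplotype
#'
#' For every pair of a focal-population chromosome carrying the core and a
#' reference-breed chromosome carrying the same core, alleles are compared
#' SNP by SNP outward from the core's edges; the shared span runs from the
#' last matching SNP upstream to the last matching SNP downstream (so an
#' immediate mismatch on both sides gives the core's own bp span), and is
#' truncated at the window's terminal SNPs when no mismatch occurs.
#'
#' @param panel a combined \code{\link{phased_panel}} containing the focal
#'   population and the reference breeds (population labels distinguish
#'   them).
#' @param core one row of \code{\link{extract_core_haplotypes}} output (or a
#'   list with \code{haplotype}), plus its attributes; alternatively pass
#'   the whole \code{core_haplotypes} object and \code{core_index}.
#' @param core_index which core to use when \code{core} is the full table.
#' @param focal_pop label of the focal population (default "focal").
#' @param window_bp half-width of the scan window around the focal SNP in bp
#'   (default 5e6); the window never extends past the chromosome.
#' @return data.frame with one row per reference breed: breed, n_pairs,
#'   mean_bp, sd_bp, plus the core bp span in attribute \code{"core_span"}.
#'   Breeds without core carriers get n_pairs = 0 and NA means.
#' @export
hs_lengths <- function(panel, core, core_index = 1L, focal_pop = "focal",
                       window_bp = 5e6) {
  stopifnot(inherits(panel, "phased_panel"))
  if (inherits(core, "core_haplotypes")) {
    snps <- attr(core, "snps")
    core_str <- core$haplotype[core$core == core_index]
    if (length(core_str) != 1) stop("core_index not found")
  } else stop("core must be a core_haplotypes object")
  jcore <- match(snps, panel$map$snp)
  if (anyNA(jcore)) stop("core member SNPs missing from panel map")
  ch <- panel$map$chr[jcore[1]]
  focal_bp <- panel$map$bp[jcore[4]]   # focal = 4th of 3+1+2
  jwin <- which(panel$map$chr == ch &
                  abs(panel$map$bp - focal_bp) <= window_bp)
  ju <- jwin[jwin < min(jcore)]        # upstream, in map order
  jd <- jwin[jwin > max(jcore)]        # downstream
  core_alleles <- as.integer(strsplit(core_str, "")[[1]])
  hap_pop <- rep(panel$pop, each = 2)
  carries <- function(rows) {
    rows[colSums(t(panel$haps[rows, jcore, drop = FALSE]) != core_alleles) == 0]
  }
  f_rows <- carries(which(hap_pop == focal_pop))
  if (length(f_rows) == 0) stop("no focal chromosomes carry this core")
  breeds <- setdiff(unique(panel$pop), focal_pop)
  bp_u <- panel$map$bp[ju]
  bp_d <- panel$map$bp[jd]
  core_span <- panel$map$bp[max(jcore)] - panel$map$bp[min(jcore)]
  out <- list()
  for (br in breeds) {
    r_rows <- carries(which(hap_pop == br))
    if (length(r_rows) == 0) {
      out[[br]] <- data.frame(breed = br, n_pairs = 0L, mean_bp = NA_real_,
                              sd_bp = NA_real_, stringsAsFactors = FALSE)
      next
    }
    Hf_u <- panel$haps[f_rows, rev(ju), drop = FALSE]  # nearest-core first
    Hr_u <- panel$haps[r_rows, rev(ju), drop = FALSE]
    Hf_d <- panel$haps[f_rows, jd, drop = FALSE]
    Hr_d <- panel$haps[r_rows, jd, drop = FALSE]
    spans <- numeric(length(f_rows) * length(r_rows))
    k <- 0L
    bp_u_rev <- rev(bp_u)
    for (i in seq_along(f_rows)) {
      # vectorized over all reference chromosomes at once
      mu <- sweep(Hr_u, 2, Hf_u[i, ], `!=`)
      md <- sweep(Hr_d, 2, Hf_d[i, ], `!=`)
      fu <- first_true(mu)               # first mismatch scanning upstream
      fd <- first_true(md)
      up_bp <- ifelse(fu == 0,
                      if (length(bp_u_rev)) bp_u_rev[length(bp_u_rev)] else
                        panel$map$bp[min(jcore)],
                      ifelse(fu == 1, panel$map$bp[min(jcore)],
                             bp_u_rev[pmax(fu - 1L, 1L)]))
      dn_bp <- ifelse(fd == 0,
                      if (length(bp_d)) bp_d[length(bp_d)] else
                        panel$map$bp[max(jcore)],
                      ifelse(fd == 1, panel$map$bp[max(jcore)],
                             bp_d[pmax(fd - 1L, 1L)]))
      spans[k + seq_along(r_rows)] <- dn_bp - up_bp
      k <- k + length(r_rows)
    }
    out[[br]] <- data.frame(breed = br, n_pairs = length(spans),
                            mean_bp = mean(spans),
                            sd_bp = if (length(spans) > 1) stats::sd(spans)
                                    else 0,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "core_span") <- core_span
  attr(res, "n_focal_carriers") <- length(f_rows)
  res
}
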