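# Genomic relatedness matrices over arbitrary SNP subsets, sampling-error
# shrinkage, and the sliding-window region definitions used by regional
# heritability mapping.

#' Compute a genomic relatedness matrix
#'
#' Uses the standard GREML estimator: for individuals j, k and SNP i with
#' allele-1 frequency p_i and dosage x,
#' \deqn{A_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' off the diagonal, and
#' \deqn{A_{jj} = 1 + \frac{1}{m}\sum_i \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)}}
#' on it. Missing dosages are mean-imputed to \eqn{2p_i}.
#'
#' @param geno a \code{\link{genotype_set}}.
#' @param snps SNP ids or column indices defining the subset (default: all).
#' @param freqs optional externally estimated allele-1 frequencies for the
#'   subset (e.g. from the full genotyped sample); must lie in (0, 1). When
#'   \code{NULL}, frequencies are computed from \code{geno} itself and
#'   monomorphic SNPs are excluded with a warning.
#' @return A \code{\link{new_grm}} object; \code{m} records the SNP count used.
#' @export
compute_grm <- function(geno, snps = NULL, freqs = NULL) {
  # the estimator is invariant to SNP order within the subset; normalise to
  # map order so arbitrary selections are accepted
  if (!is.null(snps)) {
    jj <- if (is.character(snps)) match(snps, geno$map$snp) else snps
    if (anyNA(jj)) stop("unknown SNP id(s) in subset")
    ord <- order(jj)
    snps <- jj[ord]
    if (!is.null(freqs)) freqs <- freqs[ord]
  }
  g <- subset_snps(geno, snps)
  x <- g$dosage
  m0 <- ncol(x)
  if (m0 == 0) stop("empty SNP subset")
  if (is.null(freqs)) {
    p <- colMeans(x, na.rm = TRUE) / 2
    mono <- p <= 0 | p >= 1 | is.nan(p)
    if (any(mono)) {
      warning("excluding ", sum(mono),
              " monomorphic SNP(s) from GRM: ",
              paste(utils::head(g$map$snp[mono], 5), collapse = ", "))
      x <- x[, !mono, drop = FALSE]
      p <- p[!mono]
    }
    src <- "sample"
  } else {
    if (length(freqs) != m0)
      stop("freqs must have one entry per subset SNP")
    if (any(freqs <= 0 | freqs >= 1))
      stop("external allele frequencies must lie strictly in (0, 1)")
    p <- freqs
    src <- "external"
  }
  m <- length(p)
  if (m == 0) stop("no polymorphic SNPs left in subset")
  # mean-impute missing to 2p
  if (anyNA(x)) {
    miss <- which(is.na(x), arr.ind = TRUE)
    x[miss] <- 2 * p[miss[, 2]]
  }
  denom <- 2 * p * (1 - p)
  w <- sweep(x, 2, 2 * p, `-`)
  w <- sweep(w, 2, sqrt(denom), `/`)
  A <- tcrossprod(w) / m
  # GCTA-form diagonal
  dnum <- x^2 - sweep(x, 2, 1 + 2 * p, `*`)
  dnum <- sweep(dnum, 2, 2 * p^2, `+`)
  diag(A) <- 1 + rowMeans(sweep(dnum, 2, denom, `/`))
  new_grm(A, g$ids, m = m, freq_source = src)
}

#' Shrink GRM off-diagonals for marker sampling error
#'
#' Relatedness estimated from m SNPs carries sampling variance of order
#' \code{c/m}. With \code{mode = "reliability"}, off-diagonals are scaled by
#' the reliability \eqn{\beta = v/(v + c/m)} where \eqn{v} is the observed
#' off-diagonal variance minus the expected sampling variance \code{c/m}
#' (floored at 0 with a warning if negative). The diagonal is untouched.
#' \code{mode = "off"} returns the input unchanged.
#'
#' @param grm a \code{\link{new_grm}} object.
#' @param mode "off" (default) or "reliability".
#' @param c_snp per-SNP sampling-variance constant (default 1, the value for
#'   unrelated individuals under the standardized-dosage estimator).
#' @return A \code{\link{new_grm}} object; the shrinkage factor is stored in
#'   attribute \code{"beta"}.
#' @export
adjust_grm <- function(grm, mode = c("off", "reliability"), c_snp = 1) {
  stopifnot(inherits(grm, "grm"))
  mode <- match.arg(mode)
  if (mode == "off") return(grm)
  off <- grm$mat[lower.tri(grm$mat)]
  samp <- c_snp / grm$m
  v_true <- stats::var(off) - samp
  if (is.na(v_true)) stop("GRM too small to estimate off-diagonal variance")
  if (v_true < 0) {
    warning("estimated true relatedness variance negative; shrinkage floored at 0")
    v_true <- 0
  }
  beta <- if (v_true + samp > 0) v_true / (v_true + samp) else 0
  out <- grm$mat * beta
  diag(out) <- diag(grm$mat)
  res <- new_grm(out, grm$ids, grm$m,
                 freq_source = paste0(grm$freq_source, "+adj"))
  attr(res, "beta") <- beta
  res
}

#' Define sliding SNP windows for regional heritability mapping
#'
#' Windows of \code{window} adjacent SNPs start \code{step} SNP ordinals
#' apart within each chromosome (ordinals 1, 1+step, 1+2*step, ...). A window
#' at the chromosome end spans whatever SNPs remain; windows are retained
#' only when they hold at least \code{min_snps} SNPs. Retained regions get
#' global indices in genome order.
#'
#' @param map SNP map as in \code{\link{genotype_set}} (columns snp, chr, bp).
#' @param window window size in SNPs (default 150).
#' @param step start spacing in SNPs (default 75).
#' @param min_snps minimum SNP count for a window to be retained
#'   (default 113, i.e. "more than 112").
#' @return data.frame with one row per retained region: \code{region}
#'   (global index), \code{chr}, \code{start_ord}/\code{end_ord} (1-based
#'   inclusive SNP ordinals within chromosome), \code{n_snps},
#'   \code{bp_start}/\code{bp_end}, and a list column \code{snps} of SNP ids.
#'   Chromosomes shorter than \code{min_snps} contribute no regions and are
#'   reported in attribute \code{"skipped"}.
#' @export
define_regions <- function(map, window = 150L, step = 75L, min_snps = 113L) {
  stopifnot(all(c("snp", "chr", "bp") %in% names(map)))
  out <- list()
  skipped <- character(0)
  for (ch in unique(map$chr)) {
    sel <- which(map$chr == ch)
    n <- length(sel)
    if (n < min_snps) {
      skipped <- c(skipped, ch)
      next
    }
    starts <- seq(1L, n, by = step)
    for (s in starts) {
      cnt <- min(window, n - s + 1L)
      if (cnt < min_snps) next
      e <- s + cnt - 1L
      idx <- sel[s:e]
      out[[length(out) + 1L]] <- data.frame(
        chr = ch, start_ord = s, end_ord = e, n_snps = cnt,
        bp_start = map$bp[idx[1]], bp_end = map$bp[idx[cnt]],
        stringsAsFactors = FALSE)
      out[[length(out)]]$snps <- list(map$snp[idx])
    }
  }
  if (length(out) == 0) {
    res <- data.frame(region = integer(0), chr = character(0),
                      start_ord = integer(0), end_ord = integer(0),
                      n_snps = integer(0), bp_start = integer(0),
                      bp_end = integer(0))
    res$snps <- list()
  } else {
    res <- do.call(rbind, out)
    res <- cbind(region = seq_len(nrow(res)), res)
  }
  attr(res, "skipped") <- skipped
  res
}
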