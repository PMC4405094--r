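# Chromosome partitioning of additive genetic variance, the regional
# heritability scan over sliding SNP windows, and the chromosome-length
# regression.

# Shared machinery: per-unit GRM + complement GRM built with one set of
# allele frequencies so that complements follow from the linearity
# m_tot * A_tot = m_unit * A_unit + m_comp * A_comp (exact when frequencies
# are shared across subsets).
complement_grm <- function(total, unit) {
  m_comp <- total$m - unit$m
  if (m_comp < 1) stop("complement has no SNPs")
  mat <- (total$m * total$mat - unit$m * unit$mat) / m_comp
  new_grm(mat, total$ids, m_comp, freq_source = total$freq_source)
}

# drop monomorphic SNPs and return shared full-sample frequencies
polymorphic_freqs <- function(geno) {
  p <- colMeans(geno$dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.nan(p)
  list(geno = subset_snps(geno, which(keep)), p = p[keep])
}

#' Partition additive genetic variance between chromosomes
#'
#' For each chromosome, fits an animal model with a GRM built from that
#' chromosome's SNPs plus a GRM from all remaining autosomal SNPs (and the
#' supplied non-genetic random terms), against a reduced model with the
#' complement GRM only; the chromosome's contribution is tested by a
#' likelihood-ratio test on one degree of freedom. No multiple-testing
#' adjustment is applied at this level. A whole-genome fit (all-SNP GRM) is
#' reported as the first row, and the sum of converged per-chromosome
#' estimates as the last.
#'
#' @param fixed fixed-effect formula (response on the left).
#' @param data phenotype data.frame, one row per measure.
#' @param id name of the individual-id column.
#' @param geno \code{\link{genotype_set}} covering (at least) the measured
#'   individuals; allele frequencies are taken from its full sample.
#' @param groups,permanent_env non-genetic random terms passed to
#'   \code{\link{greml}}.
#' @param adjust GRM shrinkage mode passed to \code{\link{adjust_grm}}
#'   (default "off").
#' @param ... further arguments to \code{\link{greml}}.
#' @return data.frame with rows "genome", one per chromosome, and "sum":
#'   columns unit, length_mb (NA for genome/sum), v_unit, se_v, h2, se_h2,
#'   lrt, p, converged. Non-converged chromosomes are flagged and excluded
#'   from the sum row.
#' @export
chromosome_partition <- function(fixed, data, id, geno,
                                 groups = character(0),
                                 permanent_env = FALSE, adjust = "off", ...) {
  pf <- polymorphic_freqs(geno)
  geno <- pf$geno
  p <- pf$p
  chrs <- unique(geno$map$chr)
  total <- adjust_grm(compute_grm(geno, freqs = p), mode = adjust)

  fit_g <- greml(fixed, data, id, grms = list(genome = total),
                 groups = groups, permanent_env = permanent_env, ...)
  vr_g <- variance_ratios(fit_g, "genome")
  rows <- list(data.frame(unit = "genome", length_mb = NA_real_,
                          v_unit = fit_g$sigma2[["genome"]],
                          se_v = fit_g$vc$se[fit_g$vc$term == "genome"],
                          h2 = vr_g$ratio, se_h2 = vr_g$se,
                          lrt = NA_real_, p = NA_real_,
                          converged = fit_g$converged,
                          stringsAsFactors = FALSE))
  for (ch in chrs) {
    sel <- which(geno$map$chr == ch)
    g_c <- adjust_grm(compute_grm(geno, sel, freqs = p[sel]), mode = adjust)
    g_r <- complement_grm(total, g_c)
    full <- greml(fixed, data, id, grms = list(chrom = g_c, rest = g_r),
                  groups = groups, permanent_env = permanent_env,
                  check_psd = FALSE, ...)
    red <- greml(fixed, data, id, grms = list(rest = g_r), groups = groups,
                 permanent_env = permanent_env, check_psd = FALSE, ...)
    conv <- full$converged && red$converged
    lr <- if (conv) lrt_varcomp(full, red) else list(lrt = NA_real_, p = NA_real_)
    vr <- variance_ratios(full, "chrom")
    rows[[length(rows) + 1L]] <-
      data.frame(unit = ch, length_mb = NA_real_,
                 v_unit = full$sigma2[["chrom"]],
                 se_v = full$vc$se[full$vc$term == "chrom"],
                 h2 = vr$ratio, se_h2 = vr$se, lrt = lr$lrt, p = lr$p,
                 converged = conv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- out$converged & out$unit != "genome"
  if (any(!out$converged))
    message(sum(!out$converged), " unit(s) did not converge; ",
            "excluded from the sum row")
  sum_row <- data.frame(unit = "sum", length_mb = NA_real_,
                        v_unit = sum(out$v_unit[ok]), se_v = NA_real_,
                        h2 = sum(out$h2[ok]), se_h2 = NA_real_,
                        lrt = NA_real_, p = NA_real_, converged = all(out$converged),
                        stringsAsFactors = FALSE)
  out <- rbind(out, sum_row)
  rownames(out) <- NULL
  attr(out, "whole_genome_fit") <- fit_g
  out
}

#' Regional heritability scan over sliding SNP windows
#'
#' For each retained region (see \code{\link{define_regions}}), fits the
#' region GRM plus the rest-of-genome GRM (which excludes exactly that
#' region's SNPs) against the rest-of-genome-only model, and tests the
#' region by a 1-df likelihood-ratio test. The significance threshold
#' divides alpha by HALF the number of regions whose models converged,
#' because consecutive windows overlap by 50 percent.
#'
#' @inheritParams chromosome_partition
#' @param regions region table from \code{\link{define_regions}}; computed
#'   from the SNP map with defaults when NULL.
#' @param alpha family-wise error rate for the threshold (default 0.05).
#' @param ... further arguments to \code{\link{greml}}.
#' @return data.frame with one row per region: region, chr, n_snps,
#'   bp_start, bp_end, v_region, h2, se_h2, lrt, p, converged, significant.
#'   Attributes: \code{threshold}, \code{n_converged}, \code{n_attempted}.
#' @export
regional_scan <- function(fixed, data, id, geno, regions = NULL,
                          groups = character(0), permanent_env = FALSE,
                          adjust = "off", alpha = 0.05, ...) {
  pf <- polymorphic_freqs(geno)
  geno <- pf$geno
  p <- pf$p
  if (is.null(regions)) regions <- define_regions(geno$map)
  if (nrow(regions) == 0) stop("no testable regions")
  total <- adjust_grm(compute_grm(geno, freqs = p), mode = adjust)
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    snps <- regions$snps[[r]]
    sel <- match(snps, geno$map$snp)
    sel <- sel[!is.na(sel)]
    g_c <- adjust_grm(compute_grm(geno, sel, freqs = p[sel]), mode = adjust)
    g_r <- complement_grm(total, g_c)
    full <- tryCatch(
      greml(fixed, data, id, grms = list(region = g_c, rest = g_r),
            groups = groups, permanent_env = permanent_env,
            check_psd = FALSE, ...),
      error = function(e) NULL)
    red <- tryCatch(
      greml(fixed, data, id, grms = list(rest = g_r), groups = groups,
            permanent_env = permanent_env, check_psd = FALSE, ...),
      error = function(e) NULL)
    conv <- !is.null(full) && !is.null(red) && full$converged && red$converged
    lr <- if (conv) lrt_varcomp(full, red) else list(lrt = NA_real_, p = NA_real_)
    vr <- if (!is.null(full)) variance_ratios(full, "region") else
      data.frame(ratio = NA_real_, se = NA_real_)
    rows[[r]] <- data.frame(
      region = regions$region[r], chr = regions$chr[r],
      n_snps = regions$n_snps[r], bp_start = regions$bp_start[r],
      bp_end = regions$bp_end[r],
      v_region = if (!is.null(full)) full$sigma2[["region"]] else NA_real_,
      h2 = vr$ratio, se_h2 = vr$se, lrt = lr$lrt, p = lr$p,
      converged = conv, stringsAsFactors = FALSE)
    message(sprintf("region %d (%s, %d SNPs): %s",
                    regions$region[r], regions$chr[r], regions$n_snps[r],
                    if (conv) sprintf("LRT %.3f", lr$lrt) else "not converged"))
  }
  out <- do.call(rbind, rows)
  n_conv <- sum(out$converged)
  if (n_conv == 0) stop("no testable regions: no models converged")
  threshold <- alpha / (n_conv / 2)
  out$significant <- !is.na(out$p) & out$p < threshold
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "n_converged") <- n_conv
  attr(out, "n_attempted") <- nrow(out)
  out
}

#' Regress per-chromosome variance explained on chromosome length
#'
#' Ordinary least squares of the per-chromosome heritability (or variance)
#' on physical chromosome length in Mb, with a two-sided test of the slope.
#' Under a polygenic architecture the variance a chromosome explains scales
#' with its length; a major QTL on a short chromosome disrupts the relation.
#'
#' @param partition data.frame with columns \code{unit}, \code{h2} (and
#'   optionally \code{v_unit}, \code{converged}), e.g. from
#'   \code{\link{chromosome_partition}} (genome/sum rows are ignored).
#' @param lengths named numeric vector of chromosome lengths in Mb (names =
#'   unit labels), or a \code{length_mb} column already present.
#' @param response "h2" (default) or "v" (uses \code{v_unit}).
#' @return list with slope, intercept, se_slope, r2, p, n.
#' @export
length_regression <- function(partition, lengths = NULL,
                              response = c("h2", "v")) {
  response <- match.arg(response)
  d <- partition[!partition$unit %in% c("genome", "sum"), , drop = FALSE]
  if (!is.null(d$converged)) d <- d[d$converged, , drop = FALSE]
  y <- if (response == "h2") d$h2 else d$v_unit
  x <- if (!is.null(lengths)) unname(lengths[as.character(d$unit)]) else
    d$length_mb
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 chromosomes with converged estimates")
  if (stats::var(x) == 0) stop("zero variance in chromosome lengths")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se_slope = sm$coefficients[2, 2],
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(x))
}
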