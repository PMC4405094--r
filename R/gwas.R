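# Two-stage residual association scan (GRAMMAR): mixed-model residuals
# first, then fast per-SNP score tests; genomic-inflation diagnostics,
# Bonferroni calling, and mixed-model refitting of top SNPs with the
# V_SNP = 2pq a^2 variance decomposition.

#' Per-individual mean GRAMMAR residuals
#'
#' Extracts conditional residuals from a whole-genome animal-model fit
#' (phenotype minus fixed effects and the BLUPs of every random term,
#' including the genomic effect) and averages them per individual across
#' repeated measures.
#'
#' @param fit a converged \code{\link{greml}} fit including the whole-genome
#'   GRM term.
#' @return named numeric vector of mean residuals, one entry per individual.
#' @export
grammar_residuals <- function(fit) {
  stopifnot(inherits(fit, "greml"))
  if (!fit$converged) stop("mixed-model fit did not converge")
  r <- residuals(fit, type = "conditional")
  tapply(r, fit$ids, mean)
}

#' Score-test association scan of residuals against all SNPs
#'
#' For each SNP the statistic is n r^2 where r is the Pearson correlation
#' between the residual vector and the dosage (missing dosages excluded
#' pairwise); P values come from chi-square with 1 df. The additive effect
#' is the OLS slope of the residual on the dosage, reported per copy of the
#' minor allele (minor = less frequent allele in the scanned sample).
#'
#' @param residuals named numeric vector (e.g. from
#'   \code{\link{grammar_residuals}}).
#' @param geno a \code{\link{genotype_set}}; only individuals present in
#'   \code{residuals} are used.
#' @return data.frame with one row per SNP: snp, chr, bp, major, minor, n,
#'   effect_minor (residual scale), chi2, p. Monomorphic SNPs get NA
#'   statistics and are counted in a message.
#' @export
score_scan <- function(residuals, geno) {
  stopifnot(inherits(geno, "genotype_set"))
  common <- intersect(names(residuals), geno$ids)
  if (length(common) < 3) stop("fewer than 3 individuals with residuals and genotypes")
  r <- unname(residuals[common])
  X <- geno$dosage[match(common, geno$ids), , drop = FALSE]
  M <- !is.na(X)
  X0 <- X
  X0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(X0)
  Sxx <- colSums(X0^2)
  Sr <- drop(crossprod(M, r))
  Srr <- drop(crossprod(M, r^2))
  Sxr <- drop(crossprod(X0, r))
  covxr <- Sxr - Sx * Sr / n
  varx <- Sxx - Sx^2 / n
  varr <- Srr - Sr^2 / n
  mono <- varx <= 0 | n < 3
  r2 <- rep(NA_real_, length(n))
  ok <- !mono & varr > 0
  r2[ok] <- covxr[ok]^2 / (varx[ok] * varr[ok])
  chi2 <- n * r2
  p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  slope <- ifelse(mono, NA_real_, covxr / varx)     # per allele-1 copy
  freq1 <- Sx / (2 * n)
  minor_is_1 <- freq1 <= 0.5
  if (any(mono))
    message(sum(mono), " monomorphic SNP(s) emitted with NA statistics")
  data.frame(snp = geno$map$snp, chr = geno$map$chr, bp = geno$map$bp,
             major = ifelse(minor_is_1, geno$map$a2, geno$map$a1),
             minor = ifelse(minor_is_1, geno$map$a1, geno$map$a2),
             maf = pmin(freq1, 1 - freq1),
             n = n, effect_minor = ifelse(minor_is_1, slope, -slope),
             chi2 = chi2, p = p, stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' lambda = median(observed chi-square statistics) / median of the
#' chi-square(1) reference (0.4549). Diagnostic only; no correction is
#' applied to P values. Values below 1 indicate the deflation
#' characteristic of residual-based two-stage scans on family data.
#'
#' @param statistics numeric vector of 1-df chi-square statistics.
#' @return lambda (numeric scalar).
#' @export
inflation_factor <- function(statistics) {
  statistics <- statistics[!is.na(statistics)]
  if (length(statistics) == 0) stop("no statistics supplied")
  if (length(statistics) < 100)
    warning("inflation factor estimated from fewer than 100 statistics")
  stats::median(statistics) / stats::qchisq(0.5, 1)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests number of tests (SNPs).
#' @param alpha family-wise error rate (default 0.05).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' SNP variance from its additive effect
#'
#' V_SNP = 2 p q a^2 for a biallelic locus with minor-allele frequency q
#' (p = 1 - q) and additive effect a per minor-allele copy.
#'
#' @param a additive effect (trait units per minor-allele copy).
#' @param maf minor allele frequency.
#' @return V_SNP in squared trait units.
#' @export
snp_variance <- function(a, maf) {
  if (any(maf < 0 | maf > 0.5)) stop("maf must be in [0, 0.5]")
  2 * maf * (1 - maf) * a^2
}

#' Decompose a SNP's contribution to phenotypic and additive variance
#'
#' @param a additive effect per minor-allele copy.
#' @param maf minor allele frequency.
#' @param v_a additive genetic variance of the trait.
#' @param v_p phenotypic variance; if NULL, derived as \code{v_a / h2}.
#' @param h2 heritability, used only when \code{v_p} is NULL.
#' @return list with v_snp, h2_snp (= v_snp / v_p) and share_va
#'   (= v_snp / v_a).
#' @export
snp_variance_decomposition <- function(a, maf, v_a, v_p = NULL, h2 = NULL) {
  if (is.null(v_p)) {
    if (is.null(h2)) stop("supply v_p or h2")
    v_p <- v_a / h2
  }
  v_snp <- snp_variance(a, maf)
  list(v_snp = v_snp, h2_snp = v_snp / v_p, share_va = v_snp / v_a)
}

#' Refit a top SNP inside the full mixed model
#'
#' Adds the SNP dosage (number of minor alleles, minor defined by the full
#' genotyped sample) as a fixed covariate to the whole-genome animal model
#' and refits, giving an unbiased additive effect with a Wald test. The
#' SNP's variance contribution is V_SNP = 2 p q a^2, its h^2 the ratio to
#' total phenotypic variance, and its share of additive variance the ratio
#' to the genomic component.
#'
#' @inheritParams chromosome_partition
#' @param snp SNP id to refit.
#' @param genomic_term name of the whole-genome GRM random term whose
#'   variance is taken as V_A (default "genome").
#' @param grms named list of \code{\link{new_grm}} objects for the model
#'   (must include \code{genomic_term}); if NULL, a whole-genome GRM is
#'   computed from \code{geno}.
#' @param ... further arguments to \code{\link{greml}}.
#' @return An object of class \code{snp_effect}: list with snp, a, se,
#'   wald_chi2, p, maf, v_snp, v_p, v_a, h2_snp, share_va, n, and the
#'   underlying \code{fit}.
#' @export
refit_snp_effect <- function(fixed, data, id, geno, snp,
                             grms = NULL, groups = character(0),
                             permanent_env = FALSE,
                             genomic_term = "genome", ...) {
  stopifnot(inherits(geno, "genotype_set"))
  j <- match(snp, geno$map$snp)
  if (is.na(j)) stop("unknown SNP id: ", snp)
  dos_all <- geno$dosage[, j]
  freq1 <- mean(dos_all, na.rm = TRUE) / 2        # full genotyped sample
  minor_is_1 <- freq1 <= 0.5
  q <- if (minor_is_1) freq1 else 1 - freq1
  ids <- as.character(data[[id]])
  pos <- match(ids, geno$ids)
  if (anyNA(pos)) stop("phenotyped individuals missing from genotypes")
  dos <- dos_all[pos]
  if (minor_is_1 == FALSE) dos <- 2 - dos
  if (length(unique(stats::na.omit(dos))) < 2)
    stop("SNP ", snp, " is monomorphic in the fitted sample")
  dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
  d2 <- data
  d2$.snp_dosage <- dos
  f2 <- stats::update(stats::as.formula(fixed), . ~ . + .snp_dosage)
  if (is.null(grms))
    grms <- stats::setNames(list(compute_grm(geno)), genomic_term)
  fit <- greml(f2, d2, id, grms = grms, groups = groups,
               permanent_env = permanent_env, ...)
  if (!fit$converged) stop("joint mixed-model fit did not converge")
  a <- unname(fit$beta[".snp_dosage"])
  se <- unname(fit$beta_se[".snp_dosage"])
  chi2 <- (a / se)^2
  p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  v_p <- sum(fit$sigma2)
  v_a <- fit$sigma2[[genomic_term]]
  v_snp <- snp_variance(a, q)
  structure(list(snp = snp, a = a, se = se, wald_chi2 = chi2, p = p,
                 maf = q, v_snp = v_snp, v_p = v_p, v_a = v_a,
                 h2_snp = v_snp / v_p, share_va = v_snp / v_a,
                 n = fit$n, fit = fit),
            class = "snp_effect")
}

#' @export
print.snp_effect <- function(x, ...) {
  cat("SNP", x$snp, "mixed-model refit (", x$n, "observations )\n")
  cat(sprintf("  a = %.4f (SE %.4f), Wald chi2 = %.3f, P = %.3g\n",
              x$a, x$se, x$wald_chi2, x$p))
  cat(sprintf("  MAF %.3f: V_SNP = %.4f, h2_SNP = %.4f, V_SNP/V_A = %.4f\n",
              x$maf, x$v_snp, x$h2_snp, x$share_va))
  invisible(x)
}
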