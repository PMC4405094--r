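# Genotype-level selection analysis: fitness measures derived from pedigree
# and census records, relative fitness and selection coefficients with
# bootstrap intervals, the overdominance equilibrium frequency, and the
# gene-drop drift null for allele-frequency trends.

#' Derive annual and lifetime fitness measures
#'
#' AS (annual survival) is the binary survival flag for each year an
#' individual was part of the study population; AR (annual recruits) counts
#' the individual's offspring born that year that survived past the end of
#' their first year; LBS (lifetime breeding success) counts all offspring of
#' individuals born inside \code{cohort_window}; LR (lifetime recruits)
#' counts the offspring that recruited.
#'
#' @param ped a \code{\link{pedigree}}.
#' @param census data.frame with columns id, year, survived (one row per
#'   individual-year of study membership); an \code{age} column is carried
#'   through if present.
#' @param cohort_window optional c(first, last) birth years restricting the
#'   individuals for which LBS/LR are reported.
#' @return list with \code{annual} (id, year, sex, age, AS, AR) and
#'   \code{lifetime} (id, sex, birth_year, LBS, LR).
#' @export
derive_fitness <- function(ped, census, cohort_window = NULL) {
  stopifnot(all(c("id", "year", "survived") %in% names(census)))
  validate_pedigree(ped)
  bad <- setdiff(census$id, ped$id)
  if (length(bad) > 0)
    stop("census ids absent from pedigree: ",
         paste(utils::head(bad, 5), collapse = ", "))
  byid <- stats::setNames(ped$birth_year, ped$id)
  sexv <- stats::setNames(ped$sex, ped$id)

  # recruit = survived past the end of its birth year
  recruit <- rep(FALSE, nrow(ped))
  names(recruit) <- ped$id
  bcr <- census[census$year == byid[census$id], ]
  recruit[bcr$id] <- bcr$survived

  parent_of <- function(col) ped[!is.na(ped[[col]]), c(col, "id", "birth_year")]
  annual <- census
  annual$sex <- sexv[annual$id]
  annual$AS <- as.integer(annual$survived)
  if (is.null(annual$age)) annual$age <- annual$year - byid[annual$id]
  annual$AR <- 0L
  lifetime <- data.frame(id = ped$id, sex = ped$sex,
                         birth_year = ped$birth_year,
                         LBS = 0L, LR = 0L, stringsAsFactors = FALSE)
  for (col in c("dam", "sire")) {
    po <- parent_of(col)
    if (nrow(po) == 0) next
    # annual recruits per parent-year
    rec_kids <- po[recruit[po$id], ]
    if (nrow(rec_kids) > 0) {
      key <- paste(rec_kids[[col]], rec_kids$birth_year)
      tab <- table(key)
      akey <- paste(annual$id, annual$year)
      hit <- akey %in% names(tab)
      annual$AR[hit] <- annual$AR[hit] + as.integer(tab[akey[hit]])
    }
    lb <- table(po[[col]])
    lr <- table(po[[col]][recruit[po$id]])
    i <- match(names(lb), lifetime$id)
    lifetime$LBS[i] <- lifetime$LBS[i] + as.integer(lb)
    i <- match(names(lr), lifetime$id)
    lifetime$LR[i] <- lifetime$LR[i] + as.integer(lr)
  }
  if (!is.null(cohort_window))
    lifetime <- lifetime[lifetime$birth_year >= cohort_window[1] &
                           lifetime$birth_year <= cohort_window[2], ]
  annual <- annual[, c("id", "year", "sex", "age", "AS", "AR")]
  rownames(annual) <- NULL
  rownames(lifetime) <- NULL
  list(annual = annual, lifetime = lifetime)
}

#' Genotype relative fitness and selection coefficients
#'
#' Groups a fitness measure by genotype class at a focal SNP (0/1/2 minor
#' alleles), computes mean fitness per class, relative fitness w (scaled so
#' the fittest genotype has w = 1) and selection coefficients s = 1 - w,
#' with percentile bootstrap confidence intervals over individuals.
#' Genotype classes with fewer than 5 individuals are flagged.
#'
#' @param fitness named numeric vector of one fitness measure per individual
#'   (e.g. LBS), names = individual ids.
#' @param genotypes named dosage vector (0/1/2 minor alleles) at the focal
#'   SNP; individuals missing a genotype are dropped.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class \code{selection_estimate}: data.frame with one
#'   row per genotype class (genotype, n, mean_fitness, w, s, s_lo, s_hi,
#'   flagged_small); bootstrap draws of s are kept in attribute
#'   \code{"boot_s"} for downstream propagation.
#' @export
selection_coefficients <- function(fitness, genotypes, n_boot = 1000L,
                                   seed = 1L) {
  ids <- intersect(names(fitness), names(genotypes))
  ids <- ids[!is.na(genotypes[ids]) & !is.na(fitness[ids])]
  if (length(ids) == 0) stop("no individuals with both fitness and genotype")
  f <- fitness[ids]
  g <- genotypes[ids]
  if (!all(g %in% 0:2)) stop("genotypes must be 0/1/2 minor-allele counts")
  classes <- 0:2
  mns <- vapply(classes, function(k) {
    if (any(g == k)) mean(f[g == k]) else NA_real_
  }, 0)
  ns <- vapply(classes, function(k) sum(g == k), 0L)
  present <- !is.na(mns)
  if (!any(present)) stop(">= 1 individual per genotype required")
  if (all(mns[present] == 0))
    stop("all genotype classes have zero mean fitness")
  wmax <- max(mns[present])
  w <- mns / wmax
  s <- 1 - w
  set.seed(seed)
  boot_s <- matrix(NA_real_, n_boot, 3)
  idx_by_class <- lapply(classes, function(k) which(g == k))
  for (b in seq_len(n_boot)) {
    # resample individuals within each genotype class
    mb <- vapply(seq_along(classes), function(ki) {
      ix <- idx_by_class[[ki]]
      if (length(ix) == 0) return(NA_real_)
      mean(f[sample(ix, length(ix), replace = TRUE)])
    }, 0)
    wb <- mb / max(mb, na.rm = TRUE)
    boot_s[b, ] <- 1 - wb
  }
  ci <- apply(boot_s, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  out <- data.frame(genotype = c("major_hom", "het", "minor_hom"),
                    n = ns, mean_fitness = mns, w = w, s = s,
                    s_lo = ci[1, ], s_hi = ci[2, ],
                    flagged_small = ns < 5, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, boot_s = boot_s, class = c("selection_estimate",
                                            "data.frame"))
}

#' Equilibrium minor-allele frequency under heterozygote advantage
#'
#' q_eq = s1 / (s1 + s2), where s1 is the selection coefficient of the major
#' homozygote and s2 that of the minor homozygote, valid only when the
#' heterozygote is the fittest genotype. Confidence intervals propagate the
#' bootstrap draws of (s1, s2) when supplied or when called on a
#' \code{selection_estimate}.
#'
#' @param s1 selection coefficient of the major homozygote, or a
#'   \code{selection_estimate} object.
#' @param s2 selection coefficient of the minor homozygote (ignored when
#'   \code{s1} is a \code{selection_estimate}).
#' @param boot optional 2-column matrix of bootstrap (s1, s2) draws.
#' @return list with q_eq and (when bootstrap draws are available) q_lo,
#'   q_hi.
#' @export
equilibrium_frequency <- function(s1, s2 = NULL, boot = NULL) {
  if (inherits(s1, "selection_estimate")) {
    est <- s1
    if (est$s[est$genotype == "het"] > 1e-12)
      stop("heterozygote is not the fittest genotype; ",
           "equilibrium formula invalid")
    bs <- attr(est, "boot_s")
    boot <- cbind(bs[, 1], bs[, 3])
    s2 <- est$s[est$genotype == "minor_hom"]
    s1 <- est$s[est$genotype == "major_hom"]
  }
  if (is.null(s2)) stop("supply s2")
  if (s1 < 0 || s2 < 0)
    stop("selection coefficients must be non-negative (heterozygote fittest)")
  if (s1 == 0 && s2 == 0) stop("s1 = s2 = 0: equilibrium frequency undefined")
  q <- s1 / (s1 + s2)
  out <- list(q_eq = q)
  if (!is.null(boot)) {
    ok <- stats::complete.cases(boot) & rowSums(boot) > 0 &
      boot[, 1] >= 0 & boot[, 2] >= 0
    if (any(ok)) {
      qb <- boot[ok, 1] / (boot[ok, 1] + boot[ok, 2])
      out$q_lo <- unname(stats::quantile(qb, 0.025))
      out$q_hi <- unname(stats::quantile(qb, 0.975))
    }
  }
  out
}

#' Allele-frequency trend with a gene-drop drift null
#'
#' The observed trend is the OLS slope of the yearly population allele
#' frequency on year. The null distribution comes from gene-drop
#' simulations: founders (pedigree members with unknown parents) keep their
#' observed genotypes (ungenotyped founders draw alleles from the founder
#' frequency), every descendant's alleles are re-sampled by Mendelian
#' transmission through the fixed pedigree, and yearly frequencies are
#' recomputed over the same individual-year membership. The one-tailed P is
#' the proportion of simulated slopes at least as extreme as the observed
#' one, in its direction; both tails are reported.
#'
#' @param genotypes named dosage vector (0/1/2) at the focal SNP (NA for
#'   ungenotyped individuals).
#' @param ped a \code{\link{pedigree}} spanning the study years.
#' @param membership data.frame(id, year): which individuals contribute to
#'   which yearly frequency (e.g. all genotyped animals alive that year).
#' @param n_reps gene-drop replicates (default 1000).
#' @param seed RNG seed.
#' @param founder_freq allele frequency used for ungenotyped founders
#'   (default: observed frequency among genotyped founders).
#' @return list with slope, r2, p_regression (two-sided), p_genedrop
#'   (one-tailed in the observed direction), p_upper, p_lower, n_years,
#'   yearly (data.frame year, freq), and null_slopes.
#' @export
allele_trend_test <- function(genotypes, ped, membership, n_reps = 1000L,
                              seed = 1L, founder_freq = NULL) {
  stopifnot(all(c("id", "year") %in% names(membership)))
  validate_pedigree(ped)
  years <- sort(unique(membership$year))
  if (length(years) < 3) stop("need >= 3 years of frequency data")
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  g_obs <- genotypes[ped$id]

  yearly_freq <- function(dos) {
    vapply(years, function(y) {
      mem <- membership$id[membership$year == y]
      d <- dos[idx[mem]]
      mean(d, na.rm = TRUE) / 2
    }, 0)
  }
  obs_f <- yearly_freq(g_obs)
  fit <- stats::lm(obs_f ~ years)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])

  # gene-drop: founders fixed, descendants re-dropped, membership reused
  founder <- is.na(ped$sire) & is.na(ped$dam)
  if (is.null(founder_freq)) {
    ff <- mean(g_obs[founder], na.rm = TRUE) / 2
    founder_freq <- if (is.nan(ff)) mean(g_obs, na.rm = TRUE) / 2 else ff
  }
  ord <- order(ped$birth_year)
  n <- nrow(ped)
  set.seed(seed)
  A1 <- matrix(0L, n, n_reps)
  A2 <- matrix(0L, n, n_reps)
  for (i in which(founder)) {
    gi <- g_obs[i]
    if (is.na(gi)) {
      A1[i, ] <- stats::rbinom(n_reps, 1L, founder_freq)
      A2[i, ] <- stats::rbinom(n_reps, 1L, founder_freq)
    } else if (gi == 2L) {
      A1[i, ] <- 1L; A2[i, ] <- 1L
    } else if (gi == 1L) {
      A1[i, ] <- 1L            # one copy; which slot is immaterial
    }
  }
  for (i in ord) {
    if (founder[i]) next
    di <- idx[ped$dam[i]]; si <- idx[ped$sire[i]]
    pick_d <- stats::runif(n_reps) < 0.5
    pick_s <- stats::runif(n_reps) < 0.5
    A1[i, ] <- ifelse(pick_d, A1[di, ], A2[di, ])
    A2[i, ] <- ifelse(pick_s, A1[si, ], A2[si, ])
  }
  yr_mem <- lapply(years, function(y) {
    mem <- membership$id[membership$year == y]
    unname(idx[mem[!is.na(g_obs[idx[mem]])]])   # same animals as observed series
  })
  F <- matrix(0, length(years), n_reps)
  for (k in seq_along(years)) {
    rows <- yr_mem[[k]]
    F[k, ] <- colMeans(A1[rows, , drop = FALSE] + A2[rows, , drop = FALSE]) / 2
  }
  xc <- years - mean(years)
  null_slopes <- drop(crossprod(xc, F)) / sum(xc^2)
  p_upper <- mean(null_slopes >= slope)
  p_lower <- mean(null_slopes <= slope)
  list(slope = slope, r2 = sm$r.squared,
       p_regression = sm$coefficients[2, 4],
       p_genedrop = if (slope >= 0) p_upper else p_lower,
       p_upper = p_upper, p_lower = p_lower,
       n_years = length(years),
       yearly = data.frame(year = years, freq = obs_f),
       null_slopes = null_slopes)
}
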