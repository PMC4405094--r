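# Forward simulation of pedigreed populations. Linkage disequilibrium is
# produced mechanistically: founders are mosaics of a small ancestral
# haplotype pool, and descendants arise by Mendelian transmission with
# Poisson crossovers on a uniform genetic map (1 cM/Mb by default, no
# interference). Downstream GRM/GWAS behaviour therefore rests on genuine
# identity-by-descent structure, not a parametric LD model.

#' Default scaled-down chromosome table
#'
#' Twenty-six autosomes with physical lengths (Mb) matching a sheep-like
#' genome and SNP counts scaled down ~25x from a 37k panel.
#' @return data.frame with columns \code{snps}, \code{length_mb}.
#' @export
default_chromosomes <- function() {
  len <- c(276, 249, 224, 119, 108, 117, 100, 91, 95, 86, 62, 79, 83, 63,
           81, 72, 72, 69, 60, 51, 50, 51, 62, 42, 45, 44)
  snps <- c(4138, 3842, 3540, 1992, 1702, 1784, 1653, 1535, 1546, 1416, 853,
            1218, 1165, 786, 1204, 1091, 1032, 1003, 846, 801, 587, 804,
            741, 439, 685, 634)
  data.frame(snps = pmax(20L, as.integer(round(snps / 25))), length_mb = len)
}

#' QTL specification
#'
#' @param chr chromosome index the QTL sits on.
#' @param target_maf founder minor-allele frequency in (0, 0.5].
#' @param effect additive effect (trait units per minor-allele copy).
#' @param dominance dominance deviation (trait units, applied to
#'   heterozygotes).
#' @param fitness_mode "neutral", "additive" or "overdominant".
#' @param fitness_effect multiplicative fitness effect: per minor-allele copy
#'   for "additive", for heterozygotes under "overdominant".
#' @param donor_only if TRUE the minor allele is placed only on donor
#'   (admixture-derived) haplotypes.
#' @return list of class \code{qtl_spec}.
#' @export
qtl_spec <- function(chr, target_maf = 0.05, effect = 1, dominance = 0,
                     fitness_mode = c("neutral", "additive", "overdominant"),
                     fitness_effect = 0, donor_only = FALSE) {
  fitness_mode <- match.arg(fitness_mode)
  if (target_maf <= 0 || target_maf > 0.5)
    stop("target_maf must be in (0, 0.5]")
  structure(list(chr = chr, target_maf = target_maf, effect = effect,
                 dominance = dominance, fitness_mode = fitness_mode,
                 fitness_effect = fitness_effect, donor_only = donor_only),
            class = "qtl_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: a multi-chromosome
#' SNP panel with pedigree-generated LD, a polygenic trait with
#' per-chromosome variance proportional to chromosome length, sex and age
#' fixed effects, random birth-year / year-of-measurement / permanent
#' environment effects with repeated measures, and annual survival and
#' recruitment records.
#'
#' @param n_founders number of founder individuals.
#' @param n_years number of simulated years (one birth cohort per year).
#' @param chromosomes data.frame with columns \code{snps} and
#'   \code{length_mb}; default \code{\link{default_chromosomes}()}.
#' @param maf_range founder minor-allele-frequency range.
#' @param recomb_rate expected crossovers per Mb per meiosis (0.01 = 1 cM/Mb).
#' @param qtls list of \code{\link{qtl_spec}} objects.
#' @param polygenic_h2 polygenic heritability on the phenotypic scale.
#' @param var_birth_year,var_year,var_pe,var_residual variance shares of the
#'   non-genetic random effects; together with \code{polygenic_h2} they must
#'   sum to 1 (phenotypic variance is on the unit scale; QTL variance comes
#'   on top of it).
#' @param repeat_rate mean number of measures per measured individual (>= 1).
#' @param survival baseline annual survival probability.
#' @param births_per_year birth cohort size as a fraction of living adults.
#' @param sex_effect,age_effect fixed-effect sizes (trait units).
#' @param missing_rate rate of randomly injected missing dosages.
#' @param admixture \code{NULL} or \code{list(donor_generations =,
#'   donor_proportion =)}: a donor breed's haplotypes are introduced
#'   \code{donor_generations} years before the end of the simulation at
#'   proportion \code{donor_proportion} of the population.
#' @param n_ancestral size of the native ancestral haplotype pool.
#' @param n_donor_pool size of the donor ancestral haplotype pool.
#' @param founder_generations mosaic depth of founder haplotypes (controls
#'   the LD block scale: switch rate = founder_generations * recomb_rate).
#' @param seed integer seed; all outputs are deterministic given it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_founders = 80L, n_years = 10L, chromosomes = NULL,
                       maf_range = c(0.05, 0.45), recomb_rate = 0.01,
                       qtls = list(), polygenic_h2 = 0.4,
                       var_birth_year = 0.05, var_year = 0.05, var_pe = 0.1,
                       var_residual = 0.4, repeat_rate = 2.8,
                       survival = 0.75, births_per_year = 0.45,
                       sex_effect = 0.5, age_effect = 0.1, missing_rate = 0,
                       admixture = NULL, n_ancestral = 10L,
                       n_donor_pool = 10L, founder_generations = 50,
                       seed = 1L) {
  if (is.null(chromosomes)) chromosomes <- default_chromosomes()
  if (!all(c("snps", "length_mb") %in% names(chromosomes)))
    stop("chromosomes must have columns 'snps' and 'length_mb'")
  if (any(chromosomes$snps < 1)) stop("snps per chromosome must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] >= 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be increasing within (0, 0.5)")
  shares <- c(polygenic_h2 = polygenic_h2, var_birth_year = var_birth_year,
              var_year = var_year, var_pe = var_pe,
              var_residual = var_residual)
  if (any(shares < 0)) stop("variance shares must be non-negative")
  if (abs(sum(shares) - 1) > 1e-8)
    stop("variance shares must sum to 1, got ", sum(shares))
  if (repeat_rate < 1) stop("repeat_rate must be >= 1")
  if (!is.null(admixture)) {
    if (!all(c("donor_generations", "donor_proportion") %in% names(admixture)))
      stop("admixture needs donor_generations and donor_proportion")
    if (admixture$donor_proportion < 0 || admixture$donor_proportion > 1)
      stop("donor_proportion must be in [0, 1]")
  }
  for (q in qtls) {
    if (!inherits(q, "qtl_spec")) stop("qtls must be qtl_spec objects")
    if (q$chr > nrow(chromosomes)) stop("qtl chromosome index out of range")
    if (q$donor_only &&
        (is.null(admixture) || admixture$donor_proportion == 0))
      stop("donor-only QTL allele requested with donor_proportion = 0")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_years = as.integer(n_years), chromosomes = chromosomes,
                 maf_range = maf_range, recomb_rate = recomb_rate,
                 qtls = qtls, polygenic_h2 = polygenic_h2,
                 var_birth_year = var_birth_year, var_year = var_year,
                 var_pe = var_pe, var_residual = var_residual,
                 repeat_rate = repeat_rate, survival = survival,
                 births_per_year = births_per_year, sex_effect = sex_effect,
                 age_effect = age_effect, missing_rate = missing_rate,
                 admixture = admixture, n_ancestral = as.integer(n_ancestral),
                 n_donor_pool = as.integer(n_donor_pool),
                 founder_generations = founder_generations,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# sample() that never treats a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# mosaic haplotypes over a pool: each output haplotype copies pool rows in
# segments whose boundaries are Poisson on the genetic map
mosaic_haps <- function(n_haps, pool, map, switch_rate_per_mb) {
  m <- ncol(pool)
  H <- matrix(0L, n_haps, m)
  for (ch in unique(map$chr)) {
    j <- which(map$chr == ch)
    bp <- map$bp[j]
    span_mb <- (max(bp) - min(bp)) / 1e6
    lambda <- switch_rate_per_mb * span_mb
    for (h in seq_len(n_haps)) {
      k <- stats::rpois(1, lambda)
      if (k == 0) {
        src <- sample.int(nrow(pool), 1)
        H[h, j] <- pool[src, j]
      } else {
        cuts <- sort(stats::runif(k, min(bp), max(bp)))
        seg <- findInterval(bp, cuts)
        srcs <- sample.int(nrow(pool), k + 1, replace = TRUE)
        H[h, j] <- pool[cbind(srcs[seg + 1L], j)]
      }
    }
  }
  H
}

# one gamete from a parent's two haplotypes
meiose <- function(h1, h2, map, chr_index, recomb_rate) {
  g <- integer(length(h1))
  o <- integer(length(h1))
  for (ci in seq_along(chr_index)) {
    j <- chr_index[[ci]]
    bp <- attr(chr_index, "bp")[[ci]]
    lambda <- attr(chr_index, "lambda")[ci] * recomb_rate
    k <- stats::rpois(1, lambda)
    start <- sample.int(2L, 1L)
    if (k == 0) {
      use1 <- start == 1L
      g[j] <- if (use1) h1[j] else h2[j]
      o[j] <- if (use1) 1L else 2L
    } else {
      cuts <- sort(stats::runif(k, bp[1], bp[length(bp)]))
      seg <- findInterval(bp, cuts)
      use1 <- (seg + start) %% 2L == 1L
      g[j] <- ifelse(use1, h1[j], h2[j])
      o[j] <- ifelse(use1, 1L, 2L)
    }
  }
  list(g = g, o = o)
}

#' Simulate a pedigreed population with genotypes and phased haplotypes
#'
#' Founders receive mosaic haplotypes from a small ancestral pool (per-SNP
#' founder minor-allele frequencies are forced inside \code{maf_range});
#' descendants are produced by Mendelian transmission with Poisson
#' crossovers at \code{recomb_rate} per Mb. Mating is random within year
#' among surviving adults, sexes are assigned 50:50. QTL fitness modes act
#' on survival and on parental sampling weights, so selected alleles change
#' frequency through the pedigree itself. If admixture is configured,
#' immigrant individuals carrying donor-pool haplotypes enter
#' \code{donor_generations} years before the end at the configured
#' proportion; their genetic material is tracked per SNP.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{sim_population}: list with
#'   \code{pedigree}, \code{genotypes} (\code{\link{genotype_set}} over all
#'   individuals), \code{panel} (\code{\link{phased_panel}}), \code{census}
#'   (id, year, age, alive-year survival flags), \code{qtl_table}
#'   (planted QTL SNPs and effects), \code{donor_origin} (logical matrix,
#'   TRUE where a haplotype allele descends from the donor breed),
#'   \code{donor_pool} / \code{native_pool} internals and the config.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrs <- config$chromosomes
  ncr <- nrow(chrs)
  # SNP map
  maps <- vector("list", ncr)
  for (i in seq_len(ncr)) {
    bp <- sort(sample.int(max(2L, as.integer(chrs$length_mb[i] * 1e6)),
                          chrs$snps[i]))
    maps[[i]] <- data.frame(snp = sprintf("c%d_s%d", i, seq_along(bp)),
                            chr = as.character(i), bp = bp,
                            a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  m <- nrow(map)
  chr_index <- lapply(as.character(seq_len(ncr)),
                      function(ch) which(map$chr == ch))
  attr(chr_index, "bp") <- lapply(chr_index, function(j) map$bp[j])
  attr(chr_index, "lambda") <-
    vapply(chr_index, function(j) (max(map$bp[j]) - min(map$bp[j])) / 1e6,
           0)

  # ancestral pools
  p_nat <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  native_pool <- matrix(stats::rbinom(config$n_ancestral * m, 1L,
                                      rep(p_nat, each = config$n_ancestral)),
                        config$n_ancestral, m)
  p_don <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  donor_pool <- matrix(stats::rbinom(config$n_donor_pool * m, 1L,
                                     rep(p_don, each = config$n_donor_pool)),
                       config$n_donor_pool, m)

  nf <- config$n_founders
  switch_rate <- config$founder_generations * config$recomb_rate
  H <- mosaic_haps(2L * nf, native_pool, map, switch_rate)
  pool_anc <- NULL

  # force founder MAF inside maf_range by flipping random haplotype alleles
  lo <- ceiling(2 * nf * config$maf_range[1])
  hi <- floor(2 * nf * config$maf_range[2])
  cnt <- colSums(H)
  for (j in seq_len(m)) {
    c1 <- cnt[j]
    minor1 <- c1 <= nf                       # allele 1 is the minor allele
    cmin <- if (minor1) c1 else 2L * nf - c1
    tgt <- min(max(cmin, lo), hi)
    dif <- tgt - cmin
    if (dif == 0) next
    if (dif > 0) {
      # add minor alleles: flip haplotypes currently carrying the major one
      cand <- which(H[, j] == (if (minor1) 0L else 1L))
      flip <- resample(cand, dif)
      H[flip, j] <- if (minor1) 1L else 0L
    } else {
      cand <- which(H[, j] == (if (minor1) 1L else 0L))
      flip <- resample(cand, -dif)
      H[flip, j] <- if (minor1) 0L else 1L
    }
  }

  # plant QTLs on founder haplotypes (allele 1 = minor trait allele)
  qtl_rows <- list()
  for (q in config$qtls) {
    j_chr <- chr_index[[q$chr]]
    mid <- (map$bp[j_chr[1]] + map$bp[j_chr[length(j_chr)]]) / 2
    jq <- j_chr[which.min(abs(map$bp[j_chr] - mid))]
    H[, jq] <- 0L
    if (!q$donor_only) {
      ncopies <- max(1L, round(2 * nf * q$target_maf))
      # seed the allele on haplotypes sharing local background for LD:
      # rank founder haplotypes by similarity over the 20 flanking SNPs
      fl <- j_chr[abs(match(jq, j_chr) - seq_along(j_chr)) <= 10]
      ref <- H[sample.int(2L * nf, 1L), fl]
      sim <- colSums(abs(t(H[, fl, drop = FALSE]) - ref))
      carriers <- order(sim)[seq_len(ncopies)]
      H[carriers, jq] <- 1L
    }
    qtl_rows[[length(qtl_rows) + 1L]] <-
      data.frame(snp = map$snp[jq], chr = map$chr[jq], bp = map$bp[jq],
                 col = jq, target_maf = q$target_maf, effect = q$effect,
                 dominance = q$dominance, fitness_mode = q$fitness_mode,
                 fitness_effect = q$fitness_effect,
                 donor_only = q$donor_only, stringsAsFactors = FALSE)
  }
  qtl_table <- if (length(qtl_rows)) do.call(rbind, qtl_rows) else
    data.frame(snp = character(0), chr = character(0), bp = integer(0),
               col = integer(0), target_maf = numeric(0), effect = numeric(0),
               dominance = numeric(0), fitness_mode = character(0),
               fitness_effect = numeric(0), donor_only = logical(0))

  # donor-only QTL minor alleles ride on a single introgressed haplotype
  # background: carrier pool rows are made locally identical around the QTL
  if (nrow(qtl_table) > 0) {
    for (r in which(qtl_table$donor_only)) {
      jq <- qtl_table$col[r]
      nc <- max(1L, round(nrow(donor_pool) * 0.3))
      rows_c <- sample.int(nrow(donor_pool), nc)
      jloc <- which(map$chr == map$chr[jq] & abs(map$bp - map$bp[jq]) <= 2e6)
      donor_pool[rows_c, jloc] <- matrix(donor_pool[rows_c[1], jloc],
                                         nrow = nc, ncol = length(jloc),
                                         byrow = TRUE)
      donor_pool[, jq] <- 0L
      donor_pool[rows_c, jq] <- 1L
    }
  }

  # individual bookkeeping (grow in blocks)
  cap <- 2L * nf
  grow <- function(mat, need) {
    while (nrow(mat) < need) mat <- rbind(mat, matrix(0L, nrow(mat), ncol(mat)))
    mat
  }
  haps <- H                                   # 2 rows per individual
  donor_flag <- matrix(FALSE, 2L * nf, m)     # donor descent per hap x SNP
  n_ind <- nf
  sex <- sample(rep(c("F", "M"), length.out = nf))
  birth_year <- rep(0L, nf)
  sire <- rep(NA_character_, nf)
  dam <- rep(NA_character_, nf)
  alive <- rep(TRUE, nf)
  census <- list()

  fit_mult <- function(ind_rows) {
    # multiplicative fitness from QTL genotypes; ind_rows = individual indices
    w <- rep(1, length(ind_rows))
    if (nrow(qtl_table) == 0) return(w)
    for (r in seq_len(nrow(qtl_table))) {
      if (qtl_table$fitness_mode[r] == "neutral") next
      jq <- qtl_table$col[r]
      dos <- haps[2L * ind_rows - 1L, jq] + haps[2L * ind_rows, jq]
      fe <- qtl_table$fitness_effect[r]
      w <- w * switch(qtl_table$fitness_mode[r],
                      additive = 1 + fe * dos,
                      overdominant = 1 + fe * (dos == 1L))
    }
    pmax(w, 0.01)
  }

  adm <- config$admixture
  t_imm <- if (is.null(adm) || adm$donor_proportion == 0) NA_integer_ else
    max(1L, config$n_years - as.integer(adm$donor_generations))

  for (t in seq_len(config$n_years)) {
    # immigrants enter before this year's matings
    if (!is.na(t_imm) && t == t_imm) {
      na_alive <- sum(alive)
      n_imm <- max(2L, round(adm$donor_proportion / (1 - adm$donor_proportion)
                             * na_alive))
      Himm <- mosaic_haps(2L * n_imm, donor_pool, map, switch_rate)
      need <- 2L * (n_ind + n_imm)
      haps <- grow(haps, need)
      donor_flag <- grow(donor_flag, need) > 0  # keep logical
      rows <- (2L * n_ind + 1L):(2L * (n_ind + n_imm))
      haps[rows, ] <- Himm
      donor_flag[rows, ] <- TRUE
      sex <- c(sex, sample(rep(c("F", "M"), length.out = n_imm)))
      birth_year <- c(birth_year, rep(t - 1L, n_imm))
      sire <- c(sire, rep(NA_character_, n_imm))
      dam <- c(dam, rep(NA_character_, n_imm))
      alive <- c(alive, rep(TRUE, n_imm))
      n_ind <- n_ind + n_imm
    }

    adults <- which(alive & birth_year < t)
    females <- adults[sex[adults] == "F"]
    males <- adults[sex[adults] == "M"]
    n_births <- if (length(females) > 0 && length(males) > 0)
      max(1L, round(config$births_per_year * length(adults))) else 0L
    if (n_births > 0) {
      wf <- fit_mult(females)
      wm <- fit_mult(males)
      dams <- resample(females, n_births, replace = TRUE, prob = wf)
      sires <- resample(males, n_births, replace = TRUE, prob = wm)
      need <- 2L * (n_ind + n_births)
      haps <- grow(haps, need)
      donor_flag <- grow(donor_flag, need) > 0
      for (b in seq_len(n_births)) {
        child <- n_ind + b
        dm <- dams[b]; sr <- sires[b]
        gm <- meiose(haps[2L * dm - 1L, ], haps[2L * dm, ], map, chr_index,
                     config$recomb_rate)
        gp <- meiose(haps[2L * sr - 1L, ], haps[2L * sr, ], map, chr_index,
                     config$recomb_rate)
        haps[2L * child - 1L, ] <- gm$g
        haps[2L * child, ] <- gp$g
        donor_flag[2L * child - 1L, ] <-
          ifelse(gm$o == 1L, donor_flag[2L * dm - 1L, ],
                 donor_flag[2L * dm, ])
        donor_flag[2L * child, ] <-
          ifelse(gp$o == 1L, donor_flag[2L * sr - 1L, ],
                 donor_flag[2L * sr, ])
      }
      sex <- c(sex, sample(rep(c("F", "M"), length.out = n_births)))
      birth_year <- c(birth_year, rep(t, n_births))
      sire <- c(sire, sprintf("I%d", sires))
      dam <- c(dam, sprintf("I%d", dams))
      alive <- c(alive, rep(TRUE, n_births))
      n_ind <- n_ind + n_births
    }

    # survival past the end of year t for everyone alive during year t
    cur <- which(alive)
    w <- fit_mult(cur)
    psurv <- pmin(0.99, config$survival * w)
    surv <- stats::rbinom(length(cur), 1L, psurv) == 1L
    if (!any(surv) && t < config$n_years)
      surv[sample.int(length(cur), min(2L, length(cur)))] <- TRUE
    census[[t]] <- data.frame(id = sprintf("I%d", cur), year = t,
                              age = t - birth_year[cur],
                              survived = surv, stringsAsFactors = FALSE)
    alive[cur[!surv]] <- FALSE
  }

  ids <- sprintf("I%d", seq_len(n_ind))
  haps <- haps[seq_len(2L * n_ind), , drop = FALSE]
  donor_flag <- donor_flag[seq_len(2L * n_ind), , drop = FALSE]
  ped <- pedigree(ids, sire, dam, sex, birth_year)
  panel <- phased_panel(haps, map, ids, pop = "focal")
  geno <- panel_dosage(panel)
  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(geno$dosage))
    if (nmiss > 0) {
      idx <- sample.int(length(geno$dosage), nmiss)
      geno$dosage[idx] <- NA_integer_
    }
  }
  census <- do.call(rbind, census)
  structure(list(pedigree = ped, genotypes = geno, panel = panel,
                 census = census, qtl_table = qtl_table,
                 donor_origin = donor_flag, donor_pool = donor_pool,
                 native_pool = native_pool, alive_final = alive,
                 config = config),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat("sim_population:", nrow(x$pedigree), "individuals over",
      x$config$n_years, "years;", nrow(x$genotypes$map), "SNPs on",
      nrow(x$config$chromosomes), "chromosomes;",
      nrow(x$qtl_table), "QTL(s)\n")
  invisible(x)
}

#' Simulate trait values and repeated phenotype records
#'
#' Breeding values are the sum of planted QTL effects and a polygenic part
#' built from per-chromosome sums of SNP effects whose variances are
#' proportional to chromosome length; the polygenic part is rescaled so its
#' realized variance equals \code{polygenic_h2} on the unit phenotypic
#' scale. Birth-year, year-of-measurement, permanent-environment and
#' residual deviations are added with the configured variances, plus sex and
#' age fixed effects. Individuals are measured in years they were alive at
#' age >= 1; the number of repeat measures is 1 + Poisson(repeat_rate - 1),
#' capped by the years available.
#'
#' @param pop a \code{\link{simulate_population}} result.
#' @param config a \code{\link{sim_config}} (default: the one in \code{pop}).
#' @return data.frame with columns id, sex, age, year_of_measurement,
#'   birth_year, trait (repeated rows per id). Attribute \code{"truth"}
#'   holds the per-individual breeding values and their polygenic/QTL split.
#' @export
simulate_trait_and_phenotypes <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(config$seed + 1L)
  map <- pop$genotypes$map
  haps <- pop$panel$haps
  n <- length(pop$panel$ids)
  dos <- pop$panel$haps[seq(1, 2 * n, 2), , drop = FALSE] +
    pop$panel$haps[seq(2, 2 * n, 2), , drop = FALSE]
  chrs <- config$chromosomes
  total_len <- sum(chrs$length_mb)

  g_poly <- rep(0, n)
  qtl_cols <- pop$qtl_table$col
  for (i in seq_len(nrow(chrs))) {
    j <- setdiff(which(map$chr == as.character(i)), qtl_cols)
    if (length(j) == 0) next
    b <- stats::rnorm(length(j))
    gc <- drop(dos[, j, drop = FALSE] %*% b)
    v <- stats::var(gc)
    if (v <= 0) next
    tgt <- config$polygenic_h2 * chrs$length_mb[i] / total_len
    g_poly <- g_poly + (gc - mean(gc)) * sqrt(tgt / v)
  }
  vg <- stats::var(g_poly)
  if (config$polygenic_h2 > 0 && vg > 0)
    g_poly <- g_poly * sqrt(config$polygenic_h2 / vg)

  g_qtl <- rep(0, n)
  if (nrow(pop$qtl_table) > 0) {
    for (r in seq_len(nrow(pop$qtl_table))) {
      dq <- dos[, pop$qtl_table$col[r]]
      g_qtl <- g_qtl + pop$qtl_table$effect[r] * dq +
        pop$qtl_table$dominance[r] * (dq == 1L)
    }
    g_qtl <- g_qtl - mean(g_qtl)
  }
  bv <- g_poly + g_qtl

  ped <- pop$pedigree
  years <- sort(unique(pop$census$year))
  by_dev <- stats::rnorm(length(unique(ped$birth_year)),
                         sd = sqrt(config$var_birth_year))
  names(by_dev) <- sort(unique(ped$birth_year))
  yr_dev <- stats::rnorm(length(years), sd = sqrt(config$var_year))
  names(yr_dev) <- years
  pe_dev <- stats::rnorm(n, sd = sqrt(config$var_pe))

  rows <- list()
  cen <- split(pop$census, pop$census$id)
  for (i in seq_len(n)) {
    id <- pop$panel$ids[i]
    ci <- cen[[id]]
    if (is.null(ci)) next
    adult <- ci[ci$age >= 1, , drop = FALSE]
    if (nrow(adult) == 0) next
    k <- min(nrow(adult), 1L + stats::rpois(1, config$repeat_rate - 1))
    take <- adult[sample.int(nrow(adult), k), , drop = FALSE]
    e <- stats::rnorm(k, sd = sqrt(config$var_residual))
    yv <- 10 + config$sex_effect * (ped$sex[i] == "M") +
      config$age_effect * pmin(take$age, 6L) + bv[i] +
      by_dev[as.character(ped$birth_year[i])] +
      yr_dev[as.character(take$year)] + pe_dev[i] + e
    rows[[length(rows) + 1L]] <-
      data.frame(id = id, sex = ped$sex[i], age = take$age,
                 year_of_measurement = take$year,
                 birth_year = ped$birth_year[i], trait = yv,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(ids = pop$panel$ids, bv = bv,
                             polygenic = g_poly, qtl = g_qtl)
  out
}

#' Annual and lifetime fitness records of a simulated population
#'
#' Returns the generator's own bookkeeping of annual survival (AS), annual
#' recruits (AR), lifetime breeding success (LBS) and lifetime recruits
#' (LR), computed directly from the simulated survival draws and offspring
#' lists. Recruitment follows the standard definition: an offspring is a
#' recruit if it survived past the end of its birth year.
#'
#' @param pop a \code{\link{simulate_population}} result.
#' @param config unused; present for interface symmetry.
#' @return list with \code{annual} (id, year, sex, age, AS, AR) and
#'   \code{lifetime} (id, sex, birth_year, LBS, LR) data.frames.
#' @export
simulate_fitness_records <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  ped <- pop$pedigree
  cen <- pop$census
  # recruit flag per individual: survived its birth year
  first <- cen[!duplicated(cen$id), ]               # census is year-ordered
  first_year <- stats::setNames(first$year, first$id)
  byid <- stats::setNames(ped$birth_year, ped$id)
  rec <- stats::setNames(rep(FALSE, nrow(ped)), ped$id)
  by_rows <- cen[cen$year == byid[cen$id], ]
  rec[by_rows$id] <- by_rows$survived
  sexv <- stats::setNames(ped$sex, ped$id)

  ann <- cen
  ann$AS <- as.integer(ann$survived)
  ann$sex <- sexv[ann$id]
  # offspring born in year t to each parent, recruited or not
  kids <- ped[!is.na(ped$sire) | !is.na(ped$dam), ]
  ar <- function(parent_col) {
    k <- kids[!is.na(kids[[parent_col]]), ]
    key <- paste(k[[parent_col]], k$birth_year)
    tab_all <- table(key)
    tab_rec <- table(key[rec[k$id]])
    list(all = tab_all, rec = tab_rec)
  }
  td <- ar("dam"); ts <- ar("sire")
  keyv <- paste(ann$id, ann$year)
  ann$AR <- ifelse(ann$sex == "F",
                   as.integer(td$rec[keyv]), as.integer(ts$rec[keyv]))
  ann$AR[is.na(ann$AR)] <- 0L
  annual <- ann[, c("id", "year", "sex", "age", "AS", "AR")]
  rownames(annual) <- NULL

  n_off <- function(parent_col) {
    k <- kids[!is.na(kids[[parent_col]]), ]
    list(all = table(k[[parent_col]]), rec = table(k[[parent_col]][rec[k$id]]))
  }
  od <- n_off("dam"); os <- n_off("sire")
  lbs <- ifelse(ped$sex == "F", as.integer(od$all[ped$id]),
                as.integer(os$all[ped$id]))
  lr <- ifelse(ped$sex == "F", as.integer(od$rec[ped$id]),
               as.integer(os$rec[ped$id]))
  lbs[is.na(lbs)] <- 0L
  lr[is.na(lr)] <- 0L
  lifetime <- data.frame(id = ped$id, sex = ped$sex,
                         birth_year = ped$birth_year, LBS = lbs, LR = lr,
                         stringsAsFactors = FALSE)
  list(annual = annual, lifetime = lifetime)
}

#' Build focal/donor/outgroup breed panels for haplotype-sharing analysis
#'
#' The focal samples come from the simulated admixed population (individuals
#' alive in the final year); the donor panel holds fresh haplotypes from the
#' same donor ancestral pool whose material was introgressed; outgroups are
#' panels from independent ancestral pools. Donor-derived segments in the
#' focal panel (tracked through transmission) are summarised in attribute
#' \code{"donor_segments"}.
#'
#' @param pop a \code{\link{simulate_population}} result whose config set
#'   \code{admixture} (or any population; with no admixture the focal panel
#'   simply carries no donor segments).
#' @param config a \code{\link{sim_config}} (default: the one in \code{pop}).
#' @param n_focal,n_donor,n_per_outgroup panel sizes (individuals).
#' @param n_outgroups number of outgroup breeds.
#' @return A \code{\link{phased_panel}} with population labels
#'   \code{focal}, \code{donor}, \code{outgroup_1...}; attribute
#'   \code{"donor_segments"} is a data.frame of donor tract lengths (bp) in
#'   the focal panel.
#' @export
simulate_breed_panel <- function(pop, config = pop$config, n_focal = 40L,
                                 n_donor = 20L, n_per_outgroup = 20L,
                                 n_outgroups = 3L) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(config$seed + 2L)
  map <- pop$genotypes$map
  m <- nrow(map)
  switch_rate <- config$founder_generations * config$recomb_rate
  final <- which(pop$alive_final)
  if (length(final) == 0) final <- seq_along(pop$panel$ids)
  take <- if (length(final) > n_focal) resample(final, n_focal) else final
  rows <- as.vector(rbind(2L * take - 1L, 2L * take))
  Hf <- pop$panel$haps[rows, , drop = FALSE]
  ids_f <- pop$panel$ids[take]
  seg_f <- pop$donor_origin[rows, , drop = FALSE]

  Hd <- mosaic_haps(2L * n_donor, pop$donor_pool, map, switch_rate)
  ids_d <- sprintf("D%d", seq_len(n_donor))
  Ho <- list(); ids_o <- list(); pop_o <- list()
  for (k in seq_len(n_outgroups)) {
    p_k <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    pool_k <- matrix(stats::rbinom(config$n_ancestral * m, 1L,
                                   rep(p_k, each = config$n_ancestral)),
                     config$n_ancestral, m)
    Ho[[k]] <- mosaic_haps(2L * n_per_outgroup, pool_k, map, switch_rate)
    ids_o[[k]] <- sprintf("O%d_%d", k, seq_len(n_per_outgroup))
    pop_o[[k]] <- rep(sprintf("outgroup_%d", k), n_per_outgroup)
  }
  panel <- phased_panel(rbind(Hf, Hd, do.call(rbind, Ho)), map,
                        c(ids_f, ids_d, unlist(ids_o)),
                        c(rep("focal", length(ids_f)),
                          rep("donor", n_donor), unlist(pop_o)))
  attr(panel, "donor_segments") <- donor_segment_table(seg_f, map)
  panel
}

# run-length summary of donor-descended tracts per haplotype, in bp
donor_segment_table <- function(flags, map) {
  out <- list()
  for (ch in unique(map$chr)) {
    j <- which(map$chr == ch)
    bp <- map$bp[j]
    for (h in seq_len(nrow(flags))) {
      r <- rle(flags[h, j])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      don <- which(r$values)
      if (length(don) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        hap = h, chr = ch, n_snps = r$lengths[don],
        bp_start = bp[starts[don]], bp_end = bp[ends[don]],
        length_bp = bp[ends[don]] - bp[starts[don]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(hap = integer(0), chr = character(0),
                      n_snps = integer(0), bp_start = integer(0),
                      bp_end = integer(0), length_bp = integer(0)))
  do.call(rbind, out)
}
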