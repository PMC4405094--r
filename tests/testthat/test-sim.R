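# Forward pedigree simulator: determinism, Mendelian transmission, founder
# allele frequencies, LD decay, trait variance structure, fitness modes and
# the admixture machinery.

small_cfg <- function(...) {
  sim_config(n_founders = 40, n_years = 6,
             chromosomes = data.frame(snps = c(60, 40),
                                      length_mb = c(50, 30)), ...)
}

test_that("outputs are bit-identical across runs with a fixed seed", {
  p1 <- simulate_population(small_cfg(seed = 9))
  p2 <- simulate_population(small_cfg(seed = 9))
  expect_identical(p1$panel$haps, p2$panel$haps)
  expect_identical(as.data.frame(p1$pedigree), as.data.frame(p2$pedigree))
  expect_identical(p1$census, p2$census)
  ph1 <- simulate_trait_and_phenotypes(p1)
  ph2 <- simulate_trait_and_phenotypes(p2)
  expect_identical(ph1, ph2)
  p3 <- simulate_population(small_cfg(seed = 10))
  expect_false(identical(p1$panel$haps, p3$panel$haps))
})

test_that("with no recombination every transmitted chromosome copies one parental haplotype", {
  pop <- simulate_population(small_cfg(recomb_rate = 0, seed = 3))
  ped <- pop$pedigree
  map <- pop$genotypes$map
  kids <- which(!is.na(ped$dam))
  for (i in kids[seq_len(min(30, length(kids)))]) {
    dm <- match(ped$dam[i], ped$id)
    for (ch in unique(map$chr)) {
      j <- which(map$chr == ch)
      child_m <- pop$panel$haps[2 * i - 1, j]      # maternal gamete
      expect_true(identical(child_m, pop$panel$haps[2 * dm - 1, j]) ||
                    identical(child_m, pop$panel$haps[2 * dm, j]))
    }
  }
})

test_that("every offspring allele is consistent with its parents' haplotypes", {
  pop <- simulate_population(small_cfg(seed = 4))
  ped <- pop$pedigree
  H <- pop$panel$haps
  for (i in which(!is.na(ped$dam))) {
    dm <- match(ped$dam[i], ped$id)
    sr <- match(ped$sire[i], ped$id)
    ok_m <- H[2 * i - 1, ] == H[2 * dm - 1, ] | H[2 * i - 1, ] == H[2 * dm, ]
    ok_p <- H[2 * i, ] == H[2 * sr - 1, ] | H[2 * i, ] == H[2 * sr, ]
    expect_true(all(ok_m) && all(ok_p))
  }
  # dosage = hap sum
  expect_identical(pop$genotypes$dosage,
                   panel_dosage(pop$panel)$dosage)
})

test_that("founder minor-allele frequencies land inside maf_range", {
  cfg <- small_cfg(maf_range = c(0.1, 0.4), seed = 5)
  pop <- simulate_population(cfg)
  founders <- which(is.na(pop$pedigree$sire) & is.na(pop$pedigree$dam) &
                      pop$pedigree$birth_year == 0)
  rows <- as.vector(rbind(2 * founders - 1, 2 * founders))
  f <- colMeans(pop$panel$haps[rows, ])
  maf <- pmin(f, 1 - f)
  nf <- length(founders)
  expect_true(all(maf >= floor(2 * nf * 0.1) / (2 * nf) - 1e-9))
  expect_true(all(maf <= 0.4 + 1e-9))
})

test_that("Mendelian offspring dosages from fixed parents follow the cross table", {
  # het x het cross: many offspring, dosage distribution 1/4, 1/2, 1/4
  cfg <- sim_config(n_founders = 2, n_years = 1,
                    chromosomes = data.frame(snps = 1, length_mb = 1),
                    maf_range = c(0.4, 0.499), births_per_year = 60,
                    survival = 0.99, seed = 6)
  pop <- simulate_population(cfg)
  founders <- 1:2
  fd <- pop$genotypes$dosage[founders, 1]
  kids <- which(!is.na(pop$pedigree$dam))
  kd <- pop$genotypes$dosage[kids, 1]
  if (all(fd == 1)) {
    tab <- tabulate(kd + 1, 3) / length(kd)
    expect_gt(length(kd), 40)
    cs <- stats::chisq.test(tabulate(kd + 1, 3), p = c(.25, .5, .25))
    expect_gt(cs$p.value, 0.001)
  } else {
    # general law: offspring dosage bounded by parental half-sums
    expect_true(all(kd >= max(0, sum(fd) - 2) & kd <= min(2, sum(fd))))
  }
})

test_that("adjacent-SNP r-squared decays with physical distance", {
  cfg <- sim_config(n_founders = 250, n_years = 2,
                    chromosomes = data.frame(snps = rep(600, 2),
                                             length_mb = rep(100, 2)),
                    seed = 2)
  pop <- simulate_population(cfg)
  map <- pop$genotypes$map
  H <- pop$panel$haps
  r2 <- dist_mb <- c()
  for (ch in unique(map$chr)) {
    j <- which(map$chr == ch)
    # brute-force r^2 by definition over all adjacent pairs
    for (k in seq_len(length(j) - 1)) {
      a <- H[, j[k]]; b <- H[, j[k + 1]]
      if (stats::var(a) == 0 || stats::var(b) == 0) next
      pa <- mean(a); pb <- mean(b); pab <- mean(a * b)
      r2 <- c(r2, (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb)))
      dist_mb <- c(dist_mb, (map$bp[j[k + 1]] - map$bp[j[k]]) / 1e6)
    }
  }
  bins <- cut(dist_mb, c(0, 0.05, 0.3, 2))
  means <- tapply(r2, bins, mean)
  expect_true(all(diff(means) < 0))          # monotone decay across bins
  expect_gt(means[1], 1.5 * means[3])
})

test_that("phenotypic variance matches the configured unit scale at large n", {
  cfg <- sim_config(n_founders = 350, n_years = 6, births_per_year = 0.4,
                    chromosomes = data.frame(snps = 60, length_mb = 50),
                    seed = 13)
  pop <- simulate_population(cfg)
  ph <- simulate_trait_and_phenotypes(pop)
  expect_gt(nrow(ph), 1500)
  # remove fixed effects, then the variance of the rest should be ~1
  r <- stats::resid(stats::lm(trait ~ sex + factor(pmin(age, 6)), ph))
  expect_lt(abs(stats::var(r) - 1), 0.12)
  # realized breeding-value share equals the configured heritability
  tr <- attr(ph, "truth")
  expect_equal(stats::var(tr$bv), 0.4, tolerance = 1e-6)
})

test_that("variance shares not summing to one are rejected", {
  expect_error(small_cfg(polygenic_h2 = 0.5, var_residual = 0.6),
               "sum to 1")
  expect_error(small_cfg(polygenic_h2 = -0.1, var_residual = 1.1),
               "non-negative")
})

test_that("all variance in the residual gives phenotype variance near the residual variance", {
  cfg <- sim_config(n_founders = 200, n_years = 4,
                    chromosomes = data.frame(snps = 40, length_mb = 30),
                    polygenic_h2 = 0, var_birth_year = 0, var_year = 0,
                    var_pe = 0, var_residual = 1, repeat_rate = 1,
                    sex_effect = 0, age_effect = 0, seed = 14)
  pop <- simulate_population(cfg)
  ph <- simulate_trait_and_phenotypes(pop)
  expect_lt(abs(stats::var(ph$trait) - 1), 0.15)
})

test_that("a planted QTL contributes close to 2pq a^2 of variance", {
  cfg <- sim_config(n_founders = 250, n_years = 5,
                    chromosomes = data.frame(snps = 80, length_mb = 60),
                    qtls = list(qtl_spec(1, target_maf = 0.05, effect = 1.2)),
                    seed = 15)
  pop <- simulate_population(cfg)
  ph <- simulate_trait_and_phenotypes(pop)
  tr <- attr(ph, "truth")
  j <- pop$qtl_table$col
  q <- mean(pop$genotypes$dosage[, j]) / 2
  expect_equal(stats::var(tr$qtl), 2 * q * (1 - q) * 1.2^2, tolerance = 0.1)
})

test_that("neutral QTLs leave genotype fitness differences within sampling error", {
  cfg <- sim_config(n_founders = 150, n_years = 8,
                    chromosomes = data.frame(snps = 50, length_mb = 40),
                    qtls = list(qtl_spec(1, target_maf = 0.3, effect = 0)),
                    seed = 16)
  pop <- simulate_population(cfg)
  fr <- simulate_fitness_records(pop)
  g <- stats::setNames(pop$genotypes$dosage[, pop$qtl_table$col],
                       pop$genotypes$ids)
  as_by_g <- tapply(fr$annual$AS, g[fr$annual$id], mean)
  expect_lt(max(as_by_g) - min(as_by_g), 0.12)
})

test_that("overdominant fitness gives heterozygotes the highest mean annual recruits", {
  cfg <- sim_config(n_founders = 150, n_years = 10,
                    chromosomes = data.frame(snps = 50, length_mb = 40),
                    qtls = list(qtl_spec(1, target_maf = 0.25, effect = 0,
                                         fitness_mode = "overdominant",
                                         fitness_effect = 0.4)),
                    seed = 5)
  pop <- simulate_population(cfg)
  fr <- simulate_fitness_records(pop)
  g <- stats::setNames(pop$genotypes$dosage[, pop$qtl_table$col],
                       pop$genotypes$ids)
  ar_by_g <- tapply(fr$annual$AR, g[fr$annual$id], mean)
  expect_identical(names(which.max(ar_by_g)), "1")
})

test_that("an additive fitness cost drives the minor allele down over years", {
  dec <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_founders = 120, n_years = 12,
                      chromosomes = data.frame(snps = 40, length_mb = 30),
                      qtls = list(qtl_spec(1, target_maf = 0.35, effect = 0,
                                           fitness_mode = "additive",
                                           fitness_effect = -0.35)),
                      seed = 16 + s)
    pop <- simulate_population(cfg)
    g <- pop$genotypes$dosage[, pop$qtl_table$col]
    ids <- pop$genotypes$ids
    yr_f <- vapply(sort(unique(pop$census$year)), function(y) {
      mem <- pop$census$id[pop$census$year == y]
      mean(g[match(mem, ids)]) / 2
    }, 0)
    if (unname(stats::coef(stats::lm(yr_f ~ seq_along(yr_f)))[2]) < 0)
      dec <- dec + 1
  }
  expect_gte(dec, 2)
})

test_that("fitness records round-trip through the pedigree/census derivation", {
  pop <- simulate_population(small_cfg(seed = 18))
  fr <- simulate_fitness_records(pop)
  df <- derive_fitness(pop$pedigree, pop$census)
  expect_identical(fr$annual$AS, df$annual$AS)
  expect_identical(fr$annual$AR, df$annual$AR)
  expect_identical(fr$lifetime$LBS, df$lifetime$LBS)
  expect_identical(fr$lifetime$LR, df$lifetime$LR)
  expect_true(all(fr$lifetime$LBS >= fr$lifetime$LR))
})

test_that("admixture bookkeeping: g = 0 spans chromosomes, proportion 0 leaves none", {
  cfg0 <- small_cfg(admixture = list(donor_generations = 0,
                                     donor_proportion = 0.3), seed = 19)
  pop0 <- simulate_population(cfg0)
  panel0 <- simulate_breed_panel(pop0, n_focal = 60)
  segs0 <- attr(panel0, "donor_segments")
  expect_gt(nrow(segs0), 0)
  # immigrants enter in the final year: their tracts span whole chromosomes
  map <- pop0$genotypes$map
  for (ch in unique(segs0$chr)) {
    full_span <- diff(range(map$bp[map$chr == ch]))
    expect_true(all(segs0$length_bp[segs0$chr == ch] == full_span))
  }
  popn <- simulate_population(small_cfg(seed = 19))
  pann <- simulate_breed_panel(popn, n_focal = 60)
  expect_identical(nrow(attr(pann, "donor_segments")), 0L)
})

test_that("donor tract lengths shrink as the admixture event recedes", {
  seg_mean <- function(g, seed) {
    cfg <- sim_config(n_founders = 60, n_years = 14,
                      chromosomes = data.frame(snps = 200, length_mb = 100),
                      admixture = list(donor_generations = g,
                                       donor_proportion = 0.25),
                      seed = seed)
    pop <- simulate_population(cfg)
    panel <- simulate_breed_panel(pop, n_focal = 60)
    mean(attr(panel, "donor_segments")$length_bp)
  }
  m2 <- mean(vapply(1:2, function(s) seg_mean(2, 1200 + s), 0))
  m6 <- mean(vapply(1:2, function(s) seg_mean(6, 1300 + s), 0))
  m12 <- mean(vapply(1:2, function(s) seg_mean(12, 1400 + s), 0))
  expect_gt(m2, m6)
  expect_gt(m6, m12)
  expect_gt(m2, 1.8 * m12)
})

test_that("a donor-only QTL allele with zero donor proportion is refused", {
  expect_error(
    small_cfg(qtls = list(qtl_spec(1, donor_only = TRUE)), seed = 1),
    "donor_proportion")
  # and with admixture configured, the allele sits only on donor haplotypes
  cfg <- small_cfg(qtls = list(qtl_spec(1, target_maf = 0.1, effect = 0.5,
                                        donor_only = TRUE)),
                   admixture = list(donor_generations = 3,
                                    donor_proportion = 0.3),
                   seed = 20)
  pop <- simulate_population(cfg)
  j <- pop$qtl_table$col
  carriers <- pop$panel$haps[, j] == 1
  expect_gt(sum(carriers), 0)
  expect_true(all(pop$donor_origin[carriers, j]))
})

test_that("missing-dosage injection hits the configured rate", {
  pop <- simulate_population(small_cfg(missing_rate = 0.02, seed = 21))
  rate <- mean(is.na(pop$genotypes$dosage))
  expect_equal(rate, 0.02, tolerance = 0.005)
})
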