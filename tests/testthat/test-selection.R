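# Fitness derivation, selection coefficients, the overdominance equilibrium
# and the gene-drop drift null.

toy_ped_census <- function() {
  # ewe e1 has 3 lambs (k1..k3) of which 2 survive their birth year
  ped <- pedigree(id = c("e1", "r1", "k1", "k2", "k3"),
                  sire = c(NA, NA, "r1", "r1", "r1"),
                  dam = c(NA, NA, "e1", "e1", "e1"),
                  sex = c("F", "M", "F", "M", "M"),
                  birth_year = c(2000L, 2000L, 2002L, 2002L, 2003L))
  census <- data.frame(
    id = c("e1", "e1", "e1", "e1", "r1", "r1", "r1", "r1",
           "k1", "k2", "k2", "k3"),
    year = c(2001L, 2002L, 2003L, 2004L, 2001L, 2002L, 2003L, 2004L,
             2002L, 2002L, 2003L, 2003L),
    survived = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                 FALSE, TRUE, FALSE, TRUE))
  list(ped = ped, census = census)
}

test_that("a ewe with 3 lambs of which 2 recruit gets LBS 3 and LR 2", {
  tc <- toy_ped_census()
  f <- derive_fitness(tc$ped, tc$census)
  lf <- f$lifetime
  expect_identical(lf$LBS[lf$id == "e1"], 3L)
  expect_identical(lf$LR[lf$id == "e1"], 2L)   # k2 and k3 recruit
  expect_identical(lf$LBS[lf$id == "r1"], 3L)
  # individuals with no offspring: all zero
  expect_identical(lf$LBS[lf$id == "k1"], 0L)
  expect_identical(lf$LR[lf$id == "k1"], 0L)
  # annual recruits appear in the offspring's birth year
  an <- f$annual
  expect_identical(an$AR[an$id == "e1" & an$year == 2002], 1L)  # k2 only
  expect_identical(an$AR[an$id == "e1" & an$year == 2003], 1L)  # k3
  expect_identical(an$AR[an$id == "e1" & an$year == 2001], 0L)
  expect_identical(an$AS[an$id == "e1" & an$year == 2004], 0L)
})

test_that("the lifetime cohort window restricts who is reported", {
  tc <- toy_ped_census()
  f <- derive_fitness(tc$ped, tc$census, cohort_window = c(1999, 2001))
  expect_setequal(f$lifetime$id, c("e1", "r1"))
})

test_that("census ids missing from the pedigree are an error", {
  tc <- toy_ped_census()
  tc$census$id[1] <- "ghost"
  expect_error(derive_fitness(tc$ped, tc$census), "ghost")
})

test_that("selection coefficients follow the relative-fitness arithmetic", {
  # genotype means 1.0, 1.25, 0.5 -> w = (0.8, 1, 0.4), s = (0.2, 0, 0.6)
  g <- stats::setNames(rep(0:2, each = 20), sprintf("i%d", 1:60))
  f <- stats::setNames(rep(c(1, 1.25, 0.5), each = 20), names(g))
  est <- selection_coefficients(f, g, n_boot = 50, seed = 2)
  expect_equal(est$w, c(0.8, 1, 0.4))
  expect_equal(est$s, c(0.2, 0, 0.6))
  # invariant to multiplying all fitness values by a positive constant
  est2 <- selection_coefficients(7.3 * f, g, n_boot = 50, seed = 2)
  expect_equal(est2$s, est$s)
  # equal means: all s = 0
  est3 <- selection_coefficients(stats::setNames(rep(2, 60), names(g)), g,
                                 n_boot = 20, seed = 1)
  expect_equal(est3$s, rep(0, 3))
  # all-zero fitness refused
  expect_error(selection_coefficients(stats::setNames(rep(0, 60), names(g)),
                                      g, n_boot = 10),
               "zero mean fitness")
})

test_that("rare genotype classes are flagged and bootstrap CIs cover the point estimate", {
  set.seed(4)
  g <- stats::setNames(c(rep(0L, 50), rep(1L, 30), rep(2L, 3)),
                       sprintf("i%d", 1:83))
  f <- stats::setNames(rpois(83, lambda = c(1, 1.6, 0.8)[g + 1]), names(g))
  est <- selection_coefficients(f, g, n_boot = 200, seed = 5)
  expect_identical(est$flagged_small, c(FALSE, FALSE, TRUE))
  ok <- est$s >= est$s_lo - 1e-9 & est$s <= est$s_hi + 1e-9
  expect_true(all(ok))
})

test_that("equilibrium frequency arithmetic and guards", {
  expect_equal(equilibrium_frequency(0.2, 0.2)$q_eq, 0.5)
  expect_equal(equilibrium_frequency(0.1, 0.3)$q_eq, 0.25)
  expect_equal(equilibrium_frequency(0, 0.3)$q_eq, 0)
  expect_error(equilibrium_frequency(0, 0), "undefined")
  expect_error(equilibrium_frequency(-0.1, 0.2), "non-negative")
})

test_that("equilibrium frequency from an estimate requires heterozygote advantage", {
  g <- stats::setNames(rep(0:2, each = 25), sprintf("i%d", 1:75))
  f_het <- stats::setNames(rep(c(1, 2, 0.5), each = 25), names(g))
  est <- selection_coefficients(f_het, g, n_boot = 100, seed = 6)
  q <- equilibrium_frequency(est)
  expect_equal(q$q_eq, est$s[1] / (est$s[1] + est$s[3]))
  expect_true(q$q_lo <= q$q_eq && q$q_eq <= q$q_hi)
  f_add <- stats::setNames(rep(c(2, 1.5, 1), each = 25), names(g))
  est2 <- selection_coefficients(f_add, g, n_boot = 20, seed = 6)
  expect_error(equilibrium_frequency(est2), "not the fittest")
})

test_that("gene-drop transmission from a het-by-het founder pair is binomial", {
  ped <- pedigree(id = c("f", "m", sprintf("k%d", 1:40)),
                  sire = c(NA, NA, rep("m", 40)),
                  dam = c(NA, NA, rep("f", 40)),
                  sex = c("F", "M", rep(c("F", "M"), 20)),
                  birth_year = c(0L, 0L, rep(1:4, each = 10)))
  mem <- data.frame(id = rep(ped$id, 3),
                    year = rep(2:4, each = nrow(ped)))
  g <- stats::setNames(c(1L, 1L, rep(NA_integer_, 40)), ped$id)
  g[3:42] <- 1L   # observed values irrelevant for descendants (re-dropped)
  # the observed series is flat at 0.5, so the regression fit is degenerate
  tt <- suppressWarnings(allele_trend_test(g, ped, mem, n_reps = 600,
                                           seed = 7))
  # each offspring allele count is Binomial(2, 1/2) under the drop:
  # mean yearly frequency across replicates should be 0.5
  expect_equal(mean(tt$null_slopes), 0, tolerance = 0.004)
})

test_that("gene-drop final frequencies are unbiased against the pedigree recursion oracle", {
  pop <- simulate_population(
    sim_config(n_founders = 50, n_years = 8,
               chromosomes = data.frame(snps = 30, length_mb = 20),
               seed = 71))
  j <- 7
  g <- stats::setNames(pop$genotypes$dosage[, j], pop$genotypes$ids)
  ped <- pop$pedigree
  # oracle: E[dosage] by recursion, founders at observed values
  ed <- stats::setNames(rep(NA_real_, nrow(ped)), ped$id)
  for (i in order(ped$birth_year)) {
    if (is.na(ped$sire[i])) ed[ped$id[i]] <- g[ped$id[i]]
    else ed[ped$id[i]] <- (ed[ped$dam[i]] + ed[ped$sire[i]]) / 2
  }
  # expected yearly frequencies under Mendelian dropping, and their slope
  years <- sort(unique(pop$census$year))
  e_freq <- vapply(years, function(y) {
    mean(ed[pop$census$id[pop$census$year == y]]) / 2
  }, 0)
  e_slope <- unname(stats::coef(stats::lm(e_freq ~ years))[2])
  mem <- pop$census[, c("id", "year")]
  tt <- allele_trend_test(g, ped, mem, n_reps = 2000, seed = 8)
  mc_se <- stats::sd(tt$null_slopes) / sqrt(2000)
  expect_lt(abs(mean(tt$null_slopes) - e_slope), 4 * mc_se + 1e-4)
  # fewer than 3 years of data is refused
  mem2 <- mem[mem$year %in% years[1:2], ]
  expect_error(allele_trend_test(g, ped, mem2, n_reps = 10), "3 years")
})

test_that("gene-drop P values are deterministic given the seed", {
  pop <- simulate_population(
    sim_config(n_founders = 40, n_years = 6,
               chromosomes = data.frame(snps = 20, length_mb = 20),
               seed = 72))
  g <- stats::setNames(pop$genotypes$dosage[, 3], pop$genotypes$ids)
  mem <- pop$census[, c("id", "year")]
  a <- allele_trend_test(g, pop$pedigree, mem, n_reps = 300, seed = 5)
  b <- allele_trend_test(g, pop$pedigree, mem, n_reps = 300, seed = 5)
  expect_identical(a$null_slopes, b$null_slopes)
  expect_equal(a$p_upper + a$p_lower >= 1, TRUE)   # both tails overlap at ties
})
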