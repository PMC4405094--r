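# LD matrices, haplotype enumeration, core haplotypes and the
# haplotype-sharing length statistic.

test_that("duplicated SNP columns give r^2 = 1 and monomorphic columns NA", {
  set.seed(81)
  h <- matrix(sample(0:1, 40, TRUE), 10, 4)
  h[, 2] <- h[, 1]
  h[, 4] <- 1L
  p <- toy_panel(h)
  expect_message(r2 <- ld_r2_matrix(p), "monomorphic")
  expect_equal(r2[1, 2], 1)
  expect_true(all(is.na(r2[4, ])))
  expect_equal(diag(r2)[1:3], rep(1, 3), ignore_attr = TRUE)
})

test_that("haplotype r^2 equals the brute-force 2x2 table computation", {
  set.seed(82)
  h <- matrix(rbinom(60 * 20, 1, 0.4), 60, 20)
  p <- toy_panel(rbind(h, h)[1:60, ])  # 30 samples
  r2 <- suppressMessages(ld_r2_matrix(toy_panel(h[1:60, ])))
  for (k in 1:20) {
    ij <- sample(20, 2)
    a <- h[, ij[1]]; b <- h[, ij[2]]
    if (stats::var(a) == 0 || stats::var(b) == 0) next
    pa <- mean(a); pb <- mean(b); pab <- mean(a & b)
    oracle <- (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
    expect_equal(r2[ij[1], ij[2]], oracle, tolerance = 1e-12)
  }
})

test_that("independent SNPs show mean off-diagonal r^2 near 1/(n haplotypes)", {
  set.seed(83)
  n_h <- 400
  h <- matrix(rbinom(n_h * 60, 1, 0.5), n_h, 60)
  r2 <- suppressMessages(ld_r2_matrix(toy_panel(h)))
  off <- r2[lower.tri(r2)]
  expect_lt(abs(mean(off, na.rm = TRUE) - 1 / n_h), 0.6 / n_h)
})

test_that("haplotype enumeration counts, sorts and thresholds allele strings", {
  h <- matrix(c(rep(c(0L, 1L, 0L), 7),          # 7 copies of "010"
                rep(c(1L, 1L, 1L), 4),          # 4 copies of "111"
                rep(c(0L, 0L, 0L), 1)), byrow = TRUE, ncol = 3)
  p <- toy_panel(h)
  e <- enumerate_haplotypes(p, min_count = 5)
  expect_identical(e$haplotype, "010")
  expect_identical(e$count, 7L)
  pre <- attr(e, "pre_filter")
  expect_identical(sum(pre$count), nrow(h))     # counts conserve chromosomes
  # identical panel: one haplotype with full count
  p4 <- toy_panel(matrix(rep(c(1L, 0L), each = 4), 4, 2))
  e4 <- enumerate_haplotypes(p4, min_count = 2)
  expect_identical(nrow(e4), 1L)
  expect_identical(e4$count, 4L)
  # all-distinct panel under the default threshold: empty with a warning
  hd <- diag(6)[, 1:5]
  storage.mode(hd) <- "integer"
  expect_warning(ed <- enumerate_haplotypes(toy_panel(hd), min_count = 5),
                 "threshold")
  expect_identical(nrow(ed), 0L)
  expect_error(enumerate_haplotypes(p, snps = integer(0)), "empty")
})

test_that("core haplotypes span 3 upstream + focal + 2 downstream SNPs", {
  set.seed(84)
  h <- matrix(rep(c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L), 8), byrow = TRUE,
              ncol = 8)
  p <- toy_panel(h)
  cores <- extract_core_haplotypes(p, "s4", min_count = 3)
  expect_identical(attr(cores, "snps"), paste0("s", 1:6))
  expect_identical(cores$haplotype, "010110")
  expect_identical(cores$count, 8L)
  expect_identical(cores$focal_allele, 1L)       # allele at s4
  # counts below the threshold are excluded
  h2 <- h
  h2[1:4, 3] <- 1L                               # split into 4 + 4 copies
  expect_identical(nrow(extract_core_haplotypes(toy_panel(h2), "s4",
                                                min_count = 5)), 0L)
  # too close to the chromosome end: error reports available flanks
  expect_error(extract_core_haplotypes(p, "s2"), "2 SNP\\(s\\) upstream|close")
  expect_error(extract_core_haplotypes(p, "s8"), "close")
})

test_that("HS spans hit the truncation and immediate-mismatch extremes", {
  # window of 9 SNPs, core = SNPs 3..8 (focal s6), bp = 1e5 * 1:9
  base <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  mk <- function(...) do.call(rbind, list(...))
  focal <- mk(base, base, base, base, base, base)    # 3 samples, all carriers
  ref_same <- mk(base, base)
  ref_flank <- base; ref_flank[c(2, 9)] <- 1L - ref_flank[c(2, 9)]
  ref_mm <- mk(ref_flank, ref_flank)
  h <- rbind(focal, ref_same, ref_mm)
  p <- phased_panel(h, data.frame(snp = paste0("s", 1:9), chr = "1",
                                  bp = 1e5 * (1:9), a1 = "A", a2 = "G"),
                    ids = paste0("x", 1:5),
                    pop = c("focal", "focal", "focal", "same", "mm"))
  cores <- extract_core_haplotypes(p, "s6", min_count = 3, pop = "focal")
  hs <- hs_lengths(p, cores, core_index = 1, window_bp = 5e6)
  # identical reference: HS truncates at the window's terminal SNPs
  expect_equal(hs$mean_bp[hs$breed == "same"], (9 - 1) * 1e5)
  # mismatches immediately flanking the core: HS = the core's own bp span
  expect_equal(hs$mean_bp[hs$breed == "mm"], attr(hs, "core_span"))
  expect_identical(hs$n_pairs, c(6L * 2L, 6L * 2L))
})

test_that("vectorized HS equals the brute-force per-pair scan on random panels", {
  set.seed(85)
  for (k in 1:100) {
    m <- 40
    nf <- sample(2:5, 1); nr <- sample(2:5, 1)
    bp <- sort(sample.int(4e6, m))
    core_lo <- 18L; core_hi <- 23L                 # 3 + focal(21) + 2
    core <- sample(0:1, 6, TRUE)
    H_f <- matrix(rbinom(2 * nf * m, 1, 0.5), 2 * nf, m)
    H_r <- matrix(rbinom(2 * nr * m, 1, 0.5), 2 * nr, m)
    # force at least one carrier chromosome on each side
    H_f[1, core_lo:core_hi] <- core
    H_r[1, core_lo:core_hi] <- core
    p <- phased_panel(rbind(H_f, H_r),
                      data.frame(snp = paste0("s", 1:m), chr = "1", bp = bp,
                                 a1 = "A", a2 = "G"),
                      ids = paste0("i", seq_len(nf + nr)),
                      pop = rep(c("focal", "ref"), c(nf, nr)))
    cores <- extract_core_haplotypes(p, "s21", min_count = 1, pop = "focal")
    ci <- which(cores$haplotype == paste(core, collapse = ""))
    hs <- hs_lengths(p, cores, core_index = cores$core[ci],
                     window_bp = 5e6)
    # oracle over the carrier chromosomes
    carrier <- function(H) which(apply(H[, core_lo:core_hi, drop = FALSE],
                                       1, function(z) all(z == core)))
    spans <- hs_oracle_pairs(H_f[carrier(H_f), , drop = FALSE],
                             H_r[carrier(H_r), , drop = FALSE],
                             bp, core_lo, core_hi, 1L, m)
    expect_identical(hs$n_pairs[hs$breed == "ref"], length(spans))
    expect_equal(hs$mean_bp[hs$breed == "ref"], mean(spans))
    expect_equal(hs$sd_bp[hs$breed == "ref"],
                 if (length(spans) > 1) stats::sd(spans) else 0)
    # HS never shorter than the core span
    expect_true(all(spans >= bp[core_hi] - bp[core_lo]))
  }
})

test_that("flipping an allele inside a shared tract never lengthens HS", {
  set.seed(86)
  m <- 30
  bp <- sort(sample.int(3e6, m))
  core_lo <- 13L; core_hi <- 18L
  H_f <- matrix(rbinom(2 * m, 1, 0.5), 2, m)
  H_r <- H_f                                       # fully shared pairs
  before <- hs_oracle_pairs(H_f, H_r, bp, core_lo, core_hi, 1L, m)
  for (j in c(3L, 10L, 25L)) {
    H_r2 <- H_r
    H_r2[1, j] <- 1L - H_r2[1, j]
    after <- hs_oracle_pairs(H_f, H_r2, bp, core_lo, core_hi, 1L, m)
    expect_true(all(after <= before))
  }
})

test_that("breeds without core carriers report zero pairs and no mean", {
  base <- c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  other <- 1L - base
  p <- phased_panel(rbind(base, base, base, base, other, other),
                    data.frame(snp = paste0("s", 1:9), chr = "1",
                               bp = 1e5 * (1:9), a1 = "A", a2 = "G"),
                    ids = paste0("x", 1:3),
                    pop = c("focal", "focal", "empty"))
  cores <- extract_core_haplotypes(p, "s5", min_count = 2, pop = "focal")
  hs <- hs_lengths(p, cores, core_index = 1)
  expect_identical(hs$n_pairs[hs$breed == "empty"], 0L)
  expect_true(is.na(hs$mean_bp[hs$breed == "empty"]))
})
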