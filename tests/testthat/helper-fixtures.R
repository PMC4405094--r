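# Shared fixtures: tiny hand-built objects plus one cached mid-size
# simulated population so multiple test files can reuse it.

toy_geno <- function() {
  genotype_set(
    matrix(c(0L, 1L, 2L, 2L, NA, 1L, 0L, 2L, 1L, 1L, 0L, 0L), nrow = 3),
    data.frame(snp = paste0("s", 1:4), chr = c("1", "1", "2", "2"),
               bp = c(100L, 200L, 50L, 90L), a1 = "A", a2 = "G",
               stringsAsFactors = FALSE),
    c("i1", "i2", "i3"))
}

toy_panel <- function(haps, bp = NULL, chr = "1") {
  m <- ncol(haps)
  if (is.null(bp)) bp <- seq(1e5, by = 1e5, length.out = m)
  phased_panel(haps,
               data.frame(snp = paste0("s", seq_len(m)), chr = chr, bp = bp,
                          a1 = "A", a2 = "G", stringsAsFactors = FALSE),
               ids = paste0("h", seq_len(nrow(haps) / 2)))
}

# cached simulated population with one planted QTL (built once per run)
.fixture_cache <- new.env()

cached_pop <- function() {
  if (is.null(.fixture_cache$pop)) {
    cfg <- sim_config(n_founders = 80, n_years = 8,
                      chromosomes = data.frame(snps = rep(120, 3),
                                               length_mb = rep(60, 3)),
                      qtls = list(qtl_spec(2, target_maf = 0.12,
                                           effect = 0.7)),
                      seed = 20240101)
    .fixture_cache$pop <- simulate_population(cfg)
    .fixture_cache$pheno <- simulate_trait_and_phenotypes(.fixture_cache$pop)
  }
  list(pop = .fixture_cache$pop, pheno = .fixture_cache$pheno)
}

# brute-force haplotype-sharing oracle: plain per-pair outward scan,
# written independently of the vectorized implementation
hs_oracle_pairs <- function(haps_f, haps_r, bp, core_lo, core_hi,
                            win_lo, win_hi) {
  spans <- matrix(NA_real_, nrow(haps_f), nrow(haps_r))
  for (i in seq_len(nrow(haps_f))) {
    for (j in seq_len(nrow(haps_r))) {
      up <- core_lo
      k <- core_lo - 1L
      while (k >= win_lo && haps_f[i, k] == haps_r[j, k]) {
        up <- k
        k <- k - 1L
      }
      dn <- core_hi
      k <- core_hi + 1L
      while (k <= win_hi && haps_f[i, k] == haps_r[j, k]) {
        dn <- k
        k <- k + 1L
      }
      spans[i, j] <- bp[dn] - bp[up]
    }
  }
  spans
}
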