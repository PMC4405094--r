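# End-to-end orchestration: simulate (or load) data, build GRMs and
# regions, partition variance, run the GRAMMAR scan, the selection
# analysis and the haplotype-sharing stage, writing every output with a
# content hash into a run manifest.

#' Run the full genome-partitioning pipeline
#'
#' Stages run in dependency order: \code{simulate} (synthetic population,
#' phenotypes, fitness, breed panel; writes PLINK/VCF/TSV files),
#' \code{partition} (chromosome partition + length regression),
#' \code{regions} (regional heritability scan), \code{gwas} (GRAMMAR scan,
#' inflation factor, top-SNP refit), \code{selection} (selection
#' coefficients + gene-drop trend test at the first planted QTL) and
#' \code{haplo} (core haplotypes + HS lengths across breeds). Stage outputs
#' are TSV files in \code{out_dir}; the manifest lists each with an md5
#' hash, so a rerun with the same config reproduces identical hashes.
#'
#' @param config a list (or path to a JSON file readable by jsonlite) with
#'   elements: \code{out_dir}; \code{stages} (character subset of the six
#'   stage names; empty = do nothing); \code{seed}; optional \code{sim}
#'   (arguments to \code{\link{sim_config}}); optional per-stage parameter
#'   lists \code{partition}, \code{regions}, \code{gwas}, \code{selection},
#'   \code{haplo}.
#' @return data.frame manifest (stage, file, md5), invisibly; also written
#'   to \code{out_dir/manifest.tsv}. A stage failure halts dependent stages
#'   and the partial manifest is returned with attribute \code{"failed"}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- config$stages %||% character(0)
  out_dir <- config$out_dir %||% stop("config$out_dir required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  add <- function(stage, files) {
    manifest <<- rbind(manifest,
                       data.frame(stage = stage, file = basename(files),
                                  md5 = unname(tools::md5sum(files)),
                                  stringsAsFactors = FALSE))
  }
  if (length(stages) == 0) {
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(manifest))
  }

  state <- new.env()
  failed <- NULL
  run_stage <- function(name, fun) {
    if (!name %in% stages || !is.null(failed)) return()
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     message("stage '", name, "' failed: ",
                             conditionMessage(e))
                     FALSE
                   })
    if (!ok) failed <<- name
  }

  run_stage("simulate", function() {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    pop <- simulate_population(cfg)
    pheno <- simulate_trait_and_phenotypes(pop)
    fitness <- simulate_fitness_records(pop)
    state$pop <- pop; state$pheno <- pheno; state$fitness <- fitness
    pre <- file.path(out_dir, "synthetic")
    write_plink(pop$genotypes, pre, sex = pop$pedigree$sex)
    write_phased_vcf(pop$panel, paste0(pre, ".vcf"))
    write_pedigree(pop$pedigree, paste0(pre, "_pedigree.tsv"))
    write_phenotypes(pheno, paste0(pre, "_phenotypes.tsv"))
    write_fitness(fitness, pre)
    utils::write.table(pop$qtl_table[, setdiff(names(pop$qtl_table), "col")],
                       paste0(pre, "_qtls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("simulate", c(paste0(pre, c(".bed", ".bim", ".fam", ".vcf",
                                    "_pedigree.tsv", "_phenotypes.tsv",
                                    "_annual.tsv", "_lifetime.tsv",
                                    "_qtls.tsv"))))
  })

  need_sim <- function() {
    if (is.null(state$pop))
      stop("depends on the 'simulate' stage")
  }

  run_stage("partition", function() {
    need_sim()
    part <- chromosome_partition(trait ~ sex + factor(pmin(age, 6)),
                                 state$pheno, "id", state$pop$genotypes,
                                 groups = c("birth_year",
                                            "year_of_measurement"),
                                 permanent_env = TRUE)
    lens <- stats::setNames(state$pop$config$chromosomes$length_mb,
                            as.character(seq_len(
                              nrow(state$pop$config$chromosomes))))
    lr <- tryCatch(length_regression(part, lens), error = function(e) NULL)
    state$partition <- part
    f <- file.path(out_dir, "chromosome_partition.tsv")
    utils::write.table(part, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- f
    if (!is.null(lr)) {
      f2 <- file.path(out_dir, "length_regression.tsv")
      utils::write.table(as.data.frame(lr), f2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f2)
    }
    add("partition", files)
  })

  run_stage("regions", function() {
    need_sim()
    pars <- config$regions %||% list()
    regs <- define_regions(state$pop$genotypes$map,
                           window = pars$window %||% 150L,
                           step = pars$step %||% 75L,
                           min_snps = pars$min_snps %||% 113L)
    scan <- regional_scan(trait ~ sex + factor(pmin(age, 6)), state$pheno,
                          "id", state$pop$genotypes, regions = regs,
                          groups = c("birth_year", "year_of_measurement"),
                          permanent_env = TRUE,
                          alpha = pars$alpha %||% 0.05)
    state$regions <- scan
    f <- file.path(out_dir, "regional_scan.tsv")
    hdr <- sprintf("# converged %d of %d regions; threshold %.4g",
                   attr(scan, "n_converged"), attr(scan, "n_attempted"),
                   attr(scan, "threshold"))
    writeLines(hdr, f)
    suppressWarnings(
      utils::write.table(scan, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    add("regions", f)
  })

  run_stage("gwas", function() {
    need_sim()
    fit <- greml(trait ~ sex + factor(pmin(age, 6)), state$pheno, "id",
                 grms = list(genome = compute_grm(state$pop$genotypes)),
                 groups = c("birth_year", "year_of_measurement"),
                 permanent_env = TRUE)
    res <- grammar_residuals(fit)
    scan <- score_scan(res, state$pop$genotypes)
    lam <- inflation_factor(scan$chi2)
    thr <- bonferroni_threshold(nrow(scan))
    top <- scan[order(scan$p), ][1, ]
    refit <- refit_snp_effect(trait ~ sex + factor(pmin(age, 6)),
                              state$pheno, "id", state$pop$genotypes,
                              top$snp,
                              groups = c("birth_year",
                                         "year_of_measurement"),
                              permanent_env = TRUE)
    state$gwas <- list(scan = scan, lambda = lam, threshold = thr,
                       refit = refit)
    f <- file.path(out_dir, "gwas_scan.tsv")
    writeLines(sprintf("# lambda %.4f; bonferroni threshold %.4g", lam, thr),
               f)
    suppressWarnings(
      utils::write.table(scan, f, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE))
    f2 <- file.path(out_dir, "top_snp_refit.tsv")
    utils::write.table(
      data.frame(snp = refit$snp, a = refit$a, se = refit$se, p = refit$p,
                 maf = refit$maf, v_snp = refit$v_snp, v_a = refit$v_a,
                 v_p = refit$v_p, h2_snp = refit$h2_snp,
                 share_va = refit$share_va),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    add("gwas", c(f, f2))
  })

  run_stage("selection", function() {
    need_sim()
    if (nrow(state$pop$qtl_table) == 0) {
      message("selection stage skipped: no planted QTL")
      return()
    }
    qsnp <- state$pop$qtl_table$snp[1]
    j <- match(qsnp, state$pop$genotypes$map$snp)
    gvec <- stats::setNames(state$pop$genotypes$dosage[, j],
                            state$pop$genotypes$ids)
    lif <- state$fitness$lifetime
    rows <- list()
    for (sx in c("F", "M")) {
      for (ms in c("LBS", "LR")) {
        sub <- lif[lif$sex == sx, ]
        fvec <- stats::setNames(sub[[ms]], sub$id)
        est <- tryCatch(selection_coefficients(fvec, gvec, seed = seed),
                        error = function(e) NULL)
        if (is.null(est)) next
        est$sex <- sx; est$measure <- ms
        rows[[paste(sx, ms)]] <- as.data.frame(est)
      }
    }
    sel <- do.call(rbind, rows)
    mem <- state$pop$census[, c("id", "year")]
    trend <- allele_trend_test(gvec, state$pop$pedigree, mem,
                               n_reps = (config$selection %||%
                                           list())$n_reps %||% 500L,
                               seed = seed)
    state$selection <- list(coefficients = sel, trend = trend)
    f <- file.path(out_dir, "selection_coefficients.tsv")
    utils::write.table(sel, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f2 <- file.path(out_dir, "allele_trend.tsv")
    utils::write.table(
      data.frame(slope = trend$slope, r2 = trend$r2,
                 p_regression = trend$p_regression,
                 p_genedrop = trend$p_genedrop),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    add("selection", c(f, f2))
  })

  run_stage("haplo", function() {
    need_sim()
    if (nrow(state$pop$qtl_table) == 0) {
      message("haplo stage skipped: no planted QTL")
      return()
    }
    panel <- simulate_breed_panel(state$pop)
    qsnp <- state$pop$qtl_table$snp[1]
    cores <- extract_core_haplotypes(panel, qsnp, pop = "focal",
                                     min_count = (config$haplo %||%
                                                    list())$min_count %||% 5L)
    rows <- list()
    for (ci in cores$core) {
      hs <- tryCatch(hs_lengths(panel, cores, core_index = ci),
                     error = function(e) NULL)
      if (is.null(hs)) next
      hs$core <- ci
      hs$focal_allele <- cores$focal_allele[cores$core == ci]
      rows[[ci]] <- hs
    }
    hs_all <- do.call(rbind, rows)
    state$haplo <- list(cores = cores, hs = hs_all)
    f <- file.path(out_dir, "core_haplotypes.tsv")
    utils::write.table(as.data.frame(cores), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    f2 <- file.path(out_dir, "haplotype_sharing.tsv")
    utils::write.table(hs_all, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add("haplo", c(f, f2))
  })

  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(failed)) attr(manifest, "failed") <- failed
  attr(manifest, "state") <- state
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
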