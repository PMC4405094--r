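# Readers/writers for the standard formats the pipeline touches:
# PLINK bed/bim/fam (v1.0 SNP-major), phased VCF, GCTA binary GRM triplets,
# and the delimited phenotype/pedigree/fitness tables.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Write a genotype set as PLINK bed/bim/fam
#'
#' bed is written in SNP-major v1.0 layout; dosage counts copies of the bim
#' A1 allele. Missing dosages are stored with the PLINK missing code.
#'
#' @param geno a \code{\link{genotype_set}}.
#' @param prefix path prefix; \code{.bed}, \code{.bim}, \code{.fam} are added.
#' @param sex optional "F"/"M" per individual for the fam file.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(geno, prefix, sex = NULL) {
  stopifnot(inherits(geno, "genotype_set"))
  n <- length(geno$ids); m <- nrow(geno$map)
  # 2-bit codes per individual, 4 per byte, low bits first:
  # 00 = hom A1 (dosage 2), 10 = het, 11 = hom A2 (dosage 0), 01 = missing
  code <- matrix(3L, nrow = n, ncol = m)          # dosage 0
  code[geno$dosage == 2L] <- 0L
  code[geno$dosage == 1L] <- 2L
  code[is.na(geno$dosage)] <- 1L
  npad <- 4L * ceiling(n / 4L)
  bytes <- raw(0)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(PLINK_MAGIC, con)
  mult <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    cj <- c(code[, j], integer(npad - n))
    byte_vals <- colSums(matrix(cj * rep(mult, npad / 4L), nrow = 4L))
    writeBin(as.raw(byte_vals), con)
  }
  bim <- data.frame(chr = geno$map$chr, snp = geno$map$snp, cm = 0,
                    bp = geno$map$bp, a1 = geno$map$a1, a2 = geno$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  sexcode <- if (is.null(sex)) rep(0L, n) else ifelse(sex == "M", 1L, 2L)
  fam <- data.frame(fid = geno$ids, iid = geno$ids, pat = 0, mat = 0,
                    sex = sexcode, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK bed/bim/fam into a genotype set
#'
#' @param prefix path prefix of the \code{.bed}/\code{.bim}/\code{.fam} triple.
#' @return A \code{\link{genotype_set}}; dosage counts bim A1 alleles.
#' @export
read_plink <- function(prefix) {
  bedf <- paste0(prefix, ".bed")
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3L || !identical(raw[1:3], PLINK_MAGIC))
    stop("not a PLINK v1.0 SNP-major bed file (bad magic bytes): ", bedf)
  bps <- ceiling(n / 4L)
  body <- raw[-(1:3)]
  if (length(body) != bps * m)
    stop("bed size mismatch in ", bedf, ": expected ", bps * m,
         " data bytes for ", n, " individuals x ", m, " SNPs, found ",
         length(body))
  ints <- as.integer(body)
  # unpack 2-bit codes, low bits = first individual
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bps, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dos <- matrix(NA_integer_, n, m)
  dos[codes == 0L] <- 2L
  dos[codes == 2L] <- 1L
  dos[codes == 3L] <- 0L
  map <- data.frame(snp = bim[[2]], chr = bim[[1]], bp = as.integer(bim[[4]]),
                    a1 = bim[[5]], a2 = bim[[6]], stringsAsFactors = FALSE)
  genotype_set(dos, map, fam[[2]])
}

#' Write a phased panel as VCF
#'
#' One sample column per individual with phased GT ("|" separator).
#' REF is allele 2 and ALT is allele 1 of the SNP map, so GT code 1
#' corresponds to haplotype allele 1.
#'
#' @param panel a \code{\link{phased_panel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "phased_panel"))
  n <- length(panel$ids)
  h1 <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE]
  h2 <- panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = nrow(panel$map))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(panel$map$chr), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$ids), collapse = "\t"))
  body <- paste(panel$map$chr, panel$map$bp, panel$map$snp, panel$map$a2,
                panel$map$a1, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Only biallelic records with fully phased GT ("|" separator) are accepted;
#' any unphased record is an error naming the offending sites.
#'
#' @param path VCF file path (uncompressed).
#' @param region optional \code{list(chr =, start =, end =)} restricting the
#'   records read (1-based, inclusive).
#' @param pop population label(s) for the samples (default "focal").
#' @return A \code{\link{phased_panel}}.
#' @export
read_phased_vcf <- function(path, region = NULL, pop = "focal") {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hline <- body[1]
  if (!startsWith(hline, "#CHROM")) stop("missing #CHROM header in ", path)
  cols <- strsplit(sub("^#", "", hline), "\t")[[1]]
  samples <- cols[-(1:9)]
  recs <- body[-1]
  if (length(recs) > 0) {
    f <- strsplit(recs, "\t")
    chr <- vapply(f, `[[`, "", 1L)
    bp <- as.integer(vapply(f, `[[`, "", 2L))
  } else {
    f <- list(); chr <- character(0); bp <- integer(0)
  }
  if (!is.null(region)) {
    keep <- chr == as.character(region$chr) &
      bp >= region$start & bp <= region$end
    if (!any(keep))
      warning("region query returned no records: ", region$chr, ":",
              region$start, "-", region$end)
    f <- f[keep]; chr <- chr[keep]; bp <- bp[keep]
  }
  m <- length(f)
  map <- data.frame(snp = vapply(f, `[[`, "", 3L), chr = chr, bp = bp,
                    a1 = vapply(f, `[[`, "", 5L),   # ALT = allele 1
                    a2 = vapply(f, `[[`, "", 4L),   # REF = allele 2
                    stringsAsFactors = FALSE)
  if (m == 0) {
    return(phased_panel(matrix(0L, 2 * length(samples), 0),
                        map[0, ], samples, pop))
  }
  gts <- t(vapply(f, function(x) x[-(1:9)], character(length(samples))))
  if (length(samples) == 1L) gts <- matrix(gts, ncol = 1L)
  gts <- sub(":.*$", "", gts)
  unph <- grepl("/", gts, fixed = TRUE)
  if (any(unph)) {
    bad <- unique(map$snp[row(gts)[unph]])
    stop("unphased genotypes (\"/\" separator) at: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  a <- substr(gts, 1, 1); b <- substr(gts, 3, 3)
  if (any(!(a %in% c("0", "1")) | !(b %in% c("0", "1"))))
    stop("non-biallelic or missing GT codes in ", path)
  haps <- matrix(0L, nrow = 2L * length(samples), ncol = m)
  for (s in seq_along(samples)) {
    haps[2L * s - 1L, ] <- as.integer(a[, s])
    haps[2L * s, ] <- as.integer(b[, s])
  }
  phased_panel(haps, map, samples, pop)
}

#' Write a GRM in GCTA binary triplet format
#'
#' \code{.grm.bin} holds the lower triangle (diagonal included) row by row as
#' 4-byte floats, \code{.grm.N.bin} the per-pair SNP counts, \code{.grm.id}
#' the sample ids.
#'
#' @param grm a \code{\link{new_grm}} object.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  idx <- which(lower.tri(grm$mat, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- grm$mat[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m), length(vals)), con, size = 4L)
  close(con)
  utils::write.table(data.frame(grm$ids, grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM from GCTA binary triplet format
#'
#' @param prefix path prefix of \code{.grm.bin}/\code{.grm.N.bin}/\code{.grm.id}.
#' @return A \code{\link{new_grm}} object; \code{m} is the maximum pair SNP
#'   count found in \code{.grm.N.bin}.
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           colClasses = "character")[[2]]
  n <- length(ids)
  nel <- n * (n + 1L) / 2L
  binf <- paste0(prefix, ".grm.bin")
  nfound <- file.size(binf) / 4L
  if (nfound != nel)
    stop("GRM size inconsistency in ", binf, ": expected ", nel,
         " elements for ", n, " ids, found ", nfound)
  vals <- readBin(binf, "numeric", n = nel, size = 4L)
  nbin <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nel, size = 4L)
  mat <- matrix(0, n, n)
  k <- 1L
  for (i in seq_len(n)) {
    mat[i, 1:i] <- vals[k:(k + i - 1L)]
    k <- k + i
  }
  mat[upper.tri(mat)] <- t(mat)[upper.tri(mat)]
  new_grm(mat, ids, m = max(nbin), freq_source = "file")
}

#' Read a pedigree table
#'
#' Tab-separated with header columns id, sire, dam, sex, birth_year; "NA",
#' "0" or empty parent fields mean unknown. Validates acyclicity via birth
#' years, parent existence and parental sexes.
#'
#' @param path file path.
#' @return A \code{\link{pedigree}}.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", na.strings = c("NA", "", "0"))
  req <- c("id", "sire", "dam", "sex", "birth_year")
  if (!all(req %in% names(d)))
    stop("pedigree file must have columns: ", paste(req, collapse = ", "))
  pedigree(d$id, d$sire, d$dam, d$sex, as.integer(d$birth_year))
}

#' Write a pedigree table
#' @param ped a \code{\link{pedigree}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated with header; requires id, sex, age, year_of_measurement,
#' birth_year plus one or more numeric trait columns. Repeated measures per
#' individual are allowed; the repeat count is recorded in attribute
#' \code{"repeats"}.
#'
#' @param path file path.
#' @param traits names of the trait columns (default: all non-structural
#'   columns).
#' @param ped optional \code{\link{pedigree}}; ids absent from it are an error.
#' @return A validated data.frame of phenotype records.
#' @export
read_phenotypes <- function(path, traits = NULL, ped = NULL) {
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  # "F" for female must not be parsed as logical FALSE
  cls <- ifelse(hdr %in% c("id", "sex"), "character", NA)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = cls, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age", "year_of_measurement", "birth_year")
  if (!all(req %in% names(d)))
    stop("phenotype file must have columns: ", paste(req, collapse = ", "))
  if (is.null(traits)) traits <- setdiff(names(d), req)
  validate_phenotypes(d, traits, ped)
}

validate_phenotypes <- function(d, traits, ped = NULL) {
  d$id <- as.character(d$id)
  if (!all(d$sex %in% c("F", "M")))
    stop("sex must be F or M; found: ",
         paste(setdiff(unique(d$sex), c("F", "M")), collapse = ", "))
  if (any(d$age < 0)) stop("negative age")
  if (any(d$year_of_measurement < d$birth_year))
    stop("measurement year before birth year")
  for (tr in traits) {
    if (!is.numeric(d[[tr]]))
      stop("non-numeric trait column: ", tr)
  }
  if (!is.null(ped)) {
    bad <- setdiff(d$id, ped$id)
    if (length(bad) > 0)
      stop("phenotype ids absent from pedigree: ",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  attr(d, "repeats") <- table(d$id)
  attr(d, "traits") <- traits
  d
}

#' Write a phenotype table
#' @param pheno phenotype data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fitness record tables
#'
#' Expects the two-table layout written by \code{\link{write_fitness}}:
#' \code{<prefix>_annual.tsv} (id, year, sex, age, AS, AR) and
#' \code{<prefix>_lifetime.tsv} (id, sex, birth_year, LBS, LR).
#'
#' @param prefix path prefix.
#' @return A list with elements \code{annual} and \code{lifetime}.
#' @export
read_fitness <- function(prefix) {
  read_fit_tab <- function(path) {
    hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
    cls <- ifelse(hdr %in% c("id", "sex"), "character", NA)
    utils::read.table(path, header = TRUE, sep = "\t", colClasses = cls,
                      stringsAsFactors = FALSE)
  }
  ann <- read_fit_tab(paste0(prefix, "_annual.tsv"))
  lif <- read_fit_tab(paste0(prefix, "_lifetime.tsv"))
  if (!all(c("id", "year", "AS", "AR") %in% names(ann)))
    stop("annual fitness table must have columns id, year, AS, AR")
  if (!all(c("id", "LBS", "LR") %in% names(lif)))
    stop("lifetime fitness table must have columns id, LBS, LR")
  if (any(ann$AR < 0)) stop("negative annual recruit count")
  if (any(lif$LBS < lif$LR)) stop("LBS smaller than LR for some individuals")
  list(annual = ann, lifetime = lif)
}

#' Write fitness record tables
#' @param fitness list with \code{annual} and \code{lifetime} data.frames.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_fitness <- function(fitness, prefix) {
  utils::write.table(fitness$annual, paste0(prefix, "_annual.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fitness$lifetime, paste0(prefix, "_lifetime.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
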