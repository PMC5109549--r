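#' Read genotypes from standard formats
#'
#' Supports VCF (v4.x, plain or gzipped; biallelic SNVs only), PLINK1
#' bed/bim/fam triplets and a plain delimited marker table (rows = markers;
#' first three columns `marker_id`, `chrom`, `pos`; remaining columns one per
#' individual). Dosages are oriented so the minor allele is counted, with ties
#' broken toward the alternate (VCF) or A1 (PLINK) allele. Markers are sorted
#' by genome coordinate; missing calls stay `NA` until [impute_missing()].
#'
#' @param path File path. For `format = "plink"` either the `.bed` file or the
#'   common prefix of the triplet.
#' @param format `"vcf"`, `"plink"` or `"table"`; default guesses from the
#'   file extension.
#' @param ploidy_mode `"outbred"` or `"inbred"`. In inbred mode heterozygous
#'   VCF/PLINK calls are treated as missing (residual heterozygosity), so
#'   observed dosages are 0/2.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink", "table"),
                           ploidy_mode = c("outbred", "inbred")) {
  format <- match.arg(format)
  ploidy_mode <- match.arg(ploidy_mode)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
    else if (grepl("\\.(bed|bim|fam)$", path)) "plink"
    else "table"
  }
  switch(format,
         vcf = read_genotypes_vcf(path, ploidy_mode),
         plink = read_genotypes_plink(path, ploidy_mode),
         table = read_genotypes_table(path, ploidy_mode))
}

read_genotypes_table <- function(path, ploidy_mode) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) {
    stop("marker table needs marker_id, chrom, pos plus >= 1 individual",
         call. = FALSE)
  }
  values <- t(as.matrix(tab[, -(1:3), drop = FALSE]))
  storage.mode(values) <- "double"
  colnames(values) <- as.character(tab[[1]])
  genotype_matrix(values, chrom = tab[[2]], pos_bp = tab[[3]],
                  ploidy_mode = ploidy_mode)
}

read_genotypes_vcf <- function(path, ploidy_mode) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  n_skip <- sum(!bi)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic VCF record(s) skipped")
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0) stop("no biallelic records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcf@fix
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  # count ALT alleles per call; separators / or |
  alt_count <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) {
      if (any(is.na(al)) || any(al == ".")) return(NA_real_)
      sum(al == "1")
    }, numeric(1))
  }
  dose <- apply(gt, 2, alt_count)
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = 1, dimnames = dimnames(gt))
  values <- t(dose)  # individuals x markers
  colnames(values) <- ids
  if (ploidy_mode == "inbred") values[values == 1] <- NA
  values <- orient_minor(values, tie_to_flip = FALSE)
  genotype_matrix(values, chrom = fix[, "CHROM"],
                  pos_bp = as.integer(fix[, "POS"]), ploidy_mode = ploidy_mode)
}

# flip columns whose counted-allele frequency exceeds 0.5 so the minor allele
# is counted; at exactly 0.5 the current orientation (ALT / A1) is kept
orient_minor <- function(values, tie_to_flip = FALSE) {
  f <- colMeans(values, na.rm = TRUE) / 2
  flip <- if (tie_to_flip) f >= 0.5 else f > 0.5
  flip[is.na(flip)] <- FALSE
  values[, flip] <- 2 - values[, flip, drop = FALSE]
  values
}

#' Read a phenotype table
#'
#' Delimited table with a header; the first column holds individual IDs.
#'
#' @param path File path (`.csv` comma-separated, otherwise tab).
#' @param family `"gaussian"` or `"binomial"`.
#' @param value_col Column (name or index) with the phenotype values.
#' @param covariate_cols Optional columns with fixed covariates.
#' @return A [phenotype()].
#' @export
read_phenotype <- function(path, family = c("gaussian", "binomial"),
                           value_col = 2, covariate_cols = NULL) {
  family <- match.arg(family)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  cov <- if (is.null(covariate_cols)) NULL else
    as.matrix(tab[, covariate_cols, drop = FALSE])
  phenotype(tab[[value_col]], individual_ids = tab[[1]], family = family,
            covariates = cov)
}

#' Write genotypes
#'
#' Writers exist for the delimited marker-table dialect and for PLINK1
#' bed/bim/fam. Both round-trip through [read_genotypes()].
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path; for `format = "plink"` the triplet prefix.
#' @param format `"table"` or `"plink"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("table", "plink")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "genotype_matrix"))
  if (format == "table") {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- data.frame(marker_id = marker_ids(geno), chrom = geno$chrom,
                      pos = geno$pos_bp, t(geno$values),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    write_plink(geno, path)
  }
  invisible(path)
}

#' Write a phenotype table
#'
#' @param pheno A `phenotype`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(pheno, path) {
  tab <- data.frame(individual_id = names(pheno$values), value = pheno$values,
                    stringsAsFactors = FALSE)
  if (!is.null(pheno$covariates)) tab <- cbind(tab, pheno$covariates)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
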