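#' Additive-coded genotype matrix
#'
#' The central genotype container: an `n` individuals by `p` markers matrix of
#' additive allele dosages together with per-marker genome coordinates. Dosages
#' are 0/1/2 for outbred material and 0/2 for fully homozygous (inbred) panels;
#' after mean imputation entries may be fractional. Markers are kept sorted by
#' `(chrom, pos_bp)` with strictly increasing positions within a chromosome.
#'
#' @param values Numeric matrix, individuals in rows, markers in columns.
#' @param chrom Character vector of chromosome labels, one per marker.
#' @param pos_bp Integer vector of 1-based base-pair positions, one per marker.
#' @param ploidy_mode `"outbred"` (dosages 0/1/2) or `"inbred"` (0/2).
#' @param individual_ids,marker_ids Identifiers; default to the dimnames of
#'   `values`.
#' @param subpop Optional per-individual subpopulation labels (simulators
#'   record them here; never used by the association method itself).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `values`, `chrom`, `pos_bp`, `ploidy_mode` and optionally `subpop`.
#' @export
genotype_matrix <- function(values, chrom, pos_bp,
                            ploidy_mode = c("outbred", "inbred"),
                            individual_ids = rownames(values),
                            marker_ids = colnames(values),
                            subpop = NULL) {
  ploidy_mode <- match.arg(ploidy_mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (n < 2) stop("at least 2 individuals are required", call. = FALSE)
  if (p < 1) stop("at least 1 marker is required", call. = FALSE)
  if (is.null(individual_ids)) individual_ids <- paste0("ind_", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("m_", seq_len(p))
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker IDs: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(chrom) != p || length(pos_bp) != p) {
    stop("chrom and pos_bp must have one entry per marker", call. = FALSE)
  }
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  ord <- order(chrom, pos_bp)
  if (is.unsorted(ord, strictly = TRUE) || any(ord != seq_len(p))) {
    warning("markers were not sorted by (chrom, pos_bp); sorting", call. = FALSE)
    values <- values[, ord, drop = FALSE]
    marker_ids <- marker_ids[ord]
    chrom <- chrom[ord]
    pos_bp <- pos_bp[ord]
  }
  if (anyDuplicated(paste(chrom, pos_bp, sep = ":"))) {
    stop("positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  dimnames(values) <- list(as.character(individual_ids), marker_ids)
  structure(
    list(values = values, chrom = chrom, pos_bp = pos_bp,
         ploidy_mode = ploidy_mode, subpop = subpop),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%s)\n",
              nrow(x$values), ncol(x$values), x$ploidy_mode))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat(sprintf("  missing entries: %d\n", n_na))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x A `genotype_matrix`.
#' @export
n_individuals <- function(x) nrow(x$values)

#' @rdname genotype_matrix
#' @export
n_markers <- function(x) ncol(x$values)

#' @rdname genotype_matrix
#' @export
individual_ids <- function(x) rownames(x$values)

#' @rdname genotype_matrix
#' @export
marker_ids <- function(x) colnames(x$values)

#' Per-marker metadata as a tibble
#'
#' @param x A `genotype_matrix`.
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp`.
#' @export
marker_info <- function(x) {
  tibble::tibble(marker_id = marker_ids(x), chrom = x$chrom, pos_bp = x$pos_bp)
}

subset_markers <- function(x, idx) {
  genotype_matrix(x$values[, idx, drop = FALSE],
                  chrom = x$chrom[idx], pos_bp = x$pos_bp[idx],
                  ploidy_mode = x$ploidy_mode, subpop = x$subpop)
}

#' Phenotype container
#'
#' Holds the response vector of the association model plus optional fixed
#' covariates (for example sex), keyed by individual ID so it can be aligned
#' with a genotype matrix.
#'
#' @param values Numeric vector; continuous for `family = "gaussian"`, 0/1
#'   case-control for `family = "binomial"`.
#' @param individual_ids Identifiers aligned with `values`.
#' @param family `"gaussian"` or `"binomial"`.
#' @param covariates Optional numeric matrix of fixed covariates (one row per
#'   individual); always modelled unpenalized in screening and testing.
#' @return An object of class `phenotype`.
#' @export
phenotype <- function(values, individual_ids = names(values),
                      family = c("gaussian", "binomial"), covariates = NULL) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (is.null(individual_ids)) {
    stop("individual_ids are required", call. = FALSE)
  }
  if (length(individual_ids) != length(values)) {
    stop("individual_ids must match values in length", call. = FALSE)
  }
  if (anyNA(values)) stop("phenotype values must not be missing", call. = FALSE)
  if (family == "binomial" && !all(values %in% c(0, 1))) {
    stop("binomial phenotypes must be coded 0/1", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(values)) {
      stop("covariates must have one row per individual", call. = FALSE)
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov_", seq_len(ncol(covariates)))
    }
  }
  names(values) <- as.character(individual_ids)
  structure(list(values = values, family = family, covariates = covariates),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("<phenotype> %d individuals, family = %s", length(x$values),
              x$family))
  if (!is.null(x$covariates)) {
    cat(sprintf(", %d covariate(s)", ncol(x$covariates)))
  }
  cat("\n")
  invisible(x)
}

#' Align a phenotype and a genotype matrix on shared individuals
#'
#' Intersects the individual IDs and returns both objects restricted and
#' reordered to the common set.
#'
#' @param geno A `genotype_matrix`.
#' @param pheno A `phenotype`.
#' @return A list with elements `genotypes` and `phenotype`.
#' @export
align_individuals <- function(geno, pheno) {
  common <- intersect(individual_ids(geno), names(pheno$values))
  if (length(common) < 2) {
    stop("fewer than 2 shared individual IDs between genotypes and phenotype",
         call. = FALSE)
  }
  gi <- match(common, individual_ids(geno))
  pi <- match(common, names(pheno$values))
  geno$values <- geno$values[gi, , drop = FALSE]
  if (!is.null(geno$subpop)) geno$subpop <- geno$subpop[gi]
  cov <- if (is.null(pheno$covariates)) NULL else
    pheno$covariates[pi, , drop = FALSE]
  list(genotypes = geno,
       phenotype = phenotype(pheno$values[pi], common, pheno$family, cov))
}

#' Mean-impute missing genotype calls
#'
#' Replaces every missing dosage by the observed mean of its marker. Observed
#' entries are untouched, so per-marker observed means are preserved.
#'
#' @param geno A `genotype_matrix`.
#' @return The imputed `genotype_matrix` (no missing values).
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$values
  na_col <- which(colSums(is.na(v)) > 0)
  if (length(na_col) == 0) return(geno)
  all_na <- na_col[colSums(!is.na(v[, na_col, drop = FALSE])) == 0]
  if (length(all_na) > 0) {
    stop("marker(s) with no observed genotype: ",
         paste(colnames(v)[all_na], collapse = ", "), call. = FALSE)
  }
  for (j in na_col) {
    mj <- mean(v[, j], na.rm = TRUE)
    v[is.na(v[, j]), j] <- mj
  }
  geno$values <- v
  geno
}

#' Collapse perfectly correlated markers
#'
#' Markers with `|Pearson r| >= 1 - tol` carry identical association
#' information and are collapsed onto one representative (the first of the
#' class in genome order) before clustering and testing; the collapsed markers
#' are remembered so they can be reinstated into the final QTCs, where they
#' contribute to localization. Anti-correlated pairs (possible under inbred
#' 0/2 coding) collapse too, with a sign flag of -1. Monomorphic
#' (zero-variance) markers carry no information and are dropped into a
#' discard list.
#'
#' Duplicate classes are found by hashing a random projection of the
#' standardized columns and verifying candidate pairs exactly, avoiding the
#' full O(p^2) scan.
#'
#' @param geno An imputed `genotype_matrix`.
#' @param tol Correlation tolerance; markers with `|r| >= 1 - tol` collapse.
#' @return A list with elements `genotypes` (representatives only), `dup_map`
#'   (tibble: `representative_id`, `marker_id`, `sign`) and `dropped`
#'   (character vector of zero-variance marker IDs).
#' @export
deduplicate_markers <- function(geno, tol = 1e-12) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$values
  if (anyNA(v)) stop("impute missing genotypes before deduplication",
                     call. = FALSE)
  p <- ncol(v)
  sds <- col_sds(v)
  dropped <- colnames(v)[sds == 0]
  keep <- which(sds > 0)
  if (length(keep) == 0) {
    stop("all markers are monomorphic", call. = FALSE)
  }
  z <- scale(v[, keep, drop = FALSE])  # columns: mean 0, sd 1
  n <- nrow(z)
  # deterministic projection vectors; key is sign-invariant so anti-correlated
  # duplicates hash together
  proj <- matrix(sin(outer(seq_len(n), c(1.3, 2.7))) + 0.1, n, 2)
  key <- abs(crossprod(z, proj)) / (n - 1)
  key_chr <- paste(round(key[, 1], 7), round(key[, 2], 7))
  groups <- split(seq_along(keep), key_chr)

  rep_of <- integer(length(keep))   # index (within keep) of representative
  sign_of <- rep(1, length(keep))
  for (g in groups) {
    if (length(g) == 1) { rep_of[g] <- g; next }
    g <- sort(g)                     # genome order (columns already sorted)
    reps <- integer(0)
    for (j in g) {
      placed <- FALSE
      for (r in reps) {
        r_jr <- sum(z[, r] * z[, j]) / (n - 1)
        if (abs(r_jr) >= 1 - tol) {
          rep_of[j] <- r
          sign_of[j] <- if (r_jr >= 0) 1 else -1
          placed <- TRUE
          break
        }
      }
      if (!placed) { reps <- c(reps, j); rep_of[j] <- j }
    }
  }
  is_rep <- rep_of == seq_along(keep)
  rep_idx <- keep[is_rep]
  dup_map <- tibble::tibble(
    representative_id = colnames(v)[keep[rep_of[!is_rep]]],
    marker_id = colnames(v)[keep[!is_rep]],
    sign = sign_of[!is_rep]
  )
  list(genotypes = subset_markers(geno, rep_idx),
       dup_map = dup_map,
       dropped = dropped)
}

#' Expand a representative marker set through the duplicate map
#'
#' Inverse of [deduplicate_markers()] at the ID level: returns the given
#' representatives plus every marker collapsed onto them.
#'
#' @param ids Character vector of representative marker IDs.
#' @param dup_map Tibble from [deduplicate_markers()].
#' @return Character vector of marker IDs (representatives first, then their
#'   duplicates in map order).
#' @export
expand_duplicates <- function(ids, dup_map) {
  if (is.null(dup_map) || nrow(dup_map) == 0) return(ids)
  c(ids, dup_map$marker_id[dup_map$representative_id %in% ids])
}
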