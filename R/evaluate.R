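#' Match reported QTCs to simulated causal loci
#'
#' A QTC is a candidate match for a causal locus if any of its member markers
#' (reinstated duplicates included) lies within `window_bp` of the locus on
#' the same chromosome (closed window). Candidates are resolved by greedy
#' one-to-one assignment in order of increasing distance: each causal locus
#' is matched at most once and every unmatched QTC is a false positive.
#'
#' @param qtcs A `qtc_result`.
#' @param truth A `sim_truth`.
#' @param marker_map Tibble (`marker_id`, `chrom`, `pos_bp`) covering both
#'   QTC members and causal markers.
#' @param window_bp Matching window (default 10 kb).
#' @return An `eval_report`: list with `n_true_positive`, `n_false_positive`,
#'   `precision`, `matches` (tibble `qtc_id`, `causal_id`, `distance_bp`),
#'   `n_causal`, and `r_squared` (filled by [explained_variance()] callers,
#'   `NA` here).
#' @export
match_to_truth <- function(qtcs, truth, marker_map, window_bp = 10000) {
  stopifnot(inherits(qtcs, "qtc_result"), inherits(truth, "sim_truth"))
  causal <- marker_map[match(truth$causal_ids, marker_map$marker_id), ]
  if (anyNA(causal$pos_bp)) {
    stop("marker_map does not cover all causal markers", call. = FALSE)
  }
  qtc_ids <- qtcs$qtcs$qtc_id
  cand <- list()
  for (qid in qtc_ids) {
    mem <- qtcs$members$marker_id[qtcs$members$qtc_id == qid]
    mi <- marker_map[match(mem, marker_map$marker_id), ]
    for (ci in seq_len(nrow(causal))) {
      same <- mi$chrom == causal$chrom[ci]
      if (!any(same)) next
      d <- min(abs(mi$pos_bp[same] - causal$pos_bp[ci]))
      if (d <= window_bp) {
        cand[[length(cand) + 1]] <-
          tibble::tibble(qtc_id = qid, causal_id = truth$causal_ids[ci],
                         distance_bp = d)
      }
    }
  }
  matches <- tibble::tibble(qtc_id = character(0), causal_id = character(0),
                            distance_bp = numeric(0))
  if (length(cand) > 0) {
    cand <- dplyr::arrange(dplyr::bind_rows(cand), .data$distance_bp,
                           .data$qtc_id, .data$causal_id)
    used_q <- character(0); used_c <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$qtc_id[i] %in% used_q || cand$causal_id[i] %in% used_c) next
      keep[i] <- TRUE
      used_q <- c(used_q, cand$qtc_id[i])
      used_c <- c(used_c, cand$causal_id[i])
    }
    matches <- cand[keep, ]
  }
  tp <- nrow(matches)
  fp <- length(qtc_ids) - tp
  structure(
    list(n_true_positive = tp, n_false_positive = fp,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         matches = matches, n_causal = length(truth$causal_ids),
         r_squared = NA_real_),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP = %d, FP = %d, precision = %s\n",
              x$n_true_positive, x$n_false_positive,
              ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision))))
  invisible(x)
}

#' Variance explained by a set of markers
#'
#' Coefficient of determination of the least-squares fit of the phenotype on
#' the given markers (typically one medoid per QTC) plus an intercept.
#' Collinear columns are dropped with a warning.
#'
#' @param geno A `genotype_matrix`.
#' @param ids Marker IDs (or indices); may be empty.
#' @param y Phenotype values aligned with `geno`.
#' @return R-squared in `[0, 1]`.
#' @export
explained_variance <- function(geno, ids, y) {
  if (length(ids) == 0) return(0)
  idx <- if (is.character(ids)) match(ids, marker_ids(geno)) else
    as.integer(ids)
  if (anyNA(idx)) stop("unknown marker IDs", call. = FALSE)
  if (length(y) <= length(idx) + 1) {
    stop("need n > number of regressors + 1", call. = FALSE)
  }
  x <- geno$values[, idx, drop = FALSE]
  fit <- stats::lm(y ~ x)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear marker columns dropped from the regression",
            call. = FALSE)
  }
  summary(fit)$r.squared
}

#' Genomic relationship matrix
#'
#' Cross-product of the column-standardized genotype matrix divided by the
#' number of polymorphic markers (monomorphic markers are excluded). This is
#' the VanRaden form up to per-marker scaling — only relative structure
#' matters for the diagnostics computed from it. The mean diagonal is about
#' 1. The GRM is used here purely as a population-structure diagnostic,
#' never as a correction.
#'
#' @param geno An imputed `genotype_matrix`.
#' @return Symmetric n x n matrix.
#' @export
compute_grm <- function(geno) {
  v <- geno$values
  if (anyNA(v)) stop("impute missing genotypes first", call. = FALSE)
  poly <- which(col_sds(v) > 0)
  if (length(poly) < 2) {
    stop("need at least 2 polymorphic markers", call. = FALSE)
  }
  z <- scale(v[, poly, drop = FALSE])
  grm <- tcrossprod(z) / length(poly)
  dimnames(grm) <- list(rownames(v), rownames(v))
  grm
}

#' Population-structure involvement of a marker
#'
#' The share of a marker's genotype variance explained by the leading
#' principal coordinates of the GRM: the marker is regressed on the top
#' `n_axes` eigenvectors of the double-centered GRM and the regression
#' R-squared is returned. Markers strongly shaped by structure score near 1.
#'
#' @param geno An imputed `genotype_matrix`.
#' @param grm Matrix from [compute_grm()].
#' @param marker Marker index or ID (must be polymorphic).
#' @param n_axes Number of principal coordinates (0 returns 0).
#' @return R-squared in `[0, 1]`.
#' @export
structure_involvement <- function(geno, grm, marker, n_axes = 5) {
  if (n_axes == 0) return(0)
  idx <- if (is.character(marker)) match(marker, marker_ids(geno)) else
    as.integer(marker)
  x <- geno$values[, idx]
  if (stats::sd(x) == 0) stop("marker is monomorphic", call. = FALSE)
  n <- nrow(grm)
  ctr <- diag(n) - matrix(1 / n, n, n)
  k <- ctr %*% grm %*% ctr
  ev <- eigen(k, symmetric = TRUE)
  axes <- ev$vectors[, seq_len(min(n_axes, n)), drop = FALSE]
  fit <- stats::lm(x ~ axes)
  summary(fit)$r.squared
}

#' True/false positives at a grid of significance levels
#'
#' Re-calls QTCs from one fitted HIT run at each `alpha`, matches them to the
#' simulation truth and tabulates true and false positives; true positives
#' are monotone nondecreasing in `alpha` by threshold nesting.
#'
#' @param fit A `hit_fit`.
#' @param hierarchy,geno,dup_map,marker_map As in [call_qtcs()].
#' @param truth A `sim_truth`.
#' @param alphas Ascending significance levels.
#' @param window_bp Matching window for [match_to_truth()].
#' @param max_height Localization cutoff passed to [call_qtcs()].
#' @return Tibble with `alpha`, `n_qtc`, `tp`, `fp`, `precision`.
#' @export
power_curve <- function(fit, hierarchy, geno, truth, alphas,
                        dup_map = NULL, marker_map = NULL,
                        window_bp = 10000, max_height = 0.5) {
  stopifnot(!is.unsorted(alphas))
  if (is.null(marker_map)) marker_map <- marker_info(geno)
  rows <- lapply(alphas, function(a) {
    q <- call_qtcs(fit, hierarchy, geno, dup_map = dup_map,
                   marker_map = marker_map, alpha = a,
                   max_height = max_height)
    r <- match_to_truth(q, truth, marker_map, window_bp = window_bp)
    tibble::tibble(alpha = a, n_qtc = nrow(q$qtcs), tp = r$n_true_positive,
                   fp = r$n_false_positive, precision = r$precision)
  })
  dplyr::bind_rows(rows)
}
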