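#' LASSO screening on one half of the individuals
#'
#' Cross-validated L1-penalized regression used as a liberal variable screen:
#' the markers with nonzero coefficients at the penalty minimizing the
#' cross-validation error are carried into the testing stage. The penalty is
#' deliberately the CV minimum rather than the 1-s.e. choice — screening
#' should over-select; the downstream hierarchical test controls the error.
#' Marker columns are standardized internally; the intercept and any fixed
#' covariates are unpenalized.
#'
#' @param values Numeric matrix of marker dosages (screening individuals).
#' @param y Phenotype values for the same individuals.
#' @param family `"gaussian"` or `"binomial"`.
#' @param covariates Optional fixed-covariate matrix (unpenalized).
#' @param cv_folds Number of cross-validation folds.
#' @param seed Seed for the fold assignment; the selection is deterministic
#'   given the seed.
#' @return Integer vector of selected marker indices, with the fitted
#'   coefficients in attribute `"beta"`.
#' @export
lasso_screen <- function(values, y, family = c("gaussian", "binomial"),
                         covariates = NULL, cv_folds = 10, seed = 1) {
  family <- match.arg(family)
  n <- length(y)
  if (nrow(values) != n) stop("dimension mismatch", call. = FALSE)
  if (n < 2 * cv_folds) {
    stop("screening half needs at least 2 x cv_folds individuals",
         call. = FALSE)
  }
  if (family == "binomial" && length(unique(y)) < 2) {
    stop("binomial phenotype with a single class", call. = FALSE)
  }
  if (stats::sd(y) == 0) stop("constant phenotype", call. = FALSE)
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  x <- cbind(covariates, values)
  pf <- c(rep(0, q), rep(1, ncol(values)))
  if (ncol(x) < 2) {  # glmnet needs >= 2 columns; pad with an inert one
    x <- cbind(x, 0)
    pf <- c(pf, 1)
  }
  foldid <- with_local_seed(seed,
                            sample(rep(seq_len(cv_folds), length.out = n)))
  cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                          penalty.factor = pf, standardize = TRUE)
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]  # drop intercept
  beta <- beta[seq_len(ncol(values)) + q]
  sel <- which(beta != 0)
  attr(sel, "beta") <- beta[sel]
  sel
}

#' Test one cluster against the background of all screened markers
#'
#' Contrasts the influence of a cluster's screened members with the influence
#' of all other screened markers: for a gaussian phenotype a partial F-test
#' between the linear model on all screened markers `S` and the model on
#' `S` without the cluster's members; for a binomial phenotype the
#' likelihood-ratio chi-square between the corresponding nested logistic
#' models. Collinear columns are dropped by the pivoted decomposition inside
#' `lm`/`glm`, with degrees of freedom adjusted accordingly.
#'
#' @param values Marker dosage matrix (testing individuals).
#' @param y Phenotype values (testing individuals, disjoint from screening).
#' @param members_in_s Indices of the cluster's members within the screen set
#'   (subset of `s`, nonempty).
#' @param s All screened marker indices.
#' @param family `"gaussian"` or `"binomial"`.
#' @param covariates Optional fixed-covariate matrix (always in both models).
#' @return Raw p-value in `[0, 1]`.
#' @export
cluster_test <- function(values, y, members_in_s, s,
                         family = c("gaussian", "binomial"),
                         covariates = NULL) {
  family <- match.arg(family)
  if (length(members_in_s) == 0) stop("empty cluster", call. = FALSE)
  if (!all(members_in_s %in% s)) {
    stop("cluster members must be screened markers", call. = FALSE)
  }
  q <- if (is.null(covariates)) 0L else ncol(covariates)
  n <- length(y)
  if (n - length(s) - q - 1 <= 0) {
    stop("no residual degrees of freedom on the testing half; ",
         "reduce the screened set S", call. = FALSE)
  }
  x_full <- cbind(covariates, values[, s, drop = FALSE])
  rest <- setdiff(s, members_in_s)
  x_red <- cbind(covariates, values[, rest, drop = FALSE])
  if (ncol(x_red) == 0) x_red <- NULL
  if (family == "gaussian") {
    fit_full <- if (is.null(x_full)) stats::lm(y ~ 1) else stats::lm(y ~ x_full)
    fit_red <- if (is.null(x_red)) stats::lm(y ~ 1) else stats::lm(y ~ x_red)
    a <- stats::anova(fit_red, fit_full)
    pval <- a$`Pr(>F)`[2]
  } else {
    # separation warnings are expected under strong effects; the LRT stands
    fit_full <- suppressWarnings(
      stats::glm(y ~ ., family = stats::binomial(),
                 data = data.frame(y = y, x_full, check.names = FALSE)))
    fit_red <- suppressWarnings(if (is.null(x_red)) {
      stats::glm(y ~ 1, family = stats::binomial())
    } else {
      stats::glm(y ~ ., family = stats::binomial(),
                 data = data.frame(y = y, x_red, check.names = FALSE))
    })
    dev_diff <- fit_red$deviance - fit_full$deviance
    df_diff <- fit_red$df.residual - fit_full$df.residual
    pval <- if (df_diff <= 0) NA else
      stats::pchisq(max(dev_diff, 0), df_diff, lower.tail = FALSE)
  }
  # all member columns aliased with the reduced model: nothing testable
  if (is.na(pval)) pval <- 1
  min(max(pval, 0), 1)
}

#' Hierarchical multiplicity adjustment for one tested cluster
#'
#' The raw cluster p-value is inflated by the share of screened markers the
#' cluster holds, `|S| / |C intersect S|`, capped at 1, and then monotonized
#' against the parent's adjusted p-value so significance can only shrink
#' going down the tree.
#'
#' @param raw_p Raw p-value of the cluster test.
#' @param cluster_hits `|C intersect S|`, number of screened markers in the
#'   cluster (must be >= 1; untested clusters are never passed here).
#' @param total_selected `|S|`, total screened markers.
#' @param parent_adjusted_p Adjusted p-value of the parent (0 at the root).
#' @return Adjusted p-value in `[0, 1]`.
#' @export
hierarchical_adjust <- function(raw_p, cluster_hits, total_selected,
                                parent_adjusted_p = 0) {
  stopifnot(cluster_hits >= 1, cluster_hits <= total_selected,
            parent_adjusted_p >= 0, parent_adjusted_p <= 1)
  p_adj <- min(1, raw_p * total_selected / cluster_hits)
  max(p_adj, parent_adjusted_p)
}

#' One random sample split: screen, then test down the hierarchy
#'
#' Individuals are split at random; the LASSO screen runs on one half and the
#' hierarchical test on the other. Testing starts at the root and recurses
#' into the children of a node only while the node's adjusted p-value is at
#' most `alpha`, skipping clusters containing no screened marker. Every
#' tested node is recorded; untested nodes count as p = 1.
#'
#' @param geno Imputed (deduplicated) `genotype_matrix`.
#' @param pheno Aligned `phenotype`.
#' @param hierarchy `marker_hierarchy` over the same markers.
#' @param alpha Significance level steering the descent.
#' @param split_fraction Fraction of individuals used for screening.
#' @param cv_folds CV folds for the screen.
#' @param seed Seed; the whole split is deterministic given it.
#' @return A `split_result`: list with `selected` (marker indices),
#'   `screen_ids`, `test_ids`, `tested` (tibble `node_id`, `p_adjusted`) and
#'   `truncated` (flag).
#' @export
run_split <- function(geno, pheno, hierarchy, alpha = 0.05,
                      split_fraction = 0.5, cv_folds = 10, seed = 1) {
  y <- pheno$values
  n <- length(y)
  if (n < 20) stop("need at least 20 individuals", call. = FALSE)
  seeds <- derive_seeds(seed, 2)
  screen_idx <- with_local_seed(seeds[1],
                                sort(sample.int(n, round(n * split_fraction))))
  test_idx <- setdiff(seq_len(n), screen_idx)
  cov <- pheno$covariates
  cov_s <- if (is.null(cov)) NULL else cov[screen_idx, , drop = FALSE]
  cov_t <- if (is.null(cov)) NULL else cov[test_idx, , drop = FALSE]
  s <- lasso_screen(geno$values[screen_idx, , drop = FALSE], y[screen_idx],
                    family = pheno$family, covariates = cov_s,
                    cv_folds = cv_folds, seed = seeds[2])
  truncated <- FALSE
  n_test <- length(test_idx)
  q <- if (is.null(cov)) 0L else ncol(cov)
  if (length(s) >= n_test - length(s) - q - 1) {
    cap <- min(floor(n_test / 2), n_test - q - 2)
    keep <- order(abs(attr(s, "beta")), decreasing = TRUE)[seq_len(min(cap, length(s)))]
    s <- sort(s[keep])
    truncated <- TRUE
  }
  s <- as.integer(s)
  attr(s, "beta") <- NULL
  res <- list(selected = s,
              screen_ids = individual_ids(geno)[screen_idx],
              test_ids = individual_ids(geno)[test_idx],
              tested = tibble::tibble(node_id = integer(0),
                                      p_adjusted = numeric(0)),
              truncated = truncated)
  class(res) <- "split_result"
  if (length(s) == 0) return(res)

  vt <- geno$values[test_idx, , drop = FALSE]
  yt <- y[test_idx]
  node_ids <- integer(0)
  p_vals <- numeric(0)
  # iterative top-down descent; stack entries carry the parent's adjusted p
  stack <- list(list(node = hierarchy$root, parent_p = 0))
  while (length(stack) > 0) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- fr$node
    hits <- intersect(hierarchy$members[[v]], s)
    raw <- cluster_test(vt, yt, members_in_s = hits, s = s,
                        family = pheno$family, covariates = cov_t)
    p_adj <- hierarchical_adjust(raw, length(hits), length(s), fr$parent_p)
    node_ids <- c(node_ids, v)
    p_vals <- c(p_vals, p_adj)
    if (p_adj <= alpha) {
      for (ch in hierarchy$children[[v]]) {
        if (length(intersect(hierarchy$members[[ch]], s)) > 0) {
          stack[[length(stack) + 1]] <- list(node = ch, parent_p = p_adj)
        }
      }
    }
  }
  ord <- order(node_ids)
  res$tested <- tibble::tibble(node_id = node_ids[ord],
                               p_adjusted = p_vals[ord])
  res
}

#' Aggregate per-split p-values for one node
#'
#' Quantile aggregation over the `B` sample splits: with
#' `Q(gamma) = min(1, gamma-quantile of {p_b / gamma})`, the aggregate is
#' `min(1, (1 - log(gamma_min)) * inf_{gamma in [gamma_min, 1]} Q(gamma))`,
#' the infimum evaluated on the grid of order statistics (between order
#' statistics the empirical quantile is constant and `1/gamma` decreasing, so
#' the grid attains the infimum).
#'
#' @param p Numeric vector of per-split p-values (length `B >= 1`).
#' @param gamma_min Lower end of the quantile range searched.
#' @return Aggregated p-value in `[0, 1]`.
#' @export
aggregate_pvalues <- function(p, gamma_min = 0.05) {
  stopifnot(length(p) >= 1, all(p >= 0 & p <= 1), gamma_min > 0,
            gamma_min < 1)
  b <- length(p)
  ps <- sort(p)
  k <- seq.int(max(1L, ceiling(gamma_min * b)), b)
  q_inf <- min(ps[k] * b / k)
  min(1, (1 - log(gamma_min)) * q_inf)
}

#' Run the full repeated sample-splitting inference
#'
#' Executes `n_splits` independent sample splits (seeds derived from the
#' master seed by a counter, so results do not depend on execution order or
#' thread count), aggregates the per-node p-values across splits, monotonizes
#' them down the tree, and records per-marker selection frequencies.
#'
#' @inheritParams run_split
#' @param n_splits Number of sample splits `B`.
#' @param gamma_min Quantile-aggregation lower bound.
#' @param n_threads Splits are run in parallel with this many processes.
#' @return A `hit_fit`: list with `table` (tibble `node_id`, `p_aggregated`;
#'   nodes absent from the table have p = 1), `selection_freq` (tibble
#'   `marker_id`, `freq`), the `splits` list, and the run settings.
#' @export
run_hit <- function(geno, pheno, hierarchy, alpha = 0.05, n_splits = 50,
                    gamma_min = 0.05, split_fraction = 0.5, cv_folds = 10,
                    seed = 1, n_threads = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(pheno, "phenotype"),
            inherits(hierarchy, "marker_hierarchy"))
  if (!identical(individual_ids(geno), names(pheno$values))) {
    stop("genotypes and phenotype are not aligned; see align_individuals()",
         call. = FALSE)
  }
  if (n_markers(geno) != hierarchy$n_markers) {
    stop("hierarchy and genotype matrix disagree on the marker set",
         call. = FALSE)
  }
  split_seeds <- derive_seeds(seed, n_splits)
  one <- function(b) run_split(geno, pheno, hierarchy, alpha = alpha,
                               split_fraction = split_fraction,
                               cv_folds = cv_folds, seed = split_seeds[b])
  splits <- if (n_threads > 1) {
    parallel::mclapply(seq_len(n_splits), one, mc.cores = n_threads)
  } else {
    lapply(seq_len(n_splits), one)
  }
  # union of tested nodes; per-split p defaults to 1 where untested
  tested_nodes <- sort(unique(unlist(lapply(splits, function(s)
    s$tested$node_id))))
  p_agg <- vapply(tested_nodes, function(v) {
    pv <- vapply(splits, function(s) {
      i <- match(v, s$tested$node_id)
      if (is.na(i)) 1 else s$tested$p_adjusted[i]
    }, numeric(1))
    aggregate_pvalues(pv, gamma_min)
  }, numeric(1))
  # final monotonization down the tree (ancestors of any tested node are
  # themselves tested, so parent lookups stay within the table)
  names(p_agg) <- tested_nodes
  for (v in tested_nodes[order(tested_nodes, decreasing = TRUE)]) {
    pa <- hierarchy$parent[v]
    if (!is.na(pa) && as.character(pa) %in% names(p_agg)) {
      p_agg[as.character(v)] <- max(p_agg[as.character(v)],
                                    p_agg[as.character(pa)])
    }
  }
  sel_count <- integer(n_markers(geno))
  for (s in splits) sel_count[s$selected] <- sel_count[s$selected] + 1L
  fit <- list(
    table = tibble::tibble(node_id = tested_nodes,
                           p_aggregated = unname(p_agg)),
    selection_freq = tibble::tibble(marker_id = marker_ids(geno),
                                    chrom = geno$chrom, pos_bp = geno$pos_bp,
                                    freq = sel_count / n_splits),
    splits = splits,
    alpha = alpha, n_splits = n_splits, gamma_min = gamma_min,
    split_fraction = split_fraction, cv_folds = cv_folds, seed = seed,
    family = pheno$family
  )
  class(fit) <- "hit_fit"
  fit
}

#' @export
print.hit_fit <- function(x, ...) {
  cat(sprintf("<hit_fit> %d sample splits, family = %s, alpha = %g\n",
              x$n_splits, x$family, x$alpha))
  cat(sprintf("  tested nodes: %d; min aggregated p: %s\n",
              nrow(x$table),
              if (nrow(x$table)) format(min(x$table$p_aggregated)) else "-"))
  invisible(x)
}

#' Call quantitative trait clusters
#'
#' The QTCs are the minimal significant clusters: nodes with aggregated
#' p-value at most `alpha` none of whose descendants is significant. A
#' reportable QTC must additionally be localizable: its node height
#' (`1 - mean |r|` among members under average linkage) may not exceed
#' `max_height`, so its markers are predominantly correlated with each other.
#' A minimal significant node above that height carries a diffuse signal —
#' typically population structure, which many weakly correlated markers
#' jointly predict — that cannot be attributed to any marker cluster, and is
#' not reported. Markers collapsed during deduplication are reinstated into
#' the QTC of their representative and contribute to its genomic span, which
#' is reported per chromosome present in the QTC.
#'
#' @param fit A `hit_fit` (or its `table`).
#' @param hierarchy The `marker_hierarchy` the fit was run on.
#' @param geno The (deduplicated, imputed) `genotype_matrix` of the run; used
#'   for medoid computation.
#' @param dup_map Optional duplicate map from [deduplicate_markers()].
#' @param marker_map Optional tibble (`marker_id`, `chrom`, `pos_bp`) covering
#'   reinstated duplicate markers too; defaults to `marker_info(geno)`.
#' @param alpha Significance level; defaults to the fit's.
#' @param max_height Largest node height reportable as a QTC.
#' @return A `qtc_result`: list with `qtcs` (one row per QTC), `spans` (one
#'   row per QTC x chromosome), `members` (one row per member marker) and the
#'   run settings.
#' @export
call_qtcs <- function(fit, hierarchy, geno, dup_map = NULL,
                      marker_map = NULL, alpha = NULL, max_height = 0.5) {
  tab <- if (inherits(fit, "hit_fit")) fit$table else fit
  if (is.null(alpha)) alpha <- if (inherits(fit, "hit_fit")) fit$alpha else 0.05
  if (is.null(marker_map)) marker_map <- marker_info(geno)
  if (!is.null(dup_map) && nrow(dup_map) > 0 &&
      !all(dup_map$marker_id %in% marker_map$marker_id)) {
    stop("marker_map must cover the duplicate markers; pass the metadata of ",
         "the pre-deduplication matrix", call. = FALSE)
  }
  sig <- tab$node_id[tab$p_aggregated <= alpha]
  is_sig <- rep(FALSE, hierarchy$n_nodes)
  is_sig[sig] <- TRUE
  qtc_nodes <- sig[vapply(sig, function(v)
    !any(is_sig[hierarchy$children[[v]]]), logical(1))]
  qtc_nodes <- qtc_nodes[hierarchy$height[qtc_nodes] <= max_height]
  empty <- list(
    qtcs = tibble::tibble(qtc_id = character(0), node_id = integer(0),
                          n_markers = integer(0), medoid = character(0),
                          p_aggregated = numeric(0)),
    spans = tibble::tibble(qtc_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           n_markers = integer(0)),
    members = tibble::tibble(qtc_id = character(0), marker_id = character(0),
                             is_duplicate = logical(0)),
    alpha = alpha
  )
  if (length(qtc_nodes) == 0) return(structure(empty, class = "qtc_result"))
  # order QTCs by genome position of their first member
  first_mem <- vapply(qtc_nodes, function(v)
    min(hierarchy$members[[v]]), integer(1))
  qtc_nodes <- qtc_nodes[order(first_mem)]
  qtcs <- list(); spans <- list(); members <- list()
  for (i in seq_along(qtc_nodes)) {
    v <- qtc_nodes[i]
    qid <- sprintf("qtc_%02d", i)
    mem_idx <- hierarchy$members[[v]]
    rep_ids <- hierarchy$marker_ids[mem_idx]
    all_ids <- expand_duplicates(rep_ids, dup_map)
    med <- hierarchy$marker_ids[cluster_medoid(geno, mem_idx)]
    info <- marker_map[match(all_ids, marker_map$marker_id), ]
    sp <- dplyr::summarise(dplyr::group_by(info, .data$chrom),
                           start = min(.data$pos_bp),
                           end = max(.data$pos_bp),
                           n_markers = dplyr::n(), .groups = "drop")
    qtcs[[i]] <- tibble::tibble(
      qtc_id = qid, node_id = v, n_markers = length(all_ids), medoid = med,
      p_aggregated = tab$p_aggregated[match(v, tab$node_id)])
    spans[[i]] <- dplyr::mutate(sp, qtc_id = qid, .before = 1)
    members[[i]] <- tibble::tibble(qtc_id = qid, marker_id = all_ids,
                                   is_duplicate = !(all_ids %in% rep_ids))
  }
  structure(list(qtcs = dplyr::bind_rows(qtcs), spans = dplyr::bind_rows(spans),
                 members = dplyr::bind_rows(members), alpha = alpha),
            class = "qtc_result")
}

#' @export
print.qtc_result <- function(x, ...) {
  cat(sprintf("<qtc_result> %d QTC(s) at alpha = %g\n", nrow(x$qtcs),
              x$alpha))
  if (nrow(x$qtcs) > 0) print(tidy(x))
  invisible(x)
}
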