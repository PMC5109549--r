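test_that("LASSO screen recovers a strong causal marker and is deterministic", {
  g <- toy_genotypes(n = 80, p = 20, seed = 41)
  withr::with_seed(42, y <- 3 * g$values[, 7] + 0.1 * rnorm(80))
  s1 <- lasso_screen(g$values, y, seed = 9)
  expect_true(7 %in% s1)
  s2 <- lasso_screen(g$values, y, seed = 9)
  expect_identical(as.integer(s1), as.integer(s2))
  expect_equal(length(attr(s1, "beta")), length(s1))
})

test_that("LASSO screen handles the single-marker edge case", {
  withr::with_seed(5, {
    x <- matrix(rbinom(60, 2, 0.4), 60, 1)
    y <- 2 * x[, 1] + 0.2 * rnorm(60)
  })
  s <- lasso_screen(x, y, seed = 3)
  expect_identical(as.integer(s), 1L)
})

test_that("LASSO screen validates its inputs", {
  g <- toy_genotypes(n = 30, p = 5, seed = 2)
  expect_error(lasso_screen(g$values, rep(1, 30)), "constant")
  expect_error(lasso_screen(g$values, rep(1, 30), family = "binomial"),
               "single class")
  expect_error(lasso_screen(g$values[1:15, ], rnorm(15), cv_folds = 10),
               "2 x cv_folds")
})

test_that("cluster test matches textbook F arithmetic on a small toy", {
  withr::with_seed(14, {
    x <- matrix(rnorm(30), 10, 3)
    y <- x[, 1] + 0.5 * rnorm(10)
  })
  # oracle via normal equations
  rss <- function(a) {
    b <- solve(crossprod(a), crossprod(a, y))
    sum((y - a %*% b)^2)
  }
  rss_null <- sum((y - mean(y))^2)
  rss_full <- rss(cbind(1, x))
  f_all <- ((rss_null - rss_full) / 3) / (rss_full / (10 - 4))
  p_all <- pf(f_all, 3, 6, lower.tail = FALSE)
  expect_equal(cluster_test(x, y, members_in_s = 1:3, s = 1:3), p_all,
               tolerance = 1e-12)
  # partial test of marker 1 given markers 2 and 3
  rss_red <- rss(cbind(1, x[, 2:3]))
  f_1 <- ((rss_red - rss_full) / 1) / (rss_full / 6)
  p_1 <- pf(f_1, 1, 6, lower.tail = FALSE)
  expect_equal(cluster_test(x, y, members_in_s = 1, s = 1:3), p_1,
               tolerance = 1e-12)
})

test_that("cluster test p-values are uniform under a conditional null", {
  withr::with_seed(77, {
    pvals <- replicate(200, {
      x <- matrix(rnorm(500 * 5), 500, 5)
      y <- rnorm(500)
      cluster_test(x, y, members_in_s = 1, s = 1:5)
    })
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("cluster test is decisive in the signal-dominant limit", {
  withr::with_seed(15, {
    x <- matrix(rbinom(200 * 4, 2, 0.4), 200, 4)
    y <- as.numeric(x[, 2])  # noiseless
  })
  expect_lt(cluster_test(x, y, members_in_s = 2, s = 1:4), 1e-6)
})

test_that("cluster test covers binomial likelihood-ratio and degenerate cases", {
  withr::with_seed(16, {
    x <- matrix(rbinom(200 * 3, 2, 0.4), 200, 3)
    eta <- x[, 1] - 1
    y <- rbinom(200, 1, 1 / (1 + exp(-eta)))
  })
  p <- cluster_test(x, y, members_in_s = 1, s = 1:3, family = "binomial")
  full <- glm(y ~ x, family = binomial())
  red <- glm(y ~ x[, 2:3], family = binomial())
  p_oracle <- anova(red, full, test = "Chisq")$`Pr(>Chi)`[2]
  expect_equal(p, p_oracle, tolerance = 1e-10)
  # aliased member column: nothing testable, p = 1
  x2 <- cbind(x[, 1], x[, 1], x[, 2])
  expect_equal(cluster_test(x2, rnorm(200), members_in_s = 2, s = 1:3), 1)
  # no residual degrees of freedom
  expect_error(cluster_test(x[1:4, ], rnorm(4), members_in_s = 1, s = 1:3),
               "reduce")
})

test_that("hierarchical adjustment inflates, caps and monotonizes", {
  expect_equal(hierarchical_adjust(0.01, 2, 4, 0), 0.02)
  expect_equal(hierarchical_adjust(0.9, 1, 4, 0), 1)        # capped
  expect_equal(hierarchical_adjust(0.03, 3, 3, 0), 0.03)    # root factor 1
  expect_equal(hierarchical_adjust(0.01, 2, 4, 0.5), 0.5)   # parent floor
  expect_error(hierarchical_adjust(0.01, 0, 4, 0))
  expect_error(hierarchical_adjust(0.01, 5, 4, 0))
})

test_that("p-value aggregation matches a dense-grid oracle and hand cases", {
  agg_oracle <- function(p, gmin = 0.05) {
    gs <- seq(gmin, 1, by = 1e-4)
    q <- vapply(gs, function(g)
      min(1, stats::quantile(p / g, g, type = 1)), numeric(1))
    min(1, (1 - log(gmin)) * min(q))
  }
  expect_equal(aggregate_pvalues(rep(1, 10)), 1)
  expect_equal(aggregate_pvalues(rep(0, 10)), 0)
  # constant list: infimum attained at gamma = 1
  expect_equal(aggregate_pvalues(rep(0.001, 50)), (1 - log(0.05)) * 0.001,
               tolerance = 1e-12)
  expect_equal(aggregate_pvalues(rep(0.001, 50)), 0.0039957,
               tolerance = 1e-4)
  withr::with_seed(6, {
    for (b in c(1, 7, 50)) {
      p <- runif(b)^2
      expect_equal(aggregate_pvalues(p), agg_oracle(p), tolerance = 2e-3)
      expect_true(aggregate_pvalues(p) >= 0 && aggregate_pvalues(p) <= 1)
    }
  })
  # single split: plain (1 - log(gamma_min)) scaling
  expect_equal(aggregate_pvalues(0.012), min(1, (1 - log(0.05)) * 0.012))
})

test_that("a split with an empty screen set tests no nodes", {
  g <- toy_genotypes(n = 60, p = 10, seed = 55)
  h <- build_hierarchy(g)
  found <- FALSE
  for (seed in 1:40) {
    y <- with_seed_rnorm(seed + 100, 60)
    ph <- phenotype(y, individual_ids(g))
    sp <- run_split(g, ph, h, seed = seed)
    if (length(sp$selected) == 0) {
      expect_equal(nrow(sp$tested), 0)
      found <- TRUE
      break
    }
  }
  expect_true(found)  # pure noise must yield at least one empty screen
})

test_that("a strong causal marker is traced to its leaf within one split", {
  g <- toy_genotypes(n = 200, p = 30, seed = 57)
  withr::with_seed(58, y <- 2 * g$values[, 12] + 0.1 * rnorm(200))
  ph <- phenotype(y, individual_ids(g))
  h <- build_hierarchy(g)
  sp <- run_split(g, ph, h, seed = 3)
  expect_true(12 %in% sp$selected)
  leaf_row <- sp$tested[sp$tested$node_id == 12, ]
  expect_equal(nrow(leaf_row), 1)
  expect_lte(leaf_row$p_adjusted, 0.05)
  # determinism
  sp2 <- run_split(g, ph, h, seed = 3)
  expect_identical(sp$tested, sp2$tested)
  expect_identical(sp$selected, sp2$selected)
})

test_that("run_hit aggregates splits reproducibly and monotonically", {
  g <- toy_genotypes(n = 120, p = 40, seed = 60)
  withr::with_seed(61, y <- 1.5 * g$values[, 9] - g$values[, 30] +
                     0.5 * rnorm(120))
  ph <- phenotype(y, individual_ids(g))
  h <- build_hierarchy(g)
  fit1 <- run_hit(g, ph, h, n_splits = 6, seed = 10)
  fit2 <- run_hit(g, ph, h, n_splits = 6, seed = 10)
  expect_identical(fit1$table, fit2$table)  # bit-identical rerun
  # child aggregated p >= parent aggregated p everywhere
  tab <- fit1$table
  for (i in seq_len(nrow(tab))) {
    pa <- h$parent[tab$node_id[i]]
    if (!is.na(pa) && pa %in% tab$node_id) {
      expect_gte(tab$p_aggregated[i],
                 tab$p_aggregated[match(pa, tab$node_id)])
    }
  }
  # selection frequencies live in [0, 1] with the causal marker selected often
  expect_true(all(fit1$selection_freq$freq >= 0 &
                    fit1$selection_freq$freq <= 1))
  expect_gte(fit1$selection_freq$freq[9], 0.5)
})

test_that("single-split aggregation is the scaled split table", {
  g <- toy_genotypes(n = 100, p = 25, seed = 63)
  withr::with_seed(64, y <- g$values[, 5] + 0.3 * rnorm(100))
  ph <- phenotype(y, individual_ids(g))
  h <- build_hierarchy(g)
  fit <- run_hit(g, ph, h, n_splits = 1, seed = 8)
  sp <- fit$splits[[1]]
  expected <- pmin(1, (1 - log(0.05)) * sp$tested$p_adjusted)
  # monotonization down the tree can only raise values
  expect_true(all(fit$table$p_aggregated >=
                    expected[match(fit$table$node_id, sp$tested$node_id)] -
                    1e-12))
  expect_identical(fit$table$node_id, sp$tested$node_id)
})

test_that("QTC calling reports minimal significant localized clusters", {
  g <- block_genotypes(groups = 2, per_group = 3, seed = 70)
  h <- build_hierarchy(g)
  kids <- cut_children(h, h$root)
  # fabricated aggregated table: root and first block significant
  tab <- tibble::tibble(node_id = c(h$root, kids[1], kids[2]),
                        p_aggregated = c(0.001, 0.004, 0.8))
  q <- call_qtcs(tab, h, g, alpha = 0.05)
  expect_equal(nrow(q$qtcs), 1)
  expect_equal(q$qtcs$node_id, kids[1])
  # brute-force minimality oracle: significant nodes with no significant
  # descendant (descendant = member subset) and admissible height
  sig <- tab$node_id[tab$p_aggregated <= 0.05]
  minimal <- sig[vapply(sig, function(v) {
    others <- setdiff(sig, v)
    !any(vapply(others, function(w)
      all(h$members[[w]] %in% h$members[[v]]) &&
        length(h$members[[w]]) < length(h$members[[v]]), logical(1)))
  }, logical(1))]
  minimal <- minimal[h$height[minimal] <= 0.5]
  expect_setequal(q$qtcs$node_id, minimal)
  # no significant node -> empty result
  q0 <- call_qtcs(tibble::tibble(node_id = h$root, p_aggregated = 0.2),
                  h, g, alpha = 0.05)
  expect_equal(nrow(q0$qtcs), 0)
})

test_that("diffuse significant clusters are not reported as QTCs", {
  g <- toy_genotypes(n = 50, p = 30, seed = 72)
  h <- build_hierarchy(g)
  expect_gt(h$height[h$root], 0.5)  # random markers merge high
  tab <- tibble::tibble(node_id = h$root, p_aggregated = 1e-6)
  q <- call_qtcs(tab, h, g, alpha = 0.05)
  expect_equal(nrow(q$qtcs), 0)
  # the same node is reported if localization is disabled
  q2 <- call_qtcs(tab, h, g, alpha = 0.05, max_height = 1)
  expect_equal(q2$qtcs$node_id, h$root)
})

test_that("duplicate markers are reinstated into the QTC of their representative", {
  withr::with_seed(73, {
    x <- rbinom(40, 2, 0.5)
    z1 <- rbinom(40, 2, 0.5)
    z2 <- rbinom(40, 2, 0.5)
    values <- cbind(m1 = x, m2 = x, m3 = 2 - x, m4 = z1, m5 = z2)
  })
  g <- genotype_matrix(values, chrom = rep("chr1", 5),
                       pos_bp = c(100, 200, 300, 5e5, 9e5))
  dd <- deduplicate_markers(g)
  h <- build_hierarchy(dd$genotypes)
  leaf <- match("m1", marker_ids(dd$genotypes))
  tab <- tibble::tibble(node_id = c(h$root, leaf),
                        p_aggregated = c(0.01, 0.01))
  q <- call_qtcs(tab, h, dd$genotypes, dup_map = dd$dup_map,
                 marker_map = marker_info(g), alpha = 0.05)
  expect_equal(nrow(q$qtcs), 1)
  expect_setequal(q$members$marker_id, c("m1", "m2", "m3"))
  expect_equal(q$qtcs$n_markers, 3)
  sp <- q$spans
  expect_equal(sp$start, 100)
  expect_equal(sp$end, 300)  # duplicates extend the span
})

test_that("binomial phenotypes run through the full inference", {
  G <- simulate_structured_genotypes(300, 120, k_subpops = 2, fst = 0.02,
                                     seed = 80)
  sim <- simulate_phenotype(G, 2, effect_distribution("gamma", shape = 3),
                            h2 = 0.9, seed = 81)
  yb <- simulate_binary_phenotype(G, sim$truth, prevalence = 0.5, seed = 82)
  dd <- deduplicate_markers(impute_missing(G))
  h <- build_hierarchy(dd$genotypes)
  fit <- run_hit(dd$genotypes, yb, h, n_splits = 4, seed = 83)
  expect_s3_class(fit, "hit_fit")
  expect_true(all(fit$table$p_aggregated >= 0 &
                    fit$table$p_aggregated <= 1))
  tab <- fit$table
  for (i in seq_len(nrow(tab))) {
    pa <- h$parent[tab$node_id[i]]
    if (!is.na(pa) && pa %in% tab$node_id) {
      expect_gte(tab$p_aggregated[i] + 1e-12,
                 tab$p_aggregated[match(pa, tab$node_id)])
    }
  }
})
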