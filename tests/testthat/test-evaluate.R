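marker_map_toy <- function() {
  tibble::tibble(
    marker_id = sprintf("m%02d", 1:8),
    chrom = c(rep("chr1", 5), rep("chr2", 3)),
    pos_bp = c(1e5, 1.05e5, 1.101e5, 5e5, 9e5, 2e5, 2.08e5, 7e5)
  )
}

test_that("truth matching applies the closed 10-kb window", {
  mm <- marker_map_toy()
  truth <- make_truth("m01", mm)
  # QTC containing the causal marker itself: distance 0
  r <- match_to_truth(make_qtc_result(list("m01"), mm), truth, mm)
  expect_equal(r$n_true_positive, 1)
  expect_equal(r$matches$distance_bp, 0)
  # 5,000 bp away on the same chromosome: inside the window
  r <- match_to_truth(make_qtc_result(list("m02"), mm), truth, mm)
  expect_equal(r$n_true_positive, 1)
  # 10,100 bp away: outside the closed window -> false positive
  r <- match_to_truth(make_qtc_result(list("m03"), mm), truth, mm)
  expect_equal(c(r$n_true_positive, r$n_false_positive), c(0, 1))
  expect_equal(r$precision, 0)
  # same position, different chromosome: never a match
  truth2 <- make_truth("m06", mm)
  r <- match_to_truth(make_qtc_result(list("m01"), mm), truth2, mm)
  expect_equal(r$n_true_positive, 0)
})

test_that("matching is one-to-one and greedy by distance", {
  mm <- marker_map_toy()
  truth <- make_truth("m01", mm)
  # two QTCs within the window of one causal locus: 1 TP + 1 FP
  r <- match_to_truth(make_qtc_result(list("m01", "m02"), mm), truth, mm)
  expect_equal(c(r$n_true_positive, r$n_false_positive), c(1, 1))
  expect_equal(r$matches$qtc_id, "qtc_01")  # the closer one wins
  expect_equal(r$precision, 0.5)
  # greedy equals exhaustive optimal assignment on small instances
  brute_max_matching <- function(member_list, truth_ids, mm, window = 1e4) {
    dist_ok <- function(mem, cid) {
      mi <- mm[match(mem, mm$marker_id), ]
      ci <- mm[match(cid, mm$marker_id), ]
      same <- mi$chrom == ci$chrom
      any(same) && min(abs(mi$pos_bp[same] - ci$pos_bp)) <= window
    }
    best <- 0
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (ord in perms(seq_along(member_list))) {
      used <- character(0); n <- 0
      for (qi in ord) {
        for (cid in setdiff(truth_ids, used)) {
          if (dist_ok(member_list[[qi]], cid)) {
            used <- c(used, cid); n <- n + 1; break
          }
        }
      }
      best <- max(best, n)
    }
    best
  }
  cases <- list(
    list(q = list("m01", "m02", "m04"), t = c("m01", "m03")),
    list(q = list(c("m01", "m02"), "m03"), t = c("m02", "m05")),
    list(q = list("m06", "m07"), t = c("m06", "m07"))
  )
  for (cs in cases) {
    truth <- make_truth(cs$t, mm)
    r <- match_to_truth(make_qtc_result(cs$q, mm), truth, mm)
    expect_equal(r$n_true_positive, brute_max_matching(cs$q, cs$t, mm))
    expect_equal(r$n_false_positive, length(cs$q) - r$n_true_positive)
  }
})

test_that("explained variance matches normal-equation arithmetic", {
  g <- toy_genotypes(n = 5, p = 3, seed = 30)
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  expect_equal(explained_variance(g, character(0), y), 0)
  # hand computation via normal equations on one regressor
  x <- cbind(1, g$values[, 2])
  b <- solve(crossprod(x), crossprod(x, y))
  r2_hand <- 1 - sum((y - x %*% b)^2) / sum((y - mean(y))^2)
  expect_equal(explained_variance(g, marker_ids(g)[2], y), r2_hand,
               tolerance = 1e-12)
  # exact linear function of the markers
  y2 <- 2 * g$values[, 1] - g$values[, 3] + 1
  expect_equal(suppressWarnings(
    explained_variance(g, marker_ids(g)[c(1, 3)], y2)), 1)
  # collinear regressors are dropped with a warning
  v <- g$values
  v[, 2] <- v[, 1]
  g$values <- v
  expect_warning(r2 <- explained_variance(g, marker_ids(g)[1:2], y),
                 "collinear")
  expect_true(r2 >= 0 && r2 <= 1)
})

test_that("GRM is the standardized cross-product with unit mean diagonal", {
  v <- matrix(c(0, 0, 2,
                2, 2, 0,
                1, 1, 1), 3, 3, byrow = FALSE,
              dimnames = list(c("a", "b", "c"), c("m1", "m2", "m3")))
  g <- genotype_matrix(v, chrom = rep("chr1", 3), pos_bp = 1:3 * 100)
  grm <- compute_grm(g)
  z <- scale(v[, 1:2])  # m3 is monomorphic and excluded
  expect_equal(grm, tcrossprod(z) / 2, ignore_attr = TRUE)
  # identical individuals: identical rows, off-diagonal equals diagonal
  expect_equal(grm["a", ], grm["b", ])
  expect_equal(grm["a", "b"], grm["a", "a"])
  gr <- compute_grm(toy_genotypes(n = 40, p = 60, seed = 31))
  expect_equal(gr, t(gr))
  expect_gt(mean(diag(gr)), 0.9)
  expect_lt(mean(diag(gr)), 1.1)
  mono <- genotype_matrix(matrix(1, 4, 2,
                                 dimnames = list(NULL, c("m1", "m2"))),
                          chrom = c("chr1", "chr1"), pos_bp = c(1, 2))
  expect_error(compute_grm(mono), "polymorphic")
})

test_that("structure involvement reflects alignment with the leading axes", {
  # two clean subpopulations: axis 1 is the split
  withr::with_seed(33, {
    n <- 40
    grp <- rep(c(0, 1), each = n / 2)
    values <- sapply(1:30, function(j) 2 * grp + 0)  # perfectly aligned
    noise <- matrix(rnorm(n * 10), n, 10)
    values <- cbind(values, noise)
    colnames(values) <- sprintf("mk%02d", 1:40)
  })
  g <- genotype_matrix(values, chrom = rep("chr1", 40), pos_bp = 1:40 * 50)
  grm <- compute_grm(g)
  expect_equal(structure_involvement(g, grm, 1), 1, tolerance = 1e-3)
  expect_equal(structure_involvement(g, grm, 1, n_axes = 0), 0)
  mono <- g
  mono$values[, 2] <- 1
  expect_error(structure_involvement(mono, grm, 2), "monomorphic")
})

test_that("mean structure involvement increases with simulated fst", {
  means <- vapply(c(0.01, 0.05, 0.2), function(fst) {
    g <- simulate_structured_genotypes(200, 150, k_subpops = 3, fst = fst,
                                       seed = 35)
    grm <- compute_grm(g)
    poly <- which(apply(g$values, 2, stats::sd) > 0)
    mean(vapply(poly[seq(1, length(poly), by = 3)], function(j)
      structure_involvement(g, grm, j), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("power curve counts are consistent and monotone in alpha", {
  G <- simulate_structured_genotypes(250, 400, k_subpops = 2, fst = 0.02,
                                     seed = 37)
  sim <- simulate_phenotype(G, 3, effect_distribution("gamma", shape = 3),
                            h2 = 0.9, seed = 38)
  dd <- deduplicate_markers(impute_missing(G))
  h <- build_hierarchy(dd$genotypes)
  fit <- run_hit(dd$genotypes, sim$phenotype, h, n_splits = 5, seed = 39)
  alphas <- c(0, 0.01, 0.05, 0.1)
  pc <- power_curve(fit, h, dd$genotypes, sim$truth, alphas,
                    dup_map = dd$dup_map, marker_map = marker_info(G))
  expect_equal(pc$alpha, alphas)
  expect_equal(unlist(pc[pc$alpha == 0, c("tp", "fp")], use.names = FALSE),
               c(0, 0))
  expect_false(is.unsorted(pc$tp))  # threshold nesting
  # direct recomputation at one level agrees
  q <- call_qtcs(fit, h, dd$genotypes, dup_map = dd$dup_map,
                 marker_map = marker_info(G), alpha = 0.05)
  r <- match_to_truth(q, sim$truth, marker_info(G))
  expect_equal(pc$tp[pc$alpha == 0.05], r$n_true_positive)
  expect_equal(pc$fp[pc$alpha == 0.05], r$n_false_positive)
  # precision and FP fraction sum to one whenever anything is reported
  rep_rows <- pc[pc$tp + pc$fp > 0, ]
  expect_equal(rep_rows$precision + rep_rows$fp / (rep_rows$tp + rep_rows$fp),
               rep(1, nrow(rep_rows)))
})
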