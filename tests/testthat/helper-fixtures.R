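# In-code fixture builders; no fixture files are stored.

with_seed_rnorm <- function(seed, n) withr::with_seed(seed, stats::rnorm(n))

# random genotype matrix with metadata; dosages 0/1/2
toy_genotypes <- function(n = 20, p = 10, seed = 1, na_frac = 0,
                          ploidy_mode = "outbred", n_chrom = 2) {
  withr::with_seed(seed, {
    values <- matrix(stats::rbinom(n * p, 2, 0.3), n, p)
    if (ploidy_mode == "inbred") values <- 2 * (values > 0)
    if (na_frac > 0) {
      values[sample(length(values), round(na_frac * length(values)))] <- NA
    }
    rownames(values) <- sprintf("ind%02d", seq_len(n))
    colnames(values) <- sprintf("mk%03d", seq_len(p))
    chrom <- sort(rep_len(sprintf("chr%d", seq_len(n_chrom)), p))
    pos <- unlist(lapply(split(seq_len(p), chrom), function(i)
      sort(sample.int(1e6, length(i)))), use.names = FALSE)
    genotype_matrix(values, chrom = chrom, pos_bp = pos,
                    ploidy_mode = ploidy_mode)
  })
}

# markers in `groups` latent blocks: high |r| within a block, ~0 across
block_genotypes <- function(n = 80, groups = 2, per_group = 3, noise = 0.15,
                            seed = 1) {
  withr::with_seed(seed, {
    p <- groups * per_group
    values <- matrix(0, n, p)
    for (g in seq_len(groups)) {
      latent <- stats::rnorm(n)
      for (j in seq_len(per_group)) {
        col <- (g - 1) * per_group + j
        values[, col] <- latent + noise * stats::rnorm(n)
      }
    }
    rownames(values) <- sprintf("ind%02d", seq_len(n))
    colnames(values) <- sprintf("mk%03d", seq_len(p))
    genotype_matrix(values, chrom = rep("chr1", p),
                    pos_bp = seq_len(p) * 1000)
  })
}

# exact average-linkage oracle: member sets and heights per merge of
# stats::hclust on 1 - |cor|
average_linkage_oracle <- function(values) {
  d <- 1 - abs(stats::cor(values))
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  p <- ncol(values)
  sets <- vector("list", p - 1)
  leaf_sets <- as.list(seq_len(p))
  for (r in seq_len(p - 1)) {
    get <- function(k) if (k < 0) leaf_sets[[-k]] else sets[[k]]
    sets[[r]] <- sort(c(get(hc$merge[r, 1]), get(hc$merge[r, 2])))
  }
  list(sets = sets, heights = hc$height)
}

# minimal synthetic qtc_result for the evaluation module (the matcher only
# reads qtc ids and member markers)
make_qtc_result <- function(member_list, marker_map, p = 1e-4, alpha = 0.05) {
  qids <- sprintf("qtc_%02d", seq_along(member_list))
  members <- dplyr::bind_rows(lapply(seq_along(member_list), function(i)
    tibble::tibble(qtc_id = qids[i], marker_id = member_list[[i]],
                   is_duplicate = FALSE)))
  qtcs <- tibble::tibble(qtc_id = qids, node_id = seq_along(qids),
                         n_markers = lengths(member_list),
                         medoid = vapply(member_list, `[`, character(1), 1),
                         p_aggregated = p)
  structure(list(qtcs = qtcs, spans = tibble::tibble(), members = members,
                 alpha = alpha),
            class = "qtc_result")
}

# sim_truth wrapper for fabricated causal sets
make_truth <- function(causal_ids, marker_map) {
  structure(list(causal_idx = match(causal_ids, marker_map$marker_id),
                 causal_ids = causal_ids,
                 effects = rep(1, length(causal_ids)), h2_target = 0.7,
                 g = NULL, var_e = 0, h2_realized = 0.7),
            class = "sim_truth")
}
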