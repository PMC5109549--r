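#' Effect-size distribution for simulated causal loci
#'
#' Additive effects are drawn either from a Gamma distribution
#' (shape 0.5, scale 1 by default: a few predominant major loci, many small
#' ones) or from a standard normal (no predominant loci). The effect of each
#' causal marker is applied to a randomly chosen allele, i.e. its sign is
#' randomized.
#'
#' @param kind `"gamma"` or `"normal"`.
#' @param shape,scale Gamma parameters.
#' @param mean,sd Normal parameters.
#' @return An `effect_distribution` object.
#' @export
effect_distribution <- function(kind = c("gamma", "normal"), shape = 0.5,
                                scale = 1, mean = 0, sd = 1) {
  kind <- match.arg(kind)
  structure(list(kind = kind, shape = shape, scale = scale, mean = mean,
                 sd = sd), class = "effect_distribution")
}

draw_effects <- function(dist, n) {
  raw <- switch(dist$kind,
                gamma = stats::rgamma(n, shape = dist$shape,
                                      scale = dist$scale),
                normal = stats::rnorm(n, dist$mean, dist$sd))
  sign <- sample(c(-1, 1), n, replace = TRUE)  # random allele choice
  raw * sign
}

#' Simulate island-model genotypes with population structure
#'
#' Balding–Nichols-style generator: an ancestral allele frequency is drawn
#' uniformly from `maf_range` per marker, subpopulation frequencies are Beta
#' distributed around it with variance `fst * p0 * (1 - p0)`, and genotypes
#' are drawn per subpopulation. Individuals are assigned to subpopulations in
#' equal shares (recorded in the `subpop` field). This reproduces the feature
#' of structured panels that matters for association testing: correlation
#' between physically unlinked markers induced by structure.
#'
#' @param n_individuals,p_markers Panel dimensions.
#' @param k_subpops Number of islands.
#' @param fst Wright's fixation index in `[0, 1)`; 0 gives an unstructured
#'   panel.
#' @param maf_range Range of the ancestral allele frequency.
#' @param ploidy_mode `"inbred"` draws one allele per individual (dosages
#'   0/2); `"outbred"` draws two (0/1/2).
#' @param n_chrom,chrom_length_bp Synthetic genome layout; marker positions
#'   are uniform over the chromosomes, then sorted.
#' @param seed Seed; the matrix is reproducible given it.
#' @return A [genotype_matrix()] with `subpop` set.
#' @export
simulate_structured_genotypes <- function(n_individuals, p_markers,
                                          k_subpops = 5, fst = 0.1,
                                          maf_range = c(0.05, 0.5),
                                          ploidy_mode = c("inbred", "outbred"),
                                          n_chrom = 5,
                                          chrom_length_bp = 30e6,
                                          seed = 1) {
  ploidy_mode <- match.arg(ploidy_mode)
  stopifnot(n_individuals >= 2, p_markers >= 1, k_subpops >= 1)
  if (fst >= 1 || fst < 0) stop("fst must be in [0, 1)", call. = FALSE)
  with_local_seed(seed, {
    p0 <- stats::runif(p_markers, maf_range[1], maf_range[2])
    freq <- if (fst == 0) {
      matrix(p0, k_subpops, p_markers, byrow = TRUE)
    } else {
      a <- p0 * (1 - fst) / fst
      b <- (1 - p0) * (1 - fst) / fst
      matrix(stats::rbeta(k_subpops * p_markers, rep(a, each = k_subpops),
                          rep(b, each = k_subpops)),
             k_subpops, p_markers)
    }
    subpop <- sort(rep_len(seq_len(k_subpops), n_individuals))
    f_ind <- freq[subpop, , drop = FALSE]
    values <- if (ploidy_mode == "inbred") {
      2 * matrix(stats::rbinom(n_individuals * p_markers, 1, f_ind),
                 n_individuals, p_markers)
    } else {
      matrix(stats::rbinom(n_individuals * p_markers, 2, f_ind),
             n_individuals, p_markers)
    }
    chrom <- sprintf("chr%02d", sample.int(n_chrom, p_markers,
                                           replace = TRUE))
    pos <- integer(p_markers)
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- sort(sample.int(chrom_length_bp, length(i)))
    }
    ord <- order(chrom, pos)
    values <- values[, ord, drop = FALSE]
    colnames(values) <- sprintf("m%05d", seq_len(p_markers))
    rownames(values) <- sprintf("ind_%04d", seq_len(n_individuals))
    g <- genotype_matrix(values, chrom = chrom[ord], pos_bp = pos[ord],
                         ploidy_mode = ploidy_mode, subpop = subpop)
    # subpopulation allele frequencies, kept for generator diagnostics
    attr(g, "subpop_freq") <- freq[, ord, drop = FALSE]
    g
  })
}

#' Simulate an additive phenotype with calibrated heritability
#'
#' Causal markers are drawn uniformly without replacement, each receives an
#' additive effect from `effect_dist` applied to a randomly chosen allele
#' (random sign), and Gaussian environmental noise is calibrated on the
#' realized genetic variance: `var_e = var(g) * (1 - h2) / h2`, so the
#' expected realized heritability `var(g) / var(y)` equals the target `h2`
#' (`h2 = 1` gives zero noise).
#'
#' @param geno A `genotype_matrix`.
#' @param n_causal Number of causal markers.
#' @param effect_dist An [effect_distribution()].
#' @param h2 Target narrow-sense heritability in `(0, 1]`.
#' @param seed Seed.
#' @return A list with `phenotype` (a [phenotype()]) and `truth` (a
#'   `sim_truth`: causal indices and IDs, effects, target `h2`, genetic
#'   values `g`, noise variance and realized heritability).
#' @export
simulate_phenotype <- function(geno, n_causal,
                               effect_dist = effect_distribution("gamma"),
                               h2 = 0.7, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), n_causal <= n_markers(geno),
            h2 > 0, h2 <= 1)
  with_local_seed(seed, {
    draw <- function() {
      causal <- sort(sample.int(n_markers(geno), n_causal))
      effects <- draw_effects(effect_dist, n_causal)
      g <- drop(geno$values[, causal, drop = FALSE] %*% effects)
      list(causal = causal, effects = effects, g = g)
    }
    d <- draw()
    if (stats::var(d$g) == 0) {
      d <- draw()  # one resample if all causal markers were monomorphic
      if (stats::var(d$g) == 0) {
        stop("causal markers carry no genetic variance", call. = FALSE)
      }
    }
    var_g <- stats::var(d$g)
    var_e <- var_g * (1 - h2) / h2
    y <- d$g + if (var_e > 0) stats::rnorm(length(d$g), 0, sqrt(var_e)) else 0
    truth <- structure(
      list(causal_idx = d$causal,
           causal_ids = marker_ids(geno)[d$causal],
           effects = d$effects, h2_target = h2, g = d$g, var_e = var_e,
           h2_realized = var_g / stats::var(y)),
      class = "sim_truth")
    list(phenotype = phenotype(y, individual_ids(geno), "gaussian"),
         truth = truth)
  })
}

#' Simulate a structured-null phenotype
#'
#' A phenotype that depends on the subpopulation label only — no marker is
#' causal. Each subpopulation gets a random mean; the subpopulation component
#' is rescaled to the requested share of the phenotypic variance and Gaussian
#' noise fills the rest. The global-null benchmark for family-wise error
#' control under population structure.
#'
#' @param geno A `genotype_matrix` with `subpop` set.
#' @param structure_share Fraction of phenotypic variance carried by the
#'   subpopulation means.
#' @param seed Seed.
#' @return A [phenotype()].
#' @export
simulate_null_phenotype <- function(geno, structure_share = 0.3, seed = 1) {
  if (is.null(geno$subpop)) {
    stop("genotype matrix carries no subpopulation labels", call. = FALSE)
  }
  stopifnot(structure_share >= 0, structure_share < 1)
  with_local_seed(seed, {
    k <- length(unique(geno$subpop))
    mu <- stats::rnorm(k)
    s <- mu[match(geno$subpop, sort(unique(geno$subpop)))]
    e <- stats::rnorm(n_individuals(geno))
    # orthogonalize the noise against the subpopulation means so the realized
    # structure share equals the requested one exactly
    e <- e - stats::ave(e, geno$subpop)
    y <- if (structure_share > 0 && stats::sd(s) > 0) {
      sqrt(structure_share) * (s - mean(s)) / stats::sd(s) +
        sqrt(1 - structure_share) * e / stats::sd(e)
    } else {
      e
    }
    phenotype(y, individual_ids(geno), "gaussian")
  })
}

#' Synthetic genetic map
#'
#' Uniform marker positions over `n_chrom` chromosomes with map distance
#' proportional to physical distance. Convenience input for
#' [simulate_ril_genotypes()].
#'
#' @param p_markers Number of markers.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp,chrom_length_cm Physical and map length per
#'   chromosome.
#' @param seed Seed.
#' @return Tibble with `marker_id`, `chrom`, `pos_bp`, `cm`.
#' @export
make_genetic_map <- function(p_markers, n_chrom = 5, chrom_length_bp = 30e6,
                             chrom_length_cm = 100, seed = 1) {
  with_local_seed(seed, {
    chrom <- sprintf("chr%02d", sample.int(n_chrom, p_markers,
                                           replace = TRUE))
    pos <- integer(p_markers)
    for (cc in unique(chrom)) {
      i <- which(chrom == cc)
      pos[i] <- sort(sample.int(chrom_length_bp, length(i)))
    }
    ord <- order(chrom, pos)
    tibble::tibble(marker_id = sprintf("m%05d", seq_len(p_markers)),
                   chrom = chrom[ord], pos_bp = pos[ord],
                   cm = pos[ord] / chrom_length_bp * chrom_length_cm)
  })
}

#' Simulate a recombinant inbred line population
#'
#' Biparental RILs: per line and chromosome the number of crossovers is
#' Poisson with mean `map_expansion` times the map length in Morgans (the
#' expansion factor approximates the extra recombination accumulated over
#' selfing generations under single-seed descent), crossover positions are
#' uniform on the genetic map, and each line is a fully homozygous mosaic of
#' the two parental haplotypes coded 0/2 — no residual heterozygosity, no
#' crossover interference.
#'
#' @param parent_a,parent_b Haploid allele vectors (0/1), one entry per map
#'   marker.
#' @param map Genetic map as from [make_genetic_map()]: `marker_id`, `chrom`,
#'   `pos_bp`, `cm` (monotone within chromosome).
#' @param n_lines Number of lines.
#' @param map_expansion Crossover-rate multiplier.
#' @param seed Seed.
#' @return A [genotype_matrix()] (inbred mode) counting the parent-B allele;
#'   attribute `"n_crossovers"` holds the lines x chromosomes crossover
#'   counts.
#' @export
simulate_ril_genotypes <- function(parent_a, parent_b, map, n_lines,
                                   map_expansion = 2, seed = 1) {
  stopifnot(length(parent_a) == nrow(map), length(parent_b) == nrow(map))
  chroms <- unique(map$chrom)
  for (cc in chroms) {
    if (is.unsorted(map$cm[map$chrom == cc])) {
      stop("genetic map must be monotone within a chromosome", call. = FALSE)
    }
  }
  total_len <- sum(vapply(chroms, function(cc)
    diff(range(map$cm[map$chrom == cc])), numeric(1)))
  if (all(parent_a == parent_b) && total_len == 0) {
    warning("identical parents and a zero-length map: degenerate population",
            call. = FALSE)
  }
  with_local_seed(seed, {
    values <- matrix(0, n_lines, nrow(map))
    n_co <- matrix(0L, n_lines, length(chroms),
                   dimnames = list(NULL, chroms))
    for (ci in seq_along(chroms)) {
      idx <- which(map$chrom == chroms[ci])
      cm <- map$cm[idx]
      len_m <- diff(range(cm)) / 100  # Morgans
      for (l in seq_len(n_lines)) {
        k <- stats::rpois(1, map_expansion * len_m)
        n_co[l, ci] <- k
        start <- sample(c(0L, 1L), 1)  # 0 = parent A, 1 = parent B
        if (k == 0) {
          origin <- rep(start, length(idx))
        } else {
          xo <- sort(stats::runif(k, min(cm), max(cm)))
          origin <- (start + findInterval(cm, xo)) %% 2L
        }
        values[l, idx] <- ifelse(origin == 1L, parent_b[idx], parent_a[idx])
      }
    }
    values <- 2 * values  # inbred dosage of the parent-B allele
    rownames(values) <- sprintf("ril_%04d", seq_len(n_lines))
    colnames(values) <- map$marker_id
    g <- genotype_matrix(values, chrom = map$chrom, pos_bp = map$pos_bp,
                         ploidy_mode = "inbred")
    attr(g, "n_crossovers") <- n_co
    g
  })
}

#' Simulate a binary (case-control) phenotype from a liability
#'
#' Liability = genetic values of an existing simulation truth plus Gaussian
#' noise with the truth's calibrated variance; individuals above the
#' empirical `(1 - prevalence)` liability quantile are cases.
#'
#' @param geno The `genotype_matrix` the truth was simulated on.
#' @param truth A `sim_truth` from [simulate_phenotype()].
#' @param prevalence Case fraction in `(0, 1)`.
#' @param seed Seed.
#' @return A binomial [phenotype()] (0 control / 1 case).
#' @export
simulate_binary_phenotype <- function(geno, truth, prevalence, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"), prevalence > 0, prevalence < 1)
  with_local_seed(seed, {
    n <- n_individuals(geno)
    liab <- truth$g + if (truth$var_e > 0)
      stats::rnorm(n, 0, sqrt(truth$var_e)) else 0
    thr <- stats::quantile(liab, 1 - prevalence, names = FALSE)
    phenotype(as.numeric(liab > thr), individual_ids(geno), "binomial")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d causal markers, target h2 = %g, realized h2 = %.3f\n",
    length(x$causal_idx), x$h2_target, x$h2_realized))
  invisible(x)
}

#' Simulation truth as a tibble
#'
#' @param x A `sim_truth`.
#' @param ... Unused.
#' @return Tibble with `marker_id`, `effect`.
#' @method tidy sim_truth
#' @export
tidy.sim_truth <- function(x, ...) {
  tibble::tibble(marker_id = x$causal_ids, effect = x$effects)
}
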