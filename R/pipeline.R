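#' Configuration for an end-to-end run
#'
#' A flat, fully serializable set of run parameters. Either file inputs
#' (`genotypes`, `phenotype`, optionally `truth`) or simulator settings
#' (`simulate = TRUE`) are given. One master `seed` drives every source of
#' randomness: per-stage seeds are derived from it by a counter, so reruns
#' and thread counts cannot change results.
#'
#' @param genotypes,phenotype,truth Input file paths (ignored when
#'   `simulate = TRUE`; `truth` is an optional marker_id/effect TSV).
#' @param genotype_format Passed to [read_genotypes()].
#' @param simulate Generate inputs with the built-in simulators instead of
#'   reading files.
#' @param n_individuals,p_markers,k_subpops,fst,n_chrom,chrom_length_bp
#'   Island-model settings (when simulating).
#' @param n_causal,h2,effect_kind Phenotype settings; `n_causal = 0` gives a
#'   structured-null phenotype with structure share `structure_share`.
#' @param structure_share Variance share of the subpopulation component under
#'   the null phenotype.
#' @param family,alpha,n_splits,gamma_min,split_fraction,cv_folds Passed to
#'   [run_hit()].
#' @param max_partition_size Passed to [build_hierarchy()].
#' @param max_qtc_height Localization cutoff for reportable QTCs, passed to
#'   [call_qtcs()].
#' @param window_bp Truth-matching window.
#' @param seed Master seed.
#' @param threads Worker processes for the sample splits.
#' @param out_prefix If non-empty, artifacts (QTC table, selection
#'   frequencies, config echo, truth) are written under this prefix.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes = "", phenotype = "", truth = "",
                       genotype_format = "auto", simulate = FALSE,
                       n_individuals = 400, p_markers = 3000, k_subpops = 5,
                       fst = 0.1, n_chrom = 5, chrom_length_bp = 30e6,
                       n_causal = 50, h2 = 0.7, effect_kind = "gamma",
                       structure_share = 0.3, family = "gaussian",
                       alpha = 0.05, n_splits = 50, gamma_min = 0.05,
                       split_fraction = 0.5, cv_folds = 10,
                       max_partition_size = 2000, max_qtc_height = 0.5,
                       window_bp = 10000,
                       seed = 1, threads = 1, out_prefix = "") {
  cfg <- list(genotypes = genotypes, phenotype = phenotype, truth = truth,
              genotype_format = genotype_format, simulate = simulate,
              n_individuals = n_individuals, p_markers = p_markers,
              k_subpops = k_subpops, fst = fst, n_chrom = n_chrom,
              chrom_length_bp = chrom_length_bp, n_causal = n_causal,
              h2 = h2, effect_kind = effect_kind,
              structure_share = structure_share, family = family,
              alpha = alpha, n_splits = n_splits, gamma_min = gamma_min,
              split_fraction = split_fraction, cv_folds = cv_folds,
              max_partition_size = max_partition_size,
              max_qtc_height = max_qtc_height,
              window_bp = window_bp, seed = seed, threads = threads,
              out_prefix = out_prefix)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$n_splits >= 1,
            cfg$gamma_min > 0, cfg$gamma_min < 1,
            cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$family %in% c("gaussian", "binomial"))
  if (!cfg$simulate && (cfg$genotypes == "" || cfg$phenotype == "")) {
    stop("either set simulate = TRUE or provide genotype and phenotype files",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a run configuration (flat `key: value` file)
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) / a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  m <- regmatches(lines, regexec("^\\s*([^:]+):\\s*(.*)\\s*$", lines))
  vals <- lapply(m, function(x) x[3])
  names(vals) <- vapply(m, function(x) trimws(x[2]), character(1))
  defaults <- lapply(formals(run_config), eval)
  known <- intersect(names(vals), names(defaults))
  vals <- lapply(known, function(k) {
    v <- vals[[k]]
    d <- defaults[[k]]
    if (is.character(d)) as.character(v)
    else if (is.logical(d)) as.logical(v)
    else as.numeric(v)
  })
  names(vals) <- known
  do.call(run_config, vals)
}

#' Run the full pipeline
#'
#' load/simulate -> align -> impute -> deduplicate -> cluster -> repeated
#' sample-splitting inference -> QTC calling -> (when truth is available)
#' evaluation. Progress is logged to stderr with the stage name; a failing
#' stage aborts with that name.
#'
#' @param config A [run_config()].
#' @return A list with `qtcs` (`qtc_result`), `fit` (`hit_fit`), `hierarchy`,
#'   `genotypes` (deduplicated), `dup_map`, `marker_map` (pre-deduplication
#'   metadata), `truth` and `eval` (`eval_report` or `NULL`), and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    message("[qtcgwas] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- derive_seeds(config$seed, 4)
  truth <- NULL
  if (config$simulate) {
    geno <- stage("simulate-genotypes", simulate_structured_genotypes(
      config$n_individuals, config$p_markers, k_subpops = config$k_subpops,
      fst = config$fst, n_chrom = config$n_chrom,
      chrom_length_bp = config$chrom_length_bp, seed = seeds[1]))
    if (config$n_causal > 0) {
      sim <- stage("simulate-phenotype", simulate_phenotype(
        geno, config$n_causal,
        effect_dist = effect_distribution(config$effect_kind),
        h2 = config$h2, seed = seeds[2]))
      pheno <- sim$phenotype
      truth <- sim$truth
    } else {
      pheno <- stage("simulate-phenotype", simulate_null_phenotype(
        geno, structure_share = config$structure_share, seed = seeds[2]))
    }
  } else {
    geno <- stage("load-genotypes", read_genotypes(
      config$genotypes, format = config$genotype_format))
    pheno <- stage("load-phenotype", read_phenotype(
      config$phenotype, family = config$family))
    al <- stage("align", align_individuals(geno, pheno))
    geno <- al$genotypes
    pheno <- al$phenotype
    if (nzchar(config$truth)) {
      tt <- utils::read.table(config$truth, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      idx <- match(tt$marker_id, marker_ids(geno))
      truth <- structure(list(causal_idx = idx, causal_ids = tt$marker_id,
                              effects = tt$effect, h2_target = NA_real_,
                              g = NULL, var_e = NA_real_,
                              h2_realized = NA_real_),
                         class = "sim_truth")
    }
  }
  geno <- stage("impute", impute_missing(geno))
  marker_map <- marker_info(geno)
  dd <- stage("deduplicate", deduplicate_markers(geno))
  hierarchy <- stage("cluster", build_hierarchy(
    dd$genotypes, max_partition_size = config$max_partition_size,
    seed = seeds[3]))
  fit <- stage("hit", run_hit(
    dd$genotypes, pheno, hierarchy, alpha = config$alpha,
    n_splits = config$n_splits, gamma_min = config$gamma_min,
    split_fraction = config$split_fraction, cv_folds = config$cv_folds,
    seed = seeds[4], n_threads = config$threads))
  qtcs <- stage("call-qtcs", call_qtcs(fit, hierarchy, dd$genotypes,
                                       dup_map = dd$dup_map,
                                       marker_map = marker_map,
                                       max_height = config$max_qtc_height))
  ev <- NULL
  if (!is.null(truth)) {
    ev <- stage("evaluate", {
      r <- match_to_truth(qtcs, truth, marker_map,
                          window_bp = config$window_bp)
      if (nrow(qtcs$qtcs) > 0) {
        r$r_squared <- explained_variance(dd$genotypes, qtcs$qtcs$medoid,
                                          pheno$values)
      }
      r
    })
  }
  if (nzchar(config$out_prefix)) {
    stage("write-outputs", {
      utils::write.table(tidy(qtcs), paste0(config$out_prefix, "_qtcs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(qtcs$members,
                         paste0(config$out_prefix, "_qtc_members.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fit$selection_freq,
                         paste0(config$out_prefix, "_selection_freq.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_run_config(config, paste0(config$out_prefix, "_config.txt"))
      if (!is.null(truth)) {
        utils::write.table(tidy(truth),
                           paste0(config$out_prefix, "_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }
  list(qtcs = qtcs, fit = fit, hierarchy = hierarchy,
       genotypes = dd$genotypes, dup_map = dd$dup_map,
       marker_map = marker_map, truth = truth, eval = ev, config = config)
}
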