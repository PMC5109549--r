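#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-node p-value table of a HIT fit
#'
#' @param x A `hit_fit`.
#' @param ... Unused.
#' @return Tibble with `node_id` and `p_aggregated` (tested nodes only;
#'   untested nodes have p = 1).
#' @method tidy hit_fit
#' @export
tidy.hit_fit <- function(x, ...) x$table

#' One-row summary of a HIT fit
#'
#' @param x A `hit_fit`.
#' @param ... Unused.
#' @method glance hit_fit
#' @export
glance.hit_fit <- function(x, ...) {
  sel_sizes <- vapply(x$splits, function(s) length(s$selected), numeric(1))
  tibble::tibble(
    n_splits = x$n_splits, alpha = x$alpha, gamma_min = x$gamma_min,
    family = x$family, n_tested_nodes = nrow(x$table),
    min_p_aggregated = if (nrow(x$table)) min(x$table$p_aggregated) else
      NA_real_,
    mean_selected = mean(sel_sizes), seed = x$seed
  )
}

#' Tidy a QTC result into one row per QTC and chromosome span
#'
#' @param x A `qtc_result`.
#' @param ... Unused.
#' @method tidy qtc_result
#' @export
tidy.qtc_result <- function(x, ...) {
  dplyr::left_join(x$spans,
                   x$qtcs[, c("qtc_id", "medoid", "p_aggregated")],
                   by = "qtc_id")
}

#' One-row summary of a QTC result
#'
#' @param x A `qtc_result`.
#' @param ... Unused.
#' @method glance qtc_result
#' @export
glance.qtc_result <- function(x, ...) {
  tibble::tibble(n_qtcs = nrow(x$qtcs), alpha = x$alpha,
                 n_markers = sum(x$qtcs$n_markers),
                 min_p = if (nrow(x$qtcs)) min(x$qtcs$p_aggregated) else
                   NA_real_)
}

#' Tidy an evaluation report (matched pairs)
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$matches

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n_true_positive = x$n_true_positive,
                 n_false_positive = x$n_false_positive,
                 n_causal = x$n_causal, precision = x$precision,
                 r_squared = x$r_squared)
}

#' Manhattan-style selection-frequency plot
#'
#' Per-marker selection frequency over the sample splits along the genome,
#' with QTC member markers highlighted when a `qtc_result` is supplied.
#'
#' @param object A `hit_fit`.
#' @param qtcs Optional `qtc_result` to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hit_fit
#' @export
autoplot.hit_fit <- function(object, qtcs = NULL, ...) {
  sf <- object$selection_freq
  chrom_levels <- unique(sf$chrom)
  offs <- c(0, cumsum(vapply(chrom_levels, function(cc)
    max(sf$pos_bp[sf$chrom == cc]) * 1.05, numeric(1))))
  sf$genome_pos <- sf$pos_bp + offs[match(sf$chrom, chrom_levels)]
  sf$in_qtc <- if (is.null(qtcs)) FALSE else
    sf$marker_id %in% qtcs$members$marker_id
  ggplot2::ggplot(sf, ggplot2::aes(x = .data$genome_pos, y = .data$freq,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_point(data = sf[sf$in_qtc, , drop = FALSE],
                        colour = "red", size = 1.2) +
    ggplot2::labs(x = "genome position", y = "selection frequency") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' True positives against false positives across significance levels, in the
#' style of a power/error trade-off curve.
#'
#' @param curve Tibble from [power_curve()].
#' @return A ggplot.
#' @export
plot_power_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fp, y = .data$tp)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$alpha))) +
    ggplot2::labs(x = "false positives", y = "true positives",
                  colour = "alpha") +
    ggplot2::theme_minimal()
}
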