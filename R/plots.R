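#' Plot scar-score components for a cohort
#'
#' Stacked bar chart of the HRD-LOH, LST and TAI components per sample,
#' ordered by total HRD score, with the HR-deficiency cut-off drawn as a
#' dashed line.
#'
#' @param scores A tibble from [hrd_score()] (one row per sample).
#' @param cutoff HRD-score threshold to draw (default 42).
#' @return A ggplot object.
#' @export
plot_hrd_scores <- function(scores, cutoff = 42) {
  long <- tidyr::pivot_longer(
    scores[c("sample_id", "hrd_loh", "lst", "tai", "total")],
    cols = c("hrd_loh", "lst", "tai"),
    names_to = "component", values_to = "count")
  long$sample_id <- stats::reorder(long$sample_id, long$total)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$count,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "HRD score", fill = "component") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname fit_exposures
#' @param object An `exposure_fit`.
#' @method autoplot exposure_fit
#' @export
autoplot.exposure_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$proportion,
                                   fill = .data$pruned)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25", `TRUE` = "grey80")) +
    ggplot2::labs(x = NULL, y = "exposure proportion",
                  title = sprintf("%s  (cosine %.4f)", object$sample_id,
                                  object$reconstruction_cosine)) +
    ggplot2::theme_minimal()
}

#' @rdname km_estimate
#' @param object A `km_fit`.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(tibble::tibble(time = 0, n_risk = object$n,
                                        n_event = 0, n_censor = 0,
                                        survival = 1), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "proportion surviving") +
    ggplot2::theme_minimal()
}

#' Plot a segment profile
#'
#' Per-chromosome ASCN tracks: major allele above, minor allele below,
#' LOH segments (minor allele zero) highlighted.
#'
#' @param profile A single-sample `segment_profile`.
#' @return A ggplot object.
#' @export
plot_segment_profile <- function(profile) {
  require_single_sample(profile)
  df <- unclass_tbl(profile)
  long <- tidyr::pivot_longer(df, cols = c("a_copies", "b_copies"),
                              names_to = "allele", values_to = "copies")
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start / 1e6, xend = .data$end / 1e6,
      y = .data$copies, yend = .data$copies, colour = .data$allele),
      linewidth = 1.2) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "position (Mb)", y = "copy number", colour = NULL) +
    ggplot2::theme_minimal()
}
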