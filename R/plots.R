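#' Plot an end-signal track with called peaks
#'
#' Per-position pooled signal in a genomic window, with cluster spans and
#' dominant positions overlaid — the visual check that clustering and
#' dominant-position calling behave as intended.
#'
#' @param track An end count track (TPM added if absent).
#' @param peaks Optional peak tibble to overlay.
#' @param chrom,from,to Window to draw (default: whole track).
#' @return A ggplot object.
#' @export
plot_end_track <- function(track, peaks = NULL, chrom = NULL,
                           from = NULL, to = NULL) {
  if (!("tpm" %in% names(track))) track <- tpm_normalize(track)
  chrom <- chrom %||% track$chrom[1]
  track <- dplyr::filter(track, .data$chrom == !!chrom)
  if (!is.null(from)) track <- dplyr::filter(track, .data$pos >= from)
  if (!is.null(to)) track <- dplyr::filter(track, .data$pos <= to)
  pooled <- dplyr::summarise(
    dplyr::group_by(track, .data$strand, .data$pos),
    tpm = sum(.data$tpm), .groups = "drop"
  )
  p <- ggplot2::ggplot(pooled, ggplot2::aes(x = .data$pos, y = .data$tpm)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = paste0(chrom, " position (bp)"),
                  y = "signal (TPM)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    pk <- dplyr::filter(peaks, .data$chrom == !!chrom)
    if (!is.null(from)) pk <- dplyr::filter(pk, .data$end >= from)
    if (!is.null(to)) pk <- dplyr::filter(pk, .data$start <= to)
    p <- p +
      ggplot2::geom_rect(
        data = pk, inherit.aes = FALSE, alpha = 0.2, fill = "steelblue",
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf)
      ) +
      ggplot2::geom_vline(data = pk, linetype = "dashed",
                          colour = "firebrick",
                          ggplot2::aes(xintercept = .data$dominant_pos))
  }
  p
}

#' Plot staged isoform log-ratio dynamics
#'
#' One line per gene: the log2 usage ratio of the two alternative ends
#' across trajectory stages.
#'
#' @param ratios Output of [stage_ratios()].
#' @return A ggplot object.
#' @export
plot_stage_ratios <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$stage, y = .data$log_ratio,
                                       group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = sort(unique(ratios$stage))) +
    ggplot2::labs(x = "trajectory stage",
                  y = "log2 ratio (end A / end B)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare classifier test accuracies
#'
#' @param object An `end_classifier_set` from [train_end_classifiers()].
#' @param ... Unused.
#' @return A ggplot bar chart of held-out accuracy per algorithm.
#' @method autoplot end_classifier_set
#' @export
autoplot.end_classifier_set <- function(object, ...) {
  d <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$acc)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "held-out accuracy") +
    ggplot2::theme_minimal()
}
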