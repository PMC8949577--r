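#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_col facet_grid
#'   labs theme_bw scale_y_log10 vars
NULL

#' @export
ggplot2::autoplot

#' Plot a peak set along the genome
#'
#' Each peak is drawn as a horizontal segment at its fold enrichment,
#' faceted by chromosome, so enriched regions and their spread are visible
#' at a glance.
#'
#' @param object A [peak_set()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peak_set <- function(object, ...) {
  tab <- as_tibble(object)
  ggplot(tab, aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                  y = .data$fold_enrichment, yend = .data$fold_enrichment)) +
    geom_segment(linewidth = 2) +
    facet_grid(rows = vars(.data$chrom)) +
    scale_y_log10() +
    labs(x = "position (Mb)", y = "fold enrichment",
         title = peak_source(object) %||% NULL) +
    theme_bw()
}

#' Plot workflow stage counts
#'
#' Bar chart of peak counts per gRNA at each pipeline stage: as parsed,
#' after negative elimination, after filtering, and the final common set.
#'
#' @param object A `workflow_report` from [run_workflow()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.workflow_report <- function(object, ...) {
  counts <- object$counts
  counts$stage <- factor(counts$stage, levels = unique(counts$stage))
  ggplot(counts, aes(x = .data$stage, y = .data$n)) +
    geom_col() +
    facet_grid(cols = vars(.data$grna)) +
    labs(x = NULL, y = "peaks", title = "peaks surviving each stage") +
    theme_bw()
}

#' @rdname autoplot.workflow_report
#' @export
plot_stage_counts <- function(object, ...) autoplot.workflow_report(object, ...)
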