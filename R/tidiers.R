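#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a peak-algebra result
#'
#' One row per surviving base record, with the operation mode attached.
#'
#' @param x A `peak_algebra` from [extract_common()] or
#'   [eliminate_negative()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.peak_algebra <- function(x, ...) {
  out <- as_tibble(x)
  out$mode <- attr(x, "mode")
  out
}

#' Summarize a peak-algebra result
#'
#' @param x A `peak_algebra`.
#' @param ... Unused.
#' @return One-row tibble: operation mode, number of input sets, base and
#'   surviving record counts.
#' @export
glance.peak_algebra <- function(x, ...) {
  tibble(
    mode = attr(x, "mode"),
    n_inputs = attr(x, "n_inputs"),
    n_base = attr(x, "n_base"),
    n_surviving = nrow(x)
  )
}

#' Tidy a workflow report
#'
#' Stage-by-stage peak counts: parsed, after negative elimination, after
#' filtering ("specific"), and the final common set.
#'
#' @param x A `workflow_report` from [run_workflow()].
#' @param ... Unused.
#' @return Tibble with columns `stage`, `grna`, `n`.
#' @export
tidy.workflow_report <- function(x, ...) {
  x$counts
}

#' Summarize a workflow report
#'
#' @param x A `workflow_report`.
#' @param ... Unused.
#' @return One-row tibble with the run's shape and the final common-peak
#'   count (`NA` when only one gRNA was analysed).
#' @export
glance.workflow_report <- function(x, ...) {
  tibble(
    n_grnas = length(x$per_grna_specific),
    n_negatives = length(x$config$negative_files),
    base = x$config$base,
    tag_percent = x$config$tag_percent %||% NA_real_,
    fold_enrichment_min = x$config$fold_enrichment_min %||% NA_real_,
    min_overlap_bp = x$config$rule$min_overlap_bp,
    n_common = if (is.null(x$common)) NA_integer_ else nrow(x$common)
  )
}
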