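#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical column order of a peak table. Required columns must be present in
# every input file; optional ones may be NA.
.peak_cols <- c(
  "chrom", "start", "end", "length", "summit", "tags",
  "neg10log10_pvalue", "fold_enrichment", "fdr_percent"
)
.peak_cols_required <- c("chrom", "start", "end", "tags", "fold_enrichment")

#' Construct a peak set
#'
#' A `peak_set` is a tibble with one row per MACS peak, carrying the genomic
#' interval (1-based, closed on both ends), the supporting tag (read) count
#' and the fold enrichment over input DNA, plus the optional MACS score
#' columns. It is the unit on which the peak-set algebra
#' ([extract_common()], [eliminate_negative()]) and the filters
#' ([apply_filters()]) operate.
#'
#' Rows are canonically sorted by `(chrom, start, end)`. Duplicate identical
#' rows are retained: the parser preserves input fidelity, and deduplication
#' happens only when [run_workflow()] writes its outputs.
#'
#' @param x A data frame with at least columns `chrom`, `start`, `end`,
#'   `tags`, `fold_enrichment`; optionally `length`, `summit`,
#'   `neg10log10_pvalue`, `fdr_percent`. Missing optional columns are filled
#'   with `NA` (`length` is derived as `end - start + 1`).
#' @param source File identifier recorded on the set (used in BED names and
#'   messages).
#' @param comments Character vector of preserved `#` comment lines.
#' @param header The original header line of the source file, if any.
#' @return A `peak_set` tibble.
#' @examples
#' peak_set(data.frame(
#'   chrom = "chr1", start = 100, end = 400,
#'   tags = 50, fold_enrichment = 12.5
#' ))
#' @export
peak_set <- function(x, source = NA_character_, comments = character(),
                     header = NA_character_) {
  x <- as_tibble(x)
  missing_req <- setdiff(.peak_cols_required, names(x))
  if (length(missing_req) > 0) {
    abort(
      sprintf("peak table is missing required column(s): %s",
              paste(missing_req, collapse = ", ")),
      class = "enchipr_format_error"
    )
  }
  for (col in setdiff(.peak_cols, names(x))) {
    x[[col]] <- NA_real_
  }
  x <- x[.peak_cols]
  x$chrom <- trimws(as.character(x$chrom))
  for (col in setdiff(.peak_cols, "chrom")) x[[col]] <- as.numeric(x[[col]])

  validate_peak_table(x)

  # `length` is derived, not primary: some MACS dialects write end - start.
  expected_len <- x$end - x$start + 1
  n_bad <- sum(x$length != expected_len, na.rm = TRUE)
  if (n_bad > 0) {
    warn(sprintf(
      "%d record(s) had length != end - start + 1; length recomputed", n_bad
    ))
  }
  x$length <- expected_len

  x <- x[order(x$chrom, x$start, x$end), ]
  new_peak_set(x, source = source, comments = comments, header = header)
}

new_peak_set <- function(x, source = NA_character_, comments = character(),
                         header = NA_character_) {
  structure(
    x,
    source = source,
    comments = comments,
    macs_header = header,
    class = c("peak_set", class(as_tibble(x)))
  )
}

validate_peak_table <- function(x) {
  bad <- function(msg) abort(msg, class = "enchipr_format_error")
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$tags)) {
    bad("start, end and tags must be numeric and non-missing")
  }
  if (any(x$start < 1)) bad("interval starts must be >= 1 (1-based coordinates)")
  if (any(x$end < x$start)) bad("interval ends must be >= starts")
  if (any(x$tags < 0)) bad("tag counts must be non-negative")
  fe <- x$fold_enrichment
  if (any(!is.na(fe) & fe <= 0)) bad("fold enrichment must be positive")
  invisible(x)
}

#' Drop peak-set metadata, returning a plain tibble
#'
#' @param x A `peak_set`.
#' @param ... Passed on.
#' @return A bare tibble of the peak table, without the source, comment or
#'   algebra attributes.
#' @export
as_tibble.peak_set <- function(x, ...) {
  for (a in c("source", "comments", "macs_header", "mode", "n_inputs",
              "n_base")) {
    attr(x, a) <- NULL
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  as_tibble(x, ...)
}

#' @export
print.peak_set <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf(
    "<peak_set> %d peak(s)%s\n", nrow(x),
    if (is.na(src)) "" else paste0(" from ", src)
  ))
  NextMethod()
}

# Retain peak_set attributes after a transformation that returns a bare tibble.
restore_peak_set <- function(x, template) {
  new_peak_set(
    as_tibble(x),
    source = attr(template, "source"),
    comments = attr(template, "comments"),
    header = attr(template, "macs_header")
  )
}

#' Source file identifier of a peak set
#' @param x A `peak_set`.
#' @return A string (possibly `NA`).
#' @export
peak_source <- function(x) attr(x, "source")

#' Preserved comment lines of a peak set
#' @param x A `peak_set`.
#' @return Character vector of `#` lines retained from the source file.
#' @export
peak_comments <- function(x) attr(x, "comments")
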