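# Threshold filters on tag number and fold enrichment. The comparator set is
# {>=, =, <=}, all inclusive. A tag criterion may be expressed relative to
# the target-locus peak ("tags >= 5% of the target peak's tag count"), in
# which case it must be resolved against a concrete peak set before use.

.filter_fields <- c("tags", "fold_enrichment")
.filter_ops <- c(">=", "=", "<=")

#' Define a filter criterion
#'
#' A single threshold criterion on a peak field. Criteria combine by logical
#' AND in [apply_filters()]. A relative tag criterion carries a percentage
#' instead of an absolute count: `filter_criterion("tags", ">=", 5,
#' relative_to_target = TRUE)` means "tag number at least 5% of the
#' target-locus peak's tag count", interpretable as an interacting ratio of
#' at least 5%. Relative criteria must pass through
#' [resolve_criteria()] before filtering.
#'
#' @param field `"tags"` or `"fold_enrichment"` (alias `"fe"`).
#' @param comparator `">="`, `"="` or `"<="`; all inclusive.
#' @param threshold Non-negative number; for a relative criterion, a
#'   percentage in \[0, 100\].
#' @param relative_to_target Interpret `threshold` as a percentage of the
#'   target-locus peak's tag count (only valid with `field = "tags"`).
#' @return A `filter_criterion` object.
#' @export
filter_criterion <- function(field, comparator = ">=", threshold,
                             relative_to_target = FALSE) {
  if (identical(field, "fe")) field <- "fold_enrichment"
  if (!field %in% .filter_fields) {
    abort(sprintf("filter field must be one of: %s",
                  paste(.filter_fields, collapse = ", ")),
          class = "enchipr_usage_error")
  }
  if (!comparator %in% .filter_ops) {
    abort("comparator must be one of: >=, =, <=",
          class = "enchipr_usage_error")
  }
  threshold <- as.numeric(threshold)
  if (is.na(threshold) || threshold < 0) {
    abort("threshold must be a non-negative number",
          class = "enchipr_usage_error")
  }
  if (relative_to_target) {
    if (field != "tags") {
      abort("a relative-to-target criterion must filter on tags",
            class = "enchipr_usage_error")
    }
    if (threshold > 100) {
      abort("a relative threshold is a percentage and must lie in [0, 100]",
            class = "enchipr_usage_error")
    }
  }
  structure(
    list(field = field, comparator = comparator, threshold = threshold,
         relative_to_target = relative_to_target),
    class = "filter_criterion"
  )
}

#' @export
format.filter_criterion <- function(x, ...) {
  sprintf("%s %s %s%s", x$field, x$comparator, format(x$threshold),
          if (x$relative_to_target) "% of target" else "")
}

#' @export
print.filter_criterion <- function(x, ...) {
  cat("<filter_criterion>", format(x), "\n")
  invisible(x)
}

#' Parse filter criteria from strings
#'
#' Grammar: `field op value[%target]` with `field` one of `tags`, `fe`,
#' `fold_enrichment`, `op` one of `>=`, `=`, `<=`, and an optional `%target`
#' suffix marking a relative tag criterion. Whitespace is ignored.
#' Examples: `"tags>=50"`, `"fe>=10"`, `"tags>=5%target"`.
#'
#' @param x Character vector of criterion strings.
#' @return List of [filter_criterion()] objects.
#' @export
parse_criteria <- function(x) {
  lapply(x, function(s) {
    s0 <- gsub("[[:space:]]", "", s)
    m <- regmatches(
      s0,
      regexec("^(tags|fe|fold_enrichment)(>=|<=|=)([0-9.]+)(%target)?$", s0)
    )[[1]]
    if (length(m) == 0) {
      abort(sprintf(
        "cannot parse criterion '%s'; expected 'field op value[%%target]' with field in {tags, fe, fold_enrichment} and op in {>=, =, <=}",
        s), class = "enchipr_usage_error")
    }
    filter_criterion(m[2], m[3], as.numeric(m[4]),
                     relative_to_target = m[5] == "%target")
  })
}

#' Locate the target locus
#'
#' Coordinates (1-based, closed) of the enChIP target locus, used to find
#' the target peak inside a peak list when resolving a relative tag
#' threshold.
#'
#' @param chrom Chromosome name.
#' @param start,end Interval bounds in bp, `end >= start`.
#' @return A `target_locus` object.
#' @export
target_locus <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    abort("target locus must be a valid interval with end >= start >= 1",
          class = "enchipr_usage_error")
  }
  structure(list(chrom = trimws(as.character(chrom)), start = start, end = end),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("<target_locus> %s:%s-%s\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE)))
  invisible(x)
}

# Find the target-locus peak: among peaks overlapping the locus, the one
# with the highest tag count, ties broken by leftmost start.
find_target_peak <- function(peaks, target, rule = overlap_rule()) {
  stopifnot(inherits(target, "target_locus"))
  locus <- tibble(chrom = target$chrom, start = target$start, end = target$end)
  hit <- overlaps_any(peaks, locus, as_overlap_rule(rule))
  if (!any(hit)) {
    abort(sprintf(
      "no peak in %s overlaps the target locus %s:%s-%s; check the target coordinates (the target locus should appear in its own enChIP peak list)",
      peak_source(peaks) %||% "the peak set", target$chrom,
      format(target$start, scientific = FALSE),
      format(target$end, scientific = FALSE)),
      class = "enchipr_resolution_error")
  }
  cand <- as_tibble(peaks)[hit, ]
  cand <- cand[order(-cand$tags, cand$start), ]
  cand[1, ]
}

#' Resolve a relative tag threshold against the target-locus peak
#'
#' Finds the peak(s) overlapping the target locus, takes the one with the
#' highest tag count (ties broken by leftmost start), and returns
#' `percent / 100` times its tag count. The result is used as an absolute
#' tag threshold; it is deliberately not rounded to an integer — the
#' comparison uses the real value.
#'
#' @param peaks The [peak_set()] in which to locate the target peak.
#' @param target A [target_locus()].
#' @param percent Percentage in \[0, 100\].
#' @param rule Overlap rule for locating the target peak.
#' @return The absolute tag threshold (a real number).
#' @export
resolve_relative_threshold <- function(peaks, target, percent,
                                       rule = overlap_rule()) {
  percent <- as.numeric(percent)
  if (is.na(percent) || percent < 0 || percent > 100) {
    abort("percent must lie in [0, 100]", class = "enchipr_usage_error")
  }
  ref <- find_target_peak(peaks, target, rule)
  percent / 100 * ref$tags
}

#' Resolve relative criteria to absolute thresholds
#'
#' Replaces every relative-to-target criterion in a list with its absolute
#' equivalent, resolved against `peaks` via [resolve_relative_threshold()].
#' Absolute criteria pass through unchanged.
#'
#' @param criteria List of [filter_criterion()] objects.
#' @param peaks The peak set carrying the target peak.
#' @param target A [target_locus()].
#' @param rule Overlap rule for locating the target peak.
#' @return List of absolute `filter_criterion` objects.
#' @export
resolve_criteria <- function(criteria, peaks, target, rule = overlap_rule()) {
  lapply(criteria, function(cr) {
    if (!cr$relative_to_target) return(cr)
    filter_criterion(
      cr$field, cr$comparator,
      resolve_relative_threshold(peaks, target, cr$threshold, rule)
    )
  })
}

# EQ on fold enrichment uses an absolute tolerance: fold enrichment is a
# printed decimal, so exact float equality would be meaningless. Tags are
# integers and compare exactly.
.fe_eq_tol <- 1e-6

criterion_keep <- function(values, cr) {
  switch(cr$comparator,
    ">=" = values >= cr$threshold,
    "<=" = values <= cr$threshold,
    "=" = if (cr$field == "fold_enrichment") {
      abs(values - cr$threshold) <= .fe_eq_tol
    } else {
      values == cr$threshold
    }
  )
}

#' Filter a peak set on tag number and fold enrichment
#'
#' Keeps the peaks satisfying the conjunction (logical AND) of all criteria;
#' record order is preserved, and an empty criteria list returns the input
#' unchanged. All comparators are inclusive: a peak with fold enrichment
#' exactly 10 survives `fe >= 10`.
#'
#' @param peaks A [peak_set()].
#' @param criteria List of [filter_criterion()] objects (or a character
#'   vector understood by [parse_criteria()]). Relative criteria must be
#'   resolved first via [resolve_criteria()].
#' @return A `peak_set` of the surviving peaks.
#' @examples
#' p <- peak_set(data.frame(chrom = "chr1", start = c(1, 100, 300),
#'                          end = c(50, 160, 400), tags = c(5, 10, 11),
#'                          fold_enrichment = c(9.9, 10, 12)))
#' apply_filters(p, parse_criteria(c("tags>=10", "fe>=10")))
#' @export
apply_filters <- function(peaks, criteria) {
  if (is.character(criteria)) criteria <- parse_criteria(criteria)
  if (inherits(criteria, "filter_criterion")) criteria <- list(criteria)
  if (length(criteria) == 0) return(peaks)
  for (cr in criteria) {
    if (!inherits(cr, "filter_criterion")) {
      abort("criteria must be filter_criterion objects",
            class = "enchipr_usage_error")
    }
    if (cr$relative_to_target) {
      abort(sprintf(
        "criterion '%s' is relative to the target locus and must be resolved with resolve_criteria() before filtering",
        format(cr)), class = "enchipr_usage_error")
    }
  }
  keep <- rep(TRUE, nrow(peaks))
  for (cr in criteria) keep <- keep & criterion_keep(peaks[[cr$field]], cr)
  restore_peak_set(peaks[keep, ], peaks)
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
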