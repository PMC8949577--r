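# Peak-set algebra. Two operations mirror the analyzer's two modes:
#  - Positive (AND): keep base peaks that overlap peaks in every other file
#    ("common peak information"),
#  - Negative (OR): drop base peaks that overlap the union of all negative
#    files ("negative peak information").
# Results always report the BASE file's records verbatim, never merged or
# intersected coordinates. Overlap queries run on GenomicRanges; intervals
# are 1-based closed, matching IRanges semantics directly.

as_granges <- function(peaks, seqlevels) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = peaks$start, end = peaks$end)
  )
}

shared_seqlevels <- function(...) {
  unique(unlist(lapply(list(...), function(p) unique(p$chrom))))
}

#' Overlap rule
#'
#' The minimum number of shared bases two peaks must have to count as
#' overlapping. The analyzer's default is any overlap, including a single
#' shared base; the required extent is configurable because peak widths and
#' the desired stringency vary between experiments.
#'
#' @param min_overlap_bp Minimum shared bases, an integer >= 1.
#' @return An `overlap_rule` object.
#' @export
overlap_rule <- function(min_overlap_bp = 1) {
  min_overlap_bp <- as.integer(min_overlap_bp)
  if (is.na(min_overlap_bp) || min_overlap_bp < 1) {
    abort("min_overlap_bp must be an integer >= 1",
          class = "enchipr_usage_error")
  }
  structure(list(min_overlap_bp = min_overlap_bp), class = "overlap_rule")
}

as_overlap_rule <- function(x) {
  if (inherits(x, "overlap_rule")) x else overlap_rule(x)
}

#' Do two peaks overlap?
#'
#' Vectorized overlap predicate on closed intervals: peaks overlap when they
#' lie on the same chromosome and share at least `min_overlap_bp` bases,
#' i.e. `min(end) - max(start) + 1 >= min_overlap_bp`. Symmetric in its
#' arguments. Adjacent closed intervals such as `[100, 200]` and `[200, 300]`
#' share base 200 and therefore overlap under the default rule.
#'
#' @param a,b Peak tables (rows are recycled if one has a single row).
#' @param rule An [overlap_rule()] or a bare integer minimum overlap.
#' @return Logical vector, one element per pair.
#' @export
peak_overlaps <- function(a, b, rule = overlap_rule()) {
  rule <- as_overlap_rule(rule)
  shared <- pmin(a$end, b$end) - pmax(a$start, b$start) + 1
  a$chrom == b$chrom & shared >= rule$min_overlap_bp
}

# Logical vector: does each base row overlap >= 1 row of `other`?
overlaps_any <- function(base, other, rule) {
  if (nrow(base) == 0) return(logical(0))
  if (nrow(other) == 0) return(rep(FALSE, nrow(base)))
  lev <- shared_seqlevels(base, other)
  hits <- GenomicRanges::findOverlaps(
    as_granges(base, lev), as_granges(other, lev),
    minoverlap = rule$min_overlap_bp
  )
  seq_len(nrow(base)) %in% S4Vectors::queryHits(hits)
}

new_peak_algebra <- function(surviving, base, mode, n_inputs) {
  out <- restore_peak_set(surviving, base)
  structure(
    out,
    mode = mode,
    n_inputs = n_inputs,
    n_base = nrow(base),
    class = c("peak_algebra", class(out))
  )
}

#' Extract peaks common to several peak sets
#'
#' Returns the base-file peaks that overlap (under `rule`) at least one peak
#' in **every** other set — the analyzer's Positive (AND) mode. Surviving
#' records are taken verbatim from the base set (coordinates, tags, fold
#' enrichment of the base file), in canonical order, each reported at most
#' once however many partners it overlaps.
#'
#' With `mutual = TRUE` a stricter variant is used: a base peak survives
#' only if some single genomic stretch of at least `min_overlap_bp` bases
#' within it is covered by every other set simultaneously. The default
#' base-centric reading requires overlap with each other set individually.
#'
#' @param base The base [peak_set()]; results are drawn from it.
#' @param others A `peak_set` or list of peak sets to compare against
#'   (at least one, so that two or more files enter the comparison).
#' @param rule An [overlap_rule()] or bare integer.
#' @param mutual Require a genomic position shared by all sets at once.
#' @return A `peak_algebra` object: a `peak_set` of the surviving base
#'   records with mode `"common"`; its row count is the common-peak count.
#' @examples
#' a <- peak_set(data.frame(chrom = "chr1", start = c(100, 500),
#'                          end = c(200, 600), tags = c(30, 40),
#'                          fold_enrichment = c(12, 15)))
#' b <- peak_set(data.frame(chrom = "chr1", start = 150, end = 520,
#'                          tags = 10, fold_enrichment = 11))
#' extract_common(a, b)
#' @export
extract_common <- function(base, others, rule = overlap_rule(),
                           mutual = FALSE) {
  rule <- as_overlap_rule(rule)
  others <- as_peak_set_list(others)
  if (length(others) < 1) {
    abort("common extraction needs two or more files: supply at least one set to compare against the base",
          class = "enchipr_usage_error")
  }
  keep <- if (mutual) {
    mutual_common_keep(base, others, rule)
  } else {
    Reduce(`&`, lapply(others, function(o) overlaps_any(base, o, rule)),
           rep(TRUE, nrow(base)))
  }
  new_peak_algebra(base[keep, ], base, mode = "common",
                   n_inputs = length(others) + 1L)
}

# Mutual-position variant: track, per base peak, the fragments of it covered
# by every other set so far; a peak survives while some fragment has width
# >= the rule's minimum.
mutual_common_keep <- function(base, others, rule) {
  if (nrow(base) == 0) return(logical(0))
  lev <- do.call(shared_seqlevels, c(list(base), others))
  frags <- as_granges(base, lev)
  S4Vectors::mcols(frags)$base_idx <- seq_len(nrow(base))
  for (o in others) {
    if (length(frags) == 0) break
    cover <- GenomicRanges::reduce(as_granges(o, lev))
    hits <- GenomicRanges::findOverlaps(frags, cover)
    pieces <- GenomicRanges::pintersect(
      frags[S4Vectors::queryHits(hits)], cover[S4Vectors::subjectHits(hits)]
    )
    frags <- pieces[GenomicRanges::width(pieces) >= 1]
  }
  ok <- unique(S4Vectors::mcols(
    frags[GenomicRanges::width(frags) >= rule$min_overlap_bp]
  )$base_idx)
  seq_len(nrow(base)) %in% ok
}

#' Eliminate negative-control peaks from a peak set
#'
#' Forms the union of all peaks in the negative sets and returns the base
#' peaks that overlap **none** of it — the analyzer's Negative (OR) mode,
#' used to subtract off-target binding sites detected in no-gRNA or
#' irrelevant-gRNA controls. Surviving records are the base file's records
#' verbatim.
#'
#' @param base The base [peak_set()].
#' @param negatives A `peak_set` or list of peak sets of negative peaks
#'   (at least one set; an *empty* set is legal and eliminates nothing).
#' @param rule An [overlap_rule()] or bare integer.
#' @return A `peak_algebra` with mode `"negative-eliminated"`.
#' @examples
#' a <- peak_set(data.frame(chrom = "chr1", start = c(100, 500),
#'                          end = c(200, 600), tags = c(30, 40),
#'                          fold_enrichment = c(12, 15)))
#' neg <- peak_set(data.frame(chrom = "chr1", start = 480, end = 700,
#'                            tags = 25, fold_enrichment = 9))
#' eliminate_negative(a, neg)
#' @export
eliminate_negative <- function(base, negatives, rule = overlap_rule()) {
  rule <- as_overlap_rule(rule)
  negatives <- as_peak_set_list(negatives)
  if (length(negatives) < 1) {
    abort("negative elimination needs at least one negative peak set",
          class = "enchipr_usage_error")
  }
  union_tab <- dplyr::bind_rows(lapply(negatives, as_tibble))
  hit <- overlaps_any(base, union_tab, rule)
  new_peak_algebra(base[!hit, ], base, mode = "negative-eliminated",
                   n_inputs = length(negatives) + 1L)
}

as_peak_set_list <- function(x) {
  if (is.data.frame(x)) list(x) else as.list(x)
}

#' @export
print.peak_algebra <- function(x, ...) {
  cat(sprintf("<peak_algebra: %s> %d of %d base peak(s) surviving\n",
              attr(x, "mode"), nrow(x), attr(x, "n_base")))
  print(as_tibble(x), ...)
  invisible(x)
}
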