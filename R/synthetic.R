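# Seeded generator of synthetic enChIP-Seq experiments with planted ground
# truth. It emulates the comparison-set structure of a real experiment:
#  - a target-locus peak (high tags, high fold enrichment) in every positive
#    file — the pulled-down locus itself;
#  - common peaks planted in all positive files and absent from negatives —
#    the true interacting regions;
#  - decoy peaks unique to one file — irreproducible noise;
#  - off-target peaks planted in positives AND negatives — CRISPR off-target
#    binding, removed by negative elimination.
# Categories occupy pairwise non-overlapping intervals by construction, so
# workflow recovery of the planted common peaks is exact.

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters for a synthetic enChIP-Seq experiment
#'
#' Defaults describe a desk-scale experiment: two on-target gRNA samples
#' and one negative control over a synthetic genome of three 10-Mb
#' chromosomes, with six true common peaks. The target peak carries 1000
#' tags at fold enrichment 50; planted peak tags are drawn uniformly over
#' `tags_range` and fold enrichments over `fe_range`, ranges that straddle
#' the default filter thresholds (5% of 1000 = 50 tags; fold enrichment 10)
#' so that both filter outcomes occur.
#'
#' @param n_grnas Number of positive (on-target gRNA) files.
#' @param n_negatives Number of negative-control files.
#' @param n_common True common peaks planted in every positive file.
#' @param n_decoys File-specific decoy peaks planted per file.
#' @param n_offtargets Off-target peaks planted in all positives and all
#'   negatives.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param peak_width Min and max planted peak width in bp.
#' @param target_tags,target_fe Tag count and fold enrichment of the
#'   target-locus peak.
#' @param tags_range Integer range for planted peak tag counts.
#' @param fe_range Range for planted peak fold enrichments (drawn uniformly,
#'   rounded to 2 decimals as MACS prints them).
#' @param tag_percent,fe_min Filter settings used to mark which planted
#'   common peaks are recoverable (`passes_filters` in the truth table).
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_grnas = 2, n_negatives = 1, n_common = 6,
                             n_decoys = 10, n_offtargets = 8,
                             chrom_sizes = c(chr1 = 1e7, chr2 = 1e7,
                                             chr3 = 1e7),
                             peak_width = c(200, 2000),
                             target_tags = 1000, target_fe = 50,
                             tags_range = c(20, 200), fe_range = c(5, 20),
                             tag_percent = 5, fe_min = 10) {
  counts <- c(n_grnas, n_negatives, n_common, n_decoys, n_offtargets)
  if (any(counts < 0) || n_grnas < 1) {
    abort("counts must be non-negative and at least one gRNA is required",
          class = "enchipr_usage_error")
  }
  structure(
    list(n_grnas = n_grnas, n_negatives = n_negatives, n_common = n_common,
         n_decoys = n_decoys, n_offtargets = n_offtargets,
         chrom_sizes = chrom_sizes, peak_width = peak_width,
         target_tags = target_tags, target_fe = target_fe,
         tags_range = tags_range, fe_range = fe_range,
         tag_percent = tag_percent, fe_min = fe_min),
    class = "synthetic_params"
  )
}

#' Generate a synthetic enChIP-Seq experiment
#'
#' Writes one MACS-style tab file per positive gRNA sample and per negative
#' control into `dir`, plants the peak categories described in
#' [synthetic_params()], and returns the ground truth. Deterministic: the
#' same seed and parameters produce byte-identical files.
#'
#' @param params A [synthetic_params()] list.
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @return A list with `positive_files` (named by gRNA label),
#'   `negative_files`, `truth` (tibble of planted peaks with their category,
#'   carrying file, and `passes_filters` flag for common peaks),
#'   `target_locus`, `params` and `seed`.
#' @examples
#' exp <- generate_synthetic_experiment(synthetic_params(n_common = 3),
#'                                      seed = 7, dir = tempfile())
#' dplyr::count(exp$truth, category)
#' @export
generate_synthetic_experiment <- function(params = synthetic_params(), seed,
                                          dir) {
  stopifnot(inherits(params, "synthetic_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  slot <- params$peak_width[2] + 100
  bins_per_chrom <- floor(params$chrom_sizes / slot)
  total_bins <- sum(bins_per_chrom)
  n_files <- params$n_grnas + params$n_negatives
  n_total <- 1 + params$n_common + params$n_offtargets +
    params$n_decoys * n_files
  if (n_total > total_bins) {
    abort(sprintf(
      "cannot place %d non-overlapping peaks in %d available slots; enlarge the genome or reduce peak counts",
      n_total, total_bins), class = "enchipr_generation_error")
  }

  grna_labels <- paste0("gRNA", seq_len(params$n_grnas))
  neg_labels <- if (params$n_negatives > 0) {
    paste0("neg", seq_len(params$n_negatives))
  } else character()

  truth <- run_with_seed(seed, {
    bins <- sample.int(total_bins, n_total)
    chrom_idx <- findInterval(bins - 1, cumsum(c(0, bins_per_chrom)),
                              rightmost.closed = FALSE)
    chrom <- names(params$chrom_sizes)[chrom_idx]
    bin_in_chrom <- bins - c(0, cumsum(bins_per_chrom))[chrom_idx]
    widths <- sample(seq(params$peak_width[1], params$peak_width[2]), n_total,
                     replace = TRUE)
    slack <- as.integer(slot - widths)
    offsets <- vapply(slack, function(s) sample.int(s + 1L, 1L) - 1L,
                      integer(1))
    start <- (bin_in_chrom - 1) * slot + 1 + offsets
    end <- start + widths - 1

    category <- rep("decoy", n_total)
    category[1] <- "target"
    if (params$n_common > 0) category[1 + seq_len(params$n_common)] <- "common"
    if (params$n_offtargets > 0) {
      category[1 + params$n_common + seq_len(params$n_offtargets)] <-
        "offtarget"
    }
    file_lab <- rep(NA_character_, n_total)
    decoy_idx <- which(category == "decoy")
    file_lab[decoy_idx] <- rep(c(grna_labels, neg_labels),
                               each = params$n_decoys)

    tags <- sample(seq(params$tags_range[1], params$tags_range[2]), n_total,
                   replace = TRUE)
    fe <- round(stats::runif(n_total, params$fe_range[1], params$fe_range[2]),
                2)
    tags[1] <- params$target_tags
    fe[1] <- params$target_fe
    pval <- round(stats::runif(n_total, 50, 300), 2)
    fdr <- round(stats::runif(n_total, 0, 5), 2)

    tibble(
      category = category, file = file_lab, chrom = chrom,
      start = start, end = end, length = widths,
      summit = floor(widths / 2), tags = tags, fold_enrichment = fe,
      neg10log10_pvalue = pval, fdr_percent = fdr
    )
  })

  thr <- params$tag_percent / 100 * params$target_tags
  truth$passes_filters <- truth$category == "common" &
    truth$tags >= thr & truth$fold_enrichment >= params$fe_min

  peak_cols <- setdiff(names(truth), c("category", "file", "passes_filters"))
  file_table <- function(label, positive) {
    shared <- if (positive) c("target", "common", "offtarget") else "offtarget"
    rows <- truth$category %in% shared |
      (truth$category == "decoy" & !is.na(truth$file) & truth$file == label)
    peak_set(truth[rows, peak_cols], source = label,
             comments = c("# synthetic enChIP-Seq peak file",
                          sprintf("# label=%s seed=%d", label, seed)))
  }
  write_one <- function(label, positive) {
    path <- file.path(dir, paste0(label, "_peaks.tab"))
    write_macs_tab(file_table(label, positive), path)
    path
  }
  positive_files <- vapply(grna_labels, write_one, character(1),
                           positive = TRUE)
  negative_files <- vapply(neg_labels, write_one, character(1),
                           positive = FALSE)

  list(
    positive_files = positive_files, negative_files = negative_files,
    truth = truth,
    target_locus = target_locus(truth$chrom[1], truth$start[1], truth$end[1]),
    params = params, seed = seed, dir = dir
  )
}

#' Workflow configuration for a generated experiment
#'
#' Convenience wrapper: builds the [workflow_config()] that analyses a
#' synthetic experiment under the filter settings it was generated with.
#'
#' @param experiment Result of [generate_synthetic_experiment()].
#' @param ... Overrides passed on to [workflow_config()].
#' @return A `workflow_config`.
#' @export
synthetic_workflow_config <- function(experiment, ...) {
  defaults <- list(
    positive_files = experiment$positive_files,
    negative_files = experiment$negative_files,
    target_locus = experiment$target_locus,
    tag_percent = experiment$params$tag_percent,
    fold_enrichment_min = experiment$params$fe_min
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(workflow_config, args)
}
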