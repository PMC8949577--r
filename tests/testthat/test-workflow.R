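local_experiment <- function(seed = 1, params = synthetic_params(),
                             env = parent.frame()) {
  generate_synthetic_experiment(params, seed = seed,
                                dir = withr::local_tempdir(.local_envir = env))
}

test_that("the workflow recovers exactly the planted common peaks", {
  e <- local_experiment(seed = 202,
                        params = synthetic_params(n_grnas = 3, n_common = 8))
  report <- run_workflow(synthetic_workflow_config(e))
  want <- e$truth[e$truth$passes_filters, ]
  got <- as_tibble(report$common)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got[c("chrom", "start", "end", "tags", "fold_enrichment")],
               want[order(want$chrom, want$start),
                    c("chrom", "start", "end", "tags", "fold_enrichment")],
               ignore_attr = TRUE)
})

test_that("workflow equals the manual composition of module operations", {
  e <- local_experiment(seed = 55)
  cfg <- synthetic_workflow_config(e)
  report <- run_workflow(cfg)

  negatives <- lapply(cfg$negative_files, read_macs_peaks)
  manual <- list()
  for (g in names(cfg$positive_files)) {
    p <- read_macs_peaks(cfg$positive_files[[g]])
    thr <- resolve_relative_threshold(p, cfg$target_locus, cfg$tag_percent)
    s <- eliminate_negative(p, negatives)
    s <- apply_filters(s, list(
      filter_criterion("tags", ">=", thr),
      filter_criterion("fold_enrichment", ">=", cfg$fold_enrichment_min)
    ))
    locus <- tibble::tibble(chrom = cfg$target_locus$chrom,
                            start = cfg$target_locus$start,
                            end = cfg$target_locus$end)
    s <- s[!peak_overlaps(s, locus[rep(1, nrow(s)), ]), ]
    manual[[g]] <- s
  }
  common <- extract_common(manual[[cfg$base]],
                           manual[setdiff(names(manual), cfg$base)])
  for (g in names(manual)) {
    expect_same_records(report$per_grna_specific[[g]], manual[[g]])
  }
  expect_same_records(report$common, common)
})

test_that("report counts agree with recomputing each stage", {
  e <- local_experiment(seed = 14)
  report <- run_workflow(synthetic_workflow_config(e))
  counts <- tidy(report)
  for (g in names(report$per_grna_specific)) {
    expect_equal(counts$n[counts$stage == "specific" & counts$grna == g],
                 nrow(report$per_grna_specific[[g]]))
    expect_equal(counts$n[counts$stage == "parsed" & counts$grna == g],
                 nrow(read_macs_peaks(e$positive_files[[g]])))
  }
  expect_equal(counts$n[counts$stage == "common"], nrow(report$common))
  expect_equal(glance(report)$n_common, nrow(report$common))
})

test_that("the common set is a subset of the base gRNA's specific set", {
  e <- local_experiment(seed = 77, params = synthetic_params(n_grnas = 4))
  report <- run_workflow(synthetic_workflow_config(e))
  base_specific <- record_key(report$per_grna_specific[[report$config$base]])
  common <- record_key(report$common)
  expect_equal(
    nrow(dplyr::inner_join(common, base_specific, by = names(common))),
    nrow(common)
  )
})

test_that("a single positive with an empty negative and no filters passes through", {
  e <- local_experiment(seed = 31,
                        params = synthetic_params(n_grnas = 1,
                                                  n_offtargets = 0,
                                                  n_decoys = 0))
  # the negative file is empty (no off-targets, no decoys)
  cfg <- workflow_config(
    positive_files = e$positive_files,
    negative_files = e$negative_files,
    tag_percent = NULL, fold_enrichment_min = NULL
  )
  report <- run_workflow(cfg)
  expect_null(report$common)
  expect_same_records(report$per_grna_specific[[1]],
                      read_macs_peaks(e$positive_files[[1]]))
})

test_that("zero survivors is a valid outcome, not an error", {
  e <- local_experiment(seed = 40,
                        params = synthetic_params(n_common = 0,
                                                  n_decoys = 0))
  report <- run_workflow(synthetic_workflow_config(e))
  expect_equal(nrow(report$common), 0)
})

test_that("subtract-then-intersect equals intersect-then-subtract", {
  set.seed(99)
  for (seed in 1:15) {
    e <- local_experiment(seed = seed,
                          params = synthetic_params(
                            n_grnas = sample(2:4, 1),
                            n_negatives = sample(1:2, 1)
                          ))
    expect_true(order_independence_check(synthetic_workflow_config(e)))
  }
})

test_that("order independence holds when a negative hits a common peak in one file only", {
  # construct: common peak c in both positives; negative peak overlapping c
  mkset <- function(tab, path) {
    write_macs_tab(peak_set(tab), path)
    path
  }
  d <- withr::local_tempdir()
  common_peak <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000,
                                tags = 100, fold_enrichment = 15)
  extra <- tibble::tibble(chrom = "chr2", start = 5000, end = 6000,
                          tags = 50, fold_enrichment = 12)
  p1 <- mkset(rbind(common_peak, extra), file.path(d, "p1.tab"))
  p2 <- mkset(common_peak, file.path(d, "p2.tab"))
  neg <- mkset(tibble::tibble(chrom = "chr1", start = 1900, end = 2500,
                              tags = 30, fold_enrichment = 8),
               file.path(d, "neg.tab"))
  cfg <- workflow_config(
    positive_files = c(a = p1, b = p2), negative_files = neg,
    tag_percent = NULL, fold_enrichment_min = NULL
  )
  expect_true(order_independence_check(cfg))
})

test_that("per-stage CSVs and the run log are written to output_dir", {
  e <- local_experiment(seed = 8)
  out <- withr::local_tempdir()
  report <- run_workflow(synthetic_workflow_config(e, output_dir = out))
  for (g in names(report$per_grna_specific)) {
    f <- file.path(out, paste0(g, "_specific.csv"))
    expect_true(file.exists(f))
    expect_same_records(read_peaks_csv(f), report$per_grna_specific[[g]])
  }
  expect_same_records(read_peaks_csv(file.path(out, "common.csv")),
                      report$common)
  expect_true(file.exists(file.path(out, "run_log.txt")))
})

test_that("identical configs produce byte-identical outputs", {
  e <- local_experiment(seed = 19)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_workflow(synthetic_workflow_config(e, output_dir = out1))
  run_workflow(synthetic_workflow_config(e, output_dir = out2))
  for (f in list.files(out1, pattern = "\\.csv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("YAML configuration round-trips into an equivalent run", {
  e <- local_experiment(seed = 23)
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  tl <- e$target_locus
  writeLines(c(
    "positive_files:",
    sprintf("  %s: %s", names(e$positive_files), e$positive_files),
    "negative_files:",
    sprintf("  - %s", e$negative_files),
    sprintf("target_locus: {chrom: %s, start: %d, end: %d}",
            tl$chrom, tl$start, tl$end),
    "tag_percent: 5",
    "fold_enrichment_min: 10",
    "min_overlap_bp: 1"
  ), cfg_path)
  cfg <- read_workflow_config(cfg_path)
  expect_s3_class(cfg, "workflow_config")
  expect_equal(cfg$base, names(e$positive_files)[1])
  report_yaml <- run_workflow(cfg)
  report_direct <- run_workflow(synthetic_workflow_config(e))
  expect_same_records(report_yaml$common, report_direct$common)
})

test_that("config validation catches bad inputs", {
  expect_error(workflow_config(character(), "n.tab"),
               class = "enchipr_usage_error")
  expect_error(workflow_config(c(a = "p.tab"), character()),
               class = "enchipr_usage_error")
  expect_error(workflow_config(c(a = "p.tab"), "n.tab", tag_percent = 120,
                               target_locus = target_locus("chr1", 1, 10)),
               class = "enchipr_usage_error")
  expect_error(workflow_config(c(a = "p.tab"), "n.tab", tag_percent = 5),
               "target_locus", class = "enchipr_usage_error")
  expect_error(workflow_config(c(a = "p.tab"), "n.tab", tag_percent = NULL,
                               fold_enrichment_min = NULL, base = "zz"),
               class = "enchipr_usage_error")
})
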