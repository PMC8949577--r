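tagged <- function(tags, fe = rep(10, length(tags))) {
  n <- length(tags)
  peak_set(tibble::tibble(
    chrom = "chr1", start = seq(1, by = 1000, length.out = n),
    end = seq(500, by = 1000, length.out = n),
    tags = tags, fold_enrichment = fe
  ))
}

test_that("criterion strings parse under the documented grammar", {
  cr <- parse_criteria(c("tags>=50", "fe<=3.5", "fold_enrichment=10",
                         "tags >= 5%target"))
  expect_equal(cr[[1]]$field, "tags")
  expect_equal(cr[[1]]$comparator, ">=")
  expect_equal(cr[[1]]$threshold, 50)
  expect_false(cr[[1]]$relative_to_target)
  expect_equal(cr[[2]]$field, "fold_enrichment")
  expect_equal(cr[[2]]$comparator, "<=")
  expect_equal(cr[[3]]$comparator, "=")
  expect_true(cr[[4]]$relative_to_target)
  expect_error(parse_criteria("tags>50"), class = "enchipr_usage_error")
  expect_error(parse_criteria("fdr>=1"), class = "enchipr_usage_error")
  expect_error(parse_criteria("fe>=10%target"), class = "enchipr_usage_error")
})

test_that("empty criteria list is the identity", {
  p <- tagged(c(5, 10, 11))
  expect_equal(as_tibble(apply_filters(p, list())), as_tibble(p))
})

test_that("comparators are inclusive on their boundary", {
  p <- tagged(c(5, 10, 11))
  expect_equal(apply_filters(p, parse_criteria("tags>=10"))$tags, c(10, 11))
  expect_equal(apply_filters(p, parse_criteria("tags<=10"))$tags, c(5, 10))
  expect_equal(apply_filters(p, parse_criteria("tags=10"))$tags, 10)

  q <- tagged(c(1, 1), fe = c(9.9, 10))
  expect_equal(apply_filters(q, parse_criteria("fe>=10"))$fold_enrichment, 10)
})

test_that("equality on fold enrichment uses a small absolute tolerance", {
  q <- tagged(c(1, 1, 1), fe = c(10 + 5e-7, 10.001, 9.5))
  expect_equal(nrow(apply_filters(q, parse_criteria("fe=10"))), 1)
})

test_that("criteria combine by conjunction and never grow the survivor set", {
  set.seed(21)
  p <- random_peaks(200)
  c1 <- parse_criteria("tags>=100")
  c2 <- parse_criteria(c("tags>=100", "fe>=15"))
  s1 <- apply_filters(p, c1)
  s2 <- apply_filters(p, c2)
  expect_lte(nrow(s2), nrow(s1))
  expect_equal(as_tibble(s2),
               as_tibble(apply_filters(s1, parse_criteria("fe>=15"))))
  # idempotence
  expect_equal(as_tibble(apply_filters(s2, c2)), as_tibble(s2))
})

test_that("raising a >= threshold never grows the survivor set", {
  set.seed(22)
  p <- random_peaks(150)
  sizes <- vapply(seq(0, 300, by = 25), function(t) {
    nrow(apply_filters(p, list(filter_criterion("tags", ">=", t))))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  sizes_le <- vapply(seq(0, 300, by = 25), function(t) {
    nrow(apply_filters(p, list(filter_criterion("tags", "<=", t))))
  }, numeric(1))
  expect_true(all(diff(sizes_le) >= 0))
})

test_that("filtered survivors match per-record predicate recomputation", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_peaks(80)
    thr_t <- sample(0:250, 1)
    thr_f <- round(stats::runif(1, 0, 25), 1)
    got <- apply_filters(p, list(
      filter_criterion("tags", ">=", thr_t),
      filter_criterion("fold_enrichment", "<=", thr_f)
    ))
    want <- as_tibble(p)[p$tags >= thr_t & p$fold_enrichment <= thr_f, ]
    expect_equal(as_tibble(got), want)
  }
})

test_that("the relative threshold is percent of the target peak's tags", {
  p <- peak_set(tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 5000, 1000), end = c(1999, 5999, 1999),
    tags = c(1000, 80, 500), fold_enrichment = c(50, 12, 20)
  ))
  tl <- target_locus("chr1", 900, 1200)
  expect_equal(resolve_relative_threshold(p, tl, 5), 50)
  expect_equal(resolve_relative_threshold(p, tl, 0), 0)
  # not rounded to an integer
  expect_equal(resolve_relative_threshold(p, tl, 0.25), 2.5)
})

test_that("relative resolution on planted targets matches direct arithmetic", {
  set.seed(31)
  for (i in 1:25) {
    tags_t <- sample(200:2000, 1)
    p <- random_peaks(30, chroms = "chrA", max_pos = 40000)
    tab <- as_tibble(p)
    tab <- rbind(tab[, c("chrom", "start", "end", "tags", "fold_enrichment")],
                 tibble::tibble(chrom = "chrZ", start = 100000, end = 101000,
                                tags = tags_t, fold_enrichment = 60))
    p2 <- peak_set(tab)
    pct <- stats::runif(1, 0, 100)
    expect_equal(
      resolve_relative_threshold(p2, target_locus("chrZ", 100500, 100700),
                                 pct),
      pct * tags_t / 100,
      tolerance = 1e-12
    )
  }
})

test_that("the highest-tag overlapping peak is the referent, leftmost on ties", {
  p <- peak_set(tibble::tibble(
    chrom = "chr1", start = c(100, 300, 600), end = c(400, 700, 900),
    tags = c(200, 500, 500), fold_enrichment = c(10, 10, 10)
  ))
  tl <- target_locus("chr1", 100, 900)
  expect_equal(resolve_relative_threshold(p, tl, 10), 50)  # 10% of 500
  # leftmost of the two tied 500-tag peaks is the referent either way;
  # shrink the locus so only the rightmost tied peak overlaps
  expect_equal(resolve_relative_threshold(p, target_locus("chr1", 800, 900),
                                          10), 50)
})

test_that("a target locus with no overlapping peak is a resolution error", {
  p <- tagged(c(10, 20))
  expect_error(
    resolve_relative_threshold(p, target_locus("chr9", 1, 100), 5),
    "target locus", class = "enchipr_resolution_error"
  )
})

test_that("unresolved relative criteria cannot be applied directly", {
  p <- tagged(c(10, 20))
  rel <- filter_criterion("tags", ">=", 5, relative_to_target = TRUE)
  expect_error(apply_filters(p, list(rel)), "resolve",
               class = "enchipr_usage_error")
  # only the first peak [1, 500] (tags 10) overlaps the locus
  resolved <- resolve_criteria(list(rel), p, target_locus("chr1", 1, 500))
  expect_false(resolved[[1]]$relative_to_target)
  expect_equal(resolved[[1]]$threshold, 5 / 100 * 10)
})

test_that("criterion construction validates its domain", {
  expect_error(filter_criterion("fdr_percent", ">=", 1),
               class = "enchipr_usage_error")
  expect_error(filter_criterion("tags", ">", 1),
               class = "enchipr_usage_error")
  expect_error(filter_criterion("tags", ">=", -1),
               class = "enchipr_usage_error")
  expect_error(filter_criterion("fold_enrichment", ">=", 5,
                                relative_to_target = TRUE),
               class = "enchipr_usage_error")
  expect_error(filter_criterion("tags", ">=", 150,
                                relative_to_target = TRUE),
               class = "enchipr_usage_error")
})
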