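# Brute-force oracles, written independently of the package's interval
# machinery (explicit loops and per-base set arithmetic, no IRanges), plus a
# random peak-table generator for property-style tests.

random_peaks <- function(n, chroms = c("chrA", "chrB", "chrC"),
                         max_pos = 50000, max_width = 500) {
  if (n == 0) {
    return(peak_set(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      tags = numeric(), fold_enrichment = numeric()
    )))
  }
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  peak_set(tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + w - 1,
    tags = sample.int(300, n, replace = TRUE),
    fold_enrichment = round(stats::runif(n, 1, 30), 2)
  ))
}

# Per-base oracle for the pairwise overlap predicate: materialize both
# closed intervals and count shared positions.
oracle_overlap_pair <- function(a, b, min_bp = 1) {
  if (a$chrom != b$chrom) return(FALSE)
  shared <- length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
  shared >= min_bp
}

# Quadratic all-pairs membership: does base row i overlap >= 1 row of o?
oracle_hits_any <- function(base, o, min_bp = 1) {
  vapply(seq_len(nrow(base)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(o))) {
      if (o$chrom[j] == base$chrom[i] &&
          min(o$end[j], base$end[i]) - max(o$start[j], base$start[i]) + 1 >=
            min_bp) {
        hit <- TRUE
        break
      }
    }
    hit
  }, logical(1))
}

oracle_common <- function(base, others, min_bp = 1) {
  keep <- rep(TRUE, nrow(base))
  for (o in others) keep <- keep & oracle_hits_any(base, o, min_bp)
  as_tibble(base)[keep, ]
}

oracle_eliminate <- function(base, negatives, min_bp = 1) {
  hit <- rep(FALSE, nrow(base))
  for (o in negatives) hit <- hit | oracle_hits_any(base, o, min_bp)
  as_tibble(base)[!hit, ]
}

# Order-insensitive record comparison on the identity fields.
record_key <- function(x) {
  tab <- as_tibble(x)[c("chrom", "start", "end", "tags", "fold_enrichment")]
  tab <- tab[do.call(order, tab), ]
  rownames(tab) <- NULL
  tab
}

expect_same_records <- function(a, b) {
  expect_equal(record_key(a), record_key(b), ignore_attr = TRUE)
}
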