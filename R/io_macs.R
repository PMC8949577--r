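# MACS 1.x peaks.xls tab dialect: '#' comment lines, one header line, then
# one tab-separated row per peak:
#   chr  start  end  length  summit  tags  -10*log10(pvalue)  fold_enrichment  FDR(%)
# Coordinates are treated as 1-based closed intervals throughout the package;
# only BED output converts to 0-based half-open.

.macs_header_line <- paste(
  c("chr", "start", "end", "length", "summit", "tags",
    "-10*log10(pvalue)", "fold_enrichment", "FDR(%)"),
  collapse = "\t"
)

# Header tokens are matched by name after stripping case and punctuation;
# unknown extra columns are ignored.
.macs_name_map <- c(
  chr = "chrom", chrom = "chrom", chromosome = "chrom",
  start = "start", end = "end", length = "length", summit = "summit",
  tags = "tags", tag = "tags", tagnumber = "tags", pileup = "tags",
  "10log10pvalue" = "neg10log10_pvalue", log10pvalue = "neg10log10_pvalue",
  pvalue = "neg10log10_pvalue",
  foldenrichment = "fold_enrichment", fold = "fold_enrichment",
  fe = "fold_enrichment",
  fdr = "fdr_percent", fdrpercent = "fdr_percent"
)

normalize_header_token <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

is_numeric_token <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

#' Read a MACS peak tab file
#'
#' Parses a tab-delimited MACS peak list (the `peaks.xls` layout) into a
#' [peak_set()]. Lines starting with `#` are treated as comments: they are
#' not parsed into peaks but are retained as metadata on the returned set.
#' Blank lines are skipped. The header line is detected as the first
#' non-comment line whose second and third fields are not numeric; columns
#' are then mapped by header name, falling back to the standard MACS column
#' order when no header is present.
#'
#' @param path Path to a tab-delimited MACS peak file.
#' @param strict If `TRUE` (default), a malformed data line (non-numeric
#'   coordinate or wrong field count) is an error reporting the line number.
#'   If `FALSE`, malformed lines are skipped and counted in a single warning.
#' @param normalize_chrom If `TRUE`, chromosome names are normalized to the
#'   `chr`-prefixed form (`"1"` becomes `"chr1"`). Off by default: silent
#'   renaming can create false overlaps between files using different
#'   conventions.
#' @return A [peak_set()] with `source` set to `path`, rows sorted by
#'   `(chrom, start, end)`.
#' @seealso [write_macs_tab()], [write_peaks_csv()], [write_peaks_bed()]
#' @export
read_macs_peaks <- function(path, strict = TRUE, normalize_chrom = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "enchipr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  is_blank <- !nzchar(trimws(lines))
  is_comment <- startsWith(trimws(lines), "#")
  comments <- lines[is_comment]
  body_idx <- which(!is_blank & !is_comment)

  header <- NA_character_
  col_map <- NULL
  data_idx <- body_idx
  if (length(body_idx) > 0) {
    first_fields <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
    if (length(first_fields) >= 3 &&
        (!is_numeric_token(first_fields[2]) || !is_numeric_token(first_fields[3]))) {
      header <- lines[body_idx[1]]
      mapped <- .macs_name_map[normalize_header_token(first_fields)]
      col_map <- stats::setNames(seq_along(mapped)[!is.na(mapped)],
                                 mapped[!is.na(mapped)])
      data_idx <- body_idx[-1]
    }
  }
  if (is.null(col_map)) {
    # positional fallback: the standard MACS column order
    col_map <- stats::setNames(seq_along(.peak_cols), .peak_cols)
  }

  missing_req <- setdiff(.peak_cols_required, names(col_map))
  if (length(missing_req) > 0) {
    abort(
      sprintf("%s: missing required column(s): %s",
              path, paste(missing_req, collapse = ", ")),
      class = "enchipr_format_error"
    )
  }

  rows <- vector("list", length(data_idx))
  bad_lines <- integer()
  for (i in seq_along(data_idx)) {
    lineno <- data_idx[i]
    fields <- strsplit(lines[lineno], "\t", fixed = TRUE)[[1]]
    rec <- parse_macs_fields(fields, col_map)
    if (is.null(rec)) {
      if (strict) {
        abort(
          sprintf("%s: malformed data line %d: %s",
                  path, lineno, lines[lineno]),
          class = "enchipr_parse_error"
        )
      }
      bad_lines <- c(bad_lines, lineno)
    } else {
      rows[[i]] <- rec
    }
  }
  if (length(bad_lines) > 0) {
    warn(sprintf("%s: skipped %d malformed line(s): %s",
                 path, length(bad_lines),
                 paste(utils::head(bad_lines, 5), collapse = ", ")))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]

  tab <- if (length(rows) == 0) {
    tibble(
      chrom = character(), start = numeric(), end = numeric(),
      length = numeric(), summit = numeric(), tags = numeric(),
      neg10log10_pvalue = numeric(), fold_enrichment = numeric(),
      fdr_percent = numeric()
    )
  } else {
    dplyr::bind_rows(rows)
  }
  if (normalize_chrom && nrow(tab) > 0) {
    no_prefix <- !startsWith(tab$chrom, "chr")
    tab$chrom[no_prefix] <- paste0("chr", tab$chrom[no_prefix])
  }
  peak_set(tab, source = path, comments = comments, header = header)
}

parse_macs_fields <- function(fields, col_map) {
  need <- col_map[intersect(.peak_cols_required, names(col_map))]
  if (length(fields) < max(need)) return(NULL)
  get_field <- function(col) {
    if (!col %in% names(col_map)) return(NA_real_)
    idx <- col_map[[col]]
    if (is.na(idx) || idx > length(fields)) return(NA_real_)
    val <- trimws(fields[idx])
    if (!nzchar(val) || val == "NA") return(NA_real_)
    suppressWarnings(as.numeric(val))
  }
  start <- get_field("start"); end <- get_field("end")
  tags <- get_field("tags"); fe <- get_field("fold_enrichment")
  if (is.na(start) || is.na(end) || is.na(tags) || is.na(fe)) return(NULL)
  if (start < 1 || end < start || tags < 0 || fe <= 0) return(NULL)
  tibble(
    chrom = trimws(fields[col_map[["chrom"]]]),
    start = start, end = end,
    length = get_field("length"), summit = get_field("summit"), tags = tags,
    neg10log10_pvalue = get_field("neg10log10_pvalue"),
    fold_enrichment = fe, fdr_percent = get_field("fdr_percent")
  )
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

#' Write a peak set as a MACS-style tab file
#'
#' Writes the standard MACS header line and one tab-separated row per peak.
#' Comment lines preserved on the set (or supplied via `comments`) are
#' written first. Reading the file back with [read_macs_peaks()] reproduces
#' the peak table exactly.
#'
#' @param peaks A [peak_set()] (or plain peak table).
#' @param path Output path.
#' @param comments Comment lines to write (without requiring the leading
#'   `#`, which is added when absent). Defaults to the comments preserved on
#'   `peaks`.
#' @return `path`, invisibly.
#' @export
write_macs_tab <- function(peaks, path, comments = peak_comments(peaks)) {
  if (is.null(comments)) comments <- character()
  if (length(comments) > 0) {
    no_hash <- !startsWith(comments, "#")
    comments[no_hash] <- paste0("# ", comments[no_hash])
  }
  body <- if (nrow(peaks) == 0) character() else {
    paste(
      peaks$chrom,
      fmt_num(peaks$start), fmt_num(peaks$end), fmt_num(peaks$length),
      fmt_num(peaks$summit), fmt_num(peaks$tags),
      fmt_num(peaks$neg10log10_pvalue), fmt_num(peaks$fold_enrichment),
      fmt_num(peaks$fdr_percent),
      sep = "\t"
    )
  }
  write_lines_checked(c(comments, .macs_header_line, body), path)
  invisible(path)
}

#' Export a peak set as CSV
#'
#' RFC 4180 CSV with one header row (the canonical column names) and one row
#' per peak in canonical order; numbers are rendered without locale
#' formatting. This is the export format intended for downstream tools.
#'
#' @param peaks A [peak_set()] or result of the peak algebra.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  tab <- as_tibble(peaks)[.peak_cols]
  lines <- c(
    paste(.peak_cols, collapse = ","),
    if (nrow(tab) > 0) {
      paste(
        tab$chrom,
        fmt_num(tab$start), fmt_num(tab$end), fmt_num(tab$length),
        fmt_num(tab$summit), fmt_num(tab$tags),
        fmt_num(tab$neg10log10_pvalue), fmt_num(tab$fold_enrichment),
        fmt_num(tab$fdr_percent),
        sep = ","
      )
    }
  )
  write_lines_checked(lines, path)
  invisible(path)
}

#' Read back a CSV written by [write_peaks_csv()]
#'
#' @param path Path to the CSV file.
#' @return A [peak_set()].
#' @export
read_peaks_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "enchipr_io_error")
  }
  tab <- utils::read.csv(path, colClasses = c(chrom = "character"))
  peak_set(tab, source = path)
}

#' Export a peak set as BED
#'
#' Writes BED3+2: chromosome, 0-based half-open start (`start - 1`), end,
#' a name of the form `source:index`, and the tag count as score. The
#' package's internal 1-based closed interval `[start, end]` maps to the BED
#' half-open interval `[start - 1, end)`, which covers the same bases.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  src <- peak_source(peaks)
  if (is.null(src) || is.na(src)) src <- "peaks"
  lines <- if (nrow(peaks) == 0) character() else {
    paste(
      peaks$chrom,
      fmt_num(peaks$start - 1), fmt_num(peaks$end),
      paste0(basename(src), ":", seq_len(nrow(peaks))),
      fmt_num(peaks$tags),
      sep = "\t"
    )
  }
  write_lines_checked(lines, path)
  invisible(path)
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort(sprintf("cannot write to: %s", path), class = "enchipr_io_error")
  }
}
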