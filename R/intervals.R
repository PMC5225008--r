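#' Build a tibble of genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends, the convention used for
#' every coordinate inside this package (BED input/output converts at the file
#' boundary). Width is therefore `end - start + 1`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive; `end >= start >= 1`.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unstranded, the default).
#' @param ... Further columns recycled into the tibble (e.g. `name`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, plus any
#'   extra columns.
#' @examples
#' gi("chr1", 18163342, 18163563)
#' @export
gi <- function(chrom, start, end, strand = "*", ...) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    ...
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    abort(sprintf("%s coordinates must not be NA", what))
  }
  if (any(x$start < 1L)) {
    abort(sprintf("%s start must be >= 1 (1-based inclusive coordinates)", what))
  }
  bad <- which(x$end < x$start)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s end < start at row %d (%s:%d-%d)", what, bad[1],
      x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

#' Interval width in base pairs
#'
#' @param x A data frame with `start` and `end` columns (1-based inclusive),
#'   e.g. from [gi()] or [parse_interval()].
#' @return Integer vector of widths, `end - start + 1`.
#' @examples
#' interval_width(parse_interval("chr1:18163342-18163563")) # 222
#' @export
interval_width <- function(x) {
  validate_intervals(x)
  as.integer(x$end - x$start + 1L)
}

#' Pairwise overlap fraction between two interval sets
#'
#' Computes, row by row, the fraction of `a` covered by `b` (`mode = "of_a"`)
#' or the reciprocal overlap `min(shared/width(a), shared/width(b))`
#' (`mode = "reciprocal"`). Intervals on different chromosomes share nothing.
#' This is the primitive behind the "overlapping by >= 80% with common SVs"
#' exclusion filter.
#'
#' @param a,b Interval tibbles of equal length (or length 1, recycled).
#' @param mode `"of_a"` or `"reciprocal"`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, mode = c("of_a", "reciprocal")) {
  mode <- match.arg(mode)
  validate_intervals(a)
  validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), ]
  stopifnot(nrow(a) == nrow(b))
  shared <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start) + 1L)
  shared[a$chrom != b$chrom] <- 0L
  wa <- a$end - a$start + 1L
  wb <- b$end - b$start + 1L
  if (mode == "of_a") shared / wa else pmin(shared / wa, shared / wb)
}

#' Parse coordinate text like "chr1:18163342-18163563"
#'
#' Accepts both a plain hyphen and the typographic en dash as the separator.
#' Single positions ("chr1:55") are read as 1 bp intervals.
#'
#' @param text Character vector of `chrom:start-end` strings.
#' @return An interval tibble (see [gi()]).
#' @export
parse_interval <- function(text) {
  m <- stringr::str_match(
    text,
    "^\\s*([^:\\s]+):([0-9,]+)(?:\\s*[-–]\\s*([0-9,]+))?\\s*$"
  )
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(sprintf("cannot parse interval text: '%s'", text[bad[1]]))
  }
  start <- as.integer(gsub(",", "", m[, 3], fixed = TRUE))
  end <- as.integer(gsub(",", "", m[, 4], fixed = TRUE))
  end[is.na(end)] <- start[is.na(end)]
  gi(m[, 2], start, end)
}

#' Format intervals as coordinate text
#'
#' @param x Interval tibble.
#' @param dash Separator; the en dash mirrors printed junction tables, set
#'   `dash = "-"` for plain ASCII.
#' @return Character vector like `"chr1:18163342–18163563"`.
#' @export
format_interval <- function(x, dash = "–") {
  validate_intervals(x)
  sprintf("%s:%d%s%d", x$chrom, x$start, dash, x$end)
}
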