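# Coordinate conventions: BED-style 0-based half-open [start, end) everywhere
# internally; 1-based inputs (GTF, MACS2 xls) are converted at read time.
# Strand is carried but never consulted by overlap tests.

#' Validate an interval data frame
#'
#' Checks the minimal interval contract used throughout the package:
#' a `chrom` character column and integer-ish `start`/`end` columns with
#' `start >= 0` and `end > start` (0-based half-open).
#'
#' @param x A data frame with `chrom`, `start`, `end` columns.
#' @param what Label used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, what = "intervals") {
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing_cols) > 0) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) {
      stop(what, ": negative start at row ",
           which(x$start < 0)[1], call. = FALSE)
    }
    bad <- which(x$end <= x$start)
    if (length(bad) > 0) {
      stop(what, ": end <= start at row ", bad[1],
           " (", x$chrom[bad[1]], ":", x$start[bad[1]], "-", x$end[bad[1]], ")",
           call. = FALSE)
    }
  }
  invisible(x)
}

# Internal: interval tibble -> GRanges (0-based half-open -> 1-based closed).
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- as.character(x$strand)
    s[is.na(s) | !s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Overlap length of interval pairs
#'
#' Vectorised over rows: returns, for each pair, the number of shared base
#' pairs, `max(0, min(end) - max(start))` when the chromosomes match and 0
#' otherwise. Strand is ignored. Abutting half-open intervals share 0 bp.
#'
#' @param a,b Data frames of intervals (`chrom`, `start`, `end`), recycled
#'   to a common length if one has a single row.
#' @return An integer vector of overlap sizes in bp.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' overlap_length(a, b)  # 50
#' @export
overlap_length <- function(a, b) {
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L) b <- b[rep(1L, n), ]
  if (nrow(a) != nrow(b)) {
    stop("a and b must have the same number of rows (or one row)",
         call. = FALSE)
  }
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  as.integer(ov)
}

#' Find all overlapping query/subject interval pairs
#'
#' Every (query, subject) pair sharing at least `min_bp` base pairs, on the
#' same chromosome, strand-agnostic. This is the matching engine used to
#' associate repeat elements with peak coordinates.
#'
#' @param query,subject Interval data frames (`chrom`, `start`, `end`).
#' @param min_bp Minimum overlap in bp (default 1, i.e. any overlap).
#' @return A tibble with columns `query_index`, `subject_index`,
#'   `overlap_bp`, sorted by query then subject index.
#' @export
find_overlaps <- function(query, subject, min_bp = 1L) {
  query <- validate_intervals(query, "query")
  subject <- validate_intervals(subject, "subject")
  stopifnot(min_bp >= 1)
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(tibble::tibble(query_index = integer(), subject_index = integer(),
                          overlap_bp = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges(query), as_granges(subject),
    minoverlap = as.integer(min_bp), ignore.strand = TRUE
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ord <- order(qi, si)
  qi <- qi[ord]
  si <- si[ord]
  tibble::tibble(
    query_index = qi,
    subject_index = si,
    overlap_bp = overlap_length(query[qi, c("chrom", "start", "end")],
                                subject[si, c("chrom", "start", "end")])
  )
}

#' Total base pairs covered by a set of intervals
#'
#' Merges overlapping intervals per chromosome before summing, so each base
#' is counted once; this is the "total genomic length" used for repeat
#' coverage ratios. Optionally clips to a window first.
#'
#' @param intervals Interval data frame.
#' @param within Optional single-row interval data frame to clip to.
#' @return Total covered bp (numeric scalar).
#' @export
coverage_bp <- function(intervals, within = NULL) {
  intervals <- validate_intervals(intervals)
  if (nrow(intervals) == 0L) return(0)
  gr <- as_granges(intervals)
  if (!is.null(within)) {
    within <- validate_intervals(within, "within")
    gr <- GenomicRanges::intersect(
      gr, as_granges(within), ignore.strand = TRUE
    )
  }
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(red)))
}
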