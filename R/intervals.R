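#' Construct a normalized genomic interval set
#'
#' Interval sets are the common currency of the screen: chain gaps, conserved
#' elements, deletion masks and final candidates are all sets of sorted,
#' disjoint intervals on named reference sequences. They are represented as
#' unstranded [GenomicRanges::GRanges] objects (1-based, closed ends, the
#' Bioconductor convention); BED and chain files, which are 0-based half-open
#' on disk, are converted at the I/O boundary.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors of interval ends. With the default
#'   `zero_based = FALSE` these are 1-based closed coordinates; with
#'   `zero_based = TRUE` they are 0-based half-open (BED convention).
#' @param zero_based interpret `start`/`end` as 0-based half-open.
#' @return A `GRanges` sorted with overlapping or abutting intervals merged.
#' @examples
#' interval_set("chr1", c(0, 30), c(10, 40), zero_based = TRUE)
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), zero_based = FALSE) {
  if (zero_based) start <- start + 1
  if (length(start) && any(end < start))
    stop("interval end must not precede start")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
  normalize_intervals(gr)
}

#' Normalize an interval set
#'
#' Sorts and merges overlapping or abutting intervals so that the result is a
#' set of disjoint intervals, the invariant all set operations assume.
#'
#' @param gr a `GRanges`.
#' @return A normalized `GRanges`.
#' @export
normalize_intervals <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), ignore.strand = TRUE)
}

#' Merge intervals separated by at most `distance` bases
#'
#' Implements the screen's "within 20 bp of each other" merging rule. The
#' separation between two intervals is the number of bases strictly between
#' them; a separation equal to `distance` merges (inclusive reading of
#' "within").
#'
#' @param gr a `GRanges` interval set.
#' @param distance maximum separation, in bases, that still merges (>= 0).
#' @return A merged, normalized `GRanges`. Idempotent, and coverage is
#'   non-decreasing in `distance`.
#' @examples
#' gr <- interval_set("chr1", c(0, 30), c(10, 40), zero_based = TRUE)
#' merge_within(gr, 20)  # separation of exactly 20 merges
#' @export
merge_within <- function(gr, distance) {
  stopifnot(is.numeric(distance), length(distance) == 1L, distance >= 0)
  GenomicRanges::reduce(gr, min.gapwidth = distance + 1L, ignore.strand = TRUE)
}

#' Interval set algebra
#'
#' Exact base-level set operations used throughout the screen, e.g.
#' subtracting masked chain gaps or intersecting target deletions with
#' conserved regions. Thin wrappers over the `GenomicRanges` set operations,
#' ignoring strand.
#'
#' @param a,b `GRanges` interval sets sharing a sequence namespace.
#' @return A normalized `GRanges`.
#' @name interval-algebra
NULL

#' @rdname interval-algebra
#' @export
interval_intersect <- function(a, b) {
  if (!length(a) || !length(b)) return(GenomicRanges::GRanges())
  hits <- suppressWarnings(GenomicRanges::findOverlaps(a, b,
                                                       ignore.strand = TRUE))
  if (!length(hits)) return(GenomicRanges::GRanges())
  pieces <- GenomicRanges::pintersect(
    GenomicRanges::granges(a)[S4Vectors::queryHits(hits)],
    GenomicRanges::granges(b)[S4Vectors::subjectHits(hits)])
  normalize_intervals(pieces)
}

#' @rdname interval-algebra
#' @export
interval_subtract <- function(a, b) {
  if (!length(a) || !length(b)) return(normalize_intervals(a))
  a <- normalize_intervals(a)
  b <- normalize_intervals(b)
  chrom_a <- as.character(GenomicRanges::seqnames(a))
  chrom_b <- as.character(GenomicRanges::seqnames(b))
  per <- lapply(unique(chrom_a), function(ch) {
    ra <- GenomicRanges::ranges(a)[chrom_a == ch]
    rb <- GenomicRanges::ranges(b)[chrom_b == ch]
    res <- if (length(rb)) IRanges::setdiff(ra, rb) else ra
    GenomicRanges::GRanges(rep(ch, length(res)), res)
  })
  normalize_intervals(suppressWarnings(do.call(c, per)))
}

#' @rdname interval-algebra
#' @export
interval_union <- function(a, b) {
  normalize_intervals(suppressWarnings(
    c(GenomicRanges::granges(a), GenomicRanges::granges(b))))
}

#' Total bases covered by an interval set
#'
#' @param gr a `GRanges` interval set.
#' @return Number of covered bases (after normalization).
#' @export
total_coverage <- function(gr) {
  sum(as.numeric(GenomicRanges::width(normalize_intervals(gr))))
}
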