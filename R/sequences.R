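#' Find assembly gaps (N-runs) in a nucleotide sequence
#'
#' Draft assemblies represent undetermined sequence as runs of N. Chain gaps
#' that fall close to such runs are excluded by the screen as likely assembly
#' artifacts rather than biological deletions. An assembly gap is a maximal
#' N-run of length >= `min_run`; the default of 6 encodes "longer than" a run
#' of five Ns. Detection is case-insensitive for N; all other characters must
#' be nucleotides (ACGT, either case).
#'
#' @param seq a single sequence: character scalar, [Biostrings::DNAString],
#'   or a length-one [Biostrings::DNAStringSet].
#' @param min_run minimum N-run length reported (default 6).
#' @return An [IRanges::IRanges] of maximal N-runs (1-based, sorted,
#'   disjoint). Total width equals the number of N bases lying in runs of at
#'   least `min_run`.
#' @examples
#' find_assembly_gaps(paste0("ACGT", strrep("N", 6), "ACGT"))
#' @export
find_assembly_gaps <- function(seq, min_run = 6L) {
  stopifnot(min_run >= 1L)
  s <- as_sequence_string(seq)
  if (nchar(s) == 0L) return(IRanges::IRanges())
  r <- charToRaw(chartr("acgtn", "ACGTN", s))
  ok <- r == charToRaw("A") | r == charToRaw("C") | r == charToRaw("G") |
    r == charToRaw("T") | r == charToRaw("N")
  if (!all(ok)) {
    bad <- rawToChar(r[which(!ok)[1L]])
    stop("non-nucleotide character in sequence: '", bad, "'")
  }
  is_n <- r == charToRaw("N")
  runs <- rle(as.vector(is_n))
  ends <- cumsum(runs$lengths)
  keep <- runs$values & runs$lengths >= min_run
  IRanges::IRanges(start = (ends - runs$lengths + 1L)[keep], end = ends[keep])
}

#' Assembly gaps across a multi-record FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet].
#' @param min_run minimum N-run length (see [find_assembly_gaps()]).
#' @return A `GRanges` of N-runs keyed by record name.
#' @export
assembly_gap_ranges <- function(seqs, min_run = 6L) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  per <- lapply(seq_along(seqs), function(i) {
    ir <- find_assembly_gaps(as.character(seqs[[i]]), min_run)
    GenomicRanges::GRanges(names(seqs)[i], ir)
  })
  out <- do.call(c, per)
  GenomicRanges::sort(out)
}

#' Count non-N bases of an assembly
#'
#' The conservation quota (5 percent of the reference) is measured against the
#' alignable, i.e. non-N, portion of the reference assembly.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or single sequence).
#' @return Total count of non-N bases.
#' @export
non_n_bases <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(as_sequence_string(seqs))
  freq <- Biostrings::alphabetFrequency(seqs)
  sum(as.numeric(Biostrings::width(seqs))) - sum(as.numeric(freq[, "N"]))
}

as_sequence_string <- function(seq) {
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(as.character(seq[[1L]]))
  }
  if (methods::is(seq, "DNAString")) return(as.character(seq))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq
}
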