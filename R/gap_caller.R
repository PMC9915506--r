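#' Gap caller configuration
#'
#' @param assembly_gap_min_run minimum N-run length treated as an assembly
#'   gap (default 6, i.e. runs longer than five Ns).
#' @param proximity maximum distance, in query bases, between a chain gap and
#'   an assembly gap for the chain gap to be excluded (default 100,
#'   inclusive).
#' @param merge_distance chain gaps within this many bases of each other are
#'   merged, per chain (default 20).
#' @return A list of class `"gap_caller_config"`.
#' @export
gap_caller_config <- function(assembly_gap_min_run = 6L, proximity = 100L,
                              merge_distance = 20L) {
  stopifnot(assembly_gap_min_run >= 0, proximity >= 0, merge_distance >= 0)
  structure(list(assembly_gap_min_run = assembly_gap_min_run,
                 proximity = proximity, merge_distance = merge_distance),
            class = "gap_caller_config")
}

#' Raw chain gaps of one chain
#'
#' Every inter-block separator with `dt > 0` marks reference bases predicted
#' to be missing from the aligned query genome: a *single-sided* gap when the
#' query side is contiguous (`dq = 0`) and a *double-sided* gap when the query
#' also carries unaligned sequence (`dq > 0`). The corresponding query-side
#' context is reported on the query plus strand (a zero-length point for
#' single-sided gaps) so it can be compared with assembly N-runs.
#'
#' @param chain a [chain()] object.
#' @return A `GRanges` on the reference (1-based) with metadata columns
#'   `side` ("single"/"double"), `q_start`, `q_end` (0-based half-open,
#'   query plus strand) and `chain_id`.
#' @export
raw_gaps <- function(chain) {
  bc <- chain_block_coords(chain)
  n <- nrow(bc)
  sep <- which(bc$dt > 0 & seq_len(n) < n)
  gr <- GenomicRanges::GRanges(rep(chain$t_name, length(sep)), IRanges::IRanges(
    start = bc$t_start[sep] + bc$size[sep] + 1,
    end = bc$t_start[sep] + bc$size[sep] + bc$dt[sep]))
  if (length(sep)) {
    qs <- bc$q_start[sep] + bc$size[sep]
    qe <- qs + bc$dq[sep]
    qp <- t(mapply(function(a, b) query_interval_on_plus(chain, a, b), qs, qe))
    gr$side <- ifelse(bc$dq[sep] > 0, "double", "single")
    gr$q_start <- qp[, 1L]
    gr$q_end <- qp[, 2L]
  } else {
    gr$side <- character(0)
    gr$q_start <- numeric(0)
    gr$q_end <- numeric(0)
  }
  gr$chain_id <- rep(chain$id, length(gr))
  gr
}

#' Drop chain gaps near assembly gaps in the query genome
#'
#' A chain gap whose query context lies within `proximity` bases (inclusive)
#' of an N-run in the query assembly is excluded: missing alignment next to
#' undetermined sequence is more likely an assembly artifact than a real
#' deletion. Distance is measured from the edges of the query context (for
#' double-sided gaps, the more conservative choice).
#'
#' @param gaps output of [raw_gaps()].
#' @param query_n_runs [IRanges::IRanges] of N-runs on the query plus strand
#'   (1-based, from [find_assembly_gaps()]).
#' @param config a [gap_caller_config()].
#' @return The retained gaps, unchanged.
#' @export
mask_by_assembly_gaps <- function(gaps, query_n_runs,
                                  config = gap_caller_config()) {
  if (!length(gaps) || !length(query_n_runs)) return(gaps)
  prox <- config$proximity
  run_s0 <- IRanges::start(query_n_runs) - 1  # 0-based half-open
  run_e0 <- IRanges::end(query_n_runs)
  drop <- vapply(seq_along(gaps), function(i) {
    q0 <- gaps$q_start[i]
    q1 <- gaps$q_end[i]
    any(run_s0 <= q1 + prox & run_e0 >= q0 - prox)
  }, logical(1))
  gaps[!drop]
}

#' Per-species chain gap set
#'
#' For each orthology-accepted chain of one species: record raw gaps, exclude
#' those near query assembly gaps, and merge gaps within
#' `config$merge_distance` of each other. Merging happens strictly per chain;
#' the per-chain results are then unioned into one reference interval set.
#' Both single- and double-sided gaps enter identically after masking.
#'
#' @param chains list of [chain()] objects for one species.
#' @param query_n_runs named list or `GRanges`: N-runs per query sequence on
#'   the plus strand. A named list maps query sequence name ->
#'   [IRanges::IRanges]; a `GRanges` is split by seqname.
#' @param config a [gap_caller_config()].
#' @return A normalized `GRanges` of missing reference sequence.
#' @export
species_gap_set <- function(chains, query_n_runs,
                            config = gap_caller_config()) {
  if (methods::is(query_n_runs, "GRanges")) {
    query_n_runs <- lapply(
      split(query_n_runs, GenomicRanges::seqnames(query_n_runs)),
      GenomicRanges::ranges)
  }
  per_chain <- lapply(chains, function(ch) {
    g <- raw_gaps(ch)
    runs <- query_n_runs[[ch$q_name]]
    if (is.null(runs)) runs <- IRanges::IRanges()
    g <- mask_by_assembly_gaps(g, runs, config)
    merge_within(GenomicRanges::granges(g), config$merge_distance)
  })
  out <- Reduce(interval_union, per_chain, GenomicRanges::GRanges())
  normalize_intervals(out)
}
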