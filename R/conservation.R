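#' Conservation scoring configuration
#'
#' @param window_sizes sliding window sizes in bases (default 10, 25, 50,
#'   100).
#' @param step offset between consecutive windows within a block (default 1,
#'   maximally sensitive; configurable for large genomes).
#' @param coverage_fraction fraction of the reference the selected windows
#'   must cover, merged and flattened (default 0.05).
#' @param merge_distance selected windows within this many bases merge into
#'   one conserved element (default 20).
#' @return A list of class `"conservation_config"`.
#' @export
conservation_config <- function(window_sizes = c(10L, 25L, 50L, 100L),
                                step = 1L, coverage_fraction = 0.05,
                                merge_distance = 20L) {
  stopifnot(all(window_sizes > 0), step >= 1,
            coverage_fraction > 0, coverage_fraction <= 1, merge_distance >= 0)
  structure(list(window_sizes = as.integer(window_sizes), step = as.integer(step),
                 coverage_fraction = coverage_fraction,
                 merge_distance = merge_distance),
            class = "conservation_config")
}

#' Sliding-window percent identity along a chain's alignment blocks
#'
#' For every ungapped block and every window size no larger than the block,
#' windows are laid at offsets 0, step, 2*step, ... inside the block (windows
#' never span a block boundary). Identity is the fraction of exactly matching
#' base pairs (case-insensitive; N never matches, on either side) over the
#' window size; gap columns cannot occur because blocks are gapless.
#'
#' @param chain a [chain()] object.
#' @param ref_seq reference chromosome sequence (character or
#'   [Biostrings::DNAString]); must cover the chain's reference span.
#' @param query_seq query sequence as stored in the assembly (plus strand);
#'   reverse-complemented internally for minus-strand chains.
#' @param config a [conservation_config()].
#' @return data.frame with columns `chrom`, `start` (1-based reference),
#'   `width`, `matches`, `identity`.
#' @export
window_identity <- function(chain, ref_seq, query_seq,
                            config = conservation_config()) {
  ref <- as_sequence_string(ref_seq)
  qry <- as_sequence_string(query_seq)
  if (nchar(ref) < chain$t_end)
    stop("reference sequence shorter than chain coordinates")
  if (nchar(qry) != chain$q_size)
    stop("query sequence length does not match chain q_size")
  if (chain$q_strand == "-")
    qry <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(qry)))
  rraw <- charToRaw(toupper(ref))
  qraw <- charToRaw(toupper(qry))
  nbyte <- charToRaw("N")
  bc <- chain_block_coords(chain)
  starts <- list(); widths <- list(); matches <- list()
  k <- 0L
  for (i in seq_len(nrow(bc))) {
    len <- bc$size[i]
    t0 <- bc$t_start[i]
    q0 <- bc$q_start[i]
    rb <- rraw[(t0 + 1):(t0 + len)]
    qb <- qraw[(q0 + 1):(q0 + len)]
    m <- (rb == qb) & (rb != nbyte) & (qb != nbyte)
    cs <- c(0, cumsum(m))
    for (w in config$window_sizes) {
      if (w > len) next
      off <- seq.int(0L, len - w, by = config$step)
      k <- k + 1L
      starts[[k]] <- t0 + off + 1
      widths[[k]] <- rep.int(w, length(off))
      matches[[k]] <- cs[off + w + 1L] - cs[off + 1L]
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = integer(), width = integer(),
                      matches = integer(), identity = numeric()))
  start <- unlist(starts, use.names = FALSE)
  width <- unlist(widths, use.names = FALSE)
  mt <- unlist(matches, use.names = FALSE)
  data.frame(chrom = rep.int(chain$t_name, length(start)), start = start,
             width = width, matches = mt, identity = mt / width,
             stringsAsFactors = FALSE)
}

#' Select per-species conserved elements by coverage quota
#'
#' All windows of one species (all sizes pooled into a single ranked list)
#' are sorted by identity, descending. Windows are accumulated in rank order
#' until their merged, flattened coverage first reaches
#' `coverage_fraction * reference_total_bases`; every remaining window whose
#' identity ties that stopping window is also included, which makes the
#' result independent of how ties are ordered. If the total supply never
#' reaches the quota, all windows are selected. Selected windows are merged
#' within `merge_distance` into conserved elements.
#'
#' Internally the accumulation is computed by thresholding on identity
#' levels: because the tie cohort is always included whole, the selected set
#' equals all windows with identity at or above the stopping level, found by
#' binary search over the distinct identity values.
#'
#' @param windows data.frame from [window_identity()] (possibly pooled over
#'   several chains of one species).
#' @param reference_total_bases the quota basis; by default the screen uses
#'   the non-N length of the reference assembly (see [non_n_bases()]).
#' @param config a [conservation_config()].
#' @return A normalized `GRanges` of conserved elements.
#' @export
select_conserved_elements <- function(windows, reference_total_bases,
                                      config = conservation_config()) {
  if (!nrow(windows)) return(GenomicRanges::GRanges())
  quota <- config$coverage_fraction * reference_total_bases
  chrom <- factor(windows$chrom)
  ## offset each chromosome into a disjoint coordinate block so merged
  ## coverage reduces to one linear sweep over start-sorted windows
  if (nlevels(chrom) == 1L) {
    offset <- stats::setNames(0, levels(chrom))
    pos <- windows$start
  } else {
    span <- tapply(windows$start + windows$width, chrom, max)
    offset <- stats::setNames(c(0, cumsum(as.numeric(span)))[seq_along(span)],
                              names(span))
    pos <- windows$start + offset[as.integer(chrom)]
  }
  ord <- order(pos)
  s_all <- pos[ord]
  e_all <- s_all + windows$width[ord]  # 0-based-exclusive ends in offset space
  id_all <- windows$identity[ord]
  cov_at <- function(sel) {  # merged length of start-sorted intervals
    s <- s_all[sel]
    e <- e_all[sel]
    if (!length(s)) return(0)
    m <- cummax(c(0, e[-length(e)]))
    sum(pmax(0, e - pmax(s, m)))
  }
  levels_desc <- sort(unique(windows$identity), decreasing = TRUE)
  if (cov_at(id_all >= levels_desc[1L]) >= quota) {
    cut <- levels_desc[1L]  # top identity level alone already meets the quota
  } else if (cov_at(rep(TRUE, nrow(windows))) < quota) {
    cut <- levels_desc[length(levels_desc)]
  } else {
    lo <- 1L; hi <- length(levels_desc)
    while (lo < hi) {  # smallest j with coverage(identity >= level j) >= quota
      mid <- (lo + hi) %/% 2L
      if (cov_at(id_all >= levels_desc[mid]) >= quota) hi <- mid
      else lo <- mid + 1L
    }
    cut <- levels_desc[lo]
  }
  ## flatten the selected, start-sorted windows in one sweep: a new merged
  ## run begins wherever a window starts beyond every previous end
  sel <- id_all >= cut
  s <- s_all[sel]
  e <- cummax(e_all[sel])
  new_run <- s > c(0, e[-length(e)])
  run_start <- s[new_run]
  run_end <- e[c(which(new_run)[-1L] - 1L, length(e))]
  chr_idx <- findInterval(run_start, c(offset, Inf)[-1L]) + 1L
  gr <- GenomicRanges::GRanges(
    levels(chrom)[chr_idx],
    IRanges::IRanges(start = run_start - offset[chr_idx],
                     end = run_end - offset[chr_idx] - 1L))
  merge_within(gr, config$merge_distance)
}

#' Conserved elements of one species from its orthologous chains
#'
#' Convenience wrapper: compute window identities for each chain, pool them,
#' and apply the quota selection.
#'
#' @param chains list of [chain()] objects of one species.
#' @param ref_seqs named [Biostrings::DNAStringSet] of reference chromosomes.
#' @param query_seqs named [Biostrings::DNAStringSet] of the species' query
#'   sequences (as stored, plus strand).
#' @param reference_total_bases quota basis (see
#'   [select_conserved_elements()]).
#' @param config a [conservation_config()].
#' @return A normalized `GRanges` of conserved elements.
#' @export
species_conserved_elements <- function(chains, ref_seqs, query_seqs,
                                       reference_total_bases,
                                       config = conservation_config()) {
  win <- lapply(chains, function(ch)
    window_identity(ch, ref_seqs[[ch$t_name]], query_seqs[[ch$q_name]], config))
  win <- do.call(rbind, win)
  if (is.null(win)) return(GenomicRanges::GRanges())
  select_conserved_elements(win, reference_total_bases, config)
}
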