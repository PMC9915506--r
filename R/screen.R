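#' Screen configuration
#'
#' Thresholds of the gene-centric genotype-phenotype scan. Defaults encode
#' the study conditions: a gene is eligible when orthology calls exist for at
#' least 17 trait-complete outgroups and 5 trait-reduced targets; the scanned
#' window spans 200 kb on both sides of the canonical TSS (400,001 bp total
#' when unclipped); a base counts as a target deletion when at least 2/3 of
#' each screened target clade shows a chain gap there; candidate pieces must
#' intersect conserved regions (supported by at least 17 outgroups) by at
#' least 20 bp, merge within 20 bp, reach 50 bp, and show a chain gap in at
#' most one scorable outgroup.
#'
#' @param min_outgroup_mappings minimum outgroup orthology calls per gene.
#' @param min_target_mappings minimum target orthology calls per gene.
#' @param flank half-width of the scan window around the TSS, in bases.
#' @param clade_fraction fraction of each screened clade that must carry the
#'   deletion at a base.
#' @param min_conserved_support minimum count of outgroups whose conserved
#'   elements cover a base (the reference itself is never counted).
#' @param min_intersection minimum size of a raw deletion-conservation
#'   intersection, in bases.
#' @param merge_distance raw candidates within this distance merge.
#' @param min_candidate minimum final candidate length, in bases.
#' @param max_outgroup_violations maximum number of scorable outgroups whose
#'   chain gap may overlap a candidate.
#' @param screened_clades character vector of clade ids that gate candidacy;
#'   `NULL` (default) screens every clade with at least two mapped members,
#'   so single-representative clades are reported but never required.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(min_outgroup_mappings = 17L, min_target_mappings = 5L,
                          flank = 200000L, clade_fraction = 2 / 3,
                          min_conserved_support = 17L, min_intersection = 20L,
                          merge_distance = 20L, min_candidate = 50L,
                          max_outgroup_violations = 1L,
                          screened_clades = NULL) {
  stopifnot(min_outgroup_mappings >= 0, min_target_mappings >= 0, flank >= 0,
            clade_fraction > 0, clade_fraction <= 1,
            min_conserved_support >= 0, min_intersection >= 0,
            merge_distance >= 0, min_candidate >= 0,
            max_outgroup_violations >= 0)
  structure(list(min_outgroup_mappings = min_outgroup_mappings,
                 min_target_mappings = min_target_mappings, flank = flank,
                 clade_fraction = clade_fraction,
                 min_conserved_support = min_conserved_support,
                 min_intersection = min_intersection,
                 merge_distance = merge_distance, min_candidate = min_candidate,
                 max_outgroup_violations = max_outgroup_violations,
                 screened_clades = screened_clades),
            class = "screen_config")
}

#' Clade quorum
#'
#' Number of clade members that must carry a deletion at a base, i.e. the
#' ceiling of `clade_fraction * clade_size`. Computed with a 1e-9 slack so
#' that rational fractions evaluated in floating point (2/3 of 3 is
#' 2.0000000000000004 in doubles) keep their intended value.
#'
#' @param clade_size number of (mapped) clade members.
#' @param clade_fraction required fraction (default 2/3).
#' @return Required species count (integer).
#' @examples
#' clade_quorum(4) # 3
#' clade_quorum(3) # 2
#' @export
clade_quorum <- function(clade_size, clade_fraction = 2 / 3) {
  stopifnot(clade_size >= 1)
  as.integer(ceiling(clade_fraction * clade_size - 1e-9))
}

support_mask <- function(interval_sets, min_support) {
  sets <- interval_sets[vapply(interval_sets, length, integer(1)) > 0]
  if (!length(sets)) return(GenomicRanges::GRanges())
  if (min_support <= length(sets)) {
    pooled <- suppressWarnings(do.call(c, unname(sets)))
    cov <- GenomicRanges::coverage(pooled)
    gr <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_support,
                                                rangesOnly = TRUE))
    return(normalize_intervals(gr))
  }
  GenomicRanges::GRanges()
}

#' Per-base support mask across species interval sets
#'
#' Bases covered by at least `min_support` of the given per-species interval
#' sets (e.g. conserved elements across outgroups, or chain gaps across a
#' target clade).
#'
#' @param interval_sets named list of `GRanges`, one per species.
#' @param min_support minimum number of covering species.
#' @return A normalized `GRanges`.
#' @export
interval_support <- function(interval_sets, min_support) {
  stopifnot(min_support >= 0)
  if (min_support == 0)
    stop("min_support of 0 would cover the whole genome; use >= 1")
  support_mask(interval_sets, min_support)
}

#' Scan one gene for candidate conserved sequence deletions
#'
#' The scan window is the interval from `flank` bases upstream to `flank`
#' bases downstream of the canonical TSS (inclusive on both sides, hence
#' `2 * flank + 1` bases when unclipped), clipped to the chromosome. Within
#' the window:
#'
#' 1. the *target deletion mask* keeps bases where, in **every** screened
#'    target clade, at least the clade quorum of mapped members shows a
#'    chain gap;
#' 2. the *conserved mask* keeps bases covered by conserved elements of at
#'    least `min_conserved_support` outgroup species;
#' 3. their intersections of at least `min_intersection` bases are merged
#'    within `merge_distance`, and pieces of at least `min_candidate` bases
#'    are kept;
#' 4. a candidate survives only if at most `max_outgroup_violations`
#'    *scorable* outgroups (outgroups whose accepted chain's reference span
#'    fully contains the candidate) show a chain gap overlapping it.
#'
#' A gene is eligible only when it has accepted orthology calls from at
#' least `min_outgroup_mappings` outgroups and `min_target_mappings` targets.
#' Clade quorums are computed over mapped members: a target species without
#' an orthology call for this gene contributes to neither numerator nor
#' denominator.
#'
#' @param gene a [gene_model()].
#' @param calls orthology call table ([orthology_calls()]).
#' @param gap_sets named list of per-species gap `GRanges`
#'   ([species_gap_set()]).
#' @param conserved_sets named list of per-outgroup conserved element
#'   `GRanges`; ignored when `conserved_mask` is supplied.
#' @param phenotypes phenotype data.frame ([read_phenotypes()]).
#' @param config a [screen_config()].
#' @param chrom_lengths optional named vector of reference chromosome lengths
#'   used to clip windows.
#' @param conserved_mask optional precomputed outgroup-support mask
#'   (`GRanges`), to avoid recomputing it for every gene.
#' @return data.frame of candidates (zero rows when none): `chrom`, `start`,
#'   `end` (1-based closed), `length`, `gene_id`, `conserved_support` (minimum
#'   over candidate bases), `violations`, `violating_species`,
#'   `clade_support` (per screened clade, "clade=deleting/mapped").
#' @export
scan_gene <- function(gene, calls, gap_sets, conserved_sets, phenotypes,
                      config = screen_config(), chrom_lengths = NULL,
                      conserved_mask = NULL) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), gene_id = character(),
                      conserved_support = integer(), violations = integer(),
                      violating_species = character(),
                      clade_support = character(), stringsAsFactors = FALSE)
  gcalls <- calls[calls$gene_id == gene$gene_id, , drop = FALSE]
  roles <- stats::setNames(phenotypes$role, phenotypes$species_id)
  clades <- stats::setNames(phenotypes$clade_id, phenotypes$species_id)
  mapped_out <- gcalls$species_id[roles[gcalls$species_id] == "outgroup"]
  mapped_tgt <- gcalls$species_id[roles[gcalls$species_id] == "target"]
  if (length(mapped_out) < config$min_outgroup_mappings ||
      length(mapped_tgt) < config$min_target_mappings)
    return(empty)

  tss <- gene_tss(gene)
  w_start <- max(1, tss - config$flank)
  w_end <- tss + config$flank
  if (!is.null(chrom_lengths) && gene$chrom %in% names(chrom_lengths))
    w_end <- min(w_end, chrom_lengths[[gene$chrom]])
  window <- GenomicRanges::GRanges(gene$chrom,
                                   IRanges::IRanges(w_start, w_end))

  screened <- config$screened_clades
  if (is.null(screened)) {
    tab <- table(clades[mapped_tgt])
    screened <- names(tab)[tab >= 2L]
  }
  if (!length(screened)) return(empty)

  target_mask <- window
  for (cl in screened) {
    members <- mapped_tgt[clades[mapped_tgt] == cl]
    if (!length(members)) return(empty)
    q <- clade_quorum(length(members), config$clade_fraction)
    cmask <- interval_support(gap_sets[members], q)
    target_mask <- interval_intersect(target_mask, cmask)
    if (!length(target_mask)) return(empty)
  }

  if (is.null(conserved_mask))
    conserved_mask <- interval_support(
      conserved_sets[names(conserved_sets) %in%
                       phenotypes$species_id[phenotypes$role == "outgroup"]],
      config$min_conserved_support)
  raw <- interval_intersect(target_mask, conserved_mask)
  raw <- raw[GenomicRanges::width(raw) >= config$min_intersection]
  cand <- merge_within(raw, config$merge_distance)
  cand <- cand[GenomicRanges::width(cand) >= config$min_candidate]
  if (!length(cand)) return(empty)

  ## candidates all lie on the gene's chromosome; evaluate violation and
  ## support bookkeeping with plain vector arithmetic on that chromosome
  on_chrom <- function(gr) {
    keep <- as.character(GenomicRanges::seqnames(gr)) == gene$chrom
    list(s = GenomicRanges::start(gr)[keep], e = GenomicRanges::end(gr)[keep])
  }
  overlaps_any <- function(set, cs, ce) {
    length(set$s) > 0 && any(set$s <= ce & set$e >= cs)
  }
  spans <- gcalls[match(mapped_out, gcalls$species_id),
                  c("t_name", "t_start", "t_end")]
  out_sets <- lapply(gap_sets[mapped_out], on_chrom)
  outgroup_ids <- phenotypes$species_id[phenotypes$role == "outgroup"]
  cons_cov <- conserved_support_coverage(
    conserved_sets[names(conserved_sets) %in% outgroup_ids], gene$chrom)
  rows <- lapply(seq_along(cand), function(i) {
    cs <- GenomicRanges::start(cand)[i]
    ce <- GenomicRanges::end(cand)[i]
    scorable <- spans$t_name == gene$chrom &
      spans$t_start + 1 <= cs & spans$t_end >= ce
    viol <- vapply(seq_along(mapped_out), function(j)
      scorable[j] && overlaps_any(out_sets[[j]], cs, ce), logical(1))
    if (sum(viol) > config$max_outgroup_violations) return(NULL)
    cons_support <- if (is.null(cons_cov) || ce > length(cons_cov)) 0L
    else min(S4Vectors::runValue(IRanges::Views(cons_cov, cs, ce)[[1L]]))
    clade_supp <- vapply(screened, function(cl) {
      members <- mapped_tgt[clades[mapped_tgt] == cl]
      del <- sum(vapply(gap_sets[members], function(gr)
        overlaps_any(on_chrom(gr), cs, ce), logical(1)))
      sprintf("%s=%d/%d", cl, del, length(members))
    }, character(1))
    data.frame(chrom = gene$chrom, start = cs, end = ce,
               length = ce - cs + 1L, gene_id = gene$gene_id,
               conserved_support = cons_support, violations = sum(viol),
               violating_species = paste(mapped_out[viol], collapse = ","),
               clade_support = paste(clade_supp, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# per-base count of species' interval sets covering one chromosome (an
# integer Rle, or NULL when no set touches the chromosome)
conserved_support_coverage <- function(interval_sets, chrom) {
  per <- lapply(interval_sets, function(gr) {
    keep <- as.character(GenomicRanges::seqnames(gr)) == chrom
    GenomicRanges::ranges(gr)[keep]
  })
  per <- per[vapply(per, length, integer(1)) > 0]
  if (!length(per)) return(NULL)
  IRanges::coverage(do.call(c, unname(per)))
}

#' Unify per-gene candidates into unique CONDELs
#'
#' Candidates produced under different genes that overlap by at least one
#' base are unified into one record whose interval is their union and whose
#' linked genes are the union of the calling genes. Violation and support
#' figures are carried over as the maximum across contributing records (they
#' are identical in practice, since all masks derive from the same
#' genome-wide sets).
#'
#' @param per_gene data.frame from [scan_gene()] rows (possibly several
#'   genes).
#' @return data.frame with `condel_id`, `chrom`, `start`, `end`, `length`,
#'   `linked_genes` (comma-separated), `conserved_support`, `violations`,
#'   `violating_species`, `clade_support`.
#' @export
merge_candidates_across_genes <- function(per_gene) {
  empty <- data.frame(condel_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      linked_genes = character(), conserved_support = integer(),
                      violations = integer(), violating_species = character(),
                      clade_support = character(), stringsAsFactors = FALSE)
  if (!nrow(per_gene)) return(empty)
  gr <- GenomicRanges::GRanges(per_gene$chrom,
                               IRanges::IRanges(per_gene$start, per_gene$end))
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- lapply(seq_along(merged), function(i) {
    idx <- which(grp == i)
    data.frame(chrom = as.character(GenomicRanges::seqnames(merged[i])),
               start = GenomicRanges::start(merged[i]),
               end = GenomicRanges::end(merged[i]),
               length = GenomicRanges::width(merged[i]),
               linked_genes = paste(sort(unique(per_gene$gene_id[idx])),
                                    collapse = ","),
               conserved_support = max(per_gene$conserved_support[idx]),
               violations = max(per_gene$violations[idx]),
               violating_species = per_gene$violating_species[idx][
                 which.max(per_gene$violations[idx])],
               clade_support = per_gene$clade_support[idx][1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(condel_id = sprintf("CONDEL.%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify candidates by genomic context
#'
#' Precedence order: a candidate overlapping any exon of any transcript is
#' `coding-exon`; otherwise, one lying within any transcript span is
#' `genic-noncoding`; otherwise `intergenic`. The three classes partition the
#' candidate set.
#'
#' @param candidates data.frame with `chrom`, `start`, `end` (1-based
#'   closed), e.g. from [merge_candidates_across_genes()].
#' @param gene_models named list of [gene_model()] objects.
#' @return The input data.frame with a `context` column appended.
#' @export
annotate_context <- function(candidates, gene_models) {
  exons <- list(); spans <- list()
  for (g in gene_models) {
    for (tx in g$transcripts) {
      spans[[length(spans) + 1L]] <-
        GenomicRanges::GRanges(g$chrom, IRanges::IRanges(tx$start, tx$end))
      if (length(tx$exons))
        exons[[length(exons) + 1L]] <- GenomicRanges::GRanges(g$chrom, tx$exons)
    }
  }
  exon_gr <- if (length(exons)) suppressWarnings(do.call(c, exons))
             else GenomicRanges::GRanges()
  span_gr <- if (length(spans)) suppressWarnings(do.call(c, spans))
             else GenomicRanges::GRanges()
  ctx <- vapply(seq_len(nrow(candidates)), function(i) {
    ci <- GenomicRanges::GRanges(candidates$chrom[i],
                                 IRanges::IRanges(candidates$start[i],
                                                  candidates$end[i]))
    if (length(exon_gr) &&
        suppressWarnings(any(IRanges::overlapsAny(ci, exon_gr))))
      "coding-exon"
    else if (length(span_gr) &&
             length(suppressWarnings(GenomicRanges::findOverlaps(ci, span_gr))))
      "genic-noncoding"
    else "intergenic"
  }, character(1))
  candidates$context <- ctx
  candidates
}
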