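#' Run the full CONDEL screen on a study bundle
#'
#' End-to-end orchestration of the comparative screen:
#'
#' 1. select, per species and gene, the orthology-confident chain
#'    ([orthology_calls()]);
#' 2. extract per-species chain gap sets from the accepted chains, masked by
#'    query assembly N-runs ([species_gap_set()]);
#' 3. delineate per-outgroup conserved elements by sliding-window identity
#'    and the 5 percent coverage quota ([species_conserved_elements()]);
#' 4. scan every eligible gene's TSS window for bases deleted in the target
#'    clades and conserved across outgroups ([scan_gene()]), unify candidates
#'    across genes ([merge_candidates_across_genes()]) and classify their
#'    genomic context ([annotate_context()]).
#'
#' @param bundle a study bundle: list with `reference`
#'   ([Biostrings::DNAStringSet]), `genes` (named list of [gene_model()]),
#'   `phenotypes` (data.frame), `chains` (named list: species -> list of
#'   [chain()]), `queries` (named list: species ->
#'   [Biostrings::DNAStringSet]); see [simulate_study()] and
#'   [read_study_bundle()].
#' @param config a [screen_config()].
#' @param gap_config a [gap_caller_config()].
#' @param cons_config a [conservation_config()].
#' @param ratio_threshold,synteny_threshold orthology acceptance thresholds
#'   (see [map_gene_to_chain()]).
#' @param verbose log per-gene eligibility decisions with `message()`.
#' @return list with `candidates` (unique CONDELs with context), `per_gene`
#'   (pre-merge records), `calls` (orthology table), `gap_sets`,
#'   `conserved_sets` (per species `GRanges`), `conserved_mask` (outgroup
#'   support mask).
#' @export
run_condel_screen <- function(bundle, config = screen_config(),
                              gap_config = gap_caller_config(),
                              cons_config = conservation_config(),
                              ratio_threshold = 10, synteny_threshold = 10,
                              verbose = FALSE) {
  phen <- validate_phenotypes(bundle$phenotypes)
  genes <- bundle$genes
  ref <- bundle$reference
  roles <- stats::setNames(phen$role, phen$species_id)

  calls <- orthology_calls(genes, bundle$chains, ratio_threshold,
                           synteny_threshold)
  species <- unique(calls$species_id)

  ## accepted chains and N-run masked gap sets, per species
  gap_sets <- list()
  accepted_chains <- list()
  for (sp in species) {
    ids <- unique(calls$chain_id[calls$species_id == sp])
    chs <- Filter(function(ch) ch$id %in% ids, bundle$chains[[sp]])
    accepted_chains[[sp]] <- chs
    n_runs <- lapply(seq_along(bundle$queries[[sp]]), function(i)
      find_assembly_gaps(as.character(bundle$queries[[sp]][[i]]),
                         gap_config$assembly_gap_min_run))
    names(n_runs) <- names(bundle$queries[[sp]])
    gap_sets[[sp]] <- species_gap_set(chs, n_runs, gap_config)
  }

  ## per-outgroup conserved elements and the outgroup support mask
  quota_bases <- non_n_bases(ref)
  outgroups <- phen$species_id[phen$role == "outgroup"]
  conserved_sets <- list()
  for (sp in intersect(species, outgroups)) {
    conserved_sets[[sp]] <- species_conserved_elements(
      accepted_chains[[sp]], ref, bundle$queries[[sp]], quota_bases,
      cons_config)
  }
  conserved_mask <- interval_support(conserved_sets,
                                     config$min_conserved_support)

  chrom_lengths <- stats::setNames(Biostrings::width(ref), names(ref))
  per_gene <- list()
  for (g in names(genes)) {
    res <- scan_gene(genes[[g]], calls, gap_sets, conserved_sets, phen,
                     config, chrom_lengths, conserved_mask = conserved_mask)
    if (verbose) {
      n_out <- sum(roles[calls$species_id[calls$gene_id == g]] == "outgroup")
      n_tgt <- sum(roles[calls$species_id[calls$gene_id == g]] == "target")
      message(sprintf("gene %s: %d outgroup / %d target mappings -> %s",
                      g, n_out, n_tgt,
                      if (n_out < config$min_outgroup_mappings ||
                          n_tgt < config$min_target_mappings) "ineligible"
                      else sprintf("%d candidate(s)", nrow(res))))
    }
    if (nrow(res)) per_gene[[g]] <- res
  }
  per_gene <- if (length(per_gene))
    do.call(rbind, c(per_gene, make.row.names = FALSE))
  else
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), gene_id = character(),
               conserved_support = integer(), violations = integer(),
               violating_species = character(), clade_support = character(),
               stringsAsFactors = FALSE)

  candidates <- merge_candidates_across_genes(per_gene)
  if (nrow(candidates))
    candidates <- annotate_context(candidates, genes)
  else candidates$context <- character(0)

  list(candidates = candidates, per_gene = per_gene, calls = calls,
       gap_sets = gap_sets, conserved_sets = conserved_sets,
       conserved_mask = conserved_mask)
}

#' Write screen results to a directory
#'
#' Emits `condels.tsv` (one row per unique CONDEL, with linked genes,
#' support, violations and context), `condels.bed` (BED6, 0-based half-open,
#' score = conserved support) and `orthology.tsv` (the acceptance table).
#'
#' @param result output of [run_condel_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$candidates, file.path(dir, "condels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- result$candidates
  if (nrow(cand)) {
    bed <- data.frame(cand$chrom, cand$start - 1L, cand$end, cand$condel_id,
                      cand$conserved_support, ".")
    utils::write.table(bed, file.path(dir, "condels.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    file.create(file.path(dir, "condels.bed"))
  }
  calls <- result$calls
  calls$accepted <- TRUE
  utils::write.table(calls, file.path(dir, "orthology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
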