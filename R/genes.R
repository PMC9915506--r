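#' Construct a gene model
#'
#' A gene model carries one or more transcripts, each a span with disjoint
#' exons. The canonical transcript is the one with the longest span
#' (ties broken by the lexicographically smallest transcript id); its
#' strand-aware 5' end is the transcription start site (TSS) used to anchor
#' screen windows.
#'
#' @param gene_id gene identifier.
#' @param chrom reference sequence name.
#' @param strand "+" or "-".
#' @param transcripts named list: for each transcript id, a list with `start`
#'   and `end` (1-based closed span) and `exons` (an [IRanges::IRanges]).
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(strand %in% c("+", "-"), length(transcripts) >= 1L,
            !is.null(names(transcripts)), !anyDuplicated(names(transcripts)))
  for (tx_id in names(transcripts)) {
    tx <- transcripts[[tx_id]]
    stopifnot(tx$start >= 1, tx$end >= tx$start)
    ex <- tx$exons
    stopifnot(methods::is(ex, "IRanges"))
    if (length(ex)) {
      if (min(IRanges::start(ex)) < tx$start || max(IRanges::end(ex)) > tx$end)
        stop("exons of transcript '", tx_id, "' exceed its span")
      red <- IRanges::reduce(ex, min.gapwidth = 0L)
      if (sum(IRanges::width(red)) != sum(IRanges::width(ex)))
        stop("exons of transcript '", tx_id, "' overlap")
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model %s> %s:%d-%d (%s), %d transcript(s), canonical %s\n",
              x$gene_id, x$chrom, IRanges::start(sp), IRanges::end(sp),
              x$strand, length(x$transcripts), canonical_transcript(x)))
  invisible(x)
}

#' Canonical transcript of a gene model
#'
#' @param gene a [gene_model()].
#' @return The canonical (longest-span) transcript id.
#' @export
canonical_transcript <- function(gene) {
  ids <- names(gene$transcripts)
  len <- vapply(gene$transcripts, function(tx) tx$end - tx$start + 1, numeric(1))
  ids[order(-len, ids)][1L]
}

#' Canonical span of a gene model
#'
#' @param gene a [gene_model()].
#' @return An [IRanges::IRanges] of length one (1-based closed).
#' @export
gene_span <- function(gene) {
  tx <- gene$transcripts[[canonical_transcript(gene)]]
  IRanges::IRanges(start = tx$start, end = tx$end)
}

#' Strand-aware transcription start site
#'
#' @param gene a [gene_model()].
#' @return 1-based TSS position: canonical span start on "+", span end on "-".
#' @export
gene_tss <- function(gene) {
  tx <- gene$transcripts[[canonical_transcript(gene)]]
  if (gene$strand == "+") tx$start else tx$end
}

#' Read gene models from a BED12 file
#'
#' One BED12 line per transcript. The `name` column is either
#' `"gene_id|transcript_id"` or a bare id (used for both). Block definitions
#' become exons. Transcripts sharing a gene id are grouped into one gene
#' model; duplicate (gene, transcript) pairs and genes split across
#' chromosomes or strands are schema errors.
#'
#' @param path path to a BED12 file.
#' @return Named list of [gene_model()] objects, keyed by gene id.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- as.character(gr$name)
  parts <- strsplit(nm, "|", fixed = TRUE)
  gene_ids <- vapply(parts, `[`, character(1), 1L)
  tx_ids <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L],
                   character(1))
  if (anyDuplicated(paste(gene_ids, tx_ids)))
    stop("duplicate gene/transcript id in ", path)
  genes <- list()
  for (g in unique(gene_ids)) {
    idx <- which(gene_ids == g)
    chroms <- unique(as.character(GenomicRanges::seqnames(gr)[idx]))
    strands <- unique(as.character(GenomicRanges::strand(gr)[idx]))
    if (length(chroms) != 1L || length(strands) != 1L)
      stop("gene '", g, "' spans multiple chromosomes or strands")
    txs <- list()
    for (i in idx) {
      blocks <- gr$blocks[[i]]  # exon starts relative to transcript start
      exons <- IRanges::shift(blocks, GenomicRanges::start(gr)[i] - 1L)
      txs[[tx_ids[i]]] <- list(start = GenomicRanges::start(gr)[i],
                               end = GenomicRanges::end(gr)[i],
                               exons = exons)
    }
    genes[[g]] <- gene_model(g, chroms, strands, txs)
  }
  genes
}

#' Write gene models to a BED12 file
#'
#' @param genes named list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (tx_id in names(g$transcripts)) {
      tx <- g$transcripts[[tx_id]]
      rows[[length(rows) + 1L]] <- list(
        chrom = g$chrom, start = tx$start, end = tx$end,
        name = paste0(g$gene_id, "|", tx_id), strand = g$strand,
        exons = tx$exons)
    }
  }
  gr <- GenomicRanges::GRanges(
    vapply(rows, `[[`, character(1), "chrom"),
    IRanges::IRanges(vapply(rows, `[[`, numeric(1), "start"),
                     vapply(rows, `[[`, numeric(1), "end")),
    strand = vapply(rows, `[[`, character(1), "strand"))
  gr$name <- vapply(rows, `[[`, character(1), "name")
  gr$blocks <- IRanges::IRangesList(lapply(rows, function(r)
    IRanges::shift(r$exons, 1L - r$start)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a species phenotype table
#'
#' Tab-separated with header columns `species_id`, `role`, `clade_id` and
#' optionally `notes`. Roles are `reference` (exactly one), `outgroup`
#' (trait-complete) or `target` (trait-reduced); every target must carry a
#' clade id so that clade quorums can be evaluated.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns species_id, role, clade_id, notes.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_phenotypes(df)
}

validate_phenotypes <- function(df) {
  need <- c("species_id", "role", "clade_id")
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (!"notes" %in% names(df)) df$notes <- ""
  df$clade_id[is.na(df$clade_id)] <- ""
  if (anyDuplicated(df$species_id)) stop("duplicate species_id")
  if (!all(df$role %in% c("reference", "outgroup", "target")))
    stop("role must be one of reference/outgroup/target")
  if (sum(df$role == "reference") != 1L)
    stop("phenotype table must contain exactly one reference species")
  tgt <- df$role == "target"
  if (any(tgt & !nzchar(df$clade_id)))
    stop("every target species must have a clade_id")
  df[, c("species_id", "role", "clade_id", "notes")]
}

#' Write a species phenotype table
#'
#' @param df phenotype data.frame (see [read_phenotypes()]).
#' @param path output path.
#' @export
write_phenotypes <- function(df, path) {
  df <- validate_phenotypes(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
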