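#' Simulation configuration for a synthetic miniature study
#'
#' Defines the study conditions the generator emulates: a single-chromosome
#' reference with annotated genes, a panel of trait-complete outgroups and
#' two multi-member trait-reduced clades (plus single-representative
#' targets), engineered true CONDELs that satisfy every screen criterion,
#' and one decoy class per screen criterion, each violating exactly that
#' criterion.
#'
#' @param seed RNG seed; identical configurations produce byte-identical
#'   bundles.
#' @param reference_length reference chromosome length in bases.
#' @param n_genes number of annotated genes.
#' @param n_outgroups number of trait-complete outgroup species.
#' @param target_clades named integer vector of screened clade sizes.
#' @param extra_single_targets number of single-representative target
#'   lineages (reported, never gating).
#' @param substitution_rate named per-role substitution rates.
#' @param n_true_condels number of engineered true CONDELs.
#' @param true_condel_length length range (min, max) of true CONDELs.
#' @param n_decoys_per_class decoys per decoy class.
#' @param n_run_injections benign assembly N-runs injected per target
#'   species, far from every engineered deletion.
#' @param breakpoint_jitter maximum per-species outward extension of true
#'   CONDEL deletion breakpoints, in bases.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              reference_length = 1000000L,
                              n_genes = 40L,
                              n_outgroups = 20L,
                              target_clades = c(cladeA = 4L, cladeB = 3L),
                              extra_single_targets = 2L,
                              substitution_rate = c(outgroup = 0.02,
                                                    target = 0.05),
                              n_true_condels = 8L,
                              true_condel_length = c(60L, 300L),
                              n_decoys_per_class = 4L,
                              n_run_injections = 4L,
                              breakpoint_jitter = 30L) {
  stopifnot(reference_length >= 20000L, n_genes >= 1L, n_outgroups >= 1L,
            all(target_clades >= 1L), n_true_condels >= 0L,
            length(true_condel_length) == 2L,
            true_condel_length[1L] <= true_condel_length[2L],
            n_decoys_per_class >= 0L, n_run_injections >= 0L,
            breakpoint_jitter >= 0L,
            all(c("outgroup", "target") %in% names(substitution_rate)))
  if (is.null(names(target_clades)))
    names(target_clades) <- paste0("clade", LETTERS[seq_along(target_clades)])
  structure(list(seed = as.integer(seed),
                 reference_length = as.integer(reference_length),
                 n_genes = as.integer(n_genes),
                 n_outgroups = as.integer(n_outgroups),
                 target_clades = target_clades,
                 extra_single_targets = as.integer(extra_single_targets),
                 substitution_rate = substitution_rate,
                 n_true_condels = as.integer(n_true_condels),
                 true_condel_length = as.integer(true_condel_length),
                 n_decoys_per_class = as.integer(n_decoys_per_class),
                 n_run_injections = as.integer(n_run_injections),
                 breakpoint_jitter = as.integer(breakpoint_jitter)),
            class = "simulation_config")
}

DECOY_CLASSES <- c("decoy_single_clade", "decoy_low_conservation",
                   "decoy_assembly_gap", "decoy_outgroup_violation")

BASE_ROT <- c(A = "C", C = "G", G = "T", T = "A")
SIM_FLANK <- 200000L       # screen window half-width the placement honours
SIM_MIN_SEPARATION <- 1000L # minimum distance between engineered intervals

#' Simulate a complete miniature study
#'
#' Draws, per species, an edit script (substitutions at the role's rate
#' outside engineered regions; deletions of engineered intervals in
#' quorum-satisfying subsets of the target clades, with outward per-species
#' jitter for true CONDELs; decoy edits per class; assembly N-runs beside
#' `decoy_assembly_gap` deletions) and derives each pairwise alignment chain
#' analytically from the edit script - no aligner is run, so chains satisfy
#' their invariants by construction. A deletion of length L yields a
#' separator with `dt = L` and `dq = 0` (single-sided), or `dq > 0` when a
#' query insertion is co-placed at the breakpoint (double-sided). Roughly a
#' third of the species are simulated on the query minus strand to exercise
#' strand bookkeeping.
#'
#' RNG draw order is fixed (reference, genes, engineered placement, per-event
#' species subsets, then per-species edit scripts in species order), so an
#' identical configuration reproduces the bundle bit for bit.
#'
#' @param config a [simulation_config()].
#' @return A bundle list: `reference` (DNAStringSet), `genes` (gene models),
#'   `phenotypes` (data.frame), `chains` (per species), `queries`
#'   (per species DNAStringSet), `truth` (data.frame with 1-based closed
#'   `start`/`end`, `class`, `expected_detected`), `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- config$reference_length
  bases <- c("A", "C", "G", "T")

  ## 1. reference sequence
  ref_chars <- sample(bases, L, replace = TRUE)
  ref_name <- "chr1"

  ## 2. gene models
  genes <- list()
  for (i in seq_len(config$n_genes)) {
    n_ex <- sample(2:5, 1L)
    exon_w <- sample(100:400, n_ex, replace = TRUE)
    intron_w <- if (n_ex > 1L) sample(500:4000, n_ex - 1L, replace = TRUE)
                else integer()
    span_len <- sum(exon_w) + sum(intron_w)
    center <- round(i * L / (config$n_genes + 1))
    start <- center - span_len %/% 2L + sample(-2000:2000, 1L)
    start <- max(1L, min(start, L - span_len))
    strand <- sample(c("+", "-"), 1L)
    ex_start <- start + cumsum(c(0L, head_pairsum(exon_w, intron_w)))
    exons <- IRanges::IRanges(start = ex_start, width = exon_w)
    gid <- sprintf("g%03d", i)
    txs <- list()
    txs[[paste0(gid, ".t1")]] <- list(start = start,
                                      end = start + span_len - 1L,
                                      exons = exons)
    if (stats::runif(1) < 0.5 && n_ex >= 2L) {
      sub <- exons[seq_len(n_ex - 1L)]
      txs[[paste0(gid, ".t2")]] <- list(start = IRanges::start(sub)[1L],
                                        end = max(IRanges::end(sub)),
                                        exons = sub)
    }
    genes[[gid]] <- gene_model(gid, ref_name, strand, txs)
  }
  tss_all <- vapply(genes, gene_tss, numeric(1))
  exon_mask <- IRanges::reduce(do.call(c, unname(lapply(genes, function(g)
    do.call(c, unname(lapply(g$transcripts, `[[`, "exons"))))))) + 150L

  ## 3. engineered interval placement
  classes <- c(rep("true_condel", config$n_true_condels),
               rep(DECOY_CLASSES, each = config$n_decoys_per_class))
  truth <- data.frame(chrom = character(), start = integer(), end = integer(),
                      class = character(), stringsAsFactors = FALSE)
  placed <- IRanges::IRanges()
  for (cls in classes) {
    len <- if (cls == "true_condel")
      sample(config$true_condel_length[1L]:config$true_condel_length[2L], 1L)
    else sample(80:250, 1L)
    margin <- min(50000L, L %/% 10L)
    ok <- FALSE
    for (try in seq_len(10000L)) {
      s <- sample(margin:(L - margin - len), 1L)
      e <- s + len - 1L
      if (length(placed)) {
        gap <- pmax(IRanges::start(placed) - e - 1L,
                    s - IRanges::end(placed) - 1L)
        if (any(gap < SIM_MIN_SEPARATION)) next
      }
      if (IRanges::overlapsAny(IRanges::IRanges(s, e), exon_mask)) next
      if (!any(tss_all - SIM_FLANK <= s & e <= tss_all + SIM_FLANK)) next
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place engineered interval of class '", cls,
           "' (separation/exon/TSS-window constraints)")
    placed <- c(placed, IRanges::IRanges(s, e))
    truth <- rbind(truth, data.frame(chrom = ref_name, start = s, end = e,
                                     class = cls, stringsAsFactors = FALSE))
  }
  truth$expected_detected <- truth$class == "true_condel"
  truth$truth_id <- sprintf("%s.%d", truth$class, seq_len(nrow(truth)))

  ## 4. species panel
  clade_members <- lapply(names(config$target_clades), function(cl)
    sprintf("%s_%d", cl, seq_len(config$target_clades[[cl]])))
  names(clade_members) <- names(config$target_clades)
  singles <- if (config$extra_single_targets > 0L)
    sprintf("single%d", seq_len(config$extra_single_targets)) else character()
  outgroups <- sprintf("out%02d", seq_len(config$n_outgroups))
  phenotypes <- rbind(
    data.frame(species_id = "ref", role = "reference", clade_id = "",
               notes = "reference assembly", stringsAsFactors = FALSE),
    data.frame(species_id = outgroups, role = "outgroup", clade_id = "",
               notes = "", stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(clade_members), function(cl)
      data.frame(species_id = clade_members[[cl]], role = "target",
                 clade_id = cl, notes = "", stringsAsFactors = FALSE))),
    if (length(singles))
      data.frame(species_id = singles, role = "target", clade_id = singles,
                 notes = "single representative", stringsAsFactors = FALSE))

  ## 5. per-event deleting species
  del_species <- vector("list", nrow(truth))
  viol_outgroups <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cls <- truth$class[i]
    dels <- character()
    for (ci in seq_along(clade_members)) {
      members <- clade_members[[ci]]
      q <- clade_quorum(length(members))
      if (cls == "decoy_single_clade" && ci > 1L) {
        take <- max(q - 1L, 0L)  # strictly below quorum
        if (take > 0L) dels <- c(dels, sample(members, take))
      } else {
        dels <- c(dels, if (q < length(members)) sample(members, q)
                  else members)
      }
    }
    if (cls == "true_condel" && length(singles))
      dels <- c(dels, singles[stats::runif(length(singles)) < 0.5])
    del_species[[i]] <- dels
    viol_outgroups[[i]] <- if (cls == "decoy_outgroup_violation")
      sample(outgroups, 2L) else character()
  }

  ## positions where neutral substitutions may fall: outside engineered
  ## intervals plus a 12 bp buffer, so engineered window identities stay
  ## interpretable
  excluded <- IRanges::reduce(IRanges::IRanges(truth$start, truth$end) + 12L)
  mutable <- setdiff(seq_len(L),
                     unlist(lapply(seq_along(excluded), function(j)
                       IRanges::start(excluded)[j]:IRanges::end(excluded)[j])))
  ## safe spots for benign N-runs: well clear of engineered deletions
  far <- IRanges::reduce(IRanges::IRanges(truth$start, truth$end) + 600L)
  nrun_safe <- setdiff(seq.int(2000L, L - 2000L, by = 50L),
                       unlist(lapply(seq_along(far), function(j)
                         IRanges::start(far)[j]:IRanges::end(far)[j])))
  low_cons <- truth[truth$class == "decoy_low_conservation", , drop = FALSE]

  ## 6. per-species edit scripts, query sequences and chains
  species <- phenotypes$species_id[phenotypes$role != "reference"]
  roles <- stats::setNames(phenotypes$role, phenotypes$species_id)
  chains <- list()
  queries <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    role <- roles[[sp]]
    rate <- config$substitution_rate[[role]]
    chars <- ref_chars

    ## neutral substitutions (deterministic rotation at sampled positions)
    if (rate > 0 && length(mutable)) {
      n_sub <- stats::rbinom(1L, length(mutable), rate)
      pos <- sample(mutable, n_sub)
      chars[pos] <- BASE_ROT[chars[pos]]
    }
    ## dense divergence of low-conservation decoys in every outgroup
    if (role == "outgroup" && nrow(low_cons)) {
      for (j in seq_len(nrow(low_cons))) {
        pos <- seq.int(low_cons$start[j], low_cons$end[j], by = 6L)
        chars[pos] <- BASE_ROT[chars[pos]]
      }
    }
    ## benign assembly N-runs in target assemblies
    if (role == "target" && config$n_run_injections > 0L &&
        length(nrun_safe) >= config$n_run_injections) {
      pos <- sample(nrun_safe, config$n_run_injections)
      for (p in pos) chars[p:(p + 9L)] <- "N"
    }

    ## deletions (with optional co-placed insertion) for this species
    ev <- which(vapply(seq_len(nrow(truth)), function(i)
      sp %in% del_species[[i]] || sp %in% viol_outgroups[[i]], logical(1)))
    ev <- ev[order(truth$start[ev])]
    del <- data.frame(start = integer(), end = integer(), ins = integer(),
                      class = character(), stringsAsFactors = FALSE)
    for (i in ev) {
      s <- truth$start[i]; e <- truth$end[i]
      if (truth$class[i] == "true_condel" && config$breakpoint_jitter > 0L) {
        s <- s - sample(0:config$breakpoint_jitter, 1L)
        e <- e + sample(0:config$breakpoint_jitter, 1L)
      }
      ins <- if (stats::runif(1) < 0.5) sample(5:40, 1L) else 0L
      del <- rbind(del, data.frame(start = s, end = e, ins = ins,
                                   class = truth$class[i],
                                   stringsAsFactors = FALSE))
    }

    ## assemble the query and derive the chain from the edit script
    keep_start <- c(1L, del$end + 1L)
    keep_end <- c(del$start - 1L, L)
    sizes <- keep_end - keep_start + 1L
    segs <- lapply(seq_along(sizes), function(j)
      chars[keep_start[j]:keep_end[j]])
    q_chars <- character(0)
    q_gap_end <- integer(nrow(del))
    for (j in seq_along(segs)) {
      q_chars <- c(q_chars, segs[[j]])
      if (j <= nrow(del)) {
        if (del$ins[j] > 0L)
          q_chars <- c(q_chars, sample(bases, del$ins[j], replace = TRUE))
        q_gap_end[j] <- length(q_chars)  # 0-based end of the query gap
      }
    }
    ## N-runs right next to assembly-gap decoy deletions (20 bp from the
    ## query gap edge, well inside the masking proximity)
    for (j in which(del$class == "decoy_assembly_gap")) {
      at <- q_gap_end[j] + 21L
      q_chars[at:(at + 9L)] <- "N"
    }
    q_len <- length(q_chars)
    minus <- si %% 3L == 0L
    q_seq <- paste(q_chars, collapse = "")
    stored <- if (minus)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(q_seq)))
    else q_seq
    q_name <- paste0(sp, ".scaf1")
    n <- length(sizes)
    ch <- chain(score = sum(sizes), t_name = ref_name, t_size = L,
                t_start = 0, t_end = L,
                q_name = q_name, q_size = q_len,
                q_strand = if (minus) "-" else "+",
                q_start = 0, q_end = q_len, id = 1,
                blocks = data.frame(size = sizes,
                                    dt = c(del$end - del$start + 1L, 0L),
                                    dq = c(del$ins, 0L)))
    chains[[sp]] <- list(ch)
    qs <- Biostrings::DNAStringSet(stored)
    names(qs) <- q_name
    queries[[sp]] <- qs
  }

  reference <- Biostrings::DNAStringSet(paste(ref_chars, collapse = ""))
  names(reference) <- ref_name
  list(reference = reference, genes = genes, phenotypes = phenotypes,
       chains = chains, queries = queries,
       truth = truth[, c("truth_id", "chrom", "start", "end", "class",
                         "expected_detected")],
       config = config)
}

# interleave exon and intron widths into step offsets between exon starts
head_pairsum <- function(exon_w, intron_w) {
  n <- length(exon_w)
  if (n <= 1L) return(integer())
  exon_w[-n] + intron_w
}

#' Write a study bundle to disk
#'
#' Emits the exact flat-text formats the pipeline consumes: `reference.fa`,
#' `genes.bed` (BED12), `phenotypes.tsv`, one chain file and one query FASTA
#' per species under `chains/` and `fasta/`, the truth set as `truth.bed`
#' (0-based half-open, name = truth id, score = expected-detected flag), and
#' `manifest.json` echoing the configuration with per-file MD5 checksums.
#'
#' @param bundle a bundle from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "chains"), showWarnings = FALSE)
  dir.create(file.path(dir, "fasta"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$reference, file.path(dir, "reference.fa"))
  write_gene_models(bundle$genes, file.path(dir, "genes.bed"))
  write_phenotypes(bundle$phenotypes, file.path(dir, "phenotypes.tsv"))
  for (sp in names(bundle$chains)) {
    write_chain(bundle$chains[[sp]],
                file.path(dir, "chains", paste0(sp, ".chain")))
    Biostrings::writeXStringSet(bundle$queries[[sp]],
                                file.path(dir, "fasta", paste0(sp, ".fa")))
  }
  tr <- bundle$truth
  utils::write.table(
    data.frame(tr$chrom, tr$start - 1L, tr$end, tr$truth_id,
               as.integer(tr$expected_detected), "."),
    file.path(dir, "truth.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  sums <- as.list(tools::md5sum(file.path(dir, files)))
  names(sums) <- files
  manifest <- list(config = unclass(bundle$config), checksums = sums)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study bundle from disk
#'
#' @param dir a directory written by [write_study_bundle()] (or assembled by
#'   hand in the same layout).
#' @return A bundle list as produced by [simulate_study()] (without
#'   `config`; `truth` is `NULL` when `truth.bed` is absent).
#' @export
read_study_bundle <- function(dir) {
  reference <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  genes <- read_gene_models(file.path(dir, "genes.bed"))
  phenotypes <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  chain_files <- list.files(file.path(dir, "chains"), pattern = "\\.chain$",
                            full.names = TRUE)
  chains <- list(); queries <- list()
  for (f in chain_files) {
    sp <- sub("\\.chain$", "", basename(f))
    chains[[sp]] <- read_chain(f)
    q <- Biostrings::readDNAStringSet(file.path(dir, "fasta",
                                                paste0(sp, ".fa")))
    names(q) <- sub("\\s.*$", "", names(q))
    queries[[sp]] <- q
  }
  truth <- NULL
  truth_path <- file.path(dir, "truth.bed")
  if (file.exists(truth_path)) {
    df <- utils::read.table(truth_path, sep = "\t",
                            col.names = c("chrom", "start0", "end", "truth_id",
                                          "expected", "strand"),
                            stringsAsFactors = FALSE)
    truth <- data.frame(truth_id = df$truth_id, chrom = df$chrom,
                        start = df$start0 + 1L, end = df$end,
                        class = sub("\\.\\d+$", "", df$truth_id),
                        expected_detected = df$expected == 1L,
                        stringsAsFactors = FALSE)
  }
  list(reference = reference, genes = genes, phenotypes = phenotypes,
       chains = chains, queries = queries, truth = truth)
}

#' Recall and precision of a candidate set against the truth
#'
#' A truth record is *recovered* when a single candidate overlaps at least
#' `min_overlap_fraction` of it. Recall is the recovered fraction of
#' `true_condel` records; precision is the fraction of candidates
#' overlapping any `true_condel` by at least one base. With zero candidates,
#' precision is reported as 1.0 with `zero_candidates = TRUE` (documented
#' convention: an empty report makes no false claims).
#'
#' @param candidates data.frame with `chrom`, `start`, `end` (1-based
#'   closed) or a `GRanges`.
#' @param truth truth data.frame (see [simulate_study()]).
#' @param min_overlap_fraction fraction of a truth interval a single
#'   candidate must cover (default 0.5).
#' @return list with `recall`, `precision`, `zero_candidates`, and a
#'   per-record data.frame `records` (`truth_id`, `class`, `best_overlap`,
#'   `recovered`).
#' @export
evaluate_recovery <- function(candidates, truth, min_overlap_fraction = 0.5) {
  if (methods::is(candidates, "GRanges")) {
    cand <- candidates
  } else {
    cand <- if (nrow(candidates))
      GenomicRanges::GRanges(candidates$chrom,
                             IRanges::IRanges(candidates$start,
                                              candidates$end))
    else GenomicRanges::GRanges()
  }
  tr <- GenomicRanges::GRanges(truth$chrom,
                               IRanges::IRanges(truth$start, truth$end))
  best <- numeric(length(tr))
  if (length(cand)) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(tr, cand))
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ow <- GenomicRanges::width(GenomicRanges::pintersect(tr[qh], cand[sh]))
      frac <- ow / GenomicRanges::width(tr[qh])
      agg <- tapply(frac, qh, max)
      best[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  recovered <- best >= min_overlap_fraction
  is_true <- truth$class == "true_condel"
  recall <- if (any(is_true)) mean(recovered[is_true]) else NA_real_
  zero <- length(cand) == 0L
  precision <- if (zero) 1.0 else {
    hits <- suppressWarnings(IRanges::overlapsAny(cand, tr[is_true]))
    mean(hits)
  }
  list(recall = recall, precision = precision, zero_candidates = zero,
       records = data.frame(truth_id = truth$truth_id, class = truth$class,
                            best_overlap = best, recovered = recovered,
                            stringsAsFactors = FALSE))
}
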