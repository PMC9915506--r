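test_that("clade quorum is the ceiling of the clade fraction", {
  expect_equal(clade_quorum(4), 3)
  expect_equal(clade_quorum(3), 2)
  expect_equal(clade_quorum(1), 1)
  expect_equal(clade_quorum(6), 4)
  expect_equal(clade_quorum(10, 0.5), 5)
})

# a hand-built 10 kb study: 18 outgroups, clades of 4 and 3 targets, one
# 120 bp engineered deletion at chr1:6001-6120 (1-based)
screen_fixture <- function(deleters_a = c("a1", "a2", "a3"),
                           deleters_b = c("b1", "b2"),
                           conserved_outgroups = sprintf("o%02d", 1:18),
                           violating_outgroups = character(),
                           del = c(6001, 6120)) {
  outgroups <- sprintf("o%02d", 1:18)
  targets <- c(paste0("a", 1:4), paste0("b", 1:3))
  phen <- rbind(
    data.frame(species_id = "ref", role = "reference", clade_id = "",
               notes = "", stringsAsFactors = FALSE),
    data.frame(species_id = outgroups, role = "outgroup", clade_id = "",
               notes = "", stringsAsFactors = FALSE),
    data.frame(species_id = targets, role = "target",
               clade_id = c(rep("cladeA", 4), rep("cladeB", 3)),
               notes = "", stringsAsFactors = FALSE))
  gene <- make_gene("gX", start = 4001, end = 5000,
                    exons = IRanges::IRanges(4001, 5000))
  calls <- data.frame(species_id = c(outgroups, targets), gene_id = "gX",
                      chain_id = 1, t_name = "chr1", t_start = 0,
                      t_end = 10000, stringsAsFactors = FALSE)
  del_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(del[1], del[2]))
  gap_sets <- stats::setNames(
    lapply(c(outgroups, targets), function(sp) {
      if (sp %in% c(deleters_a, deleters_b, violating_outgroups)) del_gr
      else GenomicRanges::GRanges()
    }), c(outgroups, targets))
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  conserved_sets <- stats::setNames(
    lapply(outgroups, function(sp) {
      if (sp %in% conserved_outgroups) whole
      else interval_subtract(whole, del_gr + 500)
    }), outgroups)
  list(gene = gene, calls = calls, gap_sets = gap_sets,
       conserved_sets = conserved_sets, phen = phen,
       chrom_lengths = c(chr1 = 10000), del = del)
}

test_that("an engineered deletion conserved in all outgroups is recovered", {
  fx <- screen_fixture()
  out <- scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                   fx$phen, screen_config(), fx$chrom_lengths)
  expect_equal(nrow(out), 1)
  expect_lte(out$start, fx$del[1])
  expect_gte(out$end, fx$del[2])
  expect_equal(out$violations, 0)
  expect_equal(out$conserved_support, 18)
  expect_equal(out$clade_support, "cladeA=3/4;cladeB=2/3")
})

test_that("conserved support below threshold kills the candidate", {
  fx <- screen_fixture(conserved_outgroups = sprintf("o%02d", 1:16))
  out <- scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                   fx$phen, screen_config(), fx$chrom_lengths)
  expect_equal(nrow(out), 0)
})

test_that("clade quorum gates per base in every screened clade", {
  fx <- screen_fixture(deleters_b = "b1")  # 1 of 3 < quorum 2
  out <- scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                   fx$phen, screen_config(), fx$chrom_lengths)
  expect_equal(nrow(out), 0)
})

test_that("violations are counted per scorable outgroup and capped", {
  fx1 <- screen_fixture(violating_outgroups = "o01")
  out1 <- scan_gene(fx1$gene, fx1$calls, fx1$gap_sets, fx1$conserved_sets,
                    fx1$phen, screen_config(), fx1$chrom_lengths)
  expect_equal(out1$violations, 1)
  expect_equal(out1$violating_species, "o01")

  fx2 <- screen_fixture(violating_outgroups = c("o01", "o02"))
  out2 <- scan_gene(fx2$gene, fx2$calls, fx2$gap_sets, fx2$conserved_sets,
                    fx2$phen, screen_config(), fx2$chrom_lengths)
  expect_equal(nrow(out2), 0)

  # a non-scorable outgroup (chain not spanning the interval) neither
  # supports nor violates
  fx3 <- screen_fixture(violating_outgroups = c("o01", "o02"))
  fx3$calls$t_end[fx3$calls$species_id == "o02"] <- 5500
  out3 <- scan_gene(fx3$gene, fx3$calls, fx3$gap_sets, fx3$conserved_sets,
                    fx3$phen, screen_config(), fx3$chrom_lengths)
  expect_equal(out3$violations, 1)
})

test_that("gene eligibility requires the mapping minima", {
  fx <- screen_fixture()
  few_out <- fx$calls[!(fx$calls$species_id %in% sprintf("o%02d", 1:2)), ]
  expect_equal(nrow(scan_gene(fx$gene, few_out, fx$gap_sets,
                              fx$conserved_sets, fx$phen, screen_config(),
                              fx$chrom_lengths)), 0)
  few_tgt <- fx$calls[!(fx$calls$species_id %in% c("a4", "b3", "b2")), ]
  expect_equal(nrow(scan_gene(fx$gene, few_tgt, fx$gap_sets,
                              fx$conserved_sets, fx$phen, screen_config(),
                              fx$chrom_lengths)), 0)
})

test_that("candidate masks equal a per-base brute-force recount", {
  fx <- screen_fixture()
  cfg <- screen_config()
  out <- scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                   fx$phen, cfg, fx$chrom_lengths)
  # brute force over every base of the 10 kb chromosome
  tss <- gene_tss(fx$gene)
  window <- max(1, tss - cfg$flank):min(10000, tss + cfg$flank)
  in_set <- function(p, gr) any(GenomicRanges::start(gr) <= p &
                                  p <= GenomicRanges::end(gr))
  clade_of <- stats::setNames(fx$phen$clade_id, fx$phen$species_id)
  keep <- vapply(window, function(p) {
    del_a <- sum(vapply(paste0("a", 1:4), function(sp)
      in_set(p, fx$gap_sets[[sp]]), logical(1)))
    del_b <- sum(vapply(paste0("b", 1:3), function(sp)
      in_set(p, fx$gap_sets[[sp]]), logical(1)))
    cons <- sum(vapply(names(fx$conserved_sets), function(sp)
      in_set(p, fx$conserved_sets[[sp]]), logical(1)))
    del_a >= clade_quorum(4) && del_b >= clade_quorum(3) &&
      cons >= cfg$min_conserved_support
  }, logical(1))
  oracle_bases <- window[keep]
  got_bases <- if (nrow(out)) unlist(lapply(seq_len(nrow(out)), function(i)
    out$start[i]:out$end[i])) else integer()
  expect_equal(sort(got_bases), sort(oracle_bases))
})

test_that("raising any threshold never increases the candidate count", {
  fx <- screen_fixture()
  base_cfg <- screen_config()
  n0 <- nrow(scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                       fx$phen, base_cfg, fx$chrom_lengths))
  stricter <- list(
    screen_config(min_outgroup_mappings = 19L),
    screen_config(min_target_mappings = 8L),
    screen_config(clade_fraction = 1),
    screen_config(min_conserved_support = 19L),
    screen_config(min_intersection = 200L),
    screen_config(min_candidate = 200L),
    screen_config(max_outgroup_violations = 0L))
  for (cfg in stricter) {
    n <- nrow(scan_gene(fx$gene, fx$calls, fx$gap_sets, fx$conserved_sets,
                        fx$phen, cfg, fx$chrom_lengths))
    expect_lte(n, n0)
  }
})

test_that("candidates called by multiple genes unify with linked gene union", {
  rec <- function(gene_id, start, end) data.frame(
    chrom = "chr1", start = start, end = end, length = end - start + 1,
    gene_id = gene_id, conserved_support = 18L, violations = 0L,
    violating_species = "", clade_support = "cladeA=3/4",
    stringsAsFactors = FALSE)
  merged <- merge_candidates_across_genes(rbind(rec("gA", 100, 220),
                                                rec("gB", 100, 220),
                                                rec("gA", 5000, 5100)))
  expect_equal(nrow(merged), 2)
  expect_equal(merged$linked_genes[merged$start == 100], "gA,gB")
  expect_equal(merged$condel_id, c("CONDEL.1", "CONDEL.2"))
  expect_lte(nrow(merged), 3)  # union bound
})

test_that("genomic context classification has fixed precedence", {
  genes <- list(
    gA = gene_model("gA", "chr1", "+", list(
      "gA.t1" = list(start = 1000, end = 3000,
                     exons = IRanges::IRanges(c(1000, 2800), c(1200, 3000))))))
  cand <- data.frame(chrom = "chr1",
                     start = c(1100, 1500, 80000),
                     end = c(1150, 1600, 80100))
  out <- annotate_context(cand, genes)
  expect_equal(out$context, c("coding-exon", "genic-noncoding", "intergenic"))
  expect_true(all(out$context %in%
                    c("coding-exon", "genic-noncoding", "intergenic")))
})

test_that("the unclipped scan window spans 400,001 reference bases", {
  cfg <- screen_config()
  tss <- 500000
  w_start <- max(1, tss - cfg$flank)
  w_end <- tss + cfg$flank
  expect_equal(w_end - w_start + 1, 400001)
})
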