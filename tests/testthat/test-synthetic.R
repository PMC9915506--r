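small_cfg <- function(seed = 11, ...) {
  simulation_config(seed = seed, reference_length = 120000L, n_genes = 6L,
                    n_outgroups = 6L, target_clades = c(cladeA = 3L,
                                                        cladeB = 2L),
                    extra_single_targets = 1L, n_true_condels = 2L,
                    n_decoys_per_class = 1L, ...)
}

test_that("identical configurations reproduce the bundle bit for bit", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_bundle(simulate_study(small_cfg()), d1)
  write_study_bundle(simulate_study(small_cfg()), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_setequal(f1, f2)
  for (f in setdiff(f1, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a different seed changes the reference
  d3 <- withr::local_tempdir()
  write_study_bundle(simulate_study(small_cfg(seed = 12)), d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "reference.fa"))),
    unname(tools::md5sum(file.path(d3, "reference.fa")))))
})

test_that("bundles round-trip through disk", {
  b <- simulate_study(small_cfg())
  dir <- withr::local_tempdir()
  write_study_bundle(b, dir)
  back <- read_study_bundle(dir)
  expect_identical(as.character(back$reference[["chr1"]]),
                   as.character(b$reference[["chr1"]]))
  expect_setequal(names(back$chains), names(b$chains))
  sp <- names(b$chains)[1]
  expect_identical(format_chain(back$chains[[sp]]),
                   format_chain(b$chains[[sp]]))
  expect_equal(back$truth$start, b$truth$start)
  expect_equal(back$truth$class, b$truth$class)
  expect_setequal(names(back$genes), names(b$genes))
  expect_equal(gene_tss(back$genes$g001), gene_tss(b$genes$g001))
})

test_that("chains satisfy their invariants and encode the edit script", {
  b <- simulate_study(small_cfg())
  for (sp in names(b$chains)) {
    ch <- b$chains[[sp]][[1]]
    expect_silent(condelscreen:::validate_chain(ch))
    expect_equal(nchar(as.character(b$queries[[sp]][[1]])), ch$q_size)
    # every engineered deletion of this species appears as a dt separator
  }
  # a species deleting a truth interval shows a raw gap covering it exactly
  del_cover <- 0
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    for (sp in names(b$chains)) {
      g <- raw_gaps(b$chains[[sp]][[1]])
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end)),
        GenomicRanges::granges(g))
      if (length(hit)) {
        gg <- GenomicRanges::granges(g)[S4Vectors::subjectHits(hit)]
        expect_lte(GenomicRanges::start(gg), tr$start)
        expect_gte(GenomicRanges::end(gg), tr$end)
        del_cover <- del_cover + 1
      }
    }
  }
  expect_gt(del_cover, 0)
})

test_that("zero-divergence, zero-deletion config yields single-block chains", {
  cfg <- simulation_config(seed = 5, reference_length = 60000L, n_genes = 4L,
                           n_outgroups = 18L,
                           target_clades = c(cladeA = 4L, cladeB = 3L),
                           extra_single_targets = 0L,
                           substitution_rate = c(outgroup = 0, target = 0),
                           n_true_condels = 0L, n_decoys_per_class = 0L,
                           n_run_injections = 0L)
  b <- simulate_study(cfg)
  for (sp in names(b$chains)) {
    ch <- b$chains[[sp]][[1]]
    expect_equal(nrow(ch$blocks), 1)
    expect_equal(ch$blocks$size, cfg$reference_length)
  }
  res <- run_condel_screen(b)
  expect_equal(nrow(res$candidates), 0)
})

test_that("evaluate_recovery implements the overlap conventions", {
  truth <- data.frame(truth_id = c("true_condel.1", "decoy_single_clade.2"),
                      chrom = "chr1", start = c(1000, 5000),
                      end = c(1199, 5100),
                      class = c("true_condel", "decoy_single_clade"),
                      expected_detected = c(TRUE, FALSE))
  exact <- data.frame(chrom = "chr1", start = 1000, end = 1199)
  ev <- evaluate_recovery(exact, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  # candidate overlapping only 40% of the truth is not recovered at 0.5
  partial <- data.frame(chrom = "chr1", start = 1000, end = 1079)
  ev40 <- evaluate_recovery(partial, truth)
  expect_equal(ev40$recall, 0)
  # zero candidates: recall 0, precision 1 with the zero flag set
  ev0 <- evaluate_recovery(data.frame(chrom = character(), start = integer(),
                                      end = integer()), truth)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)
  expect_true(ev0$zero_candidates)
})

test_that("truth intervals stay fully covered by outgroup conserved elements", {
  b <- simulate_study(small_cfg())
  qb <- non_n_bases(b$reference)
  tr <- b$truth[b$truth$class == "true_condel", ]
  tr_gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end))
  for (sp in sprintf("out%02d", 1:3)) {
    ce <- species_conserved_elements(b$chains[[sp]], b$reference,
                                     b$queries[[sp]], qb)
    covered <- interval_intersect(tr_gr, ce)
    expect_gte(total_coverage(covered) / total_coverage(tr_gr), 0.99)
  }
})
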