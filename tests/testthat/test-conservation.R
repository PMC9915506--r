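# build a chain plus sequences where the query differs from the reference at
# chosen reference positions (1-based)
ident_fixture <- function(ref_len = 60, mismatch_at = integer(),
                          blocks = data.frame(size = ref_len, dt = 0, dq = 0),
                          q_strand = "+") {
  ref <- random_dna(ref_len)
  ch <- make_chain(blocks, t_size = ref_len, q_strand = q_strand)
  # query covers the chain's blocks in order
  bc <- chain_block_coords(ch)
  q_parts <- lapply(seq_len(nrow(bc)), function(j) {
    seg <- substring(ref, bc$t_start[j] + 1, bc$t_start[j] + bc$size[j])
    c(seg, strrep("A", bc$dq[j]))
  })
  qry <- paste(unlist(q_parts), collapse = "")
  qry <- paste0(qry, strrep("G", ch$q_size - nchar(qry)))
  qv <- strsplit(qry, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  for (p in mismatch_at) {
    # locate the query offset aligned to reference position p
    j <- which(bc$t_start < p & p <= bc$t_start + bc$size)
    off <- bc$q_start[j] + (p - bc$t_start[j])
    qv[off] <- setdiff(c("A", "C", "G", "T"), rv[p])[1]
  }
  qry <- paste(qv, collapse = "")
  if (q_strand == "-")
    qry <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(qry)))
  list(chain = ch, ref = ref, qry = qry)
}

test_that("window identity counts exact matches, never spanning blocks", {
  cfg <- conservation_config(window_sizes = 10L)
  fx <- ident_fixture(10, mismatch_at = 4)
  w <- window_identity(fx$chain, fx$ref, fx$qry, cfg)
  expect_equal(nrow(w), 1)
  expect_equal(w$identity, 0.9)

  # 9-column block yields no 10-windows
  fx9 <- ident_fixture(9, blocks = data.frame(size = 9, dt = 0, dq = 0))
  expect_equal(nrow(window_identity(fx9$chain, fx9$ref, fx9$qry, cfg)), 0)

  # 12-column block, mismatches at 0-based columns 3 and 11
  fx12 <- ident_fixture(12, mismatch_at = c(4, 12),
                        blocks = data.frame(size = 12, dt = 0, dq = 0))
  w12 <- window_identity(fx12$chain, fx12$ref, fx12$qry, cfg)
  expect_equal(w12$identity, c(0.9, 0.9, 0.8))
  expect_equal(w12$start, 1:3)

  # windows never cross the separator between blocks
  fx2b <- ident_fixture(50, blocks = data.frame(size = c(25, 20),
                                                dt = c(5, 0), dq = c(0, 0)))
  w2b <- window_identity(fx2b$chain, fx2b$ref, fx2b$qry, cfg)
  expect_equal(nrow(w2b), (25 - 10 + 1) + (20 - 10 + 1))
  expect_true(all(w2b$identity == 1))
})

test_that("window identity is case-insensitive and N never matches", {
  ch <- make_chain(data.frame(size = 10, dt = 0, dq = 0), t_size = 10,
                   q_size = 10)
  ref <- "ACGTACGTAC"
  expect_equal(window_identity(ch, tolower(ref), ref,
                               conservation_config(window_sizes = 10L))$identity, 1)
  qN <- "ACGTNCGTAC"
  refN <- "ACGTNCGTAC"
  w <- window_identity(ch, refN, qN, conservation_config(window_sizes = 10L))
  expect_equal(w$identity, 0.9)  # N-N column does not match
})

test_that("window identity agrees with a per-column brute-force count", {
  set.seed(41)
  cfg <- conservation_config(window_sizes = c(5L, 9L))
  for (i in 1:40) {
    len <- sample(12:40, 1)
    fx <- ident_fixture(len, mismatch_at = sample(seq_len(len),
                                                  sample(0:5, 1)),
                        blocks = data.frame(size = len, dt = 0, dq = 0),
                        q_strand = sample(c("+", "-"), 1))
    w <- window_identity(fx$chain, fx$ref, fx$qry, cfg)
    rv <- strsplit(toupper(fx$ref), "")[[1]]
    qv <- strsplit(toupper(fx$qry), "")[[1]]
    if (fx$chain$q_strand == "-")
      qv <- rev(chartr("ACGT", "TGCA", qv))
    qv <- qv[seq_along(rv)]  # aligned portion only; the query is padded
    m <- rv == qv & rv != "N" & qv != "N"
    for (j in seq_len(nrow(w))) {
      expect_equal(w$matches[j], sum(m[w$start[j]:(w$start[j] + w$width[j] - 1)]))
    }
  }
})

test_that("sequence shorter than chain coordinates raises a coordinate error", {
  ch <- make_chain(data.frame(size = 100, dt = 0, dq = 0), t_size = 100,
                   q_size = 100)
  expect_error(window_identity(ch, random_dna(50), random_dna(100)),
               "shorter")
  expect_error(window_identity(ch, random_dna(100), random_dna(50)),
               "q_size")
})

test_that("quota selection accumulates top windows with tie inclusion", {
  # reference 1000 bases -> quota 50; A (30 bases, id 1.0) and B (30, 0.95)
  w <- data.frame(chrom = "chr1",
                  start = c(100, 200, 300, 400),
                  width = c(30, 30, 30, 30),
                  matches = c(30, 28.5, 27, 27),
                  identity = c(1.0, 0.95, 0.9, 0.9))
  got <- select_conserved_elements(w, 1000)
  expect_equal(gr_chr(got), c("chr1:100-129", "chr1:200-229"))
  expect_equal(total_coverage(got), 60)

  # insufficient supply: all selected
  w2 <- data.frame(chrom = "chr1", start = c(10, 100), width = c(20, 20),
                   matches = c(18, 18), identity = c(0.9, 0.9))
  expect_equal(total_coverage(select_conserved_elements(w2, 1000)), 40)

  # ties with the stopping window are all included
  w3 <- data.frame(chrom = "chr1", start = c(100, 200, 300, 400),
                   width = 30, matches = 27, identity = 0.9)
  got3 <- select_conserved_elements(w3, 1000)  # quota 50 reached at 2nd
  expect_equal(total_coverage(got3), 120)      # but ties pull in all four

  # selected windows 15 bases apart merge into one element
  w4 <- data.frame(chrom = "chr1", start = c(100, 145), width = 30,
                   matches = 30, identity = 1.0)
  expect_equal(gr_chr(select_conserved_elements(w4, 1000)), "chr1:100-174")
})

test_that("selection is invariant to input window order", {
  set.seed(43)
  w <- data.frame(chrom = "chr1", start = sample(1:5000, 300),
                  width = sample(c(10L, 25L, 50L), 300, TRUE))
  w$matches <- round(w$width * runif(300, 0.5, 1))
  w$identity <- w$matches / w$width
  a <- select_conserved_elements(w, 10000)
  b <- select_conserved_elements(w[sample(nrow(w)), ], 10000)
  expect_equal(gr_chr(a), gr_chr(b))
})

test_that("selection equals an independent rank-accumulation oracle", {
  set.seed(47)
  accumulation_oracle <- function(w, ref_bases, cfg = conservation_config()) {
    quota <- cfg$coverage_fraction * ref_bases
    lv <- sort(unique(w$identity), decreasing = TRUE)
    cov_of <- function(cut) {
      sel <- w$identity >= cut
      gr <- GenomicRanges::GRanges(w$chrom[sel],
                                   IRanges::IRanges(w$start[sel],
                                                    width = w$width[sel]))
      sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
    }
    cut <- lv[length(lv)]
    for (l in lv) if (cov_of(l) >= quota) { cut <- l; break }
    sel <- w$identity >= cut
    gr <- GenomicRanges::GRanges(w$chrom[sel],
                                 IRanges::IRanges(w$start[sel],
                                                  width = w$width[sel]))
    merge_within(GenomicRanges::reduce(gr), cfg$merge_distance)
  }
  for (i in 1:25) {
    w <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                    start = sample(1:3000, 200),
                    width = sample(c(10L, 25L), 200, TRUE))
    w$matches <- round(w$width * runif(200, 0.3, 1))
    w$identity <- w$matches / w$width
    quota_base <- sample(c(2000, 4000, 100000), 1)
    got <- select_conserved_elements(w, quota_base)
    expect_equal(gr_chr(got), gr_chr(accumulation_oracle(w, quota_base)))
    # final coverage meets the quota whenever the supply permits
    supply <- sum(GenomicRanges::width(GenomicRanges::reduce(
      GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start, width = w$width)))))
    if (supply >= 0.05 * quota_base)
      expect_gte(total_coverage(got), 0.05 * quota_base)
  }
})

test_that("zero divergence puts every aligned base under a smallest window", {
  fx <- ident_fixture(200, blocks = data.frame(size = c(120, 60),
                                               dt = c(20, 0), dq = c(0, 0)))
  cfg <- conservation_config()
  w <- window_identity(fx$chain, fx$ref, fx$qry, cfg)
  expect_true(all(w$identity == 1))
  w10 <- w[w$width == 10, ]
  cov10 <- GenomicRanges::reduce(GenomicRanges::GRanges(
    w10$chrom, IRanges::IRanges(w10$start, width = w10$width)))
  expect_equal(sum(GenomicRanges::width(cov10)), 120 + 60)
})
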