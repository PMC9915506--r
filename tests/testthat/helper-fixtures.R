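# Shared fixture builders. All coordinates in chain space are 0-based
# half-open (the on-disk convention); GRanges fixtures are 1-based closed.

# interval set from 0-based half-open pairs on one chromosome
iv0 <- function(starts, ends, chrom = "chr1") {
  interval_set(rep(chrom, length(starts)), starts, ends, zero_based = TRUE)
}

# flatten a GRanges to a character representation for exact comparisons
gr_chr <- function(gr) {
  gr <- normalize_intervals(gr)
  if (!length(gr)) return(character(0))
  sort(paste0(as.character(GenomicRanges::seqnames(gr)), ":",
              GenomicRanges::start(gr), "-", GenomicRanges::end(gr)))
}

# per-base oracle: explicit position sets (1-based), keyed by chromosome
positions_of <- function(gr) {
  gr <- normalize_intervals(gr)
  out <- list()
  for (i in seq_along(gr)) {
    chr <- as.character(GenomicRanges::seqnames(gr))[i]
    out[[chr]] <- c(out[[chr]],
                    GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i])
  }
  lapply(out, sort)
}

granges_from_positions <- function(pos_list) {
  if (!length(pos_list)) return(GenomicRanges::GRanges())
  grs <- lapply(names(pos_list), function(chr) {
    p <- sort(unique(pos_list[[chr]]))
    if (!length(p)) return(GenomicRanges::GRanges())
    brk <- c(0, which(diff(p) > 1), length(p))
    GenomicRanges::GRanges(chr, IRanges::IRanges(
      start = p[brk[-length(brk)] + 1], end = p[brk[-1]]))
  })
  normalize_intervals(suppressWarnings(do.call(c, grs)))
}

# random small interval set with coordinates < 1000
random_set <- function(n_max = 8, chroms = "chr1") {
  n <- sample(0:n_max, 1)
  if (n == 0) return(GenomicRanges::GRanges())
  s <- sample(1:950, n, replace = TRUE)
  w <- sample(1:50, n, replace = TRUE)
  normalize_intervals(
    GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                           IRanges::IRanges(s, width = w)))
}

# minimal chain builder from block table (chain-space coordinates)
make_chain <- function(blocks, t_name = "refA", t_size = NULL, t_start = 0,
                       q_name = "qA", q_size = NULL, q_strand = "+",
                       q_start = 0, score = 100, id = 1) {
  blocks <- as.data.frame(blocks)
  t_span <- sum(blocks$size + blocks$dt)
  q_span <- sum(blocks$size + blocks$dq)
  if (is.null(t_size)) t_size <- t_start + t_span + 10
  if (is.null(q_size)) q_size <- q_start + q_span + 10
  chain(score = score, t_name = t_name, t_size = t_size, t_start = t_start,
        t_end = t_start + t_span, q_name = q_name, q_size = q_size,
        q_strand = q_strand, q_start = q_start, q_end = q_start + q_span,
        id = id, blocks = blocks)
}

# random valid chain for round-trip tests
random_chain <- function(id = 1) {
  n <- sample(1:8, 1)
  size <- sample(1:500, n, replace = TRUE)
  dt <- c(sample(0:100, n - 1, replace = TRUE), 0)[seq_len(n)]
  dq <- c(sample(0:100, n - 1, replace = TRUE), 0)[seq_len(n)]
  if (n > 1) {
    both0 <- which(dt[-n] == 0 & dq[-n] == 0)
    dt[both0] <- 1
    dt[n] <- 0; dq[n] <- 0
  }
  t_start <- sample(0:1000, 1)
  q_start <- sample(0:1000, 1)
  make_chain(data.frame(size = size, dt = dt, dq = dq),
             t_name = sample(c("chr1", "chr2"), 1),
             t_size = t_start + sum(size + dt) + sample(0:500, 1),
             t_start = t_start,
             q_name = "scafQ",
             q_size = q_start + sum(size + dq) + sample(0:500, 1),
             q_strand = sample(c("+", "-"), 1), q_start = q_start,
             score = sample(1:100000, 1), id = id)
}

# simple single-gene model
make_gene <- function(gene_id = "gA", chrom = "chr1", strand = "+",
                      start = 1000, end = 2000,
                      exons = IRanges::IRanges(c(1000, 1800), c(1200, 2000))) {
  gene_model(gene_id, chrom, strand,
             stats::setNames(list(list(start = start, end = end,
                                       exons = exons)),
                             paste0(gene_id, ".t1")))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent Boschloo oracle: naive double loop over all tables,
# grid-only nuisance maximum
boschloo_oracle <- function(a, m, b, n, grid_points = 199L,
                            alternative = "greater") {
  f <- function(x, y) {
    s <- x + y
    if (alternative == "greater")
      stats::phyper(x - 1, m, n, s, lower.tail = FALSE)
    else stats::phyper(x, m, n, s, lower.tail = TRUE)
  }
  obs <- f(a, b)
  best <- 0
  for (pi in seq_len(grid_points) / (grid_points + 1)) {
    tot <- 0
    for (A in 0:m) for (B in 0:n) {
      if (f(A, B) <= obs * (1 + 1e-12))
        tot <- tot + stats::dbinom(A, m, pi) * stats::dbinom(B, n, pi)
    }
    best <- max(best, tot)
  }
  min(1, best)
}
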