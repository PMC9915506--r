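#' Construct a pairwise alignment chain
#'
#' A chain describes one pairwise alignment between a query assembly and the
#' reference: a header carrying coordinates and strands for both sides, plus
#' an ordered list of ungapped blocks. Between consecutive blocks, `dt` bases
#' of the reference and `dq` bases of the query are unaligned; the final block
#' has `dt = dq = 0`. Coordinates follow the UCSC chain convention: 0-based,
#' half-open, given on the stated strand of each sequence (the reference
#' strand is always `+`).
#'
#' @param score alignment score (arbitrary units).
#' @param t_name,t_size,t_start,t_end reference sequence name, length and
#'   aligned span. The reference strand is always "+".
#' @param q_name,q_size,q_strand,q_start,q_end query side; `q_strand` is "+"
#'   or "-", and `q_start`/`q_end` are on that strand.
#' @param id chain identifier (integer-like).
#' @param blocks data.frame with columns `size`, `dt`, `dq`.
#' @return An object of class `"chain"`.
#' @export
chain <- function(score, t_name, t_size, t_start, t_end,
                  q_name, q_size, q_strand, q_start, q_end, id, blocks) {
  obj <- structure(list(
    score = as.numeric(score),
    t_name = as.character(t_name), t_size = as.numeric(t_size),
    t_strand = "+",
    t_start = as.numeric(t_start), t_end = as.numeric(t_end),
    q_name = as.character(q_name), q_size = as.numeric(q_size),
    q_strand = as.character(q_strand),
    q_start = as.numeric(q_start), q_end = as.numeric(q_end),
    id = as.numeric(id),
    blocks = data.frame(size = as.numeric(blocks$size),
                        dt = as.numeric(blocks$dt),
                        dq = as.numeric(blocks$dq))
  ), class = "chain")
  validate_chain(obj)
  obj
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain %s> %s:%s-%s (+) ~ %s:%s-%s (%s), %d block(s), score %s\n",
              fmt_num(x$id), x$t_name, fmt_num(x$t_start), fmt_num(x$t_end),
              x$q_name, fmt_num(x$q_start), fmt_num(x$q_end), x$q_strand,
              nrow(x$blocks), fmt_num(x$score)))
  invisible(x)
}

validate_chain <- function(x, where = "") {
  b <- x$blocks
  err <- function(...) stop("invalid chain", where, ": ", ..., call. = FALSE)
  if (nrow(b) < 1L) err("chain has no blocks")
  if (any(b$size <= 0)) err("every block size must be > 0")
  if (any(b$dt < 0) || any(b$dq < 0)) err("negative gap length")
  n <- nrow(b)
  if (b$dt[n] != 0 || b$dq[n] != 0) err("final block must have dt = dq = 0")
  if (n > 1L && any(b$dt[-n] == 0 & b$dq[-n] == 0))
    err("non-final separator with dt = 0 and dq = 0")
  if (!(x$q_strand %in% c("+", "-"))) err("query strand must be '+' or '-'")
  if (!(x$t_start >= 0 && x$t_start < x$t_end && x$t_end <= x$t_size))
    err("reference span outside [0, t_size]")
  if (!(x$q_start >= 0 && x$q_start < x$q_end && x$q_end <= x$q_size))
    err("query span outside [0, q_size]")
  if (sum(b$size + b$dt) != x$t_end - x$t_start)
    err("block sum (size + dt) does not equal reference span")
  if (sum(b$size + b$dq) != x$q_end - x$q_start)
    err("block sum (size + dq) does not equal query span")
  invisible(x)
}

#' Parse UCSC chain-format text
#'
#' Records start with a `chain` header line
#' (`chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id`), followed by block lines `size dt dq` and a final line with a
#' bare `size`; records are separated by blank lines. Every record is
#' validated against the chain invariants (block sums versus header spans,
#' non-negative gaps, strand conventions); violations raise an error naming
#' the offending line.
#'
#' @param text chain-format text (single string or vector of lines).
#' @return A list of [chain()] objects, in file order.
#' @seealso [read_chain()], [write_chain()]
#' @export
parse_chain_text <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    header <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (header[1L] != "chain" || length(header) != 13L)
      stop("malformed chain header at line ", i,
           " (expected 13 fields starting with 'chain')")
    num <- suppressWarnings(as.numeric(header[c(2, 4, 6, 7, 9, 11, 12, 13)]))
    if (anyNA(num)) stop("non-numeric header field at line ", i)
    if (any(num[-1] < 0)) stop("negative coordinate in header at line ", i)
    hline <- i
    i <- i + 1L
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    repeat {
      if (i > n || !nzchar(trimws(lines[i])))
        stop("unterminated chain record starting at line ", hline)
      fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1L]]))
      if (anyNA(fields) || !(length(fields) %in% c(1L, 3L)))
        stop("malformed block line at line ", i)
      if (any(fields < 0)) stop("negative field in block line at line ", i)
      if (length(fields) == 3L) {
        sizes <- c(sizes, fields[1L]); dts <- c(dts, fields[2L]); dqs <- c(dqs, fields[3L])
        i <- i + 1L
      } else {
        sizes <- c(sizes, fields[1L]); dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1L
        break
      }
    }
    ch <- tryCatch(
      chain(score = num[1L], t_name = header[3L], t_size = num[2L],
            t_start = num[3L], t_end = num[4L],
            q_name = header[8L], q_size = num[5L], q_strand = header[10L],
            q_start = num[6L], q_end = num[7L], id = num[8L],
            blocks = data.frame(size = sizes, dt = dts, dq = dqs)),
      error = function(e) stop("record starting at line ", hline, ": ",
                               conditionMessage(e), call. = FALSE))
    if (header[5L] != "+")
      stop("reference strand must be '+' in record at line ", hline)
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Read a chain file
#'
#' @param path path to a chain-format file.
#' @return A list of [chain()] objects.
#' @export
read_chain <- function(path) {
  parse_chain_text(readLines(path))
}

fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Serialize chains to canonical chain-format text
#'
#' The canonical form uses single spaces in headers, tab-free block lines and
#' one blank line after every record, so that `parse -> write -> parse` is a
#' fixed point and `write(parse(text))` is byte-identical for canonical input.
#'
#' @param chains a list of [chain()] objects (or a single chain).
#' @return A single string of chain-format text.
#' @export
format_chain <- function(chains) {
  if (inherits(chains, "chain")) chains <- list(chains)
  rec <- vapply(chains, function(x) {
    validate_chain(x)
    b <- x$blocks
    n <- nrow(b)
    header <- paste("chain", fmt_num(x$score), x$t_name, fmt_num(x$t_size), "+",
                    fmt_num(x$t_start), fmt_num(x$t_end),
                    x$q_name, fmt_num(x$q_size), x$q_strand,
                    fmt_num(x$q_start), fmt_num(x$q_end), fmt_num(x$id))
    body <- if (n > 1L)
      c(paste(fmt_num(b$size[-n]), fmt_num(b$dt[-n]), fmt_num(b$dq[-n])),
        fmt_num(b$size[n]))
    else fmt_num(b$size[n])
    paste0(paste(c(header, body), collapse = "\n"), "\n")
  }, character(1))
  paste(rec, collapse = "\n")
}

#' Write chains to a file
#'
#' @param chains a list of [chain()] objects.
#' @param path output path.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(format_chain(chains), con, sep = "")
  invisible(path)
}

#' Map a query-strand interval to the query plus strand
#'
#' Chain query coordinates are given on the chain's stated query strand. To
#' compare chain gaps with assembly N-runs (detected on the stored, plus
#' strand sequence), minus-strand coordinates are reflected:
#' `start' = q_size - end`, `end' = q_size - start`. Coordinates here are
#' 0-based half-open (chain space); zero-length intervals are allowed.
#'
#' @param chain a [chain()] object.
#' @param q_start,q_end 0-based half-open interval on the chain's query strand.
#' @return Numeric `c(start, end)`, 0-based half-open on the plus strand.
#' @export
query_interval_on_plus <- function(chain, q_start, q_end) {
  stopifnot(q_end >= q_start)
  if (q_start < 0 || q_end > chain$q_size)
    stop("query interval outside [0, q_size]")
  if (chain$q_strand == "+") c(q_start, q_end)
  else c(chain$q_size - q_end, chain$q_size - q_start)
}

#' Per-block coordinates of a chain
#'
#' Walks the block list and returns, for every ungapped block, its reference
#' and query start offsets (0-based, chain space) together with the gap
#' lengths that follow it.
#'
#' @param chain a [chain()] object.
#' @return data.frame with columns `t_start`, `q_start`, `size`, `dt`, `dq`.
#' @export
chain_block_coords <- function(chain) {
  b <- chain$blocks
  step_t <- cumsum(c(0, (b$size + b$dt)[-nrow(b)]))
  step_q <- cumsum(c(0, (b$size + b$dq)[-nrow(b)]))
  data.frame(t_start = chain$t_start + step_t,
             q_start = chain$q_start + step_q,
             size = b$size, dt = b$dt, dq = b$dq)
}

#' Total aligned bases of a chain
#'
#' @param chain a [chain()] object.
#' @return Sum of block sizes.
#' @export
chain_aligned_bases <- function(chain) sum(chain$blocks$size)
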