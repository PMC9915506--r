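#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: the q-value of the i-th smallest p-value is
#' `min_{j >= i} p_(j) * n / j`, clipped at 1, returned in the input order.
#' Delegates to `stats::p.adjust(method = "BH")`, which implements exactly
#' this formula.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Binomial over-representation test for gene sets
#'
#' For each annotation term with `K` background genes out of `N`, and `k`
#' observed among the `s` study genes, reports `expected = s * K / N`,
#' `fold = k / expected`, the upper-tail exact binomial p-value
#' `P(X >= k)` with `X ~ Binomial(s, K / N)`, and Benjamini-Hochberg
#' q-values across all tested terms. One-sided over-representation only;
#' terms absent from the annotation table are skipped, and terms with zero
#' background genes are rejected by construction of the table.
#'
#' @param study_genes character vector of study gene ids; must be a subset
#'   of the background.
#' @param annotations data.frame with columns `gene_id`, `term_id`.
#' @param background character vector of background gene ids; defaults to
#'   all genes in `annotations`. Every annotated gene must be in the
#'   background.
#' @return data.frame with columns `term_id`, `observed`, `background_count`,
#'   `expected`, `fold`, `p`, `q`, sorted by `p`.
#' @export
binomial_enrichment <- function(study_genes, annotations, background = NULL) {
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "term_id") %in% names(annotations)))
  if (is.null(background)) background <- unique(annotations$gene_id)
  background <- unique(background)
  if (!all(annotations$gene_id %in% background))
    stop("every annotated gene must be in the background")
  study_genes <- unique(study_genes)
  if (!length(study_genes)) stop("empty study set")
  if (!all(study_genes %in% background))
    stop("study genes must be a subset of the background")
  annotations <- unique(annotations[, c("gene_id", "term_id")])
  N <- length(background)
  s <- length(study_genes)
  terms <- unique(annotations$term_id)
  rows <- lapply(terms, function(tm) {
    genes <- annotations$gene_id[annotations$term_id == tm]
    K <- length(genes)
    k <- sum(study_genes %in% genes)
    expected <- s * K / N
    p <- stats::pbinom(k - 1, size = s, prob = K / N, lower.tail = FALSE)
    data.frame(term_id = tm, observed = k, background_count = K,
               expected = expected,
               fold = if (expected > 0) k / expected else NA_real_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$term_id), , drop = FALSE]
}

fisher_one_sided <- function(A, B, m, n, alternative) {
  s <- A + B
  if (alternative == "greater")
    stats::phyper(A - 1, m, n, s, lower.tail = FALSE)
  else
    stats::phyper(A, m, n, s, lower.tail = TRUE)
}

boschloo_one_sided <- function(a, m, b, n, alternative, grid_points, refine) {
  A <- 0:m
  B <- 0:n
  # Fisher one-sided p for every possible table (A, B), as the test statistic
  stat <- outer(A, B, function(x, y) fisher_one_sided(x, y, m, n, alternative))
  obs <- fisher_one_sided(a, b, m, n, alternative)
  reject <- stat <= obs * (1 + 1e-12)
  size_at <- function(pi) {
    pa <- stats::dbinom(A, m, pi)
    pb <- stats::dbinom(B, n, pi)
    as.numeric(pa %*% reject %*% pb)
  }
  grid <- seq_len(grid_points) / (grid_points + 1)
  sizes <- vapply(grid, size_at, numeric(1))
  best <- which.max(sizes)
  p <- sizes[best]
  if (refine) {
    h <- 1 / (grid_points + 1)
    lo <- max(1e-12, grid[best] - h)
    hi <- min(1 - 1e-12, grid[best] + h)
    opt <- stats::optimize(size_at, c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    p <- max(p, opt$objective)
  }
  min(1, p)
}

#' Boschloo's exact unconditional test for a 2x2 table (two-tailed)
#'
#' Compares success proportions between two groups of fixed sizes `m` and
#' `n`. The one-sided test statistic is Fisher's exact one-sided p-value of
#' the observed table; the one-sided Boschloo p-value maximizes, over the
#' common success probability (the nuisance parameter, scanned on an evenly
#' spaced open grid with local refinement around the maximum), the
#' probability of observing a table at least as extreme. The two-tailed
#' p-value is twice the smaller one-sided value, capped at 1 - the doubling
#' convention of the statistics library used for the original analyses.
#' Boschloo's test is uniformly at least as powerful as Fisher's exact test.
#'
#' @param a,m successes and size of group 1.
#' @param b,n successes and size of group 2.
#' @param grid_points number of nuisance-parameter grid points (default 999).
#' @param alternative "two.sided" (default), "greater" (group 1 proportion
#'   larger) or "less".
#' @param refine locally refine around the grid maximum (default TRUE).
#' @return The p-value, in (0, 1].
#' @examples
#' \donttest{boschloo_two_tailed(14, 175, 1, 236)}
#' @export
boschloo_two_tailed <- function(a, m, b, n, grid_points = 999L,
                                alternative = c("two.sided", "greater", "less"),
                                refine = TRUE) {
  alternative <- match.arg(alternative)
  stopifnot(m >= 1, n >= 1, a >= 0, a <= m, b >= 0, b <= n)
  if (alternative == "greater")
    return(boschloo_one_sided(a, m, b, n, "greater", grid_points, refine))
  if (alternative == "less")
    return(boschloo_one_sided(a, m, b, n, "less", grid_points, refine))
  pg <- boschloo_one_sided(a, m, b, n, "greater", grid_points, refine)
  pl <- boschloo_one_sided(a, m, b, n, "less", grid_points, refine)
  min(1, 2 * min(pg, pl))
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact permutation null when both
#' samples are small and untied, otherwise the normal approximation with tie
#' and continuity corrections. Thin wrapper over `stats::wilcox.test`, which
#' implements both regimes; the U statistic reported is the number of (x, y)
#' pairs with x > y (plus half the ties).
#'
#' @param x,y numeric samples (non-empty).
#' @return list with elements `U` and `p`.
#' @examples
#' mann_whitney_u_two_tailed(c(1, 2), c(3, 4))
#' @export
mann_whitney_u_two_tailed <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
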