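#' Collapse significant probesets to gene calls
#'
#' Probesets with no mapping entry (or an explicitly empty one) are counted
#' as unmapped; probesets mapping to a single gene are pooled into the
#' unique-gene set; probesets mapping to several genes are recorded as
#' composite matchings (symbols joined by `" /// "`, platform convention)
#' and excluded from the unique-gene set, so overlap tests against curated
#' lists use unambiguous calls only.
#'
#' @param probesets character vector of (significant) probeset ids.
#' @param mapping named list probeset -> character vector of gene symbols,
#'   as returned by [readGeneMapping()].
#' @return a list of class `GeneCallSummary`:
#'   \item{unique_genes}{sorted character vector;}
#'   \item{multi_matching}{sorted composite matchings;}
#'   \item{unmapped_probeset_count}{integer.}
#' @export
collapseToGenes <- function(probesets, mapping) {
  stopifnot(is.character(probesets), is.list(mapping))
  hits <- mapping[probesets]
  n_genes <- vapply(hits, function(g) if (is.null(g)) 0L else length(g),
                    integer(1))
  unique_genes <- sort(unique(unlist(hits[n_genes == 1L], use.names = FALSE)))
  multi <- sort(unique(vapply(hits[n_genes > 1L],
                              function(g) paste(sort(g), collapse = " /// "),
                              character(1))))
  out <- list(unique_genes = unique_genes, multi_matching = multi,
              unmapped_probeset_count = sum(n_genes == 0L))
  class(out) <- "GeneCallSummary"
  out
}

#' @export
print.GeneCallSummary <- function(x, ...) {
  cat("GeneCallSummary:", length(x$unique_genes), "unique genes,",
      length(x$multi_matching), "multiple matchings,",
      x$unmapped_probeset_count, "unmapped probesets\n")
  invisible(x)
}

#' Hypergeometric overlap test
#'
#' Tail probability of drawing, from a universe of `N` genes containing a
#' category of `K`, a list of `n` genes whose overlap with the category is
#' `k` or larger: \eqn{p = P(X \ge k)} for
#' \eqn{X \sim Hypergeom(N, K, n)}. Evaluated in log space
#' (\code{phyper(log.p = TRUE)}) so extreme tails keep full precision.
#'
#' @param N universe size.
#' @param K category size (`K <= N`).
#' @param n draw (query list) size (`n <= N`).
#' @param k observed overlap (`k <= min(K, n)`).
#' @return a one-row data.frame of class `OverlapTest` with columns
#'   `universe_size`, `category_size`, `draw_size`, `overlap`, `p_value`,
#'   and `log_p` (natural log of the upper tail).
#' @examples
#' hypergeometricOverlap(23437, 1367, 1285, 135)
#' @export
hypergeometricOverlap <- function(N, K, n, k) {
  N <- assert_count(N, "N"); K <- assert_count(K, "K", min = 0L)
  n <- assert_count(n, "n"); k <- assert_count(k, "k", min = 0L)
  if (K > N) stop("category size K exceeds universe size N")
  if (n > N) stop("draw size n exceeds universe size N")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  log_p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  out <- data.frame(universe_size = N, category_size = K, draw_size = n,
                    overlap = k, p_value = exp(log_p), log_p = log_p)
  class(out) <- c("OverlapTest", class(out))
  out
}

#' Over/under-representation of a gene list against gene sets
#'
#' For each gene set, intersected with the universe first, both the
#' upper-tail (over-representation, \eqn{P(X \ge k)}) and lower-tail
#' (under-representation, \eqn{P(X \le k)}) hypergeometric probabilities
#' are computed; Benjamini-Hochberg adjustment is applied across all
#' set-by-direction tests and significance called at `alpha`.
#'
#' @param genes character vector, the query list; must be a subset of
#'   `universe`.
#' @param gene_sets named list of character vectors (see
#'   [readGeneSetsGMT()]).
#' @param universe character vector, the gene universe.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per set and direction: `set`,
#'   `direction` (`"over"`/`"under"`), `universe_size`, `category_size`,
#'   `draw_size`, `overlap`, `p_value`, `p_adjusted`, `significant`.
#' @export
overrepresentation <- function(genes, gene_sets, universe, alpha = 0.05) {
  stopifnot(is.character(genes), is.list(gene_sets), is.character(universe))
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  universe <- unique(universe)
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(head(outside, 10L), collapse = ", "))
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    cat_genes <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(cat_genes)
    k <- length(intersect(genes, cat_genes))
    p_over <- exp(phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
    p_under <- exp(phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE))
    data.frame(set = nm, direction = c("over", "under"),
               universe_size = N, category_size = K, draw_size = n,
               overlap = k, p_value = c(p_over, p_under),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bhAdjust(pmin(out$p_value, 1))
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
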