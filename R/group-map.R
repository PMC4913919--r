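#' Average-correlation similarity between biological groups
#'
#' For each pair of biological groups \eqn{G_m, G_n}, the similarity is the
#' average over all sample pairs \eqn{(s \in G_m, s' \in G_n)} of the
#' Pearson correlation between their expression profiles across probesets:
#' \deqn{similarity(G_m, G_n) = \frac{\sum_{s_{mi} \in G_m} \sum_{s_{nj} \in
#'   G_n} cor(s_{mi}, s_{nj})}{|G_m| |G_n|}.}
#' The diagonal is computed by the same formula, so it includes self-pairs
#' (correlation 1) and is generally below 1 for heterogeneous groups; it is
#' reported but ignored by [clusterGroups()].
#'
#' @param es an [AnnotatedExpressionSet-class] with at least two probesets.
#' @return a symmetric numeric matrix, one row/column per biological group
#'   (lexicographic order), entries in \eqn{[-1, 1]}.
#' @export
groupSimilarity <- function(es) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  v <- exprValues(es)
  if (nrow(v) < 2L)
    stop("at least two probesets are needed for sample-profile correlations")
  sds <- apply(v, 2L, sd)
  if (any(sds == 0))
    stop("sample(s) with zero variance across probesets: ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  C <- cor(v)   # sample x sample Pearson correlations across probesets
  grp <- factor(biologicalGroup(es))
  G <- nlevels(grp)
  ind <- diag(G)[as.integer(grp), , drop = FALSE]  # samples x groups indicator
  counts <- colSums(ind)
  S <- crossprod(ind, C %*% ind) / outer(counts, counts)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(levels(grp), levels(grp))
  S
}

#' Group-mean (dimension-reduced) expression matrix
#'
#' \eqn{Y_{mn}}: the mean expression of probeset \eqn{p_m} over the samples
#' of biological group \eqn{G_n}. The probesets-by-groups matrix used for
#' biclustering probesets against groups.
#'
#' @param es an [AnnotatedExpressionSet-class].
#' @return numeric matrix, probesets x groups (groups lexicographic).
#' @export
groupMeanMatrix <- function(es) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  v <- exprValues(es)
  grp <- factor(biologicalGroup(es))
  m <- t(rowsum(t(v), grp) / as.vector(table(grp)))
  dimnames(m) <- list(rownames(v), levels(grp))
  m
}

#' Hierarchical clustering of biological groups
#'
#' Agglomerative clustering of groups on the distance \eqn{d = 1 -
#' similarity}, with the diagonal ignored. The linkage is selectable;
#' average linkage is the default for correlation-based expression maps.
#'
#' @param sim symmetric group-similarity matrix from [groupSimilarity()].
#' @param linkage one of `"average"`, `"complete"`, `"single"`.
#' @return an object of class [stats::hclust]; leaf labels are the group
#'   names.
#' @seealso [exportNewick()] to serialize the tree.
#' @export
clusterGroups <- function(sim, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!is.matrix(sim) || nrow(sim) != ncol(sim) ||
      max(abs(sim - t(sim))) > 1e-8)
    stop("'sim' must be a symmetric similarity matrix")
  if (nrow(sim) < 2L) stop("need at least two groups to cluster")
  if (is.null(rownames(sim))) rownames(sim) <- colnames(sim) <-
      paste0("G", seq_len(nrow(sim)))
  d <- as.dist(1 - sim)
  hclust(d, method = linkage)
}

#' Write a dendrogram as Newick text
#'
#' @param hc an [stats::hclust] tree, e.g. from [clusterGroups()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
exportNewick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal-component map of samples
#'
#' PCA with samples as statistical units and probesets as variables,
#' centred but not scaled (standard practice for log2 expression). Each
#' component axis is oriented so that its largest-magnitude probeset
#' loading is positive, making the sign convention reproducible.
#'
#' @param es an [AnnotatedExpressionSet-class].
#' @param k number of components to return (at most `min(samples,
#'   probesets)`). Components beyond the matrix rank are zero-padded and
#'   flagged in attribute `"padded"`.
#' @return a list of class `PcaMap`:
#'   \item{scores}{samples x k matrix of projections;}
#'   \item{variance_fractions}{length-k shares of total variance
#'     (non-increasing, summing to at most 1);}
#'   \item{loadings}{probesets x k rotation matrix.}
#' @export
pcaMap <- function(es, k = 3L) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  k <- assert_count(k, "k")
  v <- exprValues(es)
  if (k > min(dim(v)))
    stop("k = ", k, " exceeds min(samples, probesets) = ", min(dim(v)))
  pc <- prcomp(t(v), center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  avail <- ncol(pc$x)
  kk <- min(k, avail)
  scores <- pc$x[, seq_len(kk), drop = FALSE]
  load <- pc$rotation[, seq_len(kk), drop = FALSE]
  flip <- vapply(seq_len(kk), function(j) {
    l <- load[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  load <- sweep(load, 2L, flip, `*`)
  vf <- pc$sdev[seq_len(kk)]^2 / total_var
  padded <- k > kk
  if (padded) {
    scores <- cbind(scores, matrix(0, nrow(scores), k - kk))
    load <- cbind(load, matrix(0, nrow(load), k - kk))
    vf <- c(vf, rep(0, k - kk))
  }
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  out <- list(scores = scores, variance_fractions = vf, loadings = load)
  attr(out, "padded") <- padded
  class(out) <- "PcaMap"
  out
}

#' @export
print.PcaMap <- function(x, ...) {
  cat("PcaMap:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.4f", x$variance_fractions), collapse = " "), "\n")
  invisible(x)
}
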