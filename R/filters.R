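#' Keep samples from sufficiently large biological groups
#'
#' Retains exactly the samples whose biological group has at least `min_n`
#' members in the input compendium. Used before group-level clustering so
#' every group mean rests on a reasonable sample size.
#'
#' @param es an [AnnotatedExpressionSet-class]
#' @param min_n minimum group size (default 20, the size used for the
#'   compendium map).
#' @return the filtered [AnnotatedExpressionSet-class]; probesets unchanged.
#'   Idempotent: a second application is a no-op.
#' @export
filterMinGroupSize <- function(es, min_n = 20L) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  min_n <- assert_count(min_n, "min_n")
  grp <- biologicalGroup(es)
  sizes <- table(grp)
  keep_groups <- names(sizes)[sizes >= min_n]
  if (!length(keep_groups))
    stop("no biological group has at least ", min_n, " samples")
  es[, grp %in% keep_groups]
}

#' Build the paired cancer/normal tissue subset
#'
#' Retains samples from tissues carrying at least `min_n` normal and at
#' least `min_n` cancer samples; samples with disease status `"other"` are
#' dropped first. The returned samples are ordered by tissue
#' (lexicographically), then disease status (cancer before normal), then
#' original order, so repeated runs give identical column order.
#'
#' @inheritParams filterMinGroupSize
#' @return the paired-subset [AnnotatedExpressionSet-class].
#' @export
selectPairedTissues <- function(es, min_n = 20L) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  min_n <- assert_count(min_n, "min_n")
  ds <- diseaseStatus(es)
  keep <- ds %in% c("normal", "cancer")
  es2 <- es[, keep]
  tis <- tissueType(es2)
  ds2 <- diseaseStatus(es2)
  counts <- table(tis, factor(ds2, levels = c("normal", "cancer")))
  ok <- rownames(counts)[counts[, "normal"] >= min_n & counts[, "cancer"] >= min_n]
  if (!length(ok))
    stop("no tissue has at least ", min_n, " normal and ", min_n, " cancer samples")
  sel <- which(tis %in% ok)
  ord <- sel[order(tis[sel], factor(ds2[sel], levels = c("cancer", "normal")),
                   sel)]
  es2[, ord]
}

#' Keep the most variable probesets
#'
#' Keeps the `n` probesets with largest (unbiased) sample variance across
#' all currently retained samples; ties are broken by input probeset order.
#' Samples are unchanged. Used to sharpen the group-level map, mirroring the
#' probeset-reduction series n = 20000, 10000, 5000, 1000, 500.
#'
#' @param es an [AnnotatedExpressionSet-class]
#' @param n number of probesets to keep; must not exceed the probeset count.
#' @return the reduced [AnnotatedExpressionSet-class].
#' @export
selectMostVariable <- function(es, n) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  n <- assert_count(n, "n")
  if (n > nrow(es))
    stop("n = ", n, " exceeds the number of probesets (", nrow(es), ")")
  v <- exprValues(es)
  rv <- rowSums((v - rowMeans(v))^2) / (ncol(v) - 1L)
  keep <- sort(order(-rv, seq_along(rv))[seq_len(n)])
  # explicit index tiebreak keeps equal-variance probesets in input order;
  # sort() restores the original row order among the selected probesets
  es[keep, ]
}
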