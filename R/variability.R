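#' Per-probeset between-group variability statistics
#'
#' Computes, for each probeset \eqn{p} and a chosen grouping of the samples
#' into \eqn{G} groups of sizes \eqn{N_n}, the between-group variance
#' \deqn{BGV(p) = \frac{\sum_{n=1}^G N_n (\bar y_n(p) - \bar y(p))^2}{G-1},}
#' where \eqn{\bar y_n(p)} is the group mean and \eqn{\bar y(p)} the grand
#' mean over all samples (hence the size-weighted mean of the group means).
#' Group standard deviations \eqn{\sigma_n(p)} are also returned; by
#' default they use the population convention (divide by \eqn{N_n}) so
#' singleton groups get 0 rather than NA.
#'
#' @param es an [AnnotatedExpressionSet-class].
#' @param grouping which annotation defines the groups: one of
#'   `"tissue_status"` (the tissue-by-disease-status conditions, default for
#'   the paired subset), `"biological_group"`, `"tissue"`, or
#'   `"experiment"`.
#' @param sd_type `"population"` (divide by N, default) or `"sample"`
#'   (divide by N-1).
#' @return a list of class `VariabilityStats`:
#'   \item{probeset_ids}{character;}
#'   \item{bgv}{per-probeset non-negative BGV;}
#'   \item{group_means, group_sds}{probesets x groups matrices;}
#'   \item{grand_mean}{per-probeset grand mean;}
#'   \item{deviation_count}{per-probeset number of deviating groups (see
#'     [deviationGroupCount()]);}
#'   \item{group_sizes}{per-group sizes;}
#'   \item{n_groups}{G.}
#' @export
betweenGroupVariance <- function(es,
                                 grouping = c("tissue_status",
                                              "biological_group",
                                              "tissue", "experiment"),
                                 sd_type = c("population", "sample")) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  grouping <- match.arg(grouping)
  sd_type <- match.arg(sd_type)
  grp <- switch(grouping,
    tissue_status = paste(tissueType(es), diseaseStatus(es), sep = ":"),
    biological_group = biologicalGroup(es),
    tissue = tissueType(es),
    experiment = experimentId(es))
  grp <- factor(grp)
  G <- nlevels(grp)
  if (G < 2L) stop("grouping '", grouping, "' yields a single group")
  v <- exprValues(es)
  N <- as.vector(table(grp))
  sums <- t(rowsum(t(v), grp))            # probesets x groups
  means <- sweep(sums, 2L, N, `/`)
  grand <- rowMeans(v)
  dev2 <- (means - grand)^2
  bgv <- as.vector(dev2 %*% N) / (G - 1)
  sqsums <- t(rowsum(t(v^2), grp))
  ss_within <- sqsums - sweep(means^2, 2L, N, `*`)
  ss_within[ss_within < 0] <- 0           # numerical guard
  denom <- if (sd_type == "population") N else pmax(N - 1L, 1L)
  sds <- sqrt(sweep(ss_within, 2L, denom, `/`))
  if (sd_type == "sample") sds[, N == 1L] <- 0
  colnames(means) <- colnames(sds) <- levels(grp)
  out <- list(probeset_ids = rownames(v), bgv = setNames(bgv, rownames(v)),
              group_means = means, group_sds = sds,
              grand_mean = setNames(grand, rownames(v)),
              deviation_count = NULL,
              group_sizes = setNames(N, levels(grp)), n_groups = G)
  class(out) <- "VariabilityStats"
  out$deviation_count <- deviationGroupCount(out)
  out
}

#' @export
print.VariabilityStats <- function(x, ...) {
  cat("VariabilityStats:", length(x$bgv), "probesets,", x$n_groups, "groups\n")
  cat("  BGV range:", sprintf("[%.4g, %.4g]", min(x$bgv), max(x$bgv)), "\n")
  invisible(x)
}

#' Tukey upper-whisker threshold for drastically large BGV
#'
#' Flags probesets whose BGV exceeds the boxplot "maximum" whisker
#' \eqn{Q_3 + 1.5 \cdot IQR} of the BGV distribution (quartiles by the
#' linear-interpolation rule). These are the probesets whose expression
#' differs drastically across the conditions.
#'
#' @param stats a `VariabilityStats` from [betweenGroupVariance()] (at
#'   least 4 probesets).
#' @return a list with `threshold` (numeric) and `flags` (named logical,
#'   `TRUE` for BGV strictly above the threshold).
#' @export
bgvOutlierThreshold <- function(stats) {
  stopifnot(inherits(stats, "VariabilityStats"))
  if (length(stats$bgv) < 4L) stop("need at least 4 probesets")
  q <- quantile(stats$bgv, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2L] + 1.5 * (q[2L] - q[1L])
  list(threshold = threshold, flags = stats$bgv > threshold)
}

#' Count groups deviating from the grand mean
#'
#' For each probeset, counts the groups whose mean-plus/minus-SD band lies
#' strictly on one side of the grand mean: either
#' \eqn{\bar y_n(p) - \sigma_n(p) > \bar y(p)} or
#' \eqn{\bar y_n(p) + \sigma_n(p) < \bar y(p)}. A probeset with count 0
#' shows no clear expression change across any condition.
#'
#' @param stats a `VariabilityStats` from [betweenGroupVariance()].
#' @return named integer vector, one count in `[0, G]` per probeset.
#' @export
deviationGroupCount <- function(stats) {
  stopifnot(inherits(stats, "VariabilityStats"))
  above <- stats$group_means - stats$group_sds > stats$grand_mean
  below <- stats$group_means + stats$group_sds < stats$grand_mean
  counts <- rowSums(above | below)
  setNames(as.integer(counts), stats$probeset_ids)
}

#' Export variability statistics as TSV
#'
#' Writes probeset_id, bgv, deviation_count and outlier_flag columns.
#'
#' @param stats a `VariabilityStats`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeVariabilityTSV <- function(stats, path) {
  out <- bgvOutlierThreshold(stats)
  df <- data.frame(probeset_id = stats$probeset_ids, bgv = stats$bgv,
                   deviation_count = stats$deviation_count,
                   outlier_flag = out$flags, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
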