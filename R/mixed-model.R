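#' MixedModelFit: one probeset's crossed mixed-effects fit
#'
#' Result of fitting, by restricted maximum likelihood, the per-probeset
#' model
#' \deqn{y_{ijk} = \mu + \beta \cdot 1[i = cancer] + t_j + t_{ij} + e_k +
#'   e_{ik} + \epsilon_{ijk},}
#' with independent normal random intercepts for tissue, tissue-by-disease,
#' experiment and experiment-by-disease, and the disease status as the only
#' fixed effect beyond the intercept (indicator coding: 0 = normal,
#' 1 = cancer, so \eqn{\beta > 0} means higher expression in cancer).
#'
#' @slot beta_hat disease-effect estimate, log2 units.
#' @slot se_beta its standard error from generalized least squares at the
#'   estimated variance components.
#' @slot mu_hat intercept (mean normal-tissue level).
#' @slot varcomps named non-negative variances: `tissue`,
#'   `tissue_disease`, `experiment`, `experiment_disease`, `residual`.
#' @slot reml_criterion minus twice the restricted log-likelihood at the
#'   optimum.
#' @slot converged logical optimizer status.
#' @slot n_obs number of observations.
#' @seealso [fitProbeset()], [testDiseaseEffect()]
#' @export
setClass("MixedModelFit",
  representation(beta_hat = "numeric", se_beta = "numeric",
                 mu_hat = "numeric", varcomps = "numeric",
                 reml_criterion = "numeric", converged = "logical",
                 n_obs = "integer"))

setValidity("MixedModelFit", function(object) {
  msg <- character()
  if (length(object@varcomps) != 5L ||
      !identical(names(object@varcomps),
                 c("tissue", "tissue_disease", "experiment",
                   "experiment_disease", "residual")))
    msg <- c(msg, "varcomps must be the five named components")
  else {
    if (any(object@varcomps < 0)) msg <- c(msg, "variance components must be >= 0")
    if (object@varcomps[["residual"]] <= 0)
      msg <- c(msg, "residual variance must be positive")
  }
  if (object@converged && (is.na(object@se_beta) || object@se_beta <= 0))
    msg <- c(msg, "se_beta must be positive for a converged fit")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixedModelFit", function(object) {
  cat(sprintf("MixedModelFit (n = %d, %s)\n", object@n_obs,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  beta = %.4f (se %.4f), mu = %.4f\n", object@beta_hat,
              object@se_beta, object@mu_hat))
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(object@varcomps), object@varcomps),
            collapse = " "), "\n")
})

.VARCOMP_NAMES <- c("tissue", "tissue_disease", "experiment",
                    "experiment_disease", "residual")

# Build the fixed- and random-effect design for one labelling of the
# samples, with all crossproducts the profiled REML criterion needs.
# Everything downstream is O(q^3) per likelihood evaluation, independent of
# the number of samples.
.prepDesign <- function(tissue, experiment, disease) {
  tissue <- as.character(tissue)
  experiment <- as.character(experiment)
  disease <- as.character(disease)
  n <- length(tissue)
  stopifnot(length(experiment) == n, length(disease) == n)
  if (!all(disease %in% c("normal", "cancer")))
    stop("disease labels must be 'normal'/'cancer' (drop 'other' samples first)")
  tis_f <- factor(tissue)
  exp_f <- factor(experiment)
  dis <- as.numeric(disease == "cancer")
  if (nlevels(tis_f) < 2L) stop("factor 'tissue' has a single level")
  if (nlevels(exp_f) < 2L) stop("factor 'experiment' has a single level")
  if (length(unique(dis)) < 2L) stop("factor 'disease_status' has a single level")
  if (n <= 4L) stop("need more than 4 observations")
  td_f <- factor(paste(tissue, disease, sep = ":"))
  ed_f <- factor(paste(experiment, disease, sep = ":"))
  X <- cbind(`(Intercept)` = 1, cancer = dis)
  blocks <- list(tissue = tis_f, tissue_disease = td_f,
                 experiment = exp_f, experiment_disease = ed_f)
  Zl <- lapply(blocks, function(f) Matrix::t(Matrix::fac2sparse(f)))
  Z <- do.call(cbind, Zl)
  block_id <- rep(seq_along(blocks), vapply(Zl, ncol, integer(1)))
  q <- ncol(Z)
  # Group the random-effect columns into connected components: columns of
  # two factors are connected when some sample loads on both. Experiments
  # nest in tissues in practice, so the system matrix M = I + S Z'Z S is
  # block-diagonal by component (usually one small block per tissue) and
  # the REML evaluation factorizes blockwise; a genuinely crossed design
  # simply yields one large component and a dense factorization.
  offs <- cumsum(c(0L, vapply(Zl, ncol, integer(1L))))[1:4]
  cols <- cbind(as.integer(tis_f) + offs[1L], as.integer(td_f) + offs[2L],
                as.integer(exp_f) + offs[3L], as.integer(ed_f) + offs[4L])
  parent <- seq_len(q)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(cols))) {
    roots <- c(find(cols[r, 1L]), find(cols[r, 2L]), find(cols[r, 3L]),
               find(cols[r, 4L]))
    m <- min(roots)
    parent[roots] <- m
  }
  comp <- vapply(seq_len(q), find, integer(1))
  perm <- order(comp, seq_len(q))
  comp_sizes <- as.integer(table(factor(comp[perm], levels = unique(comp[perm]))))
  Z <- Z[, perm, drop = FALSE]
  block_id <- block_id[perm]
  list(n = n, X = X, Z = Z, block_id = block_id,
       block0 = block_id - 1L, comp_sizes = comp_sizes,
       XtX = crossprod(X), ZtX = as.matrix(Matrix::crossprod(Z, X)),
       ZtZ = as.matrix(Matrix::crossprod(Z)))
}

# Per-probeset sufficient statistics for a design: Z'y, X'y, y'y, computed
# for all probesets at once (Y is probesets x samples).
.probesetStats <- function(design, Y) {
  list(ZtY = as.matrix(Y %*% design$Z), XtY = Y %*% design$X,
       yty = rowSums(Y^2))
}

# Profiled REML evaluation at variance ratios gamma = sigma_r^2 / sigma^2.
# Returns the GLS solution and -2 restricted log-likelihood pieces.
.remlPieces <- function(gamma, design, zty, xty, yty) {
  s <- sqrt(gamma)[design$block_id]
  M <- design$ZtZ * tcrossprod(s)
  diag(M) <- diag(M) + 1
  C <- chol(M)
  A <- backsolve(C, cbind(design$ZtX, zty) * s, transpose = TRUE)
  XtViX <- design$XtX - crossprod(A[, 1:2, drop = FALSE])
  XtViy <- drop(crossprod(A[, 1:2, drop = FALSE], A[, 3L])) * -1 +
    drop(xty)
  ytViy <- yty - sum(A[, 3L]^2)
  det2 <- XtViX[1L] * XtViX[4L] - XtViX[2L]^2
  beta <- c(XtViX[4L] * XtViy[1L] - XtViX[2L] * XtViy[2L],
            XtViX[1L] * XtViy[2L] - XtViX[2L] * XtViy[1L]) / det2
  rss <- max(ytViy - sum(beta * XtViy), 1e-12)
  logdetM <- 2 * sum(log(diag(C)))
  list(beta = beta, rss = rss, logdetM = logdetM, logdet_xvx = log(det2),
       XtViX = XtViX)
}

.remlCriterion <- function(theta, design, zty, xty, yty) {
  .remlCritCpp(theta, design$ZtZ, cbind(design$ZtX, zty), design$XtX,
               as.numeric(xty), yty, design$block0, design$comp_sizes, design$n)
}

.LOG_LOWER <- log(1e-10)
.LOG_UPPER <- log(1e6)

# Fit one probeset given its sufficient statistics. Deterministic start:
# all variance ratios at 1 (every component at the method-of-moments
# residual scale). The criterion evaluation is compiled (src/reml.cpp);
# nlminb supplies the bound-constrained quasi-Newton iteration.
.fitCore <- function(design, zty, xty, yty, reltol = 1e-9,
                     start = rep(0, 4L)) {
  B0 <- cbind(design$ZtX, zty)
  xty <- as.numeric(xty)
  obj <- function(theta)
    .remlCritCpp(theta, design$ZtZ, B0, design$XtX, xty, yty,
                 design$block0, design$comp_sizes, design$n)
  opt <- nlminb(start, obj, lower = .LOG_LOWER, upper = .LOG_UPPER,
                control = list(rel.tol = reltol, iter.max = 300L,
                               eval.max = 600L))
  gamma <- exp(opt$par)
  pieces <- .remlPieces(gamma, design, zty, xty, yty)
  n <- design$n
  sigma2 <- pieces$rss / (n - 2)
  vc <- c(gamma * sigma2, sigma2)
  names(vc) <- .VARCOMP_NAMES
  # clamp ratios at the boundary to exact zero variance
  vc[1:4][gamma <= 1.0000001e-10] <- 0
  inv11 <- pieces$XtViX[1L] /
    (pieces$XtViX[1L] * pieces$XtViX[4L] - pieces$XtViX[2L]^2)
  se <- sqrt(sigma2 * inv11)
  crit <- (n - 2) * (1 + log(2 * pi * sigma2)) + pieces$logdetM +
    pieces$logdet_xvx
  list(beta = pieces$beta[2L], mu = pieces$beta[1L], se = se,
       varcomps = vc, criterion = crit, converged = opt$convergence == 0L,
       theta = opt$par)
}

# GLS at user-fixed variance components (no REML step); the residual
# variance is taken as given rather than profiled out.
.glsFixed <- function(design, zty, xty, yty, varcomps) {
  stopifnot(length(varcomps) == 5L, varcomps[5L] > 0)
  gamma <- pmax(varcomps[1:4] / varcomps[5L], 1e-10)
  pieces <- .remlPieces(gamma, design, zty, xty, yty)
  sigma2 <- varcomps[5L]
  vc <- setNames(as.numeric(varcomps), .VARCOMP_NAMES)
  inv11 <- pieces$XtViX[1L] /
    (pieces$XtViX[1L] * pieces$XtViX[4L] - pieces$XtViX[2L]^2)
  list(beta = pieces$beta[2L], mu = pieces$beta[1L],
       se = sqrt(sigma2 * inv11), varcomps = vc,
       criterion = NA_real_, converged = TRUE)
}

#' Fit the crossed mixed-effects model to one probeset
#'
#' Estimates the five variance components by profiled REML (variance ratios
#' parameterized on the log scale, bound below at 1e-10, quasi-Newton
#' optimizer from a fixed deterministic start), then the disease effect
#' \eqn{\hat\beta} and its standard error by generalized least squares at
#' the estimated components. The fit is deterministic given the input.
#'
#' @param y numeric vector of one probeset's log2 expression values.
#' @param annotations data.frame with per-sample columns `tissue`,
#'   `experiment`, `disease_status` (only `"normal"`/`"cancer"` rows), or
#'   an [AnnotatedExpressionSet-class] whose annotations are used.
#' @param varcomps optional named numeric of the five variance components
#'   (`tissue`, `tissue_disease`, `experiment`, `experiment_disease`,
#'   `residual`); when supplied, REML is skipped and the fit is generalized
#'   least squares at exactly these components.
#' @return a [MixedModelFit-class].
#' @export
fitProbeset <- function(y, annotations, varcomps = NULL) {
  if (is(annotations, "AnnotatedExpressionSet"))
    annotations <- data.frame(tissue = tissueType(annotations),
                              experiment = experimentId(annotations),
                              disease_status = diseaseStatus(annotations),
                              stringsAsFactors = FALSE)
  stopifnot(is.numeric(y), nrow(annotations) == length(y))
  if (anyNA(y)) stop("'y' contains missing values")
  design <- .prepDesign(annotations$tissue, annotations$experiment,
                        annotations$disease_status)
  st <- .probesetStats(design, matrix(y, nrow = 1L))
  res <- if (is.null(varcomps)) {
    .fitCore(design, st$ZtY[1L, ], st$XtY[1L, ], st$yty[1L])
  } else {
    if (!is.null(names(varcomps))) varcomps <- varcomps[.VARCOMP_NAMES]
    .glsFixed(design, st$ZtY[1L, ], st$XtY[1L, ], st$yty[1L],
              as.numeric(varcomps))
  }
  new("MixedModelFit", beta_hat = res$beta, se_beta = res$se,
      mu_hat = res$mu, varcomps = res$varcomps,
      reml_criterion = res$criterion, converged = res$converged,
      n_obs = design$n)
}

#' Approximate t test of the disease effect
#'
#' The ratio \eqn{t = \hat\beta / se(\hat\beta)} is referred to a t
#' distribution with degrees of freedom equal to the number of observations
#' minus the number of fixed-effect parameters (here \eqn{N - 2}); this is
#' an upper bound on the true degrees of freedom and anti-conservative for
#' small samples, which is why the pipeline only models classes with at
#' least 20 replicates.
#'
#' @param fit a converged [MixedModelFit-class].
#' @return a list of class `TestResult` with `t_stat`, `df` and the
#'   two-sided `p_value`.
#' @export
testDiseaseEffect <- function(fit) {
  stopifnot(is(fit, "MixedModelFit"))
  if (!fit@converged) stop("fit did not converge; no test is produced")
  t_stat <- fit@beta_hat / fit@se_beta
  df <- fit@n_obs - 2L
  structure(list(t_stat = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df = df)),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("t = %.4f on %d df, two-sided p = %.4g\n",
              x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j}, clipped at 1; output order
#' matches input order. Thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return the adjusted values, same length and order.
#' @export
bhAdjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p-values must be numeric")
  if (length(p_values) && (anyNA(p_values) ||
      min(p_values) < 0 || max(p_values) > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(p_values, method = "BH")
}

#' SignificanceTable: per-probeset disease-effect tests
#'
#' @slot table data.frame with columns `probeset_id`, `beta_hat`,
#'   `se_beta`, `t_stat`, `df`, `p_value`, `p_adjusted`, `significant`,
#'   `converged`, `rank` (ascending p among converged fits).
#' @slot alpha significance level applied to the BH-adjusted p-values.
#' @slot n_nonconverged probesets excluded from adjustment.
#' @seealso [fitAll()]
#' @export
setClass("SignificanceTable",
  representation(table = "data.frame", alpha = "numeric",
                 n_nonconverged = "integer"))

setMethod("show", "SignificanceTable", function(object) {
  cat("SignificanceTable:", nrow(object@table), "probesets, alpha =",
      object@alpha, "\n")
  cat("  significant:", sum(object@table$significant, na.rm = TRUE),
      " non-converged:", object@n_nonconverged, "\n")
})

#' @describeIn SignificanceTable-class extract the underlying data.frame.
#' @param x a `SignificanceTable`.
#' @export
significanceTable <- function(x) {
  stopifnot(is(x, "SignificanceTable"))
  x@table
}

# Shared engine: fit every row of Y (probesets x samples) against one
# labelling, returning beta, se, t and p per probeset. `starts` (P x 4
# matrix of log variance ratios) warm-starts the optimizer, e.g. from the
# unpermuted fit during permutation runs.
.fitMatrix <- function(design, Y, reltol = 1e-9, starts = NULL) {
  st <- .probesetStats(design, Y)
  P <- nrow(Y)
  out <- matrix(NA_real_, P, 4L,
                dimnames = list(rownames(Y), c("beta", "se", "t", "p")))
  theta <- matrix(0, P, 4L)
  conv <- logical(P)
  df <- design$n - 2L
  for (i in seq_len(P)) {
    s0 <- if (is.null(starts)) rep(0, 4L) else pmin(pmax(starts[i, ],
                                                         .LOG_LOWER),
                                                    .LOG_UPPER)
    fit <- .fitCore(design, st$ZtY[i, ], st$XtY[i, ], st$yty[i],
                    reltol = reltol, start = s0)
    conv[i] <- fit$converged
    theta[i, ] <- fit$theta
    tv <- fit$beta / fit$se
    out[i, ] <- c(fit$beta, fit$se, tv, 2 * pt(-abs(tv), df = df))
  }
  list(stats = out, converged = conv, df = df, theta = theta)
}

#' Fit the disease-effect model to every probeset
#'
#' One REML fit and approximate t test per probeset, followed by
#' Benjamini-Hochberg adjustment across all converged probesets;
#' significance is called at adjusted p below `alpha`. Non-converged
#' probesets are reported with `converged = FALSE`, excluded from the
#' adjustment, and counted in `n_nonconverged`.
#'
#' @param es a paired-tissue [AnnotatedExpressionSet-class] (see
#'   [selectPairedTissues()]); all samples must be normal or cancer.
#' @param alpha significance level for the adjusted p-values (default 0.01,
#'   the restrictive test size used throughout the pipeline).
#' @return a [SignificanceTable-class].
#' @export
fitAll <- function(es, alpha = 0.01) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1)
  design <- .prepDesign(tissueType(es), experimentId(es), diseaseStatus(es))
  res <- .fitMatrix(design, exprValues(es))
  st <- res$stats
  conv <- res$converged
  p_adj <- rep(NA_real_, nrow(st))
  p_adj[conv] <- bhAdjust(st[conv, "p"])
  sig <- !is.na(p_adj) & p_adj < alpha
  rank <- rep(NA_integer_, nrow(st))
  rank[conv] <- rank(st[conv, "p"], ties.method = "first")
  tab <- data.frame(probeset_id = rownames(exprValues(es)),
                    beta_hat = st[, "beta"], se_beta = st[, "se"],
                    t_stat = st[, "t"], df = res$df,
                    p_value = st[, "p"], p_adjusted = p_adj,
                    significant = sig, converged = conv, rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("SignificanceTable", table = tab, alpha = alpha,
      n_nonconverged = sum(!conv))
}

#' Volcano-plot export
#'
#' Effect size against evidence: \eqn{(\hat\beta, -\log_{10} p)} per
#' converged probeset.
#'
#' @param sig a [SignificanceTable-class].
#' @param path optional TSV output path.
#' @return data.frame with columns `probeset_id`, `beta_hat`,
#'   `neg_log10_p`.
#' @export
volcanoExport <- function(sig, path = NULL) {
  stopifnot(is(sig, "SignificanceTable"))
  tab <- sig@table[sig@table$converged, ]
  df <- data.frame(probeset_id = tab$probeset_id, beta_hat = tab$beta_hat,
                   neg_log10_p = -log10(pmax(tab$p_value, 1e-300)),
                   stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
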