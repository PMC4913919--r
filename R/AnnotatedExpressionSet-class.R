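#' AnnotatedExpressionSet: annotated expression compendium container
#'
#' An \code{AnnotatedExpressionSet} holds a probesets-by-samples matrix of
#' log2 expression values together with the per-sample annotations the
#' meta-analysis pipeline requires: the curated biological group label, the
#' tissue of origin, the experiment (study) the array came from, and the
#' disease status. It extends
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}, so all standard
#' subsetting and accessor machinery applies; the class adds validity checks
#' guaranteeing that modelling code downstream never meets missing values,
#' duplicated identifiers, or an unknown disease label.
#'
#' Disease status is a closed vocabulary: \code{"normal"}, \code{"cancer"} or
#' \code{"other"}. Samples labelled \code{"other"} are carried along for the
#' map stage but dropped when the paired cancer/normal subset is built.
#'
#' @slot .. see \code{SummarizedExperiment}; the single assay is named
#'   \code{"exprs"} and \code{colData} carries columns
#'   \code{biological_group}, \code{tissue}, \code{experiment},
#'   \code{disease_status}.
#'
#' @seealso [AnnotatedExpressionSet()] for construction,
#'   [readExpressionTSV()] to build one from text files.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData
#' @export
setClass("AnnotatedExpressionSet", contains = "SummarizedExperiment")

.DISEASE_LEVELS <- c("normal", "cancer", "other")
.ANNOTATION_COLS <- c("biological_group", "tissue", "experiment", "disease_status")

setValidity("AnnotatedExpressionSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is missing")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    if (anyNA(v)) msg <- c(msg, "expression values contain missing entries")
  }
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.ANNOTATION_COLS, colnames(cd))
  if (length(missing_cols))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(missing_cols, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probeset ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if ("disease_status" %in% colnames(cd)) {
    ds <- as.character(cd$disease_status)
    bad <- setdiff(unique(ds), .DISEASE_LEVELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown disease_status value(s): ",
                           paste(bad, collapse = ", ")))
    if (anyNA(ds)) msg <- c(msg, "disease_status contains missing values")
  }
  for (col in c("biological_group", "tissue", "experiment")) {
    if (col %in% colnames(cd) && anyNA(cd[[col]]))
      msg <- c(msg, paste0(col, " contains missing values"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedExpressionSet
#'
#' @param values numeric matrix, probesets in rows and samples in columns,
#'   log2 intensity units; row and column names supply the identifiers unless
#'   `probeset_ids` / `sample_ids` are given.
#' @param annotations a `data.frame` (or DataFrame) with one row per sample
#'   and columns `biological_group`, `tissue`, `experiment`,
#'   `disease_status`. Rows are matched to matrix columns by a `sample_id`
#'   column when present, otherwise by row names, otherwise positionally.
#' @param probeset_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#'
#' @return a validated [AnnotatedExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
#' ann <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                   biological_group = "liver_normal", tissue = "liver",
#'                   experiment = "E1",
#'                   disease_status = c("normal", "cancer", "normal"))
#' aes <- AnnotatedExpressionSet(m, ann)
#' @export
AnnotatedExpressionSet <- function(values, annotations,
                                   probeset_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(probeset_ids)) rownames(values) <- probeset_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' needs probeset row names and sample column names")
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(annotations)) {
    if (anyDuplicated(annotations$sample_id))
      stop("duplicate sample_id in annotations: ",
           paste(unique(annotations$sample_id[duplicated(annotations$sample_id)]),
                 collapse = ", "))
    rownames(annotations) <- annotations$sample_id
    annotations$sample_id <- NULL
  }
  missing <- setdiff(colnames(values), rownames(annotations))
  if (!is.null(rownames(annotations)) &&
      !all(rownames(annotations) == as.character(seq_len(nrow(annotations))))) {
    if (length(missing))
      stop("sample(s) missing from annotations: ",
           paste(missing, collapse = ", "))
    annotations <- annotations[colnames(values), , drop = FALSE]
  } else if (nrow(annotations) != ncol(values)) {
    stop("annotations have ", nrow(annotations), " rows but matrix has ",
         ncol(values), " samples and no sample_id column to match on")
  }
  lacking <- setdiff(.ANNOTATION_COLS, colnames(annotations))
  if (length(lacking))
    stop("annotations lack column(s): ", paste(lacking, collapse = ", "))
  annotations$disease_status <- as.character(annotations$disease_status)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(annotations[, .ANNOTATION_COLS, drop = FALSE],
                                   row.names = colnames(values)))
  new("AnnotatedExpressionSet", se)
}

#' Accessors for AnnotatedExpressionSet annotations
#'
#' Convenience accessors returning, per sample, the expression matrix,
#' identifiers and the four annotation columns the pipeline uses.
#'
#' @param x an [AnnotatedExpressionSet-class]
#' @return `exprValues` a numeric matrix; the others character vectors.
#' @name aes-accessors
#' @aliases exprValues probesetIds sampleIds biologicalGroup tissueType
#'   experimentId diseaseStatus
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname aes-accessors
#' @export
probesetIds <- function(x) rownames(x)

#' @rdname aes-accessors
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname aes-accessors
#' @export
biologicalGroup <- function(x)
  as.character(SummarizedExperiment::colData(x)$biological_group)

#' @rdname aes-accessors
#' @export
tissueType <- function(x)
  as.character(SummarizedExperiment::colData(x)$tissue)

#' @rdname aes-accessors
#' @export
experimentId <- function(x)
  as.character(SummarizedExperiment::colData(x)$experiment)

#' @rdname aes-accessors
#' @export
diseaseStatus <- function(x)
  as.character(SummarizedExperiment::colData(x)$disease_status)

setMethod("show", "AnnotatedExpressionSet", function(object) {
  cat("AnnotatedExpressionSet:", nrow(object), "probesets x",
      ncol(object), "samples\n")
  cat("  biological groups:", length(unique(biologicalGroup(object))), "\n")
  cat("  tissues:", length(unique(tissueType(object))),
      " experiments:", length(unique(experimentId(object))), "\n")
  tb <- table(factor(diseaseStatus(object), levels = .DISEASE_LEVELS))
  cat("  disease status:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})
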