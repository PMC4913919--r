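#' Read an annotated expression compendium from TSV files
#'
#' The expression matrix file is tab-separated with a header row of sample
#' ids and a first column of probeset ids; values are log2 intensities. The
#' annotation file is tab-separated with columns `sample_id`,
#' `biological_group`, `tissue`, `experiment`, `disease_status`. Annotation
#' rows are aligned to matrix columns by `sample_id` regardless of file
#' order. Malformed input (non-numeric cells, duplicated ids, samples
#' missing from the annotation table) is rejected with an informative error
#' rather than coerced.
#'
#' @param matrix_path path to the expression matrix TSV.
#' @param annotation_path path to the sample annotation TSV.
#' @return an [AnnotatedExpressionSet-class].
#' @seealso [writeExpressionTSV()]
#' @export
readExpressionTSV <- function(matrix_path, annotation_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("matrix file has no sample columns: ", matrix_path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probeset id(s) in ", matrix_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in ", matrix_path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  values <- matrix(NA_real_, nrow(raw), length(sample_ids),
                   dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   raw[[j + 1L]][bad[1L]], bad[1L], sample_ids[j], matrix_path))
    if (anyNA(col))
      stop(sprintf("missing value at row %d, column '%s' of %s",
                   which(is.na(col))[1L], sample_ids[j], matrix_path))
    values[, j] <- col
  }
  ann <- read.delim(annotation_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("sample_id", .ANNOTATION_COLS)
  lacking <- setdiff(need, colnames(ann))
  if (length(lacking))
    stop("annotation file lacks column(s): ", paste(lacking, collapse = ", "))
  AnnotatedExpressionSet(values, ann)
}

#' Write an AnnotatedExpressionSet to TSV files
#'
#' Inverse of [readExpressionTSV()]; the pair round-trips exactly up to
#' numeric formatting (15 significant digits are written).
#'
#' @param es an [AnnotatedExpressionSet-class]
#' @param matrix_path,annotation_path output file paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionTSV <- function(es, matrix_path, annotation_path) {
  stopifnot(is(es, "AnnotatedExpressionSet"))
  v <- exprValues(es)
  df <- data.frame(probeset_id = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = sampleIds(es),
                    biological_group = biologicalGroup(es),
                    tissue = tissueType(es),
                    experiment = experimentId(es),
                    disease_status = diseaseStatus(es),
                    stringsAsFactors = FALSE)
  write.table(ann, annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, annotation_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name`, `description`, then gene symbols. Symbols are deduplicated within
#' a set; empty trailing fields are dropped. Lines with fewer than three
#' fields are rejected with the offending line number.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of gene symbols; names are the
#'   set names, the `description` field is kept in attribute
#'   `"description"` of each element.
#' @seealso [writeGeneSetsGMT()]
#' @export
readGeneSetsGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!nzchar(fields[1L])) stop(sprintf("GMT line %d has an empty set name", i))
    attr(genes, "description") <- fields[2L]
    out[[i]] <- genes
    nms[i] <- fields[1L]
  }
  names(out) <- nms
  out
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors (as returned by
#'   [readGeneSetsGMT()]); a `"description"` attribute per element is used
#'   when present, otherwise the set name is repeated.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGeneSetsGMT <- function(gene_sets, path) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  lines <- vapply(seq_along(gene_sets), function(i) {
    desc <- attr(gene_sets[[i]], "description")
    if (is.null(desc)) desc <- names(gene_sets)[i]
    paste(c(names(gene_sets)[i], desc, gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probeset-to-gene mapping table
#'
#' Two-column TSV (`probeset_id`, `gene_symbol`), with one row per matching;
#' probesets mapping to several genes appear on several rows. A probeset may
#' be listed with an empty gene symbol to record it explicitly as unmapped.
#'
#' @param path path to the mapping TSV (with header).
#' @return a named list: one entry per probeset, a character vector of gene
#'   symbols (possibly empty).
#' @export
readGeneMapping <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("gene mapping file needs two columns: ", path)
  ps <- df[[1L]]
  gene <- df[[2L]]
  map <- split(gene, factor(ps, levels = unique(ps)))
  lapply(map, function(g) unique(g[nzchar(g)]))
}
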