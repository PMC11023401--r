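#' Construct an expression matrix container
#'
#' Wraps a genes x cells matrix of nonnegative, finite expression values
#' into a [SummarizedExperiment::SummarizedExperiment] with assay
#' `"expression"`. Values are treated as already normalized; the package
#' applies no library-size normalization of its own.
#'
#' @param values numeric matrix, rows = genes, columns = cells.
#' @param geneNames character, unique gene identifiers (defaults to
#'   rownames of `values`).
#' @param cellIds character, unique cell identifiers (defaults to
#'   colnames of `values`).
#' @param condition optional per-cell condition labels stored in
#'   `colData(.)$condition`.
#' @return a `SummarizedExperiment`.
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
#' se <- expressionMatrix(m)
#' @export
expressionMatrix <- function(values, geneNames = rownames(values),
                             cellIds = colnames(values), condition = NULL) {
    values <- as.matrix(values)
    if (nrow(values) == 0L || ncol(values) == 0L)
        stop("empty expression matrix")
    if (is.null(geneNames) || is.null(cellIds))
        stop("gene names and cell ids are required")
    if (anyDuplicated(geneNames))
        stop("duplicate gene names: ",
             paste(unique(geneNames[duplicated(geneNames)]), collapse = ", "))
    if (anyDuplicated(cellIds))
        stop("duplicate cell ids: ",
             paste(unique(cellIds[duplicated(cellIds)]), collapse = ", "))
    if (length(geneNames) != nrow(values) || length(cellIds) != ncol(values))
        stop("dimension mismatch between values and identifiers")
    if (any(!is.finite(values)))
        stop("expression values must be finite and non-missing")
    if (any(values < 0))
        stop("expression values must be nonnegative")
    dimnames(values) <- list(geneNames, cellIds)
    cd <- S4Vectors::DataFrame(row.names = cellIds)
    if (!is.null(condition)) {
        if (length(condition) != ncol(values))
            stop("one condition per cell required")
        cd$condition <- as.factor(condition)
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expression = values), colData = cd)
}

## Accepts a SummarizedExperiment or a plain matrix and returns the
## genes x cells numeric matrix.
.exprValues <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        return(SummarizedExperiment::assay(x, "expression"))
    as.matrix(x)
}

#' Read a genes x cells expression CSV
#'
#' Expects the published interchange format: comma-separated, `.` decimal,
#' UTF-8, a mandatory header row of cell identifiers and gene names in the
#' first column (rows are genes).
#'
#' @param path path to the CSV file.
#' @return a `SummarizedExperiment` preserving file row/column order.
#' @export
readExpressionCSV <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- read.csv(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("empty expression matrix in ", path)
    genes <- df[[1L]]
    cells <- colnames(df)[-1L]
    vals <- suppressWarnings(
        vapply(df[-1L], as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-numeric entry for gene '%s', cell '%s'",
                     genes[bad[1L, 1L]], cells[bad[1L, 2L]]))
    expressionMatrix(vals, geneNames = genes, cellIds = cells)
}

#' Write an expression matrix as CSV
#'
#' Inverse of [readExpressionCSV()]: gene names in the first column
#' (header `gene`), one column per cell.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionCSV <- function(x, path) {
    vals <- .exprValues(x)
    df <- data.frame(gene = rownames(vals), vals,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read per-cell condition labels
#'
#' Reads `comparison_labels.csv`-style files: either a single column of
#' labels (aligned by position) or two columns `cell_id,condition`
#' (aligned by id, any row order). The result is ordered like the columns
#' of `x`.
#'
#' @param path path to the labels CSV.
#' @param x the expression matrix the labels belong to.
#' @return a factor of length `ncol(x)`, names = cell ids.
#' @export
readLabelsCSV <- function(path, x) {
    if (!file.exists(path))
        stop("file not found: ", path)
    vals <- .exprValues(x)
    cells <- colnames(vals)
    df <- read.csv(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
    if (nrow(df) != ncol(vals))
        stop(sprintf("labels file has %d rows but the matrix has %d cells",
                     nrow(df), ncol(vals)))
    if (ncol(df) >= 2L) {
        ids <- as.character(df[[1L]])
        unknown <- setdiff(ids, cells)
        if (length(unknown))
            stop("unknown cell id(s) in labels file: ",
                 paste(head(unknown, 5L), collapse = ", "))
        cond <- df[[2L]][match(cells, ids)]
    } else {
        cond <- df[[1L]]
    }
    out <- factor(cond)
    names(out) <- cells
    out
}

#' Create a pipeline configuration
#'
#' All arguments default to the package's reference settings (see
#' [PipelineConfig-class]); pass only what you want to change.
#'
#' @param ... named settings matching the slots of `PipelineConfig`
#'   (e.g. `alpha = 0.05`, `clusterSize = 100`, `seed = 7`).
#' @return a validated `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(minNDatapointsABin = 100, seed = 3)
#' @export
pipelineConfig <- function(...) {
    args <- list(...)
    proto <- methods::new("PipelineConfig")
    intSlots <- names(which(vapply(methods::slotNames("PipelineConfig"),
        function(s) is.integer(methods::slot(proto, s)), logical(1))))
    for (nm in names(args)) {
        if (!nm %in% methods::slotNames("PipelineConfig"))
            stop("unknown configuration key: ", nm)
        val <- args[[nm]]
        if (nm %in% intSlots) val <- as.integer(val)
        methods::slot(proto, nm) <- val
    }
    methods::validObject(proto)
    proto
}

#' Read a pipeline configuration from YAML or JSON
#'
#' A flat key-value file whose keys match the slots of `PipelineConfig`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::fromJSON(path)
    } else {
        yaml::read_yaml(path)
    }
    do.call(pipelineConfig, as.list(vals))
}

## Stage logging: every stage reports its parameters and the number of
## features/cells entering and leaving it.
.logStage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}
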