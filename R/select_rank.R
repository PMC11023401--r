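#' Build an output function from selected clusters
#'
#' Restricts the data to cells whose cluster label is among `clusters`
#' and uses the cluster id itself as the (discrete) quantity to explain.
#' At least two cluster ids are required, otherwise there is no
#' difference to analyze.
#'
#' @param labels a [ClusterLabels-class].
#' @param clusters integer vector of cluster ids to compare (e.g.
#'   `c(8, 5)`).
#' @param index 0-based index of this output function.
#' @return an [OutputFunction-class] restricted to the selected cells.
#' @export
makeOutputFunction <- function(labels, clusters, index = 0L) {
    clusters <- as.integer(clusters)
    if (length(clusters) < 2L)
        stop("at least 2 cluster ids required (one class has no ",
             "difference to explain)")
    present <- unique(labels@labels)
    absent <- setdiff(clusters, present)
    if (length(absent))
        stop("cluster id(s) not present: ", paste(absent, collapse = ", "))
    keep <- labels@labels %in% clusters
    methods::new("OutputFunction",
        values = factor(labels@labels[keep], levels = sort(clusters)),
        cells = labels@cellIds[keep],
        kind = "discrete",
        index = as.integer(index))
}

#' Continuous output function from per-cell scores
#'
#' Wraps a numeric score (e.g. the manifold parameter `t`, or polar
#' coordinates r and theta as two separate output functions) for use in
#' [findClusterDifferences()]; the score is binned with the same
#' equal-occupancy scheme as the genes before testing.
#'
#' @param values numeric scores.
#' @param cells cell ids aligned with `values`.
#' @param index 0-based output-function index.
#' @return an [OutputFunction-class].
#' @export
continuousOutputFunction <- function(values, cells = names(values),
                                     index = 0L) {
    methods::new("OutputFunction", values = as.numeric(values),
                 cells = cells %||% as.character(seq_along(values)),
                 kind = "continuous", index = as.integer(index))
}

## Bin an output function: discrete levels become bins directly when all
## levels are large enough, which is exactly what the ascending sweep
## produces on the numeric encoding; continuous outputs are swept like a
## gene.
.binOutput <- function(output, minN) {
    v <- if (output@kind == "discrete") {
        as.numeric(factor(output@values))
    } else {
        output@values
    }
    if (max(v) == min(v))
        stop("output function is constant on the selected cells")
    binFeature(v, minN)
}

#' Chi-square filter of genes against output functions
#'
#' For every output function, bins each non-constant gene (and the
#' output itself when continuous) with the equal-occupancy scheme and
#' keeps the gene iff the chi-square test of independence between gene
#' bins and output bins rejects at level `alpha`. Following the
#' reference procedure no multiple-testing correction is applied by
#' default; Benjamini-Hochberg is available via `correct = "BH"`.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param outputs an [OutputFunction-class] or list of them (the
#'   combined data model places these first, genes after).
#' @param config a [PipelineConfig-class] (`minNDatapointsABin`,
#'   `alpha`).
#' @param correct `"none"` (default) or `"BH"`.
#' @return list of data.frames (one per output function) with columns
#'   `gene`, `pValue`, `retained`.
#' @export
findClusterDifferences <- function(x, outputs,
                                   config = pipelineConfig(),
                                   correct = c("none", "BH")) {
    correct <- match.arg(correct)
    if (methods::is(outputs, "OutputFunction")) outputs <- list(outputs)
    vals <- .exprValues(x)
    out <- vector("list", length(outputs))
    for (oi in seq_along(outputs)) {
        output <- outputs[[oi]]
        missing <- setdiff(output@cells, colnames(vals))
        if (length(missing))
            stop("output function refers to unknown cells")
        sub <- vals[, output@cells, drop = FALSE]
        rng <- apply(sub, 1L, function(v) max(v) - min(v))
        genes <- rownames(sub)[rng > 0]
        ob <- .binOutput(output, config@minNDatapointsABin)
        if (ob$nBins < 2L)
            warning("output function collapsed to a single bin; ",
                    "increase the number of cells or decrease ",
                    "minNDatapointsABin")
        pvals <- vapply(genes, function(g) {
            gb <- binFeature(sub[g, ], config@minNDatapointsABin)
            if (gb$nBins < 2L || ob$nBins < 2L) return(1)
            O <- contingencyTable(gb$assignments, ob$assignments,
                                  gb$nBins, ob$nBins)
            chiSquareIndependence(O, warn = FALSE)$pValue
        }, numeric(1))
        if (correct == "BH") pvals <- stats::p.adjust(pvals, "BH")
        res <- data.frame(gene = genes, pValue = pvals,
                          retained = pvals <= config@alpha,
                          stringsAsFactors = FALSE)
        if (!any(res$retained))
            warning("no gene associated with output function ",
                    output@index, " at alpha = ", config@alpha)
        .logStage("select", sprintf(
            "output %d: %d of %d non-constant genes retained at alpha=%g",
            output@index, sum(res$retained), length(genes),
            config@alpha))
        out[[oi]] <- res
    }
    out
}

#' Rank genes by mutual information with an output function
#'
#' Computes the mutual information (bits) between every candidate gene
#' and the output function on the same equal-occupancy binning as the
#' chi-square filter, and returns the full descending ranking (ties
#' broken by gene name).
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param genes candidate genes (typically the retained set of
#'   [findClusterDifferences()]).
#' @param output an [OutputFunction-class].
#' @param nHighest how many top genes to report in `head()`s and the
#'   pipeline artifact; the full ranking is always kept. If larger than
#'   the candidate set, all genes are returned with a warning.
#' @param config a [PipelineConfig-class] (`minNDatapointsABin`).
#' @return a [RankedFeatures-class].
#' @export
rankByMutualInformation <- function(x, genes, output,
                                    nHighest = 5L,
                                    config = pipelineConfig()) {
    if (length(genes) == 0L) stop("empty candidate gene set")
    vals <- .exprValues(x)[genes, output@cells, drop = FALSE]
    ob <- .binOutput(output, config@minNDatapointsABin)
    mi <- vapply(genes, function(g) {
        gb <- binFeature(vals[g, ], config@minNDatapointsABin)
        mutualInformation(gb$assignments, ob$assignments,
                          gb$nBins, ob$nBins)
    }, numeric(1))
    if (nHighest > length(genes))
        warning("nHighest exceeds the candidate set; returning all ",
                length(genes), " genes")
    df <- data.frame(gene = genes, mutual_information = mi,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$mutual_information, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    methods::new("RankedFeatures", ranking = df,
                 outputIndex = output@index)
}

#' @rdname RankedFeatures-class
#' @param object a `RankedFeatures`
#' @export
setMethod("ranking", "RankedFeatures", function(object) object@ranking)

#' Top genes of a ranking
#'
#' @param x a [RankedFeatures-class].
#' @param n number of genes.
#' @return character vector of gene names.
#' @export
topGenes <- function(x, n = 5L) {
    head(x@ranking$gene, n)
}

setMethod("show", "RankedFeatures", function(object) {
    cat("RankedFeatures for output function", object@outputIndex, "(",
        nrow(object@ranking), "genes )\n")
    print(head(object@ranking, 5L))
})

#' Write a mutual-information ranking as CSV
#'
#' Uses the interchange convention `mutual_information<i>.csv` with
#' columns `gene,mutual_information`, descending, no index column.
#'
#' @param rankedFeatures a [RankedFeatures-class].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
writeRankedFeatures <- function(rankedFeatures, dir = ".") {
    path <- file.path(dir, sprintf("mutual_information%d.csv",
                                   rankedFeatures@outputIndex))
    write.csv(rankedFeatures@ranking, path, row.names = FALSE,
              quote = FALSE)
    invisible(path)
}

#' Combined data model of output functions and genes
#'
#' Stacks the output functions as the first `length(outputs)` rows and
#' the gene expression below, restricted to the output cells — the
#' interchange layout consumed by the selection stage.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param outputs list of [OutputFunction-class] objects over the same
#'   cells.
#' @return numeric matrix with rows `output_fct_0`, ... then genes.
#' @export
makeCombinedMatrix <- function(x, outputs) {
    if (methods::is(outputs, "OutputFunction")) outputs <- list(outputs)
    cells <- outputs[[1L]]@cells
    for (o in outputs)
        if (!identical(o@cells, cells))
            stop("output functions must cover the same cells")
    vals <- .exprValues(x)[, cells, drop = FALSE]
    orows <- do.call(rbind, lapply(outputs, function(o)
        if (o@kind == "discrete") as.numeric(factor(o@values)) - 1
        else o@values))
    rownames(orows) <- sprintf("output_fct_%d",
                               vapply(outputs, methods::slot, integer(1),
                                      "index"))
    rbind(orows, vals)
}
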