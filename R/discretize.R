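#' Remove constant features
#'
#' A gene whose expression has maximum equal to minimum across all cells
#' carries no information about any difference between cells and is
#' removed before binning.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @return list with `matrix` (the retained genes, same container type as
#'   the input values) and `removed` (character, dropped gene names).
#' @export
removeConstantFeatures <- function(x) {
    vals <- .exprValues(x)
    if (nrow(vals) == 0L)
        stop("empty matrix")
    rng <- apply(vals, 1L, function(v) max(v) - min(v))
    constant <- rng == 0
    if (all(constant))
        stop("all features are constant; nothing to analyze")
    list(matrix = vals[!constant, , drop = FALSE],
         removed = rownames(vals)[constant])
}

#' Equal-occupancy binning of one feature
#'
#' Discretizes a continuous expression vector by sweeping the values in
#' ascending order: the open bin is filled until it holds at least
#' `minN` points **and** the next value is strictly larger (equal values
#' are never split across bins); then a new bin opens. A trailing
#' remainder shorter than `minN` is appended to the last opened bin, so
#' minimum occupancy holds whenever the vector has at least `minN`
#' entries.
#'
#' @param values numeric vector, non-constant.
#' @param minN positive integer, minimum points per bin
#'   (`minNDatapointsABin`).
#' @return list with `assignments` (0-based bin index per input position,
#'   ascending with value), `nBins`, and `boundaries` (lower edges of bins
#'   `2..nBins`; bins are half-open `[low, high)`, the last bin closed).
#' @examples
#' binFeature(c(1, 2, 3, 4, 5), minN = 2)$assignments  # 0 0 1 1 1
#' @export
binFeature <- function(values, minN) {
    n <- length(values)
    if (n == 0L) stop("empty feature")
    if (max(values) == min(values))
        stop("constant feature; remove it before binning")
    if (minN < 1L) stop("minN must be >= 1")
    o <- order(values)                      # stable sort back-mapping
    sv <- values[o]
    binsSorted <- integer(n)
    b <- 0L
    count <- 0L
    for (i in seq_len(n)) {
        binsSorted[i] <- b
        count <- count + 1L
        if (i < n && count >= minN && sv[i + 1L] > sv[i] &&
            (n - i) >= minN) {
            b <- b + 1L
            count <- 0L
        }
    }
    assignments <- integer(n)
    assignments[o] <- binsSorted
    nb <- b + 1L
    boundaries <- if (nb > 1L) {
        sv[match(seq_len(nb - 1L), binsSorted)]  # first value of bins 2..nb
    } else numeric(0)
    list(assignments = assignments, nBins = nb, boundaries = boundaries)
}

#' Bin every feature of an expression matrix
#'
#' Applies [removeConstantFeatures()] followed by [binFeature()] to each
#' retained feature. A feature that is already discrete with every level
#' occurring at least `minN` times keeps exactly one bin per level. If
#' the matrix has fewer than `minN` cells every feature collapses to a
#' single (uninformative) bin and a warning is raised.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param minN positive integer, minimum points per bin.
#' @return a [BinnedMatrix-class].
#' @export
binMatrix <- function(x, minN) {
    rc <- removeConstantFeatures(x)
    vals <- rc$matrix
    if (ncol(vals) < minN)
        warning("fewer cells than minNDatapointsABin: every feature ",
                "collapses to a single bin")
    feats <- lapply(seq_len(nrow(vals)),
                    function(i) binFeature(vals[i, ], minN))
    assignments <- do.call(rbind, lapply(feats, `[[`, "assignments"))
    dimnames(assignments) <- dimnames(vals)
    methods::new("BinnedMatrix",
        assignments = assignments,
        nBins = vapply(feats, `[[`, integer(1), "nBins"),
        boundaries = lapply(feats, `[[`, "boundaries"),
        removed = rc$removed,
        minNDatapointsABin = as.integer(minN))
}

#' @rdname BinnedMatrix-class
#' @aliases binAssignments nBins
#' @param object a `BinnedMatrix`
#' @export
setMethod("binAssignments", "BinnedMatrix",
          function(object) object@assignments)

#' @rdname BinnedMatrix-class
#' @export
setMethod("nBins", "BinnedMatrix", function(object) {
    stats::setNames(object@nBins, rownames(object@assignments))
})

setMethod("show", "BinnedMatrix", function(object) {
    cat("BinnedMatrix:", nrow(object@assignments), "features x",
        ncol(object@assignments), "cells\n")
    cat("  minNDatapointsABin:", object@minNDatapointsABin, "\n")
    cat("  bins per feature:", paste(range(object@nBins), collapse = "-"),
        "\n")
    cat("  constant features removed:", length(object@removed), "\n")
})
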