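#' Embed cells in a low-dimensional space
#'
#' Projects cells (points) from the gene expression space (one dimension
#' per selected gene, raw values, no discretization) into
#' `nComponents` dimensions with UMAP (via \pkg{uwot}) or t-SNE (via
#' \pkg{Rtsne}). The random seed is fixed so identical input and
#' configuration yield identical coordinates.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param featureSubset genes to embed on (default: all rows).
#' @param method `"umap"` or `"tsne"`.
#' @param nComponents embedding dimensionality (default 2).
#' @param nNeighbors UMAP number of nearest neighbors.
#' @param minDist UMAP minimum separation in the embedding.
#' @param metric distance metric in the expression space.
#' @param seed integer seed.
#' @return an [Embedding-class].
#' @export
embedCells <- function(x, featureSubset = NULL, method = c("umap", "tsne"),
                       nComponents = 2L, nNeighbors = 15L, minDist = 0.1,
                       metric = "euclidean", seed = 1L) {
    method <- match.arg(method)
    vals <- .exprValues(x)
    if (!is.null(featureSubset)) {
        missing <- setdiff(featureSubset, rownames(vals))
        if (length(missing))
            stop("unknown feature(s): ", paste(head(missing, 5),
                                               collapse = ", "))
        vals <- vals[featureSubset, , drop = FALSE]
    }
    if (nrow(vals) == 0L) stop("empty feature subset")
    if (ncol(vals) < 2L) stop("at least 2 cells required")
    pts <- t(vals)                      # cells as points, genes as dims
    set.seed(seed)
    coords <- if (method == "umap") {
        uwot::umap(pts, n_neighbors = min(nNeighbors, nrow(pts) - 1L),
                   n_components = nComponents, min_dist = minDist,
                   metric = metric, n_threads = 1, n_sgd_threads = 0)
    } else {
        perp <- min(30, floor((nrow(pts) - 1) / 3))
        Rtsne::Rtsne(pts, dims = nComponents, perplexity = perp,
                     check_duplicates = FALSE)$Y
    }
    rownames(coords) <- colnames(vals)
    colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
    .logStage("embed", sprintf("%s on %d genes x %d cells -> %d components",
                               method, nrow(vals), ncol(vals), nComponents))
    methods::new("Embedding", coords = coords, method = method,
        params = list(nComponents = nComponents, nNeighbors = nNeighbors,
                      minDist = minDist, metric = metric, seed = seed))
}

#' @rdname Embedding-class
#' @param object an `Embedding`
#' @export
setMethod("embeddingCoords", "Embedding", function(object) object@coords)

setMethod("show", "Embedding", function(object) {
    cat("Embedding (", object@method, "): ", nrow(object@coords),
        " cells x ", ncol(object@coords), " components\n", sep = "")
})

## DBSCAN over a distance matrix. minPts counts the point itself.
.dbscanLabels <- function(coords, eps, minPts) {
    n <- nrow(coords)
    D <- as.matrix(stats::dist(coords))
    nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
    core <- lengths(nb) >= minPts
    labels <- rep(-1L, n)
    cl <- -1L
    for (i in seq_len(n)) {
        if (!core[i] || labels[i] != -1L) next
        cl <- cl + 1L
        labels[i] <- cl
        frontier <- i
        while (length(frontier)) {
            nbrs <- unique(unlist(nb[frontier]))
            nbrs <- nbrs[labels[nbrs] == -1L]
            labels[nbrs] <- cl
            frontier <- nbrs[core[nbrs]]
        }
    }
    labels
}

## HDBSCAN*: single-linkage hierarchy on mutual reachability distances,
## condensed with minClusterSize, clusters extracted by excess of mass.
.hdbscanLabels <- function(coords, minClusterSize) {
    n <- nrow(coords)
    if (n < 2L * minClusterSize) return(rep(-1L, n))
    D <- as.matrix(stats::dist(coords))
    coreDist <- apply(D, 1L, function(d) sort(d)[minClusterSize])
    MR <- pmax(D, outer(coreDist, rep(1, n)), outer(rep(1, n), coreDist))
    hc <- stats::hclust(stats::as.dist(MR), method = "single")
    subtree <- function(node) {      # points below a merge-tree node
        if (node < 0L) return(-node)
        c(subtree(hc$merge[node, 1L]), subtree(hc$merge[node, 2L]))
    }
    clParent <- integer(0)
    clBirth <- numeric(0)
    clStability <- numeric(0)
    fallout <- integer(n)            # condensed cluster each point leaves
    newCluster <- function(parent, birth) {
        clParent[length(clParent) + 1L] <<- parent
        clBirth[length(clBirth) + 1L] <<- birth
        clStability[length(clStability) + 1L] <<- 0
        length(clParent)
    }
    root <- newCluster(0L, 0)
    stack <- list(list(node = n - 1L, cl = root))
    while (length(stack)) {
        top <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        lam <- 1 / max(hc$height[top$node], .Machine$double.xmin)
        kids <- hc$merge[top$node, ]
        pts <- lapply(kids, subtree)
        big <- lengths(pts) >= minClusterSize
        if (all(big)) {
            for (k in 1:2) {
                cid <- newCluster(top$cl, lam)
                stack[[length(stack) + 1L]] <- list(node = kids[k],
                                                    cl = cid)
            }
        } else {
            for (k in which(!big)) {
                clStability[top$cl] <- clStability[top$cl] +
                    length(pts[[k]]) * (lam - clBirth[top$cl])
                fallout[pts[[k]]] <- top$cl
            }
            for (k in which(big))
                stack[[length(stack) + 1L]] <- list(node = kids[k],
                                                    cl = top$cl)
        }
    }
    ncl <- length(clParent)
    score <- clStability
    selected <- logical(ncl)
    descendants <- function(c) {
        kids <- which(clParent == c)
        c(kids, unlist(lapply(kids, descendants)))
    }
    for (c in rev(seq_len(ncl))) {
        kids <- which(clParent == c)
        if (length(kids) == 0L) {
            selected[c] <- TRUE
        } else if (clStability[c] >= sum(score[kids]) && c != root) {
            selected[c] <- TRUE
            selected[descendants(c)] <- FALSE
            score[c] <- clStability[c]
        } else {
            score[c] <- sum(score[kids])
        }
    }
    selected[root] <- FALSE
    labels <- rep(-1L, n)
    selId <- which(selected)
    if (length(selId)) {
        map <- stats::setNames(seq_along(selId) - 1L, selId)
        for (p in seq_len(n)) {
            c <- fallout[p]
            while (c != 0L && !selected[c]) c <- clParent[c]
            if (c != 0L) labels[p] <- map[[as.character(c)]]
        }
    }
    labels
}

#' Density-based cluster labeling of an embedding
#'
#' Assigns every embedded cell either a cluster id (0, 1, ...) or the
#' noise label -1. `"dbscan"` uses a radius `eps` and a core-point
#' threshold `minSamples` (the cell itself counts); `"hdbscan"` needs
#' only `minClusterSize` and extracts the most stable clusters from the
#' mutual-reachability hierarchy.
#'
#' @param embedding an [Embedding-class] (or a cells x dims matrix).
#' @param method `"dbscan"` or `"hdbscan"`.
#' @param eps DBSCAN radius.
#' @param minSamples DBSCAN core-point threshold.
#' @param minClusterSize HDBSCAN minimum cluster size.
#' @return a [ClusterLabels-class].
#' @export
clusterDensity <- function(embedding, method = c("dbscan", "hdbscan"),
                           eps = 1, minSamples = 15L,
                           minClusterSize = 15L) {
    method <- match.arg(method)
    coords <- if (methods::is(embedding, "Embedding"))
        embedding@coords else as.matrix(embedding)
    if (!all(is.finite(coords))) stop("non-finite embedding coordinates")
    labels <- if (method == "dbscan") {
        .dbscanLabels(coords, eps, minSamples)
    } else {
        .hdbscanLabels(coords, minClusterSize)
    }
    if (all(labels == -1L))
        stop("all cells labeled noise; relax eps/minSamples/",
             "minClusterSize")
    .logStage("cluster", sprintf(
        "%s: %d cluster(s), %d noise cell(s) of %d (%s)",
        method, length(setdiff(unique(labels), -1L)),
        sum(labels == -1L), length(labels),
        if (method == "dbscan")
            sprintf("eps=%g, minSamples=%d", eps, minSamples)
        else sprintf("minClusterSize=%d", minClusterSize)))
    methods::new("ClusterLabels", labels = as.integer(labels),
                 method = method,
                 cellIds = rownames(coords) %||%
                     as.character(seq_len(nrow(coords))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label cells by coordinate boxes
#'
#' Cells inside the i-th axis-aligned box get label i-1; cells outside
#' every box are noise (-1). Boxes must not overlap.
#'
#' @param embedding an [Embedding-class] or coordinate matrix.
#' @param boxes list of numeric matrices, one per box; each has one row
#'   per embedding dimension and columns `c(low, high)` (closed
#'   intervals).
#' @return a [ClusterLabels-class] with method `"box"`.
#' @export
labelByBox <- function(embedding, boxes) {
    coords <- if (methods::is(embedding, "Embedding"))
        embedding@coords else as.matrix(embedding)
    labels <- rep(-1L, nrow(coords))
    inBox <- function(box) {
        box <- matrix(box, ncol = 2L)
        hits <- rep(TRUE, nrow(coords))
        for (d in seq_len(nrow(box)))
            hits <- hits & coords[, d] >= box[d, 1L] &
                coords[, d] <= box[d, 2L]
        hits
    }
    for (i in seq_along(boxes)) {
        hits <- inBox(boxes[[i]])
        if (any(labels[hits] != -1L))
            stop("overlapping boxes")
        labels[hits] <- i - 1L
    }
    methods::new("ClusterLabels", labels = labels, method = "box",
                 cellIds = rownames(coords) %||%
                     as.character(seq_len(nrow(coords))))
}

#' Wrap externally provided labels
#'
#' @param labels integer-like labels (>= 0; -1 = noise) or a factor whose
#'   levels are encoded as 0, 1, ...
#' @param cellIds cell identifiers.
#' @return a [ClusterLabels-class] with method `"external"`.
#' @export
externalLabels <- function(labels, cellIds = names(labels)) {
    force(cellIds)
    if (is.factor(labels) || is.character(labels))
        labels <- as.integer(factor(labels)) - 1L
    methods::new("ClusterLabels", labels = as.integer(labels),
                 method = "external",
                 cellIds = cellIds %||%
                     as.character(seq_along(labels)))
}

#' @rdname ClusterLabels-class
#' @param object a `ClusterLabels`
#' @export
setMethod("clusterIds", "ClusterLabels", function(object) {
    stats::setNames(object@labels, object@cellIds)
})

setMethod("show", "ClusterLabels", function(object) {
    cat("ClusterLabels (", object@method, "): ", sep = "")
    print(table(object@labels))
})

#' Cross-tabulate clusters against external condition labels
#'
#' Noise cells (-1) are excluded. Purity of a cluster is the largest
#' condition fraction within it; "clean" clusters of high purity are the
#' natural candidates for the gene-selection stage.
#'
#' @param labels a [ClusterLabels-class].
#' @param conditions per-cell condition factor aligned with the cells of
#'   `labels` (names are matched to cell ids when present).
#' @return list with `counts` (clusters x conditions), `purity` (named
#'   numeric) and `nNoise`.
#' @export
clusterComposition <- function(labels, conditions) {
    ids <- labels@cellIds
    if (!is.null(names(conditions))) {
        missing <- setdiff(ids, names(conditions))
        if (length(missing)) stop("conditions missing for some cells")
        conditions <- conditions[ids]
    }
    if (length(conditions) != length(ids))
        stop("one condition per cell required")
    keep <- labels@labels != -1L
    if (!any(keep)) stop("no non-noise cells")
    counts <- table(cluster = labels@labels[keep],
                    condition = droplevels(factor(conditions[keep])))
    purity <- apply(counts, 1L, function(r) max(r) / sum(r))
    list(counts = unclass(counts), purity = purity,
         nNoise = sum(!keep))
}

#' Bar plot of cluster composition
#'
#' @param composition result of [clusterComposition()].
#' @param file optional path; when given the plot is saved as PNG.
#' @return a ggplot object, invisibly when saved.
#' @export
plotComposition <- function(composition, file = NULL) {
    df <- as.data.frame(as.table(composition$counts))
    colnames(df) <- c("cluster", "condition", "cells")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = cluster, y = cells,
                                          fill = condition)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "cluster", y = "cells") +
        ggplot2::theme_minimal()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
        return(invisible(p))
    }
    p
}

#' Split cells into disjoint stratified subsamples
#'
#' Cells are split by cluster into `nSplits` near-equal disjoint subsets
#' (per-stratum counts differ by at most one), so that selection and
#' validation can be run on independent subsamples. Noise cells are
#' excluded.
#'
#' @param labels a [ClusterLabels-class].
#' @param nSplits number of subsets.
#' @param seed integer seed.
#' @param minClusterCells smallest admissible cluster; smaller ones
#'   raise an error because subsample statistics become unstable.
#' @return list of character vectors of cell ids.
#' @export
splitCells <- function(labels, nSplits, seed = 1L,
                       minClusterCells = nSplits) {
    keep <- labels@labels != -1L
    ids <- labels@cellIds[keep]
    cl <- labels@labels[keep]
    if (any(table(cl) < max(nSplits, minClusterCells)))
        stop("a cluster has too few cells for ", nSplits, " splits")
    out <- replicate(nSplits, character(0), simplify = FALSE)
    set.seed(seed)
    for (c in sort(unique(cl))) {
        members <- sample(ids[cl == c])
        grp <- rep(seq_len(nSplits), length.out = length(members))
        for (s in seq_len(nSplits))
            out[[s]] <- c(out[[s]], members[grp == s])
    }
    out
}
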