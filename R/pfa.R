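## Pairwise chi-square p-value with caching across dissection rounds.
## Features with a single bin are uninformative: NA (never an edge).
.pairPValue <- function(assignments, nbins, i, j, cache = NULL) {
    key <- if (i < j) paste0(i, ":", j) else paste0(j, ":", i)
    if (!is.null(cache) && !is.null(cache[[key]]))
        return(cache[[key]])
    p <- if (nbins[i] < 2L || nbins[j] < 2L) {
        NA_real_
    } else {
        O <- contingencyTable(assignments[i, ], assignments[j, ],
                              nbins[i], nbins[j])
        chiSquareIndependence(O, warn = FALSE)$pValue
    }
    if (!is.null(cache)) cache[[key]] <- p
    p
}

#' Build the dependence graph over a feature subset
#'
#' Applies the chi-square test of independence to every unordered pair of
#' features in `featureSubset` and connects two features by an edge
#' whenever the p-value is at most `alpha` (independence rejected). A
#' p-value above `alpha` means the pair is considered independent and no
#' edge is drawn.
#'
#' @param binned a [BinnedMatrix-class].
#' @param featureSubset character or integer, features to test (at least
#'   1; a singleton yields an edgeless graph).
#' @param alpha significance level.
#' @return a [DependenceGraph-class].
#' @export
buildDependenceGraph <- function(binned, featureSubset = NULL,
                                 alpha = 0.01) {
    A <- binned@assignments
    if (is.null(featureSubset)) featureSubset <- rownames(A)
    if (is.numeric(featureSubset)) featureSubset <- rownames(A)[featureSubset]
    idx <- match(featureSubset, rownames(A))
    if (anyNA(idx)) stop("unknown feature(s) in subset")
    m <- length(idx)
    pmat <- matrix(NA_real_, m, m, dimnames = list(featureSubset,
                                                   featureSubset))
    if (m >= 2L) {
        for (a in seq_len(m - 1L)) {
            for (b in seq(a + 1L, m)) {
                p <- .pairPValue(A, binned@nBins, idx[a], idx[b])
                pmat[a, b] <- pmat[b, a] <- p
            }
        }
    }
    adj <- !is.na(pmat) & pmat <= alpha
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    methods::new("DependenceGraph", graph = g, alpha = alpha,
                 pValues = pmat)
}

setMethod("show", "DependenceGraph", function(object) {
    cat("DependenceGraph:", igraph::vcount(object@graph), "features,",
        igraph::ecount(object@graph), "dependence edges (alpha =",
        object@alpha, ")\n")
})

.isComplete <- function(g) {
    n <- igraph::vcount(g)
    igraph::ecount(g) == n * (n - 1L) / 2
}

## Lexicographically smallest vertex set among equal-size candidates,
## for deterministic tie-breaking between minimum cuts.
.lexSmallest <- function(sets) {
    keys <- vapply(sets, function(s)
        paste(sort(as.character(s)), collapse = "\r"), character(1))
    sets[[order(keys)[1L]]]
}

#' Dissect a dependence-graph component with minimum vertex cuts
#'
#' Repeatedly: if a connected component is complete (including single
#' nodes), it is retained whole; otherwise a minimum vertex cut is
#' computed, the cut vertices are removed (they mediate between otherwise
#' independent parts and can be seen as functions of the remaining
#' features), and the resulting pieces are dissected recursively. Among
#' equal-size minimum cuts the lexicographically smallest vertex set is
#' taken, so the dissection is deterministic.
#'
#' @param graph a [DependenceGraph-class] or an `igraph` object with
#'   named vertices.
#' @param component optional character vector restricting the dissection
#'   to the induced subgraph on these vertices.
#' @return list with `retained` and `removed` character vectors.
#' @export
dissectComponent <- function(graph, component = NULL) {
    g <- if (methods::is(graph, "DependenceGraph")) graph@graph else graph
    if (!is.null(component))
        g <- igraph::induced_subgraph(g, component)
    retained <- character(0)
    removed <- character(0)
    queue <- list(g)
    while (length(queue)) {
        cur <- queue[[1L]]
        queue <- queue[-1L]
        if (igraph::vcount(cur) == 0L) next
        comp <- igraph::components(cur)
        if (comp$no > 1L) {
            for (k in seq_len(comp$no)) {
                queue <- c(queue, list(igraph::induced_subgraph(
                    cur, names(which(comp$membership == k)))))
            }
            next
        }
        if (.isComplete(cur)) {
            retained <- c(retained, igraph::V(cur)$name)
            next
        }
        seps <- lapply(igraph::min_separators(cur),
                       function(s) sort(igraph::as_ids(s)))
        cut <- .lexSmallest(seps)
        removed <- c(removed, cut)
        queue <- c(queue, list(igraph::delete_vertices(cur, cut)))
    }
    list(retained = sort(retained), removed = sort(removed))
}

## Apply the complete-subgraph policy to the retained vertices of a
## dissected graph: under "representative", each complete component of
## size >= 2 keeps only its largest-variance member (ties by name).
.applyPolicy <- function(g, retained, policy, variances) {
    if (policy == "all" || length(retained) < 2L)
        return(list(kept = retained, dropped = character(0)))
    sub <- igraph::induced_subgraph(g, retained)
    comp <- igraph::components(sub)
    kept <- character(0)
    dropped <- character(0)
    for (k in seq_len(comp$no)) {
        members <- sort(names(which(comp$membership == k)))
        if (length(members) == 1L) {
            kept <- c(kept, members)
        } else {
            rep <- members[order(-variances[members], members)][1L]
            kept <- c(kept, rep)
            dropped <- c(dropped, setdiff(members, rep))
        }
    }
    list(kept = sort(kept), dropped = sort(dropped))
}

#' Principal feature analysis
#'
#' Unlabeled redundancy removal. Constant genes are dropped, the rest are
#' discretized by equal-occupancy binning, and the features are processed
#' in rounds: each round shuffles the surviving features (seeded),
#' partitions them into chunks of at most `clusterSize`, builds the
#' chi-square dependence graph within each chunk and dissects it with
#' minimum vertex cuts until only complete subgraphs remain. Survivors
#' are pooled and re-chunked until a full round removes nothing or
#' `maxRounds` is reached. Retained complete subgraphs are flattened to
#' individual genes (`completeSubgraphPolicy = "all"`, the default) or
#' reduced to their largest-variance member (`"representative"`).
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param config a [PipelineConfig-class]; relevant settings are
#'   `minNDatapointsABin`, `alpha`, `clusterSize`, `maxRounds`,
#'   `completeSubgraphPolicy` and `seed`.
#' @return a [PfaResult-class].
#' @examples
#' sim <- generateSyntheticDataset(nCellsPerCondition = 150,
#'     nMarkerGenes = 2, nRedundantGenes = 5, nNoiseGenes = 20,
#'     nConstantGenes = 1, seed = 1)
#' pfa <- principalFeatureAnalysis(sim$matrix,
#'     pipelineConfig(minNDatapointsABin = 50, seed = 1))
#' @export
principalFeatureAnalysis <- function(x, config = pipelineConfig()) {
    vals <- .exprValues(x)
    binned <- binMatrix(vals, config@minNDatapointsABin)
    A <- binned@assignments
    nbins <- binned@nBins
    names(nbins) <- rownames(A)
    variances <- apply(vals[rownames(A), , drop = FALSE], 1L, var)
    removalLog <- data.frame(gene = binned@removed,
                             round = rep(0L, length(binned@removed)),
                             reason = rep("constant",
                                          length(binned@removed)),
                             stringsAsFactors = FALSE)
    survivors <- rownames(A)
    cache <- new.env(parent = emptyenv())
    rounds <- 0L
    .logStage("pfa", sprintf(
        "%d features in (%d constant removed), alpha=%g, clusterSize=%d",
        nrow(vals), length(binned@removed), config@alpha,
        config@clusterSize))
    for (r in seq_len(config@maxRounds)) {
        rounds <- r
        set.seed(config@seed + r)
        shuffled <- sample(survivors)
        chunks <- split(shuffled, ceiling(seq_along(shuffled) /
                                          config@clusterSize))
        removedThisRound <- character(0)
        for (chunk in chunks) {
            if (length(chunk) < 2L) next
            chunk <- sort(chunk)
            idx <- match(chunk, rownames(A))
            m <- length(idx)
            adj <- matrix(FALSE, m, m, dimnames = list(chunk, chunk))
            for (a in seq_len(m - 1L)) {
                for (b in seq(a + 1L, m)) {
                    p <- .pairPValue(A, nbins, idx[a], idx[b], cache)
                    adj[a, b] <- adj[b, a] <- !is.na(p) && p <= config@alpha
                }
            }
            g <- igraph::graph_from_adjacency_matrix(adj,
                mode = "undirected", diag = FALSE)
            dis <- dissectComponent(g)
            pol <- .applyPolicy(g, dis$retained,
                                config@completeSubgraphPolicy, variances)
            if (length(dis$removed))
                removalLog <- rbind(removalLog, data.frame(
                    gene = dis$removed, round = r, reason = "cut-vertex",
                    stringsAsFactors = FALSE))
            if (length(pol$dropped))
                removalLog <- rbind(removalLog, data.frame(
                    gene = pol$dropped, round = r,
                    reason = "non-representative",
                    stringsAsFactors = FALSE))
            removedThisRound <- c(removedThisRound, dis$removed,
                                  pol$dropped)
        }
        survivors <- setdiff(survivors, removedThisRound)
        if (length(removedThisRound) == 0L) break
    }
    .logStage("pfa", sprintf("%d principal features out after %d round(s)",
                             length(survivors), rounds))
    methods::new("PfaResult",
        principalFeatures = survivors[order(match(survivors,
                                                  rownames(vals)))],
        removedFeatures = removalLog,
        rounds = rounds,
        policy = config@completeSubgraphPolicy)
}

#' @rdname PfaResult-class
#' @export
setMethod("principalFeatures", "PfaResult",
          function(object) object@principalFeatures)

#' @rdname PfaResult-class
#' @export
setMethod("removedFeatures", "PfaResult",
          function(object) object@removedFeatures)

setMethod("show", "PfaResult", function(object) {
    cat("PfaResult:", length(object@principalFeatures),
        "principal features retained,", nrow(object@removedFeatures),
        "removed in", object@rounds, "round(s)\n")
    cat("  policy:", object@policy, "\n")
    if (nrow(object@removedFeatures))
        print(table(object@removedFeatures$reason))
})
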