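#' @import methods
#' @importFrom stats pchisq predict var sd prcomp quantile rlnorm rnorm runif
#' @importFrom utils head read.csv write.csv
NULL

#' Pipeline configuration
#'
#' Holds every tunable parameter of the characteristic-feature-extraction
#' pipeline. The prototype values are the settings used throughout the
#' package documentation: `minNDatapointsABin = 500`, `alpha = 0.01`,
#' `clusterSize = 50`, a 2-component UMAP embedding, DBSCAN with
#' `eps = 1` and `minSamples = 15` (HDBSCAN `minClusterSize = 15`),
#' `nHighestMutualInformation = 5`, one output function, 20 validation
#' sweeps and decision-tree pruning with `minSamplesLeaf = 10`.
#'
#' @slot minNDatapointsABin integer, minimum cells per expression bin.
#' @slot alpha numeric in (0,1), significance level of the chi-square
#'   independence test; p-values above `alpha` mean "independent".
#' @slot clusterSize integer, maximum number of features treated jointly
#'   when the dependence graph is dissected.
#' @slot maxRounds integer, cap on chunked dissection passes.
#' @slot completeSubgraphPolicy `"all"` or `"representative"`; what to keep
#'   from a fully connected group of mutually dependent features.
#' @slot embeddingMethod `"umap"` or `"tsne"`.
#' @slot nComponents integer, embedding dimensionality.
#' @slot nNeighbors integer, UMAP neighborhood size.
#' @slot minDist numeric, UMAP minimum distance.
#' @slot metric character, UMAP metric.
#' @slot clusterMethod `"dbscan"` or `"hdbscan"`.
#' @slot eps numeric, DBSCAN radius.
#' @slot minSamples integer, DBSCAN core-point threshold.
#' @slot minClusterSize integer, HDBSCAN minimum cluster size.
#' @slot nHighestMutualInformation integer, size of the reported gene set.
#' @slot clusters integer vector, cluster ids compared by the selection
#'   stage (empty = choose automatically).
#' @slot numberOutputFunctions integer, number of output functions.
#' @slot numberSweeps integer, train/test sweeps in the validation stage.
#' @slot trainFraction numeric, stratified train fraction per sweep.
#' @slot hiddenUnits integer, hidden-layer width of the MLP classifier.
#' @slot maxWeights integer, cap on total MLP weights (the hidden layer
#'   shrinks to respect it for wide inputs).
#' @slot minSamplesLeaf integer, minimum samples per decision-tree leaf.
#' @slot maxDepth integer, decision-tree depth cap (`30` = unlimited for
#'   practical purposes).
#' @slot seed integer, master seed for all stochastic stages.
#' @export
setClass("PipelineConfig", representation(
    minNDatapointsABin = "integer",
    alpha = "numeric",
    clusterSize = "integer",
    maxRounds = "integer",
    completeSubgraphPolicy = "character",
    embeddingMethod = "character",
    nComponents = "integer",
    nNeighbors = "integer",
    minDist = "numeric",
    metric = "character",
    clusterMethod = "character",
    eps = "numeric",
    minSamples = "integer",
    minClusterSize = "integer",
    nHighestMutualInformation = "integer",
    clusters = "integer",
    numberOutputFunctions = "integer",
    numberSweeps = "integer",
    trainFraction = "numeric",
    hiddenUnits = "integer",
    maxWeights = "integer",
    minSamplesLeaf = "integer",
    maxDepth = "integer",
    seed = "integer"
), prototype(
    minNDatapointsABin = 500L,
    alpha = 0.01,
    clusterSize = 50L,
    maxRounds = 10L,
    completeSubgraphPolicy = "all",
    embeddingMethod = "umap",
    nComponents = 2L,
    nNeighbors = 15L,
    minDist = 0.1,
    metric = "euclidean",
    clusterMethod = "dbscan",
    eps = 1,
    minSamples = 15L,
    minClusterSize = 15L,
    nHighestMutualInformation = 5L,
    clusters = integer(0),
    numberOutputFunctions = 1L,
    numberSweeps = 20L,
    trainFraction = 0.75,
    hiddenUnits = 100L,
    maxWeights = 3000L,
    minSamplesLeaf = 10L,
    maxDepth = 30L,
    seed = 1L
))

setValidity("PipelineConfig", function(object) {
    msg <- character(0)
    if (object@minNDatapointsABin < 1L)
        msg <- c(msg, "minNDatapointsABin must be a positive integer")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "alpha must lie in (0, 1)")
    if (object@clusterSize < 1L)
        msg <- c(msg, "clusterSize must be a positive integer")
    if (!object@completeSubgraphPolicy %in% c("all", "representative"))
        msg <- c(msg, "completeSubgraphPolicy must be 'all' or 'representative'")
    if (!object@embeddingMethod %in% c("umap", "tsne"))
        msg <- c(msg, "embeddingMethod must be 'umap' or 'tsne'")
    if (!object@clusterMethod %in% c("dbscan", "hdbscan"))
        msg <- c(msg, "clusterMethod must be 'dbscan' or 'hdbscan'")
    if (object@trainFraction <= 0 || object@trainFraction >= 1)
        msg <- c(msg, "trainFraction must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Equal-occupancy binned expression matrix
#'
#' Result of applying the ascending-sweep discretization to every
#' non-constant feature of an expression matrix. Bin indices are 0-based
#' and ascend with expression value; equal values always share a bin.
#'
#' @slot assignments integer matrix, features x cells, 0-based bin index.
#' @slot nBins integer vector, bins per feature.
#' @slot boundaries list of numeric vectors; element `i` holds the lower
#'   edges of bins `1..nBins[i]-1` of feature `i` (half-open intervals,
#'   last bin closed).
#' @slot removed character, names of constant features dropped before
#'   binning.
#' @slot minNDatapointsABin integer, occupancy parameter used.
#' @export
setClass("BinnedMatrix", representation(
    assignments = "matrix",
    nBins = "integer",
    boundaries = "list",
    removed = "character",
    minNDatapointsABin = "integer"
))

setValidity("BinnedMatrix", function(object) {
    if (nrow(object@assignments) != length(object@nBins))
        return("one bin count per binned feature required")
    if (length(object@boundaries) != length(object@nBins))
        return("one boundary vector per binned feature required")
    TRUE
})

#' Pairwise dependence graph over binned features
#'
#' Nodes are features; an edge joins two features whenever the chi-square
#' test of independence on their joint bin contingency table rejects at
#' level `alpha` (p-value <= alpha).
#'
#' @slot graph an `igraph` object with named vertices.
#' @slot alpha numeric, significance level that defined the edges.
#' @slot pValues numeric matrix of pairwise p-values (NA on the diagonal
#'   and for untested pairs).
#' @export
setClass("DependenceGraph", representation(
    graph = "ANY",
    alpha = "numeric",
    pValues = "matrix"
))

#' Principal feature analysis result
#'
#' @slot principalFeatures character, retained gene names.
#' @slot removedFeatures data.frame with columns `gene`, `round`, `reason`
#'   (`constant`, `cut-vertex` or `non-representative`).
#' @slot rounds integer, chunked dissection passes executed.
#' @slot policy character, complete-subgraph policy used.
#' @export
setClass("PfaResult", representation(
    principalFeatures = "character",
    removedFeatures = "data.frame",
    rounds = "integer",
    policy = "character"
))

#' Low-dimensional cell embedding
#'
#' @slot coords numeric matrix, cells x components, rownames = cell ids.
#' @slot method character, `"umap"` or `"tsne"`.
#' @slot params list, the embedding parameters (including the seed).
#' @export
setClass("Embedding", representation(
    coords = "matrix",
    method = "character",
    params = "list"
))

setValidity("Embedding", function(object) {
    if (!all(is.finite(object@coords)))
        return("embedding coordinates must be finite")
    TRUE
})

#' Per-cell cluster labels
#'
#' Integer labels >= 0 identify clusters; -1 marks noise cells that no
#' cluster claimed. Noise cells are excluded from composition tables and
#' from downstream gene selection.
#'
#' @slot labels integer vector, one label per cell.
#' @slot method character, `"dbscan"`, `"hdbscan"`, `"box"` or `"external"`.
#' @slot cellIds character, cell identifiers aligned with `labels`.
#' @export
setClass("ClusterLabels", representation(
    labels = "integer",
    method = "character",
    cellIds = "character"
))

setValidity("ClusterLabels", function(object) {
    if (length(object@labels) != length(object@cellIds))
        return("one label per cell id required")
    if (any(object@labels < -1L))
        return("labels must be >= -1 (-1 = noise)")
    TRUE
})

#' Output function for gene selection
#'
#' The quantity to be explained per cell: a discrete group label (cluster
#' id or condition) or a continuous score such as a manifold coordinate.
#' Continuous output functions are binned with the same equal-occupancy
#' scheme as genes before testing.
#'
#' @slot values numeric or factor values, one per selected cell.
#' @slot cells character, ids of the selected cells.
#' @slot kind character, `"discrete"` or `"continuous"`.
#' @slot index integer, 0-based position among the output functions.
#' @export
setClass("OutputFunction", representation(
    values = "ANY",
    cells = "character",
    kind = "character",
    index = "integer"
))

setValidity("OutputFunction", function(object) {
    if (length(object@values) != length(object@cells))
        return("one value per cell required")
    if (!object@kind %in% c("discrete", "continuous"))
        return("kind must be 'discrete' or 'continuous'")
    if (object@kind == "discrete" &&
        length(unique(as.character(object@values))) < 2L)
        return("a discrete output function needs at least 2 levels")
    TRUE
})

#' Genes ranked by mutual information with an output function
#'
#' @slot ranking data.frame with columns `gene` and `mutual_information`
#'   (bits), in descending order, ties broken by gene name.
#' @slot outputIndex integer, 0-based index of the output function.
#' @export
setClass("RankedFeatures", representation(
    ranking = "data.frame",
    outputIndex = "integer"
))

#' Classifier-based validation report
#'
#' Mean balanced accuracy (macro-averaged recall, in percent) of an MLP
#' classifier across repeated stratified train/test sweeps, for the
#' selected genes, for random gene sets of equal size (baseline) and for
#' all non-constant genes (control).
#'
#' @slot summary data.frame with one row per feature set (`selected`,
#'   `baseline`, `control`) and columns `meanTrain`, `meanTest`.
#' @slot perSweep data.frame with per-sweep balanced accuracies.
#' @slot numberSweeps integer.
#' @slot trainFraction numeric.
#' @slot seed integer.
#' @export
setClass("ValidationReport", representation(
    summary = "data.frame",
    perSweep = "data.frame",
    numberSweeps = "integer",
    trainFraction = "numeric",
    seed = "integer"
))

#' Exact Shapley-value explanation of the classifier
#'
#' Per class, a cells x genes matrix of Shapley values and the base value
#' (mean model output over the background sample). For every explained
#' cell, base value + sum of its Shapley values reconstructs the model
#' output exactly (additivity). Positive values push the model toward the
#' class, negative values away from it.
#'
#' @slot values named list of numeric matrices (one per class).
#' @slot baseValues numeric vector, one per class.
#' @slot modelOutput numeric matrix, cells x classes, the explained
#'   predicted probabilities.
#' @slot featureValues numeric matrix, cells x genes, expression of the
#'   explained cells (for summary plots).
#' @slot classes character.
#' @export
setClass("ShapSummary", representation(
    values = "list",
    baseValues = "numeric",
    modelOutput = "matrix",
    featureValues = "matrix",
    classes = "character"
))

#' Pruned decision-tree explanation
#'
#' @slot fit the underlying `rpart` fit.
#' @slot rules data.frame of internal nodes: `node`, `gene`, `threshold`,
#'   `lessBranch` (which child receives cells with expression below the
#'   threshold; stored orientation-free).
#' @slot leaves data.frame of leaves with per-class cell percentages.
#' @slot classes character.
#' @export
setClass("TreeExplanation", representation(
    fit = "ANY",
    rules = "data.frame",
    leaves = "data.frame",
    classes = "character"
))

#' Least-squares line fit to embedded coordinates
#'
#' Total-least-squares fit of the linear manifold x(t) = v t + c to a set
#' of 2-D points; `t` is the closed-form per-point position along the
#' line, `residual` the orthogonal distance to it.
#'
#' @slot v numeric length-2 unit direction vector.
#' @slot c numeric length-2 offset point (centroid).
#' @slot t numeric, per-point manifold parameter.
#' @slot residual numeric, per-point orthogonal distance.
#' @export
setClass("ManifoldFit", representation(
    v = "numeric",
    c = "numeric",
    t = "numeric",
    residual = "numeric"
))

setValidity("ManifoldFit", function(object) {
    if (length(object@v) != 2L || all(object@v == 0))
        return("v must be a non-zero 2-D direction")
    if (length(object@t) != length(object@residual))
        return("t and residual must be aligned")
    TRUE
})
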