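## A small matrix with a planted copy: A and C are noisy duplicates,
## B is independent noise.
copyFixture <- function(n = 600, seed = 1) {
    set.seed(seed)
    A <- rlnorm(n)
    C <- A * 1.5 + rnorm(n, 0, 0.05)
    B <- rlnorm(n)
    m <- rbind(A = A, B = B, C = C)
    colnames(m) <- sprintf("c%03d", seq_len(n))
    m
}

test_that("dependent pairs get edges, independent pairs do not", {
    bm <- binMatrix(copyFixture(), 100)
    g <- buildDependenceGraph(bm, alpha = 0.01)
    edges <- igraph::as_edgelist(g@graph)
    expect_identical(nrow(edges), 1L)
    expect_setequal(as.vector(edges), c("A", "C"))
    expect_lt(g@pValues["A", "C"], 1e-10)

    ## singleton subset: empty graph, no tests
    g1 <- buildDependenceGraph(bm, "A", alpha = 0.01)
    expect_identical(igraph::ecount(g1@graph), 0)
    expect_identical(igraph::vcount(g1@graph), 1)
})

test_that("dissection retains complete components and cuts mediators", {
    ## edgeless singleton
    g <- igraph::make_empty_graph(directed = FALSE) +
        igraph::vertices("A")
    d <- dissectComponent(g)
    expect_identical(d$retained, "A")
    expect_identical(d$removed, character(0))

    ## path A-B-C: exhaustive enumeration says {B} is the only size-1
    ## vertex cut, so B is removed and A, C retained
    path <- igraph::make_graph(~ A - B, B - C)
    cuts1 <- Filter(function(v) {
        sub <- igraph::delete_vertices(path, v)
        igraph::components(sub)$no > 1
    }, igraph::V(path)$name)
    expect_identical(cuts1, "B")
    d <- dissectComponent(path)
    expect_identical(d$removed, "B")
    expect_identical(d$retained, c("A", "C"))

    ## triangle: complete, retained whole
    tri <- igraph::make_graph(~ A - B, B - C, C - A)
    d <- dissectComponent(tri)
    expect_identical(d$retained, c("A", "B", "C"))
    expect_identical(d$removed, character(0))

    ## clique with a pendant: the attachment vertex is the cut
    g <- igraph::make_graph(~ A - B, B - C, C - A, A - D)
    d <- dissectComponent(g)
    expect_identical(d$removed, "A")
    expect_setequal(d$retained, c("B", "C", "D"))
})

test_that("chunking with clusterSize >= n equals unchunked dissection", {
    m <- copyFixture()
    res <- lapply(c(1, 99), function(s)
        suppressMessages(principalFeatureAnalysis(m, pipelineConfig(
            minNDatapointsABin = 100, clusterSize = 10, seed = s))))
    ## single chunk: seed-independent result
    expect_identical(principalFeatures(res[[1]]),
                     principalFeatures(res[[2]]))
    ## duplicate pair forms a retained complete 2-subgraph under "all"
    expect_setequal(principalFeatures(res[[1]]), c("A", "B", "C"))

    rep <- suppressMessages(principalFeatureAnalysis(m, pipelineConfig(
        minNDatapointsABin = 100, clusterSize = 10, seed = 1,
        completeSubgraphPolicy = "representative")))
    ## one of the duplicates is dropped, the independent gene survives
    expect_length(principalFeatures(rep), 2L)
    expect_true("B" %in% principalFeatures(rep))
    expect_identical(
        removedFeatures(rep)$reason[removedFeatures(rep)$gene != "B"],
        "non-representative")
})

test_that("independent noise features survive up to false-positive edges", {
    set.seed(30)
    m <- matrix(rlnorm(20 * 600), 20, 600,
                dimnames = list(sprintf("n%02d", 1:20),
                                sprintf("c%03d", 1:600)))
    pfa <- suppressMessages(principalFeatureAnalysis(m, pipelineConfig(
        minNDatapointsABin = 100, seed = 4)))
    ## ~190 pairs tested at alpha = 0.01: expected ~2 false edges, each
    ## removing at most one feature; 8 removals is far in the tail
    expect_gte(length(principalFeatures(pfa)), 12L)
})

test_that("planted parent/copy pairs are always deduplicated", {
    sim <- generateSyntheticDataset(nMarkerGenes = 0,
        nRedundantGenes = 10, nNoiseGenes = 60, nConstantGenes = 0,
        seed = 2)
    pfa <- suppressMessages(principalFeatureAnalysis(sim$matrix,
        pipelineConfig(minNDatapointsABin = 100, seed = 2,
                       completeSubgraphPolicy = "representative")))
    pf <- principalFeatures(pfa)
    pairs <- sim$truth$redundant
    bothKept <- pairs$gene %in% pf & pairs$parent %in% pf
    expect_identical(sum(bothKept), 0L)
    ## constants logged with reason, rounds bounded, termination
    expect_lte(pfa@rounds, 10L)
    expect_identical(sort(c(pf, removedFeatures(pfa)$gene)),
                     sort(rownames(sim$matrix)))
})
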