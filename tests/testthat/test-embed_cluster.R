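test_that("well-separated blobs stay separated in the embedding", {
    blobs <- twoBlobs(nPer = 80, dims = 10, sep = 10)
    m <- t(blobs$points)             # genes x cells orientation
    rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
    emb <- embedCells(m, seed = 5)
    xy <- embeddingCoords(emb)
    a <- xy[blobs$membership == 0, ]
    b <- xy[blobs$membership == 1, ]
    radius <- function(p) {
        ctr <- colMeans(p)
        stats::quantile(sqrt(rowSums(sweep(p, 2, ctr)^2)), 0.95)
    }
    centroidDist <- sqrt(sum((colMeans(a) - colMeans(b))^2))
    expect_gt(centroidDist, radius(a))
    expect_gt(centroidDist, radius(b))

    ## dimensionality and determinism
    emb3 <- embedCells(m, nComponents = 3, seed = 5)
    expect_identical(ncol(embeddingCoords(emb3)), 3L)
    emb2 <- embedCells(m, seed = 5)
    expect_identical(embeddingCoords(emb2), xy)
    expect_error(embedCells(m[, 1, drop = FALSE]), "2 cells")
})

test_that("density clustering labels blobs and flags noise", {
    set.seed(9)
    pts <- rbind(matrix(rnorm(200, 0, 0.3), 100, 2),
                 matrix(rnorm(200, 6, 0.3), 100, 2),
                 c(30, 30))           # one far-away point
    rownames(pts) <- sprintf("p%03d", seq_len(nrow(pts)))
    cl <- clusterDensity(pts, method = "dbscan", eps = 1,
                         minSamples = 15)
    ids <- clusterIds(cl)
    expect_identical(length(setdiff(unique(ids), -1L)), 2L)
    expect_identical(unname(ids[201]), -1L)
    expect_identical(sum(ids == -1L), 1L)
    ## the two blobs are label-pure
    expect_identical(length(unique(ids[1:100])), 1L)
    expect_identical(length(unique(ids[101:200])), 1L)

    hl <- clusterDensity(pts, method = "hdbscan", minClusterSize = 15)
    hid <- clusterIds(hl)
    expect_identical(length(setdiff(unique(hid), -1L)), 2L)
    expect_identical(length(unique(hid[1:100])), 1L)
    expect_identical(length(unique(hid[101:200])), 1L)
    expect_identical(unname(hid[201]), -1L)

    expect_error(clusterDensity(pts, eps = 1e-6, minSamples = 15),
                 "noise")
})

test_that("box labeling is exact and rejects overlap", {
    pts <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
                 matrix(rnorm(100, 6, 0.3), 50, 2))
    all <- labelByBox(pts, list(rbind(c(-99, 99), c(-99, 99))))
    expect_true(all(clusterIds(all) == 0L))
    none <- labelByBox(pts, list())
    expect_true(all(clusterIds(none) == -1L))
    two <- labelByBox(pts, list(rbind(c(-2, 2), c(-2, 2)),
                                rbind(c(4, 8), c(4, 8))))
    expect_identical(unname(clusterIds(two)),
                     rep(c(0L, 1L), each = 50))
    expect_error(labelByBox(pts, list(rbind(c(-2, 7), c(-2, 7)),
                                      rbind(c(4, 8), c(4, 8)))),
                 "overlap")
})

test_that("composition excludes noise and reports purity", {
    lab <- externalLabels(c(rep(0L, 30), rep(1L, 30), -1L, -1L),
                          sprintf("c%02d", 1:62))
    cond <- factor(c(rep("OLD", 30), rep("OLD", 15), rep("YOUNG", 15),
                     "OLD", "YOUNG"))
    names(cond) <- sprintf("c%02d", 1:62)
    comp <- clusterComposition(lab, cond)
    expect_equal(unname(comp$purity["0"]), 1.0)
    expect_equal(unname(comp$purity["1"]), 0.5)
    expect_identical(sum(comp$counts), 60L)   # noise never counted
    expect_identical(comp$nNoise, 2L)
    expect_error(clusterComposition(
        externalLabels(rep(-1L, 3), c("a", "b", "c")),
        factor(c("x", "y", "z"))), "non-noise")
})

test_that("stratified splits are disjoint with near-equal strata", {
    lab <- externalLabels(rep(c(0L, 1L), c(100, 100)),
                          sprintf("c%03d", 1:200))
    sp <- splitCells(lab, 2, seed = 3)
    expect_identical(lengths(sp), c(100L, 100L))
    expect_length(intersect(sp[[1]], sp[[2]]), 0L)
    ids <- clusterIds(lab)
    for (s in sp)
        expect_identical(as.integer(table(ids[s])), c(50L, 50L))

    ## identity split
    one <- splitCells(lab, 1, seed = 3)
    expect_setequal(one[[1]], names(ids))

    ## odd strata differ by at most one
    lab3 <- externalLabels(rep(c(0L, 1L), c(101, 100)),
                           sprintf("c%03d", 1:201))
    sp3 <- splitCells(lab3, 2, seed = 3)
    counts <- vapply(sp3, function(s) sum(clusterIds(lab3)[s] == 0L),
                     integer(1))
    expect_lte(abs(diff(counts)), 1L)

    small <- externalLabels(c(0L, 0L, 1L), c("a", "b", "c"))
    expect_error(splitCells(small, 2), "too few")
})

test_that("embed + cluster recovers the planted conditions with purity", {
    sim <- generateSyntheticDataset(seed = 3)
    emb <- embedCells(sim$matrix, seed = 3)
    cl <- clusterDensity(emb, eps = 1, minSamples = 15)
    comp <- clusterComposition(cl, sim$labels)
    expect_gte(nrow(comp$counts), 2L)
    expect_gte(sum(comp$purity >= 0.9), 2L)
})
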