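test_that("expression CSV round-trips bit-for-bit", {
    sim <- generateSyntheticDataset(nCellsPerCondition = 10,
        nMarkerGenes = 2, nRedundantGenes = 2, nNoiseGenes = 5,
        nConstantGenes = 1, dropoutRate = 0, seed = 7)
    f1 <- tempfile(fileext = ".csv")
    f2 <- tempfile(fileext = ".csv")
    writeExpressionCSV(sim$matrix, f1)
    se <- readExpressionCSV(f1)
    expect_identical(dim(se), dim(sim$matrix))
    expect_identical(rownames(se), rownames(sim$matrix))
    expect_identical(colnames(se), colnames(sim$matrix))
    writeExpressionCSV(se, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("reader preserves file order and rejects malformed input", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("gene,c1,c2,c3",
                 "g1,0.5,1.5,2.5",
                 "g2,3,4,5"), f)
    se <- readExpressionCSV(f)
    expect_identical(rownames(se), c("g1", "g2"))
    expect_identical(colnames(se), c("c1", "c2", "c3"))
    expect_equal(unname(SummarizedExperiment::assay(se)[2, 1]), 3)

    writeLines(c("gene,c1,c2", "g1,1,2", "g2,NA,4"), f)
    expect_error(readExpressionCSV(f), "g2.*c1")
    writeLines(c("gene,c1,c2", "g1,1,2", "g1,3,4"), f)
    expect_error(readExpressionCSV(f), "duplicate")
    expect_error(readExpressionCSV(tempfile()), "not found")
    expect_error(expressionMatrix(matrix(-1, 1, 1,
        dimnames = list("g", "c"))), "nonnegative")
})

test_that("labels align by cell id under any permutation", {
    m <- expressionMatrix(tinyMatrix())
    f <- tempfile(fileext = ".csv")
    write.csv(data.frame(cell_id = c("c3", "c1", "c2"),
                         condition = c("OLD", "YOUNG", "YOUNG")),
              f, row.names = FALSE)
    lab <- readLabelsCSV(f, m)
    expect_identical(names(lab), c("c1", "c2", "c3"))
    expect_identical(as.character(lab), c("YOUNG", "YOUNG", "OLD"))

    ## positional single-column variant
    write.csv(data.frame(condition = c("A", "B", "A")), f,
              row.names = FALSE)
    expect_identical(as.character(readLabelsCSV(f, m)),
                     c("A", "B", "A"))

    write.csv(data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                         condition = rep("A", 4)), f, row.names = FALSE)
    expect_error(readLabelsCSV(f, m), "4 rows.*3 cells")
    write.csv(data.frame(cell_id = c("c1", "c2", "cX"),
                         condition = rep("A", 3)), f, row.names = FALSE)
    expect_error(readLabelsCSV(f, m), "unknown cell id")
})

test_that("configuration defaults match the reference settings", {
    cfg <- pipelineConfig()
    expect_identical(cfg@minNDatapointsABin, 500L)
    expect_identical(cfg@alpha, 0.01)
    expect_identical(cfg@clusterSize, 50L)
    expect_identical(cfg@nComponents, 2L)
    expect_identical(cfg@eps, 1)
    expect_identical(cfg@minSamples, 15L)
    expect_identical(cfg@minClusterSize, 15L)
    expect_identical(cfg@nHighestMutualInformation, 5L)
    expect_identical(cfg@numberOutputFunctions, 1L)
    expect_identical(cfg@numberSweeps, 20L)
    expect_identical(cfg@minSamplesLeaf, 10L)
    expect_error(pipelineConfig(alpha = 2), "alpha")
    expect_error(pipelineConfig(nonsense = 1), "unknown configuration")
})

test_that("configuration files (YAML and JSON) are read back", {
    fy <- tempfile(fileext = ".yaml")
    writeLines(c("alpha: 0.05", "clusterSize: 25", "seed: 9"), fy)
    cfg <- readPipelineConfig(fy)
    expect_identical(cfg@alpha, 0.05)
    expect_identical(cfg@clusterSize, 25L)
    fj <- tempfile(fileext = ".json")
    writeLines('{"minNDatapointsABin": 100, "eps": 0.5}', fj)
    cfg <- readPipelineConfig(fj)
    expect_identical(cfg@minNDatapointsABin, 100L)
    expect_identical(cfg@eps, 0.5)
})
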