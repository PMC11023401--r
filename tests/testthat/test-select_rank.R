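test_that("output functions restrict to the selected clusters", {
    lab <- externalLabels(c(rep(0L, 40), rep(1L, 35), rep(-1L, 5)),
                          sprintf("c%02d", 1:80))
    of <- makeOutputFunction(lab, c(0, 1))
    expect_length(of@cells, 75L)
    expect_identical(nlevels(of@values), 2L)
    expect_error(makeOutputFunction(lab, 0), "at least 2")
    expect_error(makeOutputFunction(lab, c(0, 7)), "not present")
    ## arbitrary ids such as 8 and 5 are accepted verbatim
    lab2 <- externalLabels(rep(c(8L, 5L), each = 10),
                           sprintf("c%02d", 1:20))
    of2 <- makeOutputFunction(lab2, c(8, 5))
    expect_identical(levels(of2@values), c("5", "8"))
})

test_that("chi-square filter keeps markers and drops unrelated genes", {
    sim <- generateSyntheticDataset(seed = 4)
    cfg <- pipelineConfig(minNDatapointsABin = 100, seed = 4)
    of <- conditionOutput(sim)
    res <- findClusterDifferences(sim$matrix, of, cfg)[[1]]
    ## perfectly informative planted markers: p ~ 0
    markers <- res[res$gene %in% sim$truth$markers, ]
    expect_identical(nrow(markers), 5L)
    expect_true(all(markers$pValue < 1e-50))
    expect_true(all(markers$retained))
    ## constant genes never reach the test
    expect_false(any(sim$truth$constants %in% res$gene))
    ## pure-noise genes are retained at roughly the test level
    noise <- res[res$gene %in% sim$truth$noise, ]
    expect_lte(mean(noise$retained), 0.05)
    ## Benjamini-Hochberg option tightens the selection
    bh <- findClusterDifferences(sim$matrix, of, cfg,
                                 correct = "BH")[[1]]
    expect_lte(sum(bh$retained), sum(res$retained))
})

test_that("mutual-information ranking puts markers first at 1 bit", {
    sim <- generateSyntheticDataset(seed = 4)
    cfg <- pipelineConfig(minNDatapointsABin = 100, seed = 4)
    of <- conditionOutput(sim)
    res <- findClusterDifferences(sim$matrix, of, cfg)[[1]]
    rk <- rankByMutualInformation(sim$matrix, res$gene[res$retained],
                                  of, 5, cfg)
    df <- ranking(rk)
    expect_setequal(topGenes(rk, 5), sim$truth$markers)
    expect_equal(df$mutual_information[1:5], rep(1, 5))
    expect_true(all(diff(df$mutual_information) <= 0))
    ## monotone transformations leave the ranking untouched
    m2 <- SummarizedExperiment::assay(sim$matrix, "expression")
    m2[sim$truth$markers[1], ] <- log1p(m2[sim$truth$markers[1], ])
    rk2 <- rankByMutualInformation(m2, res$gene[res$retained], of, 5,
                                   cfg)
    expect_identical(ranking(rk2)$mutual_information,
                     df$mutual_information)
    expect_warning(
        rankByMutualInformation(sim$matrix, sim$truth$markers[1:2],
                                of, 5, cfg), "exceeds")
})

test_that("rankings are written in the interchange format", {
    sim <- generateSyntheticDataset(nCellsPerCondition = 100,
        nMarkerGenes = 2, nRedundantGenes = 0, nNoiseGenes = 10,
        nConstantGenes = 0, seed = 6)
    cfg <- pipelineConfig(minNDatapointsABin = 50, seed = 6)
    of <- conditionOutput(sim)
    rk <- rankByMutualInformation(sim$matrix, rownames(sim$matrix), of,
                                  2, cfg)
    d <- tempfile(); dir.create(d)
    path <- writeRankedFeatures(rk, d)
    expect_identical(basename(path), "mutual_information0.csv")
    back <- read.csv(path)
    expect_identical(colnames(back), c("gene", "mutual_information"))
    expect_identical(back$gene, ranking(rk)$gene)
})

test_that("the combined matrix places output functions first", {
    sim <- generateSyntheticDataset(nCellsPerCondition = 50,
        nMarkerGenes = 1, nRedundantGenes = 0, nNoiseGenes = 3,
        nConstantGenes = 0, seed = 2)
    of <- conditionOutput(sim)
    cm <- makeCombinedMatrix(sim$matrix, of)
    expect_identical(rownames(cm)[1], "output_fct_0")
    expect_identical(nrow(cm), nrow(sim$matrix) + 1L)
    expect_setequal(unique(cm[1, ]), c(0, 1))
})
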