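## Small two-class dataset with one perfectly separating gene and a few
## noise genes.
separableFixture <- function(n = 120, seed = 13) {
    set.seed(seed)
    y <- rep(c("A", "B"), each = n / 2)
    m <- rbind(sep = ifelse(y == "A", runif(n, 0, 0.4),
                            runif(n, 1, 1.6)),
               n1 = rlnorm(n), n2 = rlnorm(n), n3 = rlnorm(n))
    colnames(m) <- sprintf("c%03d", seq_len(n))
    of <- makeOutputFunction(externalLabels(factor(y),
                                            colnames(m)), c(0, 1))
    list(m = m, of = of, y = y)
}

test_that("balanced accuracy is the macro-average of recalls", {
    truth <- factor(c("A", "A", "A", "B"))
    pred <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
    expect_equal(balancedAccuracy(truth, pred), (2/3 + 1) / 2)
})

test_that("a perfectly separating gene validates at 100%", {
    fx <- separableFixture()
    cfg <- pipelineConfig(numberSweeps = 3, seed = 2)
    rep <- validateClassifier(fx$m, "sep", fx$of, cfg,
                              baseline = FALSE, control = FALSE)
    expect_equal(rep@summary$meanTest[rep@summary$set == "selected"],
                 100)
    expect_identical(nrow(rep@perSweep), 3L)
    expect_error(validateClassifier(fx$m[, 1:8], "sep",
        makeOutputFunction(externalLabels(
            factor(c("A", "A", "A", "B", "B", "B", "B", "B")),
            colnames(fx$m)[1:8]), c(0, 1)),
        cfg), "at least 4 cells")
})

test_that("permuted labels validate at chance level", {
    fx <- separableFixture()
    set.seed(77)
    yPerm <- sample(fx$y)
    ofPerm <- makeOutputFunction(externalLabels(factor(yPerm),
                                                colnames(fx$m)),
                                 c(0, 1))
    cfg <- pipelineConfig(numberSweeps = 8, seed = 3)
    rep <- validateClassifier(fx$m, "sep", ofPerm, cfg,
                              baseline = FALSE, control = FALSE)
    acc <- rep@summary$meanTest[rep@summary$set == "selected"]
    expect_gt(acc, 35)
    expect_lt(acc, 65)
})

test_that("Shapley values are additive and respond to variance", {
    fx <- separableFixture()
    cfg <- pipelineConfig(seed = 5)
    sh <- shapSummary(fx$m, c("sep", "n1", "n2"), fx$of, cfg,
                      nBackground = 40, nExplain = 30)
    for (cl in sh@classes) {
        recon <- sh@baseValues[cl] + rowSums(sh@values[[cl]])
        expect_lt(max(abs(recon - sh@modelOutput[, cl])), 1e-2)
    }
    ## the separating gene dominates the attribution
    ord <- sort(colMeans(abs(sh@values[[1]])), decreasing = TRUE)
    expect_identical(names(ord)[1], "sep")

    ## single player receives the full attribution
    sh1 <- shapSummary(fx$m, "sep", fx$of, cfg, nBackground = 40,
                       nExplain = 20)
    cl <- sh1@classes[1]
    expect_equal(unname(sh1@baseValues[cl] + sh1@values[[cl]][, 1]),
                 unname(sh1@modelOutput[, cl]), tolerance = 1e-10)

    ## a zero-variance gene in the selected set gets ~0 attribution
    m0 <- rbind(fx$m, flat = rep(1, ncol(fx$m)))
    sh0 <- shapSummary(m0, c("sep", "flat"), fx$of, cfg,
                       nBackground = 40, nExplain = 20)
    expect_lt(max(abs(sh0@values[[1]][, "flat"])), 1e-6)
})

test_that("the pruned tree recovers the planted threshold", {
    fx <- separableFixture()
    cfg <- pipelineConfig(maxDepth = 1, minSamplesLeaf = 10, seed = 5)
    tree <- decisionTreeExplain(fx$m, c("sep", "n1"), fx$of, cfg)
    expect_identical(nrow(tree@rules), 1L)
    expect_identical(tree@rules$gene, "sep")
    ## order-statistic bound: the split lies in the gap between classes
    lowMax <- max(fx$m["sep", fx$y == "A"])
    highMin <- min(fx$m["sep", fx$y == "B"])
    expect_gt(tree@rules$threshold, lowMax)
    expect_lt(tree@rules$threshold, highMin)
    ## two pure leaves, percentages summing to 100
    expect_identical(nrow(tree@leaves), 2L)
    pct <- as.matrix(tree@leaves[, tree@classes])
    expect_equal(unname(rowSums(pct)), c(100, 100))
    expect_setequal(round(pct[, 1]), c(0, 100))
    expect_match(paste(treeText(tree), collapse = "\n"), "if sep <")

    ## over-aggressive pruning degenerates with a warning
    expect_warning(decisionTreeExplain(fx$m, "n1", fx$of,
        pipelineConfig(minSamplesLeaf = 70, seed = 5)), "single leaf")
})
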