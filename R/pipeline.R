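#' Run the full characteristic-feature-extraction pipeline
#'
#' Executes the stages in order — principal feature analysis (optional),
#' embedding, density clustering, comparison with external condition
#' labels (optional), subsample splitting (optional), chi-square gene
#' selection, mutual-information ranking, classifier validation and
#' explainability — and writes one artifact per stage into `outDir`
#' together with a manifest recording every parameter and seed, so each
#' run is reproducible from the manifest alone. Stages can be skipped;
#' a later stage that needs a skipped stage's output raises an explicit
#' dependency error.
#'
#' Artifacts: `principal_features.txt`, `removal_log.csv`,
#' `embedding.csv`, `labels.csv`, `composition.csv` (with labels),
#' `mutual_information<i>.csv`, `validation.json`, `tree.txt`,
#' `shap_class_<class>.csv` and `manifest.json`.
#'
#' @param input a `SummarizedExperiment`, genes x cells matrix, or path
#'   to a `preprocessed_data.csv`.
#' @param labels optional per-cell conditions: a factor, or path to a
#'   `comparison_labels.csv`.
#' @param config a [PipelineConfig-class].
#' @param outDir output directory.
#' @param skipPfa embed all non-constant genes instead of the principal
#'   features.
#' @param split number of disjoint subsamples (1 = no splitting; with
#'   more, selection runs on the first subsample).
#' @param skipValidate,skipExplain disable the corresponding stages.
#' @return invisibly, a list with every intermediate result.
#' @export
runPipeline <- function(input, labels = NULL,
                        config = pipelineConfig(), outDir = "charfeat_run",
                        skipPfa = FALSE, split = 1L,
                        skipValidate = FALSE, skipExplain = FALSE) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    se <- if (is.character(input)) readExpressionCSV(input) else input
    vals <- .exprValues(se)
    conditions <- if (is.character(labels)) {
        readLabelsCSV(labels, se)
    } else labels
    manifest <- list(
        config = stats::setNames(lapply(
            methods::slotNames("PipelineConfig"),
            function(s) methods::slot(config, s)),
            methods::slotNames("PipelineConfig")),
        nGenes = nrow(vals), nCells = ncol(vals),
        skipPfa = skipPfa, split = split)

    ## 1. feature reduction
    features <- if (skipPfa) {
        removeConstantFeatures(vals)$matrix |> rownames()
    } else {
        pfa <- principalFeatureAnalysis(se, config)
        writeLines(principalFeatures(pfa),
                   file.path(outDir, "principal_features.txt"))
        write.csv(removedFeatures(pfa),
                  file.path(outDir, "removal_log.csv"),
                  row.names = FALSE, quote = FALSE)
        principalFeatures(pfa)
    }
    manifest$nPrincipalFeatures <- length(features)

    ## 2. embedding
    emb <- embedCells(se, features, method = config@embeddingMethod,
                      nComponents = config@nComponents,
                      nNeighbors = config@nNeighbors,
                      minDist = config@minDist, metric = config@metric,
                      seed = config@seed)
    write.csv(data.frame(cell_id = rownames(emb@coords), emb@coords,
                         check.names = FALSE),
              file.path(outDir, "embedding.csv"), row.names = FALSE,
              quote = FALSE)

    ## 3. density labeling
    cl <- clusterDensity(emb, method = config@clusterMethod,
                         eps = config@eps,
                         minSamples = config@minSamples,
                         minClusterSize = config@minClusterSize)
    write.csv(data.frame(cell_id = cl@cellIds, label = cl@labels),
              file.path(outDir, "labels.csv"), row.names = FALSE,
              quote = FALSE)

    ## 4. comparison with external labels (optional sanity check)
    composition <- NULL
    if (!is.null(conditions)) {
        composition <- clusterComposition(cl, conditions)
        compDf <- as.data.frame(as.table(composition$counts))
        write.csv(compDf, file.path(outDir, "composition.csv"),
                  row.names = FALSE, quote = FALSE)
        grDevices::png(file.path(outDir, "composition.png"), 900, 600)
        print(plotComposition(composition))
        grDevices::dev.off()
    }

    ## choose the clusters to compare
    clusters <- config@clusters
    if (length(clusters) < 2L) {
        sizes <- table(cl@labels[cl@labels != -1L])
        if (length(sizes) < 2L)
            stop("fewer than 2 clusters found; cannot compare ",
                 "(adjust clustering parameters or set config@clusters)")
        clusters <- as.integer(names(sort(sizes,
                                          decreasing = TRUE))[1:2])
        .logStage("select", sprintf(
            "no clusters configured; comparing the two largest (%d, %d)",
            clusters[1L], clusters[2L]))
    }
    manifest$clusters <- clusters

    ## 5. optional subsample splitting
    output <- makeOutputFunction(cl, clusters)
    if (split > 1L) {
        subsets <- splitCells(cl, split, seed = config@seed)
        keep <- output@cells %in% subsets[[1L]]
        output <- methods::new("OutputFunction",
                               values = droplevels(output@values[keep]),
                               cells = output@cells[keep],
                               kind = "discrete", index = 0L)
        manifest$selectionCells <- length(output@cells)
    }

    ## 6 + 7. chi-square selection and mutual-information ranking
    diffs <- findClusterDifferences(se, output, config)[[1L]]
    retained <- diffs$gene[diffs$retained]
    if (length(retained) == 0L)
        stop("no gene separates the selected clusters at alpha = ",
             config@alpha)
    ranked <- rankByMutualInformation(se, retained, output,
                                      config@nHighestMutualInformation,
                                      config)
    writeRankedFeatures(ranked, outDir)
    genes <- topGenes(ranked, config@nHighestMutualInformation)
    manifest$selectedGenes <- genes

    ## 8. validation
    report <- NULL
    if (!skipValidate) {
        report <- validateClassifier(se, genes, output, config)
        jsonlite::write_json(list(summary = report@summary,
                                  perSweep = report@perSweep,
                                  numberSweeps = report@numberSweeps,
                                  trainFraction = report@trainFraction,
                                  seed = report@seed),
                             file.path(outDir, "validation.json"),
                             auto_unbox = TRUE, digits = NA)
    }

    ## 9. explainability
    shap <- NULL
    tree <- NULL
    if (!skipExplain) {
        shap <- shapSummary(se, genes, output, config)
        for (cls in shap@classes) {
            write.csv(data.frame(cell_id = rownames(shap@values[[cls]]),
                                 shap@values[[cls]], check.names = FALSE),
                      file.path(outDir, sprintf("shap_class_%s.csv",
                                                cls)),
                      row.names = FALSE, quote = FALSE)
            grDevices::png(file.path(outDir,
                                     sprintf("shap_class_%s.png", cls)),
                           900, 600)
            print(plotShapSummary(shap, cls))
            grDevices::dev.off()
        }
        tree <- decisionTreeExplain(se, genes, output, config)
        writeLines(treeText(tree), file.path(outDir, "tree.txt"))
    }

    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(features = features, embedding = emb, labels = cl,
                   composition = composition, output = output,
                   differences = diffs, ranked = ranked, genes = genes,
                   validation = report, shap = shap, tree = tree,
                   manifest = manifest))
}
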