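#' Generate a synthetic two-condition expression dataset
#'
#' Seeded generator of a nonnegative genes x cells matrix carrying
#' exactly the structure the pipeline stages assume:
#'
#' * marker genes with disjoint per-condition expression ranges
#'   (log-normal within `[0, 0.9]` in one condition and `2 + lognormal`
#'   in the other — perfectly separating by construction),
#' * redundant genes, each a noisy linear copy
#'   `slope * parent + Gaussian noise` (clipped at 0) of a noise-gene
#'   parent, with the pair recorded as ground truth,
#' * condition-independent log-normal noise genes,
#' * constant genes, and
#' * optional dropout (a fraction of entries set to 0) on the noise and
#'   redundant genes. Markers and constants are exempt so that the
#'   disjoint-range and constantness guarantees hold exactly.
#'
#' The log-normal base with multiplicative noise mimics the positivity
#' and skew of normalized single-cell expression without claiming a
#' count model.
#'
#' @param nCellsPerCondition cells per condition (conditions `YOUNG`
#'   and `OLD`).
#' @param nMarkerGenes number of planted markers (upregulated in `OLD`).
#' @param nRedundantGenes number of noisy copies.
#' @param nNoiseGenes number of independent noise genes.
#' @param nConstantGenes number of constant genes.
#' @param dropoutRate fraction of noise/redundant entries set to 0.
#' @param seed integer seed; the output is deterministic in
#'   (parameters, seed).
#' @return list with `matrix` (a `SummarizedExperiment`, condition in
#'   `colData`), `labels` (named factor) and `truth` (list with
#'   `markers`, `redundant` data.frame of gene/parent/slope,
#'   `constants`, `conditions`).
#' @examples
#' sim <- generateSyntheticDataset(seed = 1)
#' dim(sim$matrix)  # 258 genes x 600 cells with the defaults
#' @export
generateSyntheticDataset <- function(nCellsPerCondition = 300L,
                                     nMarkerGenes = 5L,
                                     nRedundantGenes = 50L,
                                     nNoiseGenes = 200L,
                                     nConstantGenes = 3L,
                                     dropoutRate = 0.1,
                                     seed = 1L) {
    if (nCellsPerCondition < 1L)
        stop("at least one cell per condition required")
    nGenes <- nMarkerGenes + nRedundantGenes + nNoiseGenes +
        nConstantGenes
    if (nGenes < 1L) stop("no genes requested")
    if (nRedundantGenes > 0L && nNoiseGenes == 0L)
        stop("redundant genes need noise-gene parents")
    set.seed(seed)
    n <- 2L * nCellsPerCondition
    condition <- factor(rep(c("YOUNG", "OLD"), each = nCellsPerCondition),
                        levels = c("YOUNG", "OLD"))
    old <- condition == "OLD"

    rows <- list()
    markers <- if (nMarkerGenes > 0L)
        sprintf("marker_%02d", seq_len(nMarkerGenes)) else character(0)
    for (g in markers) {
        v <- numeric(n)
        v[!old] <- pmin(rlnorm(sum(!old), log(0.3), 0.4), 0.9)
        v[old] <- 2 + rlnorm(sum(old), log(0.5), 0.4)
        rows[[g]] <- v
    }
    noise <- if (nNoiseGenes > 0L)
        sprintf("noise_%03d", seq_len(nNoiseGenes)) else character(0)
    ## Noise amplitude is chosen so that the planted markers dominate the
    ## cell-cell distance structure even after feature reduction: with
    ## ~200 noise genes of per-gene variance <= ~0.05 the within-condition
    ## squared distance (~2 * 200 * var) stays below the between-condition
    ## excess contributed by the markers (~2 * delta^2 per marker,
    ## delta ~ 2.2), keeping the two conditions separable by the
    ## embedding.
    for (g in noise) {
        mu <- runif(1, 0.2, 1)
        rows[[g]] <- rlnorm(n, log(mu), 0.3)
    }
    redundant <- if (nRedundantGenes > 0L)
        sprintf("redundant_%02d", seq_len(nRedundantGenes)) else
        character(0)
    redundantTruth <- data.frame(gene = character(0),
                                 parent = character(0),
                                 slope = numeric(0),
                                 stringsAsFactors = FALSE)
    for (g in redundant) {
        parent <- sample(noise, 1L)
        slope <- runif(1, 0.5, 2)
        base <- slope * rows[[parent]]
        rows[[g]] <- pmax(0, base + rnorm(n, 0, 0.2 * sd(base)))
        redundantTruth <- rbind(redundantTruth, data.frame(
            gene = g, parent = parent, slope = slope,
            stringsAsFactors = FALSE))
    }
    constants <- if (nConstantGenes > 0L)
        sprintf("constant_%01d", seq_len(nConstantGenes)) else
        character(0)
    for (g in constants) rows[[g]] <- rep(runif(1, 0, 2), n)

    mat <- do.call(rbind, rows)
    rownames(mat) <- names(rows)
    if (dropoutRate > 0) {
        target <- c(noise, redundant)
        for (g in target) {
            zero <- runif(n) < dropoutRate
            mat[g, zero] <- 0
        }
    }
    cellIds <- sprintf("cell_%04d", seq_len(n))
    perm <- sample(n)                 # shuffle cells across conditions
    mat <- mat[, perm, drop = FALSE]
    condition <- condition[perm]
    colnames(mat) <- cellIds
    labels <- stats::setNames(condition, cellIds)
    se <- expressionMatrix(mat, condition = condition)
    list(matrix = se, labels = labels,
         truth = list(markers = markers,
                      redundant = redundantTruth,
                      constants = constants,
                      noise = noise,
                      conditions = levels(condition)))
}

#' Write a synthetic dataset in the interchange dialect
#'
#' Writes `preprocessed_data.csv` (genes x cells, gene names first
#' column) and `comparison_labels.csv` (`cell_id,condition`) exactly as
#' [readExpressionCSV()]/[readLabelsCSV()] expect them, plus
#' `ground_truth.json` for test assertions.
#'
#' @param sim result of [generateSyntheticDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionCSV(sim$matrix, file.path(dir,
                                             "preprocessed_data.csv"))
    labels <- data.frame(cell_id = names(sim$labels),
                         condition = as.character(sim$labels),
                         stringsAsFactors = FALSE)
    write.csv(labels, file.path(dir, "comparison_labels.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(sim$truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
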