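## Single-hidden-layer MLP (nnet) with z-scored inputs. The hidden layer
## defaults to `hidden` units but shrinks so that the total number of
## weights stays below `maxWeights`: nnet's BFGS optimizer allocates a
## dense workspace quadratic in the weight count, which is prohibitive
## for wide inputs at full width.
.fitMlp <- function(X, y, hidden = 100L, maxWeights = 3000L,
                    maxit = 150L) {
    y <- droplevels(factor(y))
    K <- nlevels(y)
    p <- ncol(X)
    size <- max(1L, min(hidden, (maxWeights - K) %/% (p + 1L + K)))
    mu <- colMeans(X)
    sdv <- apply(X, 2L, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    fit <- nnet::nnet(Xs, nnet::class.ind(y), size = size,
                      softmax = TRUE, decay = 1e-4, maxit = maxit,
                      MaxNWts = 1e6, trace = FALSE)
    list(fit = fit, mu = mu, sd = sdv, levels = levels(y), size = size)
}

.predictProb <- function(model, X) {
    Xs <- sweep(sweep(as.matrix(X), 2L, model$mu), 2L, model$sd, "/")
    pr <- predict(model$fit, Xs)
    colnames(pr) <- model$levels
    pr
}

.predictClass <- function(model, X) {
    pr <- .predictProb(model, X)
    factor(model$levels[max.col(pr, ties.method = "first")],
           levels = model$levels)
}

#' Balanced accuracy (macro-averaged recall)
#'
#' @param truth,predicted factors over the same cells.
#' @return value in `[0, 1]`.
#' @export
balancedAccuracy <- function(truth, predicted) {
    truth <- factor(truth)
    predicted <- factor(predicted, levels = levels(truth))
    recalls <- vapply(levels(truth), function(cl) {
        idx <- truth == cl
        mean(predicted[idx] == cl)
    }, numeric(1))
    mean(recalls)
}

.stratifiedSplit <- function(y, trainFraction) {
    train <- integer(0)
    for (cl in levels(y)) {
        idx <- which(y == cl)
        nTrain <- max(1L, round(length(idx) * trainFraction))
        train <- c(train, sample(idx, nTrain))
    }
    sort(train)
}

#' Classifier-based validation of a gene selection
#'
#' Repeats `numberSweeps` times: stratified train/test split (default
#' 75/25), train a multi-layer-perceptron classifier on the selected
#' genes, record the balanced accuracy (macro-averaged recall) on train
#' and test. Two reference feature sets are evaluated on the same
#' splits: a fresh random gene set of equal size drawn each sweep from
#' the non-constant genes outside the selection (baseline — the negative
#' control must not contain the genes under test), and all non-constant
#' genes (control — a high selected-set accuracy close to the control
#' shows the selection kept the separating information).
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param genes the selected genes.
#' @param output a discrete [OutputFunction-class] (>= 2 classes, each
#'   with at least 4 cells).
#' @param config a [PipelineConfig-class] (`numberSweeps`,
#'   `trainFraction`, `hiddenUnits`, `maxWeights`, `seed`).
#' @param baseline,control logical, include the reference feature sets.
#' @return a [ValidationReport-class]; accuracies are percentages.
#' @export
validateClassifier <- function(x, genes, output,
                               config = pipelineConfig(),
                               baseline = TRUE, control = TRUE) {
    vals <- .exprValues(x)
    if (output@kind != "discrete")
        stop("classification validation needs a discrete output function")
    y <- droplevels(factor(output@values))
    if (any(table(y) < 4L))
        stop("every class needs at least 4 cells")
    sub <- t(vals[, output@cells, drop = FALSE])   # cells x genes
    rng <- apply(sub, 2L, function(v) max(v) - min(v))
    nonConstant <- colnames(sub)[rng > 0]
    missing <- setdiff(genes, colnames(sub))
    if (length(missing)) stop("unknown gene(s) in selection")
    pool <- setdiff(nonConstant, genes)
    sets <- c("selected", if (baseline) "baseline",
              if (control) "control")
    sweeps <- expand.grid(sweep = seq_len(config@numberSweeps),
                          set = sets, stringsAsFactors = FALSE)
    sweeps$train <- NA_real_
    sweeps$test <- NA_real_
    for (s in seq_len(config@numberSweeps)) {
        set.seed(config@seed + s)
        trainIdx <- .stratifiedSplit(y, config@trainFraction)
        testIdx <- setdiff(seq_along(y), trainIdx)
        randomGenes <- if (baseline)
            sample(pool, min(length(genes), length(pool)))
        for (set in sets) {
            gset <- switch(set, selected = genes,
                           baseline = randomGenes, control = nonConstant)
            model <- .fitMlp(sub[trainIdx, gset, drop = FALSE],
                             y[trainIdx], hidden = config@hiddenUnits,
                             maxWeights = config@maxWeights)
            accTr <- balancedAccuracy(y[trainIdx],
                .predictClass(model, sub[trainIdx, gset, drop = FALSE]))
            accTe <- balancedAccuracy(y[testIdx],
                .predictClass(model, sub[testIdx, gset, drop = FALSE]))
            row <- sweeps$sweep == s & sweeps$set == set
            sweeps$train[row] <- 100 * accTr
            sweeps$test[row] <- 100 * accTe
        }
    }
    summary <- do.call(rbind, lapply(sets, function(set) {
        rows <- sweeps[sweeps$set == set, ]
        data.frame(set = set, meanTrain = mean(rows$train),
                   meanTest = mean(rows$test),
                   stringsAsFactors = FALSE)
    }))
    .logStage("validate", paste(sprintf(
        "%s: train %.1f%% / test %.1f%%", summary$set, summary$meanTrain,
        summary$meanTest), collapse = "; "))
    methods::new("ValidationReport", summary = summary,
                 perSweep = sweeps,
                 numberSweeps = config@numberSweeps,
                 trainFraction = config@trainFraction,
                 seed = config@seed)
}

setMethod("show", "ValidationReport", function(object) {
    cat("ValidationReport:", object@numberSweeps, "sweeps,",
        sprintf("%d/%d", round(100 * object@trainFraction),
                round(100 * (1 - object@trainFraction))),
        "stratified splits\n")
    print(object@summary, row.names = FALSE)
})

## All coalitions of m players as a 2^m x m logical matrix (bitmask
## order: coalition k contains player j iff bit j of k is set).
.coalitions <- function(m) {
    masks <- 0:(2^m - 1)
    vapply(seq_len(m), function(j) bitwAnd(masks, 2^(j - 1)) > 0,
           logical(2^m))
}

#' Exact Shapley-value explanation of the validation classifier
#'
#' Trains the MLP classifier on the selected genes (same contract as
#' [validateClassifier()], all cells) and computes exact Shapley values
#' for each explained cell by full coalition enumeration: the value of a
#' coalition S is the mean predicted class probability with the genes in
#' S fixed to the cell's values and the rest drawn from a background
#' sample. With full enumeration the additivity property
#' `base value + sum(shapley) = model output` holds to machine
#' precision. Positive values push the model toward the class under
#' inspection, negative values away from it.
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param genes selected genes (at most 16; the enumeration is exact).
#' @param output a discrete [OutputFunction-class].
#' @param config a [PipelineConfig-class].
#' @param nBackground background sample size (cost control).
#' @param nExplain number of cells to explain (seeded subsample).
#' @return a [ShapSummary-class].
#' @export
shapSummary <- function(x, genes, output, config = pipelineConfig(),
                        nBackground = 100L, nExplain = 100L) {
    m <- length(genes)
    if (m < 1L) stop("empty gene set")
    if (m > 16L)
        stop("exact enumeration supports at most 16 genes")
    vals <- .exprValues(x)
    sub <- t(vals[genes, output@cells, drop = FALSE])
    y <- droplevels(factor(output@values))
    set.seed(config@seed)
    model <- .fitMlp(sub, y, hidden = config@hiddenUnits,
                     maxWeights = config@maxWeights)
    bgIdx <- sample(nrow(sub), min(nBackground, nrow(sub)))
    exIdx <- sample(nrow(sub), min(nExplain, nrow(sub)))
    background <- sub[bgIdx, , drop = FALSE]
    nbg <- nrow(background)
    coal <- .coalitions(m)
    nC <- nrow(coal)
    masks <- 0:(nC - 1)
    sizes <- rowSums(coal)
    ## Shapley kernel weight for the marginal contribution of a player
    ## to a coalition of size s (player excluded): s!(m-s-1)!/m!
    wgt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1:m) -
               lfactorial(m))
    classes <- model$levels
    phis <- lapply(classes, function(cl)
        matrix(0, length(exIdx), m, dimnames = list(
            rownames(sub)[exIdx], genes)))
    names(phis) <- classes
    vEmpty <- colMeans(.predictProb(model, background))
    modelOut <- .predictProb(model, sub[exIdx, , drop = FALSE])
    rownames(modelOut) <- rownames(sub)[exIdx]
    for (ci in seq_along(exIdx)) {
        xcell <- sub[exIdx[ci], ]
        big <- background[rep(seq_len(nbg), times = nC), , drop = FALSE]
        for (k in seq_len(nC)) {
            S <- coal[k, ]
            if (!any(S)) next
            rows <- ((k - 1L) * nbg + 1L):(k * nbg)
            big[rows, S] <- matrix(xcell[S], nbg, sum(S), byrow = TRUE)
        }
        pr <- .predictProb(model, big)
        for (cl in classes) {
            v <- colMeans(matrix(pr[, cl], nbg, nC))  # one per coalition
            for (j in seq_len(m)) {
                bit <- 2^(j - 1)
                without <- masks[bitwAnd(masks, bit) == 0L]
                contrib <- v[without + bit + 1L] - v[without + 1L]
                phis[[cl]][ci, j] <-
                    sum(wgt[sizes[without + 1L] + 1L] * contrib)
            }
        }
    }
    methods::new("ShapSummary", values = phis, baseValues = vEmpty,
                 modelOutput = modelOut,
                 featureValues = sub[exIdx, , drop = FALSE],
                 classes = classes)
}

setMethod("show", "ShapSummary", function(object) {
    cat("ShapSummary:", nrow(object@featureValues), "cells x",
        ncol(object@featureValues), "genes,",
        length(object@classes), "classes\n")
    for (cl in object@classes)
        cat(sprintf("  class %s: base value %.3f, mean |shap| %s\n", cl,
                    object@baseValues[cl],
                    paste(sprintf("%s=%.3f",
                                  colnames(object@values[[cl]]),
                                  colMeans(abs(object@values[[cl]]))),
                          collapse = " ")))
})

#' Beeswarm-style summary plot of Shapley values
#'
#' One row per gene (ordered by mean absolute Shapley value), points are
#' cells, the x-axis is the Shapley value and the color encodes the
#' cell's expression of the gene.
#'
#' @param shap a [ShapSummary-class].
#' @param class which class to plot (default: first).
#' @param file optional PNG path.
#' @return a ggplot object.
#' @export
plotShapSummary <- function(shap, class = shap@classes[1L], file = NULL) {
    values <- shap@values[[as.character(class)]]
    fv <- shap@featureValues
    ord <- names(sort(colMeans(abs(values))))
    df <- do.call(rbind, lapply(colnames(values), function(g) {
        data.frame(gene = g, shap = values[, g],
                   value = (fv[, g] - min(fv[, g])) /
                       max(1e-12, diff(range(fv[, g]))))
    }))
    df$gene <- factor(df$gene, levels = ord)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = shap, y = gene,
                                          color = value)) +
        ggplot2::geom_jitter(height = 0.2, size = 0.8, alpha = 0.8) +
        ggplot2::scale_color_gradient(low = "blue", high = "red",
                                      name = "expression") +
        ggplot2::geom_vline(xintercept = 0, linetype = 2) +
        ggplot2::labs(x = sprintf("Shapley value (class %s)", class),
                      y = NULL) +
        ggplot2::theme_minimal()
    if (!is.null(file)) {
        ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
        return(invisible(p))
    }
    p
}

#' Pruned decision-tree explanation
#'
#' Fits a depth- and leaf-size-pruned classification tree (CART via
#' \pkg{rpart}, complexity pruning disabled) on the selected genes and
#' extracts the rule structure: every internal node carries a gene and a
#' threshold, every leaf the percentage of its cells per class. The
#' split orientation is stored explicitly (`lessBranch`: the child that
#' receives cells with expression below the threshold).
#'
#' @param x a `SummarizedExperiment` or genes x cells matrix.
#' @param genes selected genes.
#' @param output a discrete [OutputFunction-class].
#' @param config a [PipelineConfig-class] (`maxDepth`,
#'   `minSamplesLeaf`, `seed`).
#' @return a [TreeExplanation-class].
#' @export
decisionTreeExplain <- function(x, genes, output,
                                config = pipelineConfig()) {
    vals <- .exprValues(x)
    df <- as.data.frame(t(vals[genes, output@cells, drop = FALSE]))
    df$.class <- droplevels(factor(output@values))
    set.seed(config@seed)
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
        control = rpart::rpart.control(
            maxdepth = min(config@maxDepth, 30L),
            minbucket = config@minSamplesLeaf,
            minsplit = 2L * config@minSamplesLeaf,
            cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0))
    fr <- fit$frame
    isLeaf <- fr$var == "<leaf>"
    if (all(isLeaf))
        warning("tree degenerated to a single leaf; ",
                "pruning is too aggressive")
    classes <- attr(fit, "ylevels")
    rules <- if (any(!isLeaf)) {
        data.frame(node = as.integer(rownames(fr))[!isLeaf],
                   gene = as.character(fr$var[!isLeaf]),
                   threshold = fit$splits[, "index"],
                   lessBranch = ifelse(fit$splits[, "ncat"] < 0,
                                       "left", "right"),
                   stringsAsFactors = FALSE)
    } else {
        data.frame(node = integer(0), gene = character(0),
                   threshold = numeric(0), lessBranch = character(0))
    }
    counts <- fr$yval2[isLeaf, 1L + seq_along(classes), drop = FALSE]
    pct <- 100 * counts / rowSums(counts)
    colnames(pct) <- classes
    leaves <- data.frame(node = as.integer(rownames(fr))[isLeaf],
                         n = fr$n[isLeaf],
                         predicted = classes[fr$yval[isLeaf]],
                         stringsAsFactors = FALSE)
    leaves <- cbind(leaves, as.data.frame(pct))
    methods::new("TreeExplanation", fit = fit, rules = rules,
                 leaves = leaves, classes = classes)
}

#' Render a tree explanation as text
#'
#' The rule is read the same way as in the summary figures: at each node,
#' if the expression of the gene is below the threshold take the branch
#' indicated by `lessBranch`, otherwise the other one; leaves report the
#' class composition in percent.
#'
#' @param tree a [TreeExplanation-class].
#' @return character vector of lines.
#' @export
treeText <- function(tree) {
    lines <- character(0)
    recurse <- function(node, depth) {
        pad <- strrep("  ", depth)
        rule <- tree@rules[tree@rules$node == node, ]
        if (nrow(rule) == 1L) {
            lessChild <- if (rule$lessBranch == "left") 2L * node
                         else 2L * node + 1L
            moreChild <- if (rule$lessBranch == "left") 2L * node + 1L
                         else 2L * node
            lines <<- c(lines, sprintf(
                "%sif %s < %.4g:", pad, rule$gene, rule$threshold))
            recurse(lessChild, depth + 1L)
            lines <<- c(lines, sprintf("%selse:", pad))
            recurse(moreChild, depth + 1L)
        } else {
            leaf <- tree@leaves[tree@leaves$node == node, ]
            comp <- paste(sprintf("%s: %.1f%%", tree@classes,
                                  as.numeric(leaf[1L, tree@classes])),
                          collapse = ", ")
            lines <<- c(lines, sprintf("%sleaf (n=%d) -> %s [%s]", pad,
                                       leaf$n, leaf$predicted, comp))
        }
    }
    recurse(1L, 0L)
    lines
}

setMethod("show", "TreeExplanation", function(object) {
    cat("TreeExplanation:", nrow(object@rules), "split(s),",
        nrow(object@leaves), "leaf/leaves\n")
    cat(paste0("  ", treeText(object)), sep = "\n")
})
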