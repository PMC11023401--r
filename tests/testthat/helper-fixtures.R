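## Small shared fixtures, built in code.

## A tiny well-formed genes x cells matrix.
tinyMatrix <- function() {
    m <- matrix(c(0.1, 1.2, 2.3,
                  3.4, 4.5, 5.6), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
    m
}

## Two Gaussian blobs in `dims` dimensions, rows = points.
twoBlobs <- function(nPer = 100, dims = 10, sep = 8, sd = 1,
                     seed = 42) {
    set.seed(seed)
    a <- matrix(rnorm(nPer * dims, 0, sd), nPer, dims)
    b <- matrix(rnorm(nPer * dims, 0, sd), nPer, dims)
    b[, 1] <- b[, 1] + sep
    pts <- rbind(a, b)
    rownames(pts) <- sprintf("p%03d", seq_len(nrow(pts)))
    list(points = pts, membership = rep(c(0L, 1L), each = nPer))
}

## Independent plug-in MI oracle: explicit double loop over the table.
miOracle <- function(O) {
    N <- sum(O)
    pr <- rowSums(O) / N
    pc <- colSums(O) / N
    mi <- 0
    for (k in seq_len(nrow(O))) {
        for (l in seq_len(ncol(O))) {
            p <- O[k, l] / N
            if (p > 0) mi <- mi + p * log2(p / (pr[k] * pc[l]))
        }
    }
    mi
}

## Condition output function for a synthetic dataset.
conditionOutput <- function(sim) {
    makeOutputFunction(externalLabels(sim$labels), c(0L, 1L))
}
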