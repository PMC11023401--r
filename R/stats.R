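#' Contingency table of two binned features
#'
#' Joint observed frequencies O[k, l] = number of cells whose first
#' feature falls in bin k and whose second feature falls in bin l.
#'
#' @param x,y integer vectors of 0-based bin assignments over the same
#'   cells (or the `assignments`/`nBins` lists returned by
#'   [binFeature()]).
#' @param nx,ny number of bins of each feature (inferred if omitted).
#' @return integer matrix of observed counts.
#' @export
contingencyTable <- function(x, y, nx = NULL, ny = NULL) {
    if (is.list(x)) { nx <- x$nBins; x <- x$assignments }
    if (is.list(y)) { ny <- y$nBins; y <- y$assignments }
    if (length(x) != length(y))
        stop("features observed on different numbers of cells")
    if (is.null(nx)) nx <- max(x) + 1L
    if (is.null(ny)) ny <- max(y) + 1L
    counts <- tabulate(x * ny + y + 1L, nbins = nx * ny)
    matrix(as.integer(counts), nrow = nx, ncol = ny, byrow = TRUE)
}

#' Chi-square test of independence on a contingency table
#'
#' Computes the classical statistic
#' \deqn{\chi^2 = \sum_{k,l} (O_{kl} - E_{kl})^2 / E_{kl}} with expected
#' counts \eqn{E_{kl} = (\sum_l O_{kl}) (\sum_k O_{kl}) / N} and the
#' upper-tail p-value of the chi-square distribution with
#' \eqn{(m_i - 1)(m_j - 1)} degrees of freedom. No continuity correction
#' is applied. If any expected count falls below 5 the asymptotic
#' approximation is doubtful; the test is still computed but flagged
#' (`expectedOk = FALSE`) with a warning.
#'
#' @param observed nonnegative integer matrix of joint counts.
#' @param warn logical, warn when an expected count is below 5.
#' @return list with `statistic`, `dof`, `pValue`, `expectedOk`.
#' @examples
#' chiSquareIndependence(matrix(c(20, 5, 5, 20), 2))  # statistic 18, dof 1
#' @export
chiSquareIndependence <- function(observed, warn = TRUE) {
    observed <- as.matrix(observed)
    N <- sum(observed)
    if (N <= 0) stop("empty contingency table")
    if (nrow(observed) < 2L || ncol(observed) < 2L)
        stop("a margin has a single bin (dof 0); ",
             "treat the pair as uninformative")
    rowS <- rowSums(observed)
    colS <- colSums(observed)
    expected <- outer(rowS, colS) / N
    ok <- all(expected >= 5)
    if (!ok && warn)
        warning("expected count below 5; chi-square approximation doubtful")
    stat <- sum((observed - expected)^2 / expected)
    dof <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
    list(statistic = stat,
         dof = dof,
         pValue = pchisq(stat, df = dof, lower.tail = FALSE),
         expectedOk = ok)
}

#' Mutual information of two binned features
#'
#' Plug-in estimate on the joint bin distribution, in bits:
#' \deqn{I(X;Y) = \sum_{k,l} p_{kl} \log_2 \frac{p_{kl}}{p_{k.} p_{.l}}}
#' with \eqn{p = O / N} and the convention \eqn{0 \log 0 = 0}. Only the
#' ranking of features by mutual information is consumed downstream,
#' which is invariant to the logarithm base.
#'
#' @inheritParams contingencyTable
#' @return nonnegative scalar (bits).
#' @export
mutualInformation <- function(x, y, nx = NULL, ny = NULL) {
    O <- contingencyTable(x, y, nx, ny)
    miFromTable(O)
}

#' @rdname mutualInformation
#' @param observed joint count (or probability) matrix.
#' @export
miFromTable <- function(observed) {
    p <- observed / sum(observed)
    pr <- rowSums(p)
    pc <- colSums(p)
    idx <- p > 0
    sum(p[idx] * log2(p[idx] / outer(pr, pc)[idx]))
}
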