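#' Closed-form manifold parameter of a point
#'
#' For the linear manifold x(t) = v t + c, the position t of the
#' projection of a point y minimizing the Euclidean distance
#' is \deqn{t = \frac{(y_1 - c_1) v_1 + (y_2 - c_2) v_2}{v_1^2 + v_2^2}.}
#'
#' @param y numeric length-2 point (or 2-column matrix of points).
#' @param v numeric length-2 direction (non-zero).
#' @param c numeric length-2 offset.
#' @return numeric, the parameter t per point.
#' @examples
#' manifoldParameter(c(3, 4), v = c(1, 0), c = c(0, 0))  # 3
#' @export
manifoldParameter <- function(y, v, c) {
    if (all(v == 0)) stop("direction v must be non-zero")
    y <- matrix(y, ncol = 2L)
    ((y[, 1L] - c[1L]) * v[1L] + (y[, 2L] - c[2L]) * v[2L]) /
        sum(v^2)
}

#' Fit a linear manifold to 2-D embedded coordinates
#'
#' Total-least-squares line fit: `c` is the centroid and `v` the leading
#' principal direction of the centered points (unit length), which
#' minimizes the summed squared orthogonal distances — consistent with
#' the symmetric per-point distance
#' \eqn{\tfrac12((y_1 - x_1)^2 + (y_2 - x_2)^2)}. The per-point
#' parameter t follows from the closed form of
#' [manifoldParameter()] and is affine-equivalent to arc-length position
#' along the line, making it a one-dimensional output function for the
#' fine structure within a cluster.
#'
#' @param points numeric matrix, cells x 2.
#' @return a [ManifoldFit-class].
#' @export
fitLinearManifold <- function(points) {
    points <- as.matrix(points)
    if (ncol(points) != 2L)
        stop("only 2-D coordinates are supported")
    if (nrow(points) < 2L || all(duplicated(points)[-1L]))
        stop("at least 2 distinct points required")
    ctr <- colMeans(points)
    centered <- sweep(points, 2L, ctr)
    v <- svd(centered, nu = 0L, nv = 1L)$v[, 1L]
    v <- v / sqrt(sum(v^2))
    t <- manifoldParameter(centered, v, c(0, 0))
    proj <- outer(t, v)
    residual <- sqrt(rowSums((centered - proj)^2))
    methods::new("ManifoldFit", v = v, c = ctr, t = as.numeric(t),
                 residual = residual)
}

setMethod("show", "ManifoldFit", function(object) {
    cat(sprintf("ManifoldFit: v = (%.4f, %.4f), c = (%.4f, %.4f)\n",
                object@v[1L], object@v[2L], object@c[1L], object@c[2L]))
    cat(sprintf("  %d points, t in [%.3f, %.3f], mean residual %.4f\n",
                length(object@t), min(object@t), max(object@t),
                mean(object@residual)))
})

#' Polar coordinates about a midpoint
#'
#' Transforms embedded 2-D coordinates into distance r from a midpoint
#' and angle theta in (-pi, pi] via the two-argument arctangent. The two
#' components can serve as two continuous output functions (radius
#' modeling developmental progress from a center, angle modeling
#' alternative fates).
#'
#' @param points numeric matrix, cells x 2.
#' @param midpoint numeric length-2 center; defaults to the centroid.
#' @return data.frame with columns `r` and `theta`; a point equal to the
#'   midpoint gets `r = 0, theta = 0` by convention.
#' @export
toPolar <- function(points, midpoint = colMeans(points)) {
    points <- as.matrix(points)
    dx <- points[, 1L] - midpoint[1L]
    dy <- points[, 2L] - midpoint[2L]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    theta[r == 0] <- 0
    data.frame(r = r, theta = theta,
               row.names = rownames(points))
}
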