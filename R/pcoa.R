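#' Principal coordinates analysis (Gower double-centering)
#'
#' Embeds a distance matrix into Euclidean coordinates: the squared
#' distances are double-centered (B = -1/2 J D^2 J) and eigendecomposed;
#' coordinates are eigenvectors scaled by the square roots of their
#' eigenvalues, ordered by non-increasing eigenvalue. Tree (patristic)
#' distances need not be Euclidean-embeddable, so negative eigenvalues can
#' occur; those axes are dropped (truncation, the default correction used
#' here) and their count reported. For a Euclidean-embeddable input the
#' pairwise distances among the returned coordinates reproduce the input.
#'
#' @param d symmetric distance matrix with zero diagonal (or a `dist`).
#' @param tol relative tolerance deciding which eigenvalues count as zero.
#' @return list with `points` (rows = objects), `eigenvalues` (all, sorted
#'   non-increasing) and `negative` (number of dropped negative axes).
#' @export
pcoa <- function(d, tol = 1e-8) {
    if (inherits(d, "dist")) d <- as.matrix(d)
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("'d' must be a square matrix", call. = FALSE)
    if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d))))
        stop("'d' must be symmetric", call. = FALSE)
    if (any(diag(d) < 0) || max(abs(diag(d))) > 1e-8 * max(1, max(abs(d))))
        stop("'d' must have a zero diagonal", call. = FALSE)
    n <- nrow(d)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (d * d) %*% J
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    cut <- tol * max(abs(eig$values), 1e-300)
    keep <- which(eig$values > cut)
    pts <- if (length(keep))
        eig$vectors[, keep, drop = FALSE] %*%
            diag(sqrt(eig$values[keep]), length(keep))
    else matrix(0, n, 0)
    rownames(pts) <- rownames(d)
    list(points = pts, eigenvalues = eig$values,
         negative = sum(eig$values < -cut))
}
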