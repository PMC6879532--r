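## Dimension-reduction chain: Mahalanobis outlier screening, KMO/Bartlett
## factorability diagnostics, PCA on the correlation matrix with varimax
## rotation, and Anderson-Rubin component scores.

#' Mahalanobis outlier screening
#'
#' Squared Mahalanobis distances from the column-mean centroid, compared to
#' the chi-squared quantile with df = number of columns at the given tail
#' probability. Exceeders are excluded and logged.
#'
#' @param x complete numeric matrix (rows = participants); row names are the
#'   participant ids.
#' @param p upper-tail probability of the chi-squared cutoff.
#' @return List with \code{retained} (matrix), \code{excludedIds},
#'   \code{distances} (squared), and \code{cutoff}.
#' @export
mahalanobisScreen <- function(x, p = 0.001) {
    x <- as.matrix(x)
    if (nrow(x) <= ncol(x))
        stop("need more rows than columns for a stable covariance")
    S <- cov(x)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12)
        stop("singular covariance matrix; screening refused")
    d2 <- mahalanobis(x, colMeans(x), S)
    cutoff <- qchisq(1 - p, df = ncol(x))
    out <- d2 > cutoff
    list(retained = x[!out, , drop = FALSE],
         excludedIds = rownames(x)[out],
         distances = d2, cutoff = cutoff)
}

#' KMO and Bartlett factorability diagnostics
#'
#' Kaiser-Meyer-Olkin sampling adequacy from the anti-image (partial)
#' correlations, and Bartlett's sphericity test
#' chi^2 = -(n - 1 - (2p + 5)/6) log det(R) with df = p(p-1)/2.
#'
#' @param x data matrix (rows = observations), or a correlation matrix if
#'   \code{n} is supplied.
#' @param n number of observations (required when \code{x} is a correlation
#'   matrix).
#' @return List with \code{kmo}, \code{bartlettChisq}, \code{bartlettDf},
#'   \code{bartlettP}.
#' @examples
#' kmoBartlett(diag(9), n = 73)  # identity: chi-squared exactly 0
#' @export
kmoBartlett <- function(x, n = NULL) {
    x <- as.matrix(x)
    if (is.null(n)) {
        n <- nrow(x)
        R <- cor(x)
    } else {
        R <- x
    }
    p <- ncol(R)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
        stop("correlation matrix is not positive definite")
    Rinv <- solve(R)
    Q <- -Rinv / sqrt(outer(diag(Rinv), diag(Rinv)))
    off <- upper.tri(R)
    kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
    chisq <- -(n - 1 - (2 * p + 5) / 6) * sum(log(ev))
    df <- p * (p - 1) / 2
    list(kmo = kmo, bartlettChisq = chisq, bartlettDf = df,
         bartlettP = pchisq(chisq, df, lower.tail = FALSE))
}

#' PCA with varimax rotation
#'
#' Eigen-decomposition of the correlation matrix; components with eigenvalue
#' above \code{eigenCutoff} are retained and their loadings (eigenvectors
#' scaled by the root eigenvalues) varimax-rotated with Kaiser
#' normalization. Column signs are fixed so each rotated component's loading
#' sum is non-negative.
#'
#' @param x data matrix, rows = observations (more rows than columns).
#' @param eigenCutoff retention threshold on the eigenvalues.
#' @return A \code{pcaReport}: list with \code{eigenvalues},
#'   \code{nRetained}, \code{loadings} (variables x components, rotated),
#'   \code{rotation} (the varimax rotation matrix), \code{varianceExplained}
#'   (per component, percent), \code{totalVariancePct}, \code{correlation}.
#' @export
pcaVarimax <- function(x, eigenCutoff = 0.80) {
    x <- as.matrix(x)
    if (nrow(x) <= ncol(x))
        stop("need more observations than variables")
    R <- cor(x)
    ee <- eigen(R, symmetric = TRUE)
    keep <- which(ee$values > eigenCutoff)
    if (!length(keep))
        stop("no component passes the eigenvalue cutoff")
    if (length(keep) == ncol(R))
        warning("all components retained; data look spherical")
    L <- ee$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(ee$values[keep]), length(keep))
    rownames(L) <- colnames(R)
    rot <- diag(length(keep))
    if (length(keep) >= 2L) {
        vm <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
        L <- L %*% vm$rotmat
        rot <- vm$rotmat
    }
    flip <- ifelse(colSums(L) < 0, -1, 1)
    L <- sweep(L, 2L, flip, "*")
    colnames(L) <- paste0("C", seq_along(keep))
    ve <- colSums(L^2) / ncol(R) * 100
    structure(list(eigenvalues = ee$values, nRetained = length(keep),
                   loadings = L, rotation = rot,
                   varianceExplained = ve,
                   totalVariancePct = sum(ve), correlation = R),
              class = "pcaReport")
}

#' @export
print.pcaReport <- function(x, ...) {
    cat(sprintf("PCA: %d component(s) retained, %.2f%% of variance\n",
        x$nRetained, x$totalVariancePct))
    cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues),
        collapse = ", "), "\n")
    print(round(x$loadings, 2))
    invisible(x)
}

#' Anderson-Rubin component scores
#'
#' Scores constructed so that, in-sample, they have exactly zero mean and
#' identity covariance: \code{Z R^-1 L (L' R^-1 L)^-1/2} with \code{Z} the
#' standardized data, \code{R} its correlation matrix, and \code{L} the
#' (rotated) loadings.
#'
#' @param x data matrix used for the PCA.
#' @param loadings variables x components rotated loading matrix.
#' @return Observations x components score matrix.
#' @export
andersonRubinScores <- function(x, loadings) {
    x <- as.matrix(x)
    L <- as.matrix(loadings)
    Z <- scale(x)
    R <- cor(x)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= max(ev) * 1e-12)
        stop("singular correlation matrix")
    Rinv <- solve(R)
    M <- t(L) %*% Rinv %*% L
    em <- eigen(M, symmetric = TRUE)
    Minvhalf <- em$vectors %*% diag(1 / sqrt(em$values), ncol(M)) %*%
        t(em$vectors)
    S <- Z %*% Rinv %*% L %*% Minvhalf
    colnames(S) <- colnames(L)
    rownames(S) <- rownames(x)
    S
}
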