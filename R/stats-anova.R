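## Classical mixed (one between-group factor x one repeated factor) ANOVA
## with Mauchly's sphericity test, Greenhouse-Geisser adjustment, and
## partial eta squared. Cell frequencies are proportional by construction
## (every subject contributes every within level), so the weighted
## cell-mean decomposition is the exact orthogonal partition.

## orthonormal contrast basis spanning the within-subject effect space
.ortho_contrasts <- function(k) {
    C <- stats::contr.helmert(k)
    sweep(C, 2L, sqrt(colSums(C^2)), "/")
}

#' Mixed between x within ANOVA
#'
#' Partitions sums of squares for a design with one grouping factor and one
#' repeated factor measured on every subject: group, subjects-within-group
#' error, within factor, group x within interaction, and the within error.
#' Rows with missing cells are removed listwise. When the within factor has
#' three or more levels, Mauchly's test is run on the pooled within-group
#' covariance and, if significant at \code{alpha}, the Greenhouse-Geisser
#' epsilon rescales the within-effect degrees of freedom. Partial eta
#' squared is reported per effect.
#'
#' @param y numeric matrix, subjects x within-levels (columns = conditions).
#' @param groups group label per row; exactly two or more levels.
#' @param alpha level of Mauchly's test gating the adjustment.
#' @param withinName label of the repeated factor in the output.
#' @return A \code{mixedAnovaReport}: list with \code{effects}
#'   (\code{data.frame}: effect, SS, df1, df2, F, p, partialEta2, adjusted
#'   df/p columns), \code{mauchly} (W, chisq, df, p or NULL), \code{epsilon},
#'   \code{ggApplied}, \code{nSubjects}, \code{nExcluded}.
#' @examples
#' set.seed(1)
#' y <- matrix(rnorm(30 * 4), 30)
#' mixedAnova(y, rep(c("a", "b"), each = 15))
#' @export
mixedAnova <- function(y, groups, alpha = 0.05, withinName = "task") {
    y <- as.matrix(y)
    groups <- as.character(groups)
    stopifnot(nrow(y) == length(groups))
    ok <- complete.cases(y)
    nExcluded <- sum(!ok)
    y <- y[ok, , drop = FALSE]
    groups <- groups[ok]
    gl <- unique(groups)
    if (length(gl) < 2L)
        stop("at least two groups are required")
    k <- ncol(y)
    if (k < 2L) stop("at least two within-subject levels are required")
    ng <- table(factor(groups, levels = gl))
    if (any(ng < 2L)) stop("each group needs at least two subjects")
    N <- nrow(y); G <- length(gl)

    grand <- mean(y)
    m_i <- rowMeans(y)
    M_g <- tapply(m_i, factor(groups, levels = gl), mean)
    T_t <- colMeans(y)
    C_gt <- rowsum(y, factor(groups, levels = gl)) / as.vector(ng)

    ssTotal <- sum((y - grand)^2)
    ssBetweenSubj <- k * sum((m_i - grand)^2)
    ssGroup <- k * sum(ng * (M_g - grand)^2)
    ssSubjErr <- ssBetweenSubj - ssGroup
    ssWithinFac <- N * sum((T_t - grand)^2)
    ssInt <- sum(as.vector(ng) *
        (C_gt - outer(as.vector(M_g), rep(1, k)) -
         outer(rep(1, G), T_t) + grand)^2)
    ssErrW <- ssTotal - ssBetweenSubj - ssWithinFac - ssInt

    dfGroup <- G - 1L
    dfSubj <- N - G
    dfW <- k - 1L
    dfInt <- dfGroup * dfW
    dfErrW <- dfSubj * dfW

    Fg <- (ssGroup / dfGroup) / (ssSubjErr / dfSubj)
    Fw <- (ssWithinFac / dfW) / (ssErrW / dfErrW)
    Fi <- (ssInt / dfInt) / (ssErrW / dfErrW)

    ## pooled within-group covariance of the repeated measures
    mauchly <- NULL
    eps <- 1
    ggApplied <- FALSE
    if (k >= 3L && dfSubj > k) {
        cen <- y - C_gt[match(groups, gl), , drop = FALSE]
        S <- crossprod(cen) / dfSubj
        Cc <- .ortho_contrasts(k)
        A <- t(Cc) %*% S %*% Cc
        d <- k - 1L
        lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
        eps <- sum(lam)^2 / (d * sum(lam^2))
        W <- prod(lam) / (sum(lam) / d)^d
        ## Box series approximation (two terms), as in SPSS and stats::mauchly.test
        nS <- dfSubj
        rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nS)
        z <- -nS * rho * log(max(W, 1e-300))
        dfChi <- d * (d + 1) / 2 - 1
        w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * k + 2) /
            (288 * (nS * d * rho)^2)
        pr1 <- pchisq(z, dfChi, lower.tail = FALSE)
        pr2 <- pchisq(z, dfChi + 4, lower.tail = FALSE)
        mauchly <- list(W = W, chisq = z, df = dfChi,
                        p = pr1 + w2 * (pr2 - pr1))
        ggApplied <- mauchly$p < alpha
    }

    adj <- function(F, df1, df2) {
        if (ggApplied) pf(F, eps * df1, eps * df2, lower.tail = FALSE)
        else pf(F, df1, df2, lower.tail = FALSE)
    }
    effects <- data.frame(
        effect = c("group", withinName, paste0("group:", withinName)),
        SS = c(ssGroup, ssWithinFac, ssInt),
        SS_error = c(ssSubjErr, ssErrW, ssErrW),
        df1 = c(dfGroup, dfW, dfInt),
        df2 = c(dfSubj, dfErrW, dfErrW),
        F = c(Fg, Fw, Fi),
        p = c(pf(Fg, dfGroup, dfSubj, lower.tail = FALSE),
              pf(Fw, dfW, dfErrW, lower.tail = FALSE),
              pf(Fi, dfInt, dfErrW, lower.tail = FALSE)),
        partialEta2 = c(ssGroup / (ssGroup + ssSubjErr),
                        ssWithinFac / (ssWithinFac + ssErrW),
                        ssInt / (ssInt + ssErrW)),
        stringsAsFactors = FALSE)
    ## GG rescaling touches only the within-subject effects
    effects$df1_adj <- effects$df1
    effects$df2_adj <- effects$df2
    effects$p_adj <- effects$p
    if (ggApplied) {
        wr <- 2:3
        effects$df1_adj[wr] <- eps * effects$df1[wr]
        effects$df2_adj[wr] <- eps * effects$df2[wr]
        effects$p_adj[wr] <- adj(effects$F[wr], effects$df1[wr],
                                 effects$df2[wr])
    }
    structure(list(effects = effects, mauchly = mauchly, epsilon = eps,
                   ggApplied = ggApplied, nSubjects = N,
                   nExcluded = nExcluded, k = k, groups = gl),
              class = "mixedAnovaReport")
}

#' @export
print.mixedAnovaReport <- function(x, ...) {
    cat(sprintf("Mixed ANOVA: %d subjects (%d excluded listwise), %d within levels\n",
        x$nSubjects, x$nExcluded, x$k))
    if (!is.null(x$mauchly))
        cat(sprintf("Mauchly W = %.4f, p = %.4g; GG epsilon = %.4f%s\n",
            x$mauchly$W, x$mauchly$p, x$epsilon,
            if (x$ggApplied) " (applied)" else ""))
    print(x$effects, digits = 4, row.names = FALSE)
    invisible(x)
}

#' 2 x 2 mixed ANOVA on component scores
#'
#' Same engine as \code{\link{mixedAnova}} with exactly two within levels
#' (the retained components); sphericity is trivially satisfied at two
#' levels, so no correction is attempted.
#'
#' @param scores subjects x 2 matrix of component scores.
#' @param groups group label per row.
#' @param alpha passed through (unused with two levels).
#' @return A \code{mixedAnovaReport}.
#' @export
componentMixedAnova <- function(scores, groups, alpha = 0.05) {
    scores <- as.matrix(scores)
    if (ncol(scores) != 2L)
        stop("exactly two components are required")
    mixedAnova(scores, groups, alpha = alpha, withinName = "component")
}
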