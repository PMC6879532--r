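## Between-group comparison machinery: Levene-gated independent t-tests and
## the Dunn-Bonferroni multiplicity rule.

.trim_tails <- function(x, trim) {
    n <- length(x)
    k <- floor(trim * n)
    if (k == 0L) return(x)
    sort(x)[(k + 1L):(n - k)]
}

#' Levene's test statistic (mean-centered)
#'
#' One-way ANOVA F on absolute deviations from the group means, the classic
#' homogeneity-of-variance gate.
#'
#' @param group1,group2 numeric vectors.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @export
leveneStatistic <- function(group1, group2) {
    z1 <- abs(group1 - mean(group1))
    z2 <- abs(group2 - mean(group2))
    n1 <- length(z1); n2 <- length(z2)
    zb <- mean(c(z1, z2))
    ssb <- n1 * (mean(z1) - zb)^2 + n2 * (mean(z2) - zb)^2
    ssw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
    df2 <- n1 + n2 - 2L
    F <- (ssb / 1) / (ssw / df2)
    list(F = F, df1 = 1L, df2 = df2, p = pf(F, 1, df2, lower.tail = FALSE))
}

#' Levene-gated independent-samples t-test
#'
#' Runs the mean-centered Levene test at \code{alpha}; when variances are
#' homogeneous the pooled-variance t-test is reported, otherwise the Welch
#' test. Optionally trims each group's extreme values per tail first (the
#' per-variable trimmed-mean convention used for skewed behavioral scores).
#'
#' @param group1,group2 numeric vectors (each n >= 2 after trimming).
#' @param alpha significance gate for Levene's test.
#' @param conf confidence level of the reported interval.
#' @param trim per-tail trimming fraction applied to each group before
#'   testing (0 = none).
#' @return One-row \code{data.frame}: group means/SDs, mean difference
#'   (group1 - group2), CI bounds, \code{t}, \code{df}, \code{p}, Levene F/p,
#'   and the \code{variant} used (\code{"pooled"} or \code{"welch"}).
#' @examples
#' set.seed(1)
#' leveneGatedTTest(rnorm(30), rnorm(15, 1))
#' @export
leveneGatedTTest <- function(group1, group2, alpha = 0.05, conf = 0.95,
                             trim = 0) {
    if (trim > 0) {
        group1 <- .trim_tails(group1, trim)
        group2 <- .trim_tails(group2, trim)
    }
    if (length(group1) < 2L || length(group2) < 2L)
        stop("each group needs at least two values")
    if (var(group1) == 0 && var(group2) == 0)
        stop("both groups have zero variance")
    lev <- leveneStatistic(group1, group2)
    pooled <- lev$p >= alpha
    tt <- stats::t.test(group1, group2, var.equal = pooled,
                        conf.level = conf)
    data.frame(mean1 = mean(group1), sd1 = sd(group1),
               mean2 = mean(group2), sd2 = sd(group2),
               diff = mean(group1) - mean(group2),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               levene_F = lev$F, levene_p = lev$p,
               variant = if (pooled) "pooled" else "welch",
               stringsAsFactors = FALSE)
}

#' Dunn-Bonferroni adjusted decisions
#'
#' Two-tailed per-comparison level alpha/m; the critical t is the
#' corresponding t quantile at the given degrees of freedom, and each
#' comparison is declared significant when |t| meets it.
#'
#' @param tValues observed t statistics.
#' @param m number of comparisons in the family.
#' @param df degrees of freedom of the reference t distribution.
#' @param alpha family-wise level.
#' @return List with \code{criticalT}, \code{alphaPerComparison}, and the
#'   logical vector \code{significant}.
#' @examples
#' dunnBonferroni(c(-3.14, -1.23, 2.27), m = 9, df = 71)
#' @export
dunnBonferroni <- function(tValues, m, df, alpha = 0.05) {
    if (m < 1L) stop("m must be >= 1")
    if (df <= 0) stop("df must be positive")
    crit <- qt(1 - alpha / (2 * m), df)
    list(criticalT = crit,
         alphaPerComparison = alpha / m,
         significant = abs(tValues) >= crit)
}
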