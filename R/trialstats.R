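#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables no more probable than the observed one (the "small
#' p-values" method, the convention of most statistical software and the
#' one that reproduces the trial's printed p-values). The doubling
#' convention (twice the smaller one-sided tail, capped at 1) is
#' available via \code{method = "doubling"}.
#'
#' @param table 2x2 matrix of nonnegative counts, rows = biomarker class,
#'   columns = outcome.
#' @param method "minlike" (default) or "doubling".
#' @return list with \code{p.value}, \code{method} and the observed table.
#' @examples
#' fisherExactTwoSided(matrix(c(11, 0, 7, 5), 2))  # 0.0373
#' @export
fisherExactTwoSided <- function(table, method = c("minlike", "doubling")) {
    method <- match.arg(method)
    table <- as.matrix(table)
    if (!all(dim(table) == 2L)) stop("need a 2x2 table")
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be nonnegative integers")
    r1 <- sum(table[1L, ]); c1 <- sum(table[, 1L]); N <- sum(table)
    if (r1 == 0L || c1 == 0L || r1 == N || c1 == N) {
        warning("degenerate margin: p = 1")
        return(list(p.value = 1, method = method, table = table))
    }
    support <- max(0L, r1 + c1 - N):min(r1, c1)
    probs <- dhyper(support, c1, N - c1, r1)
    pObs <- dhyper(table[1L, 1L], c1, N - c1, r1)
    p <- switch(method,
        minlike = sum(probs[probs <= pObs * (1 + 1e-7)]),
        doubling = {
            lo <- sum(probs[support <= table[1L, 1L]])
            hi <- sum(probs[support >= table[1L, 1L]])
            min(1, 2 * min(lo, hi))
        })
    list(p.value = min(p, 1), method = method, table = table)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval: the lower bound is 0 for zero
#' successes and otherwise the (1-level)/2 Beta quantile with shapes
#' (x, n - x + 1); the upper bound is 1 for n successes and otherwise the
#' (1+level)/2 Beta quantile with shapes (x + 1, n - x).
#'
#' @param successes,n counts with 0 <= successes <= n.
#' @param level confidence level in (0, 1), default 0.95.
#' @return named vector \code{c(lower, upper)} on the fraction scale.
#' @examples
#' clopperPearson(3, 25)   # 0.0255 to 0.3122, printed as 2.5-31.2%
#' @export
clopperPearson <- function(successes, n, level = 0.95) {
    if (n < 1 || successes < 0 || successes > n)
        stop("need 0 <= successes <= n, n >= 1")
    if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
    a <- (1 - level) / 2
    lower <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
    upper <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
    c(lower = lower, upper = upper)
}

.rankSumU <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when both groups have at most
#' \code{exactMax} observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples.
#' @param exactMax largest per-group size for the exact test (default 10).
#' @return list with \code{U} (for the first sample), \code{p.value} and
#'   \code{method} ("exact" or "normal").
#' @export
mannWhitneyU <- function(x, y, exactMax = 10L) {
    if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
    m <- length(x); n <- length(y)
    U <- .rankSumU(x, y)
    ties <- anyDuplicated(c(x, y)) > 0L
    if (!ties && m <= exactMax && n <= exactMax) {
        # stats::pwilcox is the exact distribution of U under H0
        p <- if (U > m * n / 2) {
            2 * (1 - pwilcox(U - 1, m, n))
        } else {
            2 * pwilcox(U, m, n)
        }
        return(list(U = U, p.value = min(1, p), method = "exact"))
    }
    N <- m + n
    tieTab <- table(c(x, y))
    sigma2 <- m * n / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
    z <- U - m * n / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    list(U = U, p.value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped. With at most \code{exactMax} nonzero
#' pairs the null distribution is obtained by full enumeration of all
#' sign assignments (exact even under tied absolute differences); beyond
#' that, the normal approximation with tie correction is used.
#'
#' @param differences paired differences (or supply \code{x} and \code{y}).
#' @param x,y optional paired samples; \code{differences = x - y}.
#' @param exactMax largest number of nonzero pairs for enumeration
#'   (default 15).
#' @return list with \code{W} (sum of positive ranks), \code{p.value},
#'   \code{n} (nonzero pairs) and \code{method}.
#' @export
wilcoxonSignedRank <- function(differences = NULL, x = NULL, y = NULL,
                               exactMax = 15L) {
    if (is.null(differences)) {
        if (is.null(x) || is.null(y)) stop("supply differences or x and y")
        differences <- x - y
    }
    d <- differences[differences != 0]
    n <- length(d)
    if (n == 0L) stop("all differences are zero: test undefined")
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= exactMax) {
        # enumerate all 2^n sign assignments of the observed |ranks|
        signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
        Wall <- as.numeric(signs %*% r)
        pLo <- mean(Wall <= W + 1e-9)
        pHi <- mean(Wall >= W - 1e-9)
        return(list(W = W, p.value = min(1, 2 * min(pLo, pHi)), n = n,
                    method = "exact"))
    }
    mu <- n * (n + 1) / 4
    tieTab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(W = W, p.value = min(1, 2 * pnorm(-abs(z))), n = n,
         method = "normal")
}
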