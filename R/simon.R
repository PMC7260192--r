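#' Exact operating characteristics of a Simon two-stage design
#'
#' The rejection (declare-active) probability at response rate p is the
#' exact two-stage binomial sum
#' \deqn{\sum_{x_1 = r_1+1}^{n_1} B(x_1; n_1, p)\, P(X_2 > r - x_1;\, n - n_1, p),}
#' the probability of early termination is \eqn{P(X_1 \le r_1)}, and the
#' expected sample size is \eqn{n_1 + (1 - PET)(n - n_1)}.
#'
#' @param design a \linkS4class{SimonDesign} (or list with n1, r1, n, r).
#' @param p true response probability.
#' @return list with \code{reject}, \code{pet} and \code{expected_n}.
#' @export
simonOC <- function(design, p) {
    n1 <- design@n1; r1 <- design@r1; n <- design@n; r <- design@r
    n2 <- n - n1
    x1 <- seq.int(r1 + 1L, n1)
    k <- r - x1
    tail2 <- ifelse(k < 0, 1, 1 - pbinom(k, n2, p))
    reject <- sum(dbinom(x1, n1, p) * tail2)
    pet <- pbinom(r1, n1, p)
    list(reject = reject, pet = pet, expected_n = n1 + (1 - pet) * n2)
}

.simonFeasible <- function(p0, p1, alpha, beta, n) {
    # all feasible (n1, r1, r) at total size n; exact binomial sums,
    # vectorised over (r1, r) for each n1 via reverse cumulative sums
    res <- list()
    for (n1 in seq_len(n - 1L)) {
        n2 <- n - n1
        rs <- 0:(n - 1L)
        K <- outer(rs, 0:n1, "-")
        T0 <- matrix(ifelse(K < 0, 1, 1 - pbinom(K, n2, p0)), nrow = length(rs))
        T1 <- matrix(ifelse(K < 0, 1, 1 - pbinom(K, n2, p1)), nrow = length(rs))
        V0 <- T0 * rep(dbinom(0:n1, n1, p0), each = length(rs))
        V1 <- T1 * rep(dbinom(0:n1, n1, p1), each = length(rs))
        # C[r+1, x1+1] = sum_{x >= x1} V[r+1, x+1]
        C0 <- t(apply(V0, 1L, function(v) rev(cumsum(rev(v)))))
        C1 <- t(apply(V1, 1L, function(v) rev(cumsum(rev(v)))))
        for (r1 in 0:(n1 - 1L)) {
            a <- C0[, r1 + 2L]
            pw <- C1[, r1 + 2L]
            ok <- which(a <= alpha & pw >= 1 - beta) - 1L
            ok <- ok[ok >= r1]
            if (length(ok)) {
                r <- min(ok)
                pet <- pbinom(r1, n1, p0)
                res[[length(res) + 1L]] <- c(
                    n1 = n1, r1 = r1, n = n, r = r,
                    alpha = a[r + 1L], power = pw[r + 1L], pet = pet,
                    en = n1 + (1 - pet) * n2)
            }
        }
    }
    if (length(res)) do.call(rbind, res) else NULL
}

.asSimonDesign <- function(row, p0, p1, alpha, beta) {
    new("SimonDesign",
        n1 = as.integer(row[["n1"]]), r1 = as.integer(row[["r1"]]),
        n = as.integer(row[["n"]]), r = as.integer(row[["r"]]),
        p0 = p0, p1 = p1, alphaOneSided = alpha, beta = beta,
        attainedAlpha = row[["alpha"]], attainedPower = row[["power"]],
        petP0 = row[["pet"]], expectedNP0 = row[["en"]])
}

#' Exhaustive Simon two-stage design search
#'
#' Searches all two-stage designs (n1, r1, n, r) with exact one-sided
#' type-I error at most \code{alphaOneSided} and exact power at least
#' \code{1 - beta}. The minimax criterion returns the design with the
#' smallest total size, ties broken by smallest expected sample size under
#' p0; the optimal criterion minimises the expected sample size under p0
#' over all totals up to \code{nMax}. All operating characteristics are
#' exact binomial sums (see [simonOC()]).
#'
#' @param p0 unacceptable (null) response probability.
#' @param p1 target (alternative) response probability.
#' @param alphaOneSided one-sided type-I error bound.
#' @param beta type-II error bound (power >= 1 - beta).
#' @param nMax largest total sample size searched.
#' @param criterion "minimax" or "optimal".
#' @return a \linkS4class{SimonDesign}.
#' @examples
#' \donttest{
#' simonSearch(0.10, 0.25, alphaOneSided = 0.016, beta = 0.10)
#' }
#' @export
simonSearch <- function(p0, p1, alphaOneSided, beta, nMax = 100L,
                        criterion = c("minimax", "optimal")) {
    criterion <- match.arg(criterion)
    if (!(p0 < p1)) stop("need p0 < p1")
    if (alphaOneSided <= 0 || alphaOneSided >= 1 || beta <= 0 || beta >= 1)
        stop("error rates must lie in (0, 1)")
    best <- NULL
    for (n in 2:nMax) {
        feas <- .simonFeasible(p0, p1, alphaOneSided, beta, n)
        if (is.null(feas)) next
        cand <- feas[which.min(feas[, "en"]), ]
        if (criterion == "minimax")
            return(.asSimonDesign(cand, p0, p1, alphaOneSided, beta))
        if (is.null(best) || cand[["en"]] < best[["en"]]) best <- cand
    }
    if (is.null(best))
        stop("no feasible two-stage design with total size <= ", nMax)
    .asSimonDesign(best, p0, p1, alphaOneSided, beta)
}
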