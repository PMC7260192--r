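# Independent brute-force oracles used to cross-check the package's exact
# statistics and alignment. These deliberately share no code with the
# implementation paths they check.

# Two-sided Fisher p by explicit enumeration of all 2x2 tables with the
# observed margins, using choose() products (not dhyper).
oracleFisherP <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); N <- r1 + r2
    support <- max(0, c1 - r2):min(r1, c1)
    prob <- vapply(support, function(a)
        choose(r1, a) * choose(r2, c1 - a) / choose(N, c1), numeric(1))
    pObs <- prob[support == tab[1, 1]]
    sum(prob[prob <= pObs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
oracleMannWhitneyP <- function(x, y) {
    pooled <- c(x, y)
    m <- length(x)
    uStat <- function(idx) {
        xx <- pooled[idx]; yy <- pooled[-idx]
        sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    }
    uObs <- uStat(seq_len(m))
    combos <- utils::combn(length(pooled), m)
    uAll <- apply(combos, 2, uStat)
    mu <- m * length(y) / 2
    mean(abs(uAll - mu) >= abs(uObs - mu) - 1e-9)
}

# Global Needleman-Wunsch score with linear gap cost, bisulfite-aware
# scoring (read T opposite reference C is a match); plain O(nm) DP.
oracleAlignScore <- function(read, ref, match = 1, mismatch = -2, gap = 2) {
    p <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
    n <- length(p); m <- length(s)
    D <- matrix(0, n + 1, m + 1)
    D[, 1] <- -gap * (0:n)
    D[1, ] <- -gap * (0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        sc <- if (p[i] == s[j] || (p[i] == "T" && s[j] == "C")) match else mismatch
        D[i + 1, j + 1] <- max(D[i, j] + sc, D[i, j + 1] - gap,
                               D[i + 1, j] - gap)
    }
    D[n + 1, m + 1]
}

# Direct triple-loop Simon search (independent of the vectorised search):
# smallest n, ties by expected size under p0.
oracleSimonMinimax <- function(p0, p1, alpha, beta, nMax) {
    oc <- function(n1, r1, n, r, p) {
        x1 <- (r1 + 1):n1
        k <- r - x1
        sum(dbinom(x1, n1, p) *
                ifelse(k < 0, 1, 1 - pbinom(k, n - n1, p)))
    }
    best <- NULL
    for (n in 2:nMax) {
        for (n1 in 1:(n - 1)) for (r1 in 0:(n1 - 1)) {
            for (r in r1:(n - 1)) {
                if (oc(n1, r1, n, r, p0) > alpha) next
                if (oc(n1, r1, n, r, p1) < 1 - beta) break
                pet <- pbinom(r1, n1, p0)
                en <- n1 + (1 - pet) * (n - n1)
                if (is.null(best) || en < best["en"])
                    best <- c(n1 = n1, r1 = r1, n = n, r = r, en = en)
                break
            }
        }
        if (!is.null(best)) return(best)
    }
    NULL
}

# Small toy amplicon with a configurable number of CpG sites, CpGs at
# every fourth position: ...ACGT repeated blocks with an A spacer.
toyAmplicon <- function(nCpg = 10, name = "toy", excludedSites = integer()) {
    seq <- paste(rep("ACGTA", nCpg), collapse = "")
    ampliconReference(name, seq, excludedSites = excludedSites)
}

smallCohort <- function(n = 12, seed = 11, reads = 300) {
    generateCohort(CohortConfig(nPatients = n, methylReadCount = reads,
                                seed = seed))
}
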