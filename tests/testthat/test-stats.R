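test_that("two-sided Fisher p reproduces the trial's printed values", {
    # RAD51 deficiency x detectable mechanism: 11/18 vs 0/5
    expect_equal(fisherExactTwoSided(matrix(c(11, 0, 7, 5), 2))$p.value,
                 0.0373, tolerance = 1e-3)
    # basal-like subtype x classifier class: 12/15 vs 1/5
    expect_equal(fisherExactTwoSided(matrix(c(12, 1, 3, 4), 2))$p.value,
                 0.0307, tolerance = 1e-3)
    # classifier class x detectable mechanism: 14/19 vs 0/8
    expect_equal(fisherExactTwoSided(matrix(c(14, 0, 5, 8), 2))$p.value,
                 5.797e-4, tolerance = 1e-3)
    # identical proportions
    expect_equal(fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
})

test_that("Fisher p agrees with enumeration oracle and base R", {
    withr::with_seed(3, {
        for (i in 1:30) {
            tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
            if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
                sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
            p <- fisherExactTwoSided(tab)$p.value
            expect_equal(p, oracleFisherP(tab), tolerance = 1e-12)
            expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
            # invariant to simultaneous row and column swaps
            expect_equal(fisherExactTwoSided(tab[2:1, 2:1])$p.value, p,
                         tolerance = 1e-12)
            expect_true(p > 0 && p <= 1)
        }
    })
    expect_warning(p1 <- fisherExactTwoSided(matrix(c(0, 0, 3, 4), 2)),
                   "degenerate")
    expect_equal(p1$p.value, 1)
})

test_that("the doubling convention is available and correctly capped", {
    tab <- matrix(c(11, 0, 7, 5), 2)
    pd <- fisherExactTwoSided(tab, method = "doubling")$p.value
    # hand oracle: twice the smaller conditional tail
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
    support <- max(0, r1 + c1 - N):min(r1, c1)
    prob <- dhyper(support, c1, N - c1, r1)
    lo <- sum(prob[support <= tab[1, 1]])
    hi <- sum(prob[support >= tab[1, 1]])
    expect_equal(pd, min(1, 2 * min(lo, hi)))
    expect_equal(fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2),
                                     method = "doubling")$p.value, 1)
})

test_that("Clopper-Pearson matches the printed interval and base R", {
    ci <- clopperPearson(3, 25)
    expect_equal(round(100 * ci[["lower"]], 1), 2.5)
    expect_equal(round(100 * ci[["upper"]], 1), 31.2)
    expect_equal(clopperPearson(0, 10)[["lower"]], 0)
    expect_equal(clopperPearson(10, 10)[["upper"]], 1)
    withr::with_seed(9, {
        for (i in 1:10) {
            n <- sample(5:60, 1)
            x <- sample(0:n, 1)
            ci <- clopperPearson(x, n)
            ref <- binom.test(x, n)$conf.int
            expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-9)
        }
    })
    expect_error(clopperPearson(5, 4))
    expect_error(clopperPearson(1, 10, level = 1))
})

test_that("Clopper-Pearson attains at least nominal coverage", {
    withr::with_seed(123, {
        for (p in c(0.1, 0.5)) for (n in c(12, 40)) {
            x <- rbinom(1e4, n, p)
            lims <- vapply(0:n, clopperPearson, numeric(2), n = n)
            covered <- lims[1, x + 1] <= p & p <= lims[2, x + 1]
            se <- sqrt(0.95 * 0.05 / 1e4)
            expect_gte(mean(covered), 0.95 - 3 * se)
        }
    })
})

test_that("Mann-Whitney exact p matches full labeling enumeration", {
    res <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
    expect_equal(res$U, 0)
    expect_equal(res$p.value, 0.1)    # 2 * (1 / choose(6, 3))
    expect_identical(res$method, "exact")
    # the same multiset split evenly across groups: p effectively 1
    same <- mannWhitneyU(c(1, 2, 7, 9), c(1, 2, 7, 9))
    expect_gte(same$p.value, 0.99)
    withr::with_seed(41, {
        for (i in 1:12) {
            x <- round(rnorm(sample(3:6, 1)), 4)
            y <- round(rnorm(sample(3:6, 1), 0.5), 4)
            got <- mannWhitneyU(x, y)
            expect_identical(got$method, "exact")
            expect_equal(got$p.value, oracleMannWhitneyP(x, y),
                         tolerance = 1e-9)
        }
    })
})

test_that("Mann-Whitney normal approximation tracks the exact test", {
    withr::with_seed(55, {
        for (i in 1:10) {
            x <- rnorm(10); y <- rnorm(10, 0.8)
            pe <- mannWhitneyU(x, y, exactMax = 10)$p.value
            pa <- mannWhitneyU(x, y, exactMax = 0)$p.value
            expect_lt(abs(pe - pa), 0.02)
        }
        # ties push it onto the corrected normal path
        res <- mannWhitneyU(c(1, 1, 2, 3), c(1, 2, 2, 4))
        expect_identical(res$method, "normal")
        ref <- suppressWarnings(wilcox.test(c(1, 1, 2, 3), c(1, 2, 2, 4)))
        expect_equal(res$p.value, ref$p.value, tolerance = 1e-9)
    })
})

test_that("Wilcoxon signed-rank enumeration handles ties and boundaries", {
    # six equal positive differences: p = 2/2^6
    res <- wilcoxonSignedRank(rep(2.5, 6))
    expect_equal(res$p.value, 0.03125)
    expect_identical(res$method, "exact")
    # antisymmetric differences sit at the null centre
    resA <- wilcoxonSignedRank(c(3, -3, 5, -5, 7, -7))
    expect_gte(resA$p.value, 0.99)
    # zero differences are dropped before ranking
    resZ <- wilcoxonSignedRank(c(0, 0, 1, 2, 3, 4, 5, 6))
    expect_identical(resZ$n, 6L)
    expect_error(wilcoxonSignedRank(c(0, 0, 0)), "zero")
    # agreement with base R's exact test when there are no ties
    withr::with_seed(77, {
        for (i in 1:8) {
            d <- round(rnorm(10, 0.4), 4)
            got <- wilcoxonSignedRank(d)
            ref <- wilcox.test(d, exact = TRUE)
            expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
        }
    })
})

test_that("Wilcoxon normal approximation tracks the enumeration", {
    withr::with_seed(88, {
        for (i in 1:8) {
            d <- rnorm(12, 0.5)
            pe <- wilcoxonSignedRank(d, exactMax = 15)$p.value
            pa <- wilcoxonSignedRank(d, exactMax = 0)$p.value
            expect_lt(abs(pe - pa), 0.02)
        }
    })
})
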