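mkCatalog2 <- function() {
    m <- rbind(sigA = c(0.6, 0.3, 0.1, 0.0),
               sigB = c(0.0, 0.1, 0.4, 0.5))
    colnames(m) <- paste0("ch", 1:4)
    m
}

test_that("NNLS exposure fitting recovers exact mixtures with zero residual", {
    cat2 <- mkCatalog2()
    counts <- 2 * cat2["sigA", ] + 3 * cat2["sigB", ]
    fit <- fitExposures(cat2, counts)
    expect_equal(unname(fit$exposures), c(2, 3), tolerance = 1e-8)
    expect_lt(fit$residual, 1e-8)
    z <- fitExposures(cat2, setNames(rep(0, 4), colnames(cat2)))
    expect_true(all(z$exposures == 0))
    expect_error(fitExposures(cat2, rep(1, 5)), "length")
    expect_error(fitExposures(cat2, setNames(rep(1, 4), paste0("x", 1:4))),
                 "labels")
})

test_that("exposures are never negative and match a grid-search oracle", {
    cat2 <- mkCatalog2()
    withr::with_seed(31, {
        for (i in 1:8) {
            eTrue <- runif(2, 0, 3000)
            counts <- rpois(4, as.numeric(t(cat2) %*% eTrue))
            fit <- fitExposures(cat2, counts)
            expect_true(all(fit$exposures >= 0))
            # coarse grid-search oracle over the 2-exposure plane
            grid <- expand.grid(a = seq(0, 4000, by = 20),
                                b = seq(0, 4000, by = 20))
            rss <- colSums((t(as.matrix(grid) %*% cat2) - counts)^2)
            best <- grid[which.min(rss), ]
            expect_lt(abs(fit$exposures[["sigA"]] - best$a), 25)
            expect_lt(abs(fit$exposures[["sigB"]] - best$b), 25)
        }
    })
})

test_that("noisy large-mutation-count mixtures are recovered within 10%", {
    catalog <- syntheticSignatureCatalog()$sub
    withr::with_seed(17, {
        eTrue <- setNames(rep(0, 12), rownames(catalog))
        eTrue["sub_sig3"] <- 3500
        eTrue["sub_sig8"] <- 1500
        counts <- rpois(ncol(catalog), as.numeric(t(catalog) %*% eTrue))
        fit <- fitExposures(catalog, setNames(counts, colnames(catalog)))
        expect_lt(abs(fit$exposures[["sub_sig3"]] - 3500) / 3500, 0.10)
        expect_lt(abs(fit$exposures[["sub_sig8"]] - 1500) / 1500, 0.10)
    })
})

test_that("HRD-LOH index counts long sub-chromosomal LOH segments", {
    lens <- c(chrA = 100e6)
    seg <- function(start, end, major, minor, chrom = "chrA")
        data.frame(chrom = chrom, start = start, end = end,
                   major_cn = major, minor_cn = minor)
    expect_identical(hrdLohIndex(seg(10e6, 30e6, 1, 0), lens), 1L)  # 20 Mb
    expect_identical(hrdLohIndex(seg(10e6, 20e6, 1, 0), lens), 0L)  # 10 Mb
    expect_identical(hrdLohIndex(seg(0, 100e6, 1, 0), lens), 0L)    # whole
    expect_identical(hrdLohIndex(seg(10e6, 30e6, 2, 1), lens), 0L)  # no LOH
    expect_identical(hrdLohIndex(seg(10e6, 30e6, 0, 0), lens), 0L)  # homdel
    # exactly 15 Mb is not "> 15 Mb"
    expect_identical(hrdLohIndex(seg(0, 15e6, 1, 0), lens), 0L)
    expect_error(hrdLohIndex(rbind(seg(0, 30e6, 1, 0), seg(20e6, 50e6, 1, 0)),
                             lens), "overlap")
    expect_error(hrdLohIndex(seg(10e6, 30e6, 1, 0,
                                 chrom = "chrZ"), lens), "chrZ")
})

test_that("HRD-LOH index is invariant to segment order and splitting", {
    lens <- grch37ChromLengths()
    base <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                       start = c(10e6, 5e6, 0),
                       end = c(40e6, 12e6, 60e6),
                       major_cn = c(1, 1, 2), minor_cn = c(0, 0, 0))
    idx <- hrdLohIndex(base, lens)
    expect_identical(idx, 2L)
    expect_identical(hrdLohIndex(base[c(3, 1, 2), ], lens), idx)
    # split the chr1 segment into three contiguous same-CN pieces
    split1 <- rbind(
        data.frame(chrom = "chr1", start = c(10e6, 18e6, 33e6),
                   end = c(18e6, 33e6, 40e6), major_cn = 1, minor_cn = 0),
        base[-1, ])
    expect_identical(hrdLohIndex(split1, lens), idx)
})

test_that("weighted logistic score behaves as the formula dictates", {
    m0 <- hrdetectModel(0, setNames(rep(0, 6),
                        c("sub_sig3", "sub_sig8", "rearr_sig3",
                          "rearr_sig5", "del_mh_prop", "hrd_loh")),
                        center = setNames(rep(0, 6),
                        c("sub_sig3", "sub_sig8", "rearr_sig3",
                          "rearr_sig5", "del_mh_prop", "hrd_loh")),
                        scale = setNames(rep(1, 6),
                        c("sub_sig3", "sub_sig8", "rearr_sig3",
                          "rearr_sig5", "del_mh_prop", "hrd_loh")))
    f <- c(sub_sig3 = 5, sub_sig8 = 1, rearr_sig3 = 2, rearr_sig5 = 1,
           del_mh_prop = 0.3, hrd_loh = 4)
    res0 <- hrdetectScore(f, m0)
    expect_equal(res0@score, 0.5)
    expect_false(res0@positive)
    mSat <- m0; mSat@intercept <- 10
    resSat <- hrdetectScore(f, mSat)
    expect_gt(resSat@score, 0.99)
    expect_true(resSat@positive)
    # direct formula evaluation against the default model
    model <- defaultHrdetectModel()
    z <- (log(f + 1) - model@center[names(model@weights)]) /
        model@scale[names(model@weights)]
    lp <- model@intercept + sum(model@weights * z[names(model@weights)])
    expect_equal(hrdetectScore(f, model)@score, plogis(lp))
    expect_error(hrdetectScore(f[-1], model), "sub_sig3")
})

test_that("score is monotone in positively weighted features", {
    model <- defaultHrdetectModel()
    base <- c(sub_sig3 = 100, sub_sig8 = 100, rearr_sig3 = 10,
              rearr_sig5 = 10, del_mh_prop = 0.1, hrd_loh = 3)
    for (feat in names(model@weights)) {
        lo <- hrdetectScore(base, model)@score
        up <- base
        up[feat] <- up[feat] * 3 + 1
        hi <- hrdetectScore(up, model)@score
        expect_gt(hi, lo)
    }
    # deficient-like profile scores above proficient-like profile
    hrd <- c(sub_sig3 = 2000, sub_sig8 = 500, rearr_sig3 = 150,
             rearr_sig5 = 100, del_mh_prop = 0.5, hrd_loh = 18)
    hrp <- c(sub_sig3 = 40, sub_sig8 = 200, rearr_sig3 = 5,
             rearr_sig5 = 30, del_mh_prop = 0.05, hrd_loh = 2)
    expect_gt(hrdetectScore(hrd, model)@score,
              hrdetectScore(hrp, model)@score)
})

test_that("composite HRD score classification is strictly above 42", {
    expect_true(classifyHrdScore(43))
    expect_false(classifyHrdScore(42))
    expect_false(classifyHrdScore(0))
    expect_error(classifyHrdScore(-1))
})

test_that("model round-trips through its JSON representation", {
    model <- defaultHrdetectModel()
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(list(intercept = model@intercept,
                              weights = as.list(model@weights),
                              center = as.list(model@center),
                              scale = as.list(model@scale),
                              offset = model@offset),
                         path, auto_unbox = TRUE, digits = NA)
    back <- readHrdetectModel(path)
    f <- c(sub_sig3 = 900, sub_sig8 = 300, rearr_sig3 = 80,
           rearr_sig5 = 60, del_mh_prop = 0.4, hrd_loh = 12)
    expect_equal(hrdetectScore(f, back)@score, hrdetectScore(f, model)@score)
})
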