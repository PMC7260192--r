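test_that("conversion-aware identity treats read T opposite reference C as match", {
    amp <- toyAmplicon(10)
    conv <- bisulfiteTemplate(amp, methylated = FALSE)
    aln <- bisulfiteAlign(conv, amp)
    expect_equal(aln$identity, 1)
    expect_identical(aln$non_bisulfite_mismatches, 0L)
    expect_identical(aln$cpg_methylated, 0L)
    meth <- bisulfiteTemplate(amp, methylated = TRUE)
    alnM <- bisulfiteAlign(meth, amp)
    expect_equal(alnM$identity, 1)
    expect_identical(alnM$cpg_methylated, 10L)
})

test_that("non-bisulfite substitutions are counted as mismatches", {
    amp <- toyAmplicon(10)
    meth <- strsplit(bisulfiteTemplate(amp, methylated = TRUE), "")[[1]]
    aPos <- which(meth == "A")[c(2, 5)]
    meth[aPos] <- "G"       # two A->G substitutions at non-C positions
    aln <- bisulfiteAlign(paste(meth, collapse = ""), amp)
    expect_identical(aln$non_bisulfite_mismatches, 2L)
    expect_equal(aln$identity, 1 - 2 / 50)
})

test_that("QC rejects in the documented order with recorded reasons", {
    amp <- toyAmplicon(10)

    # > 1 non-bisulfite mismatch at high identity -> excess_mismatch
    twoMm <- strsplit(bisulfiteTemplate(amp, methylated = TRUE), "")[[1]]
    twoMm[which(twoMm == "A")[c(1, 3)]] <- "G"
    calls <- callReads(paste(twoMm, collapse = ""), amp)
    expect_identical(calls$reject_reason, "excess_mismatch")
    expect_false(calls$methylated)

    # a raw (unconverted) genomic read over an amplicon with non-CpG
    # cytosines aligns perfectly but fails conversion QC
    ampC <- ampliconReference("withC", "ACGTACATTACGTTCAATTACGTT")
    raw <- callReads(as.character(ampC@sequence), ampC)
    expect_identical(raw$reject_reason, "incomplete_conversion")
    expect_equal(raw$identity, 1)
    expect_identical(raw$unconverted_noncpg_c, 2L)
    # the default tolerance of 0 unconverted cytosines is configurable
    lax <- callReads(as.character(ampC@sequence), ampC, maxUnconverted = 2)
    expect_true(lax$passed_qc)

    # low identity dominates all other reasons
    short <- substr(bisulfiteTemplate(amp, methylated = TRUE), 1, 20)
    expect_identical(callReads(short, amp)$reject_reason, "low_identity")
    random <- paste(rep("A", 50), collapse = "")
    expect_identical(callReads(random, amp)$reject_reason, "low_identity")
})

test_that("read call uses a strict >90% CpG threshold", {
    amp <- toyAmplicon(10)
    meth <- strsplit(bisulfiteTemplate(amp, methylated = TRUE), "")[[1]]
    full <- callReads(paste(meth, collapse = ""), amp)
    expect_true(full$methylated)
    # 9 of 10 sites methylated is exactly 0.90 -> NOT methylated
    nine <- meth
    nine[amp@cpgPositions[1] + 1] <- "T"
    res9 <- callReads(paste(nine, collapse = ""), amp)
    expect_identical(res9$cpg_methylated, 9L)
    expect_false(res9$methylated)
})

test_that("excluded CpG sites leave numerator and denominator", {
    # 12 sites, 2 excluded; both excluded sites methylated on every read
    amp12 <- toyAmplicon(12)
    excl <- amp12@cpgPositions[c(3, 9)]
    ampEx <- ampliconReference("RAD51C_like",
                               as.character(amp12@sequence),
                               excludedSites = excl)
    meth <- strsplit(bisulfiteTemplate(ampEx, methylated = TRUE), "")[[1]]
    # unmethylate one non-excluded site: 9/10 remaining = 0.90 -> negative
    keepSites <- setdiff(ampEx@cpgPositions, excl)
    read <- meth
    read[keepSites[1] + 1] <- "T"
    res <- callReads(paste(read, collapse = ""), ampEx)
    expect_identical(res$cpg_total, 10L)
    expect_identical(res$cpg_methylated, 9L)
    expect_false(res$methylated)
    # all 10 remaining methylated -> positive
    expect_true(callReads(paste(meth, collapse = ""), ampEx)$methylated)
})

test_that("alignment scores agree with an exhaustive DP oracle on toys", {
    withr::with_seed(99, {
        for (i in 1:25) {
            ref <- paste(sample(c("A", "C", "G", "T"), sample(12:20, 1),
                                replace = TRUE), collapse = "")
            if (!grepl("CG", ref)) next
            amp <- ampliconReference("toy", ref)
            n <- sample(8:20, 1)
            read <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
            got <- bisulfiteAlign(read, amp, gapOpening = 0, gapExtension = 2)
            if (!got$aligned) next
            expect_equal(got$score,
                         oracleAlignScore(read, ref, gap = 2),
                         tolerance = 1e-9)
        }
    })
})

test_that("error-free synthetic reads round-trip exactly", {
    amp <- defaultAmplicons()$BRCA1
    methReads <- simulateBisulfiteReads(amp, 1, 80, 0, 0, seed = 21)
    convReads <- simulateBisulfiteReads(amp, 0, 80, 0, 0, seed = 22)
    expect_true(all(callReads(methReads, amp)$methylated))
    expect_false(any(callReads(convReads, amp)$methylated))
})

test_that("called methylated fraction tracks the simulated fraction", {
    amp <- defaultAmplicons()$RAD51C
    reads <- simulateBisulfiteReads(amp, 0.3, 2000, 0.002, 0.001, seed = 31)
    res <- summarizeSample(callReads(reads, amp), sampleId = "s")
    se <- sqrt(0.3 * 0.7 / 2000)
    expect_lt(abs(res@methylatedFraction - 0.3), 3 * se + 0.01)
    expect_true(res@samplePositive)
})

test_that("calling is invariant to read order", {
    amp <- defaultAmplicons()$BRCA1
    reads <- simulateBisulfiteReads(amp, 0.4, 150, 0.005, 0.003, seed = 41)
    fwd <- callReads(reads, amp)
    perm <- withr::with_seed(5, sample(length(reads)))
    rev <- callReads(reads[perm], amp)
    expect_equal(rev$methylated, fwd$methylated[perm])
    sFwd <- summarizeSample(fwd, sampleId = "a")
    sRev <- summarizeSample(rev, sampleId = "a")
    expect_identical(sFwd@methylatedReads, sRev@methylatedReads)
    expect_identical(sFwd@readsPassed, sRev@readsPassed)
})

test_that("raising conversion error never increases passed reads", {
    amp <- defaultAmplicons()$BRCA1
    lo <- simulateBisulfiteReads(amp, 0.5, 2000, 0.000, 0.001, seed = 51)
    hi <- simulateBisulfiteReads(amp, 0.5, 2000, 0.030, 0.001, seed = 51)
    nLo <- sum(callReads(lo, amp)$passed_qc)
    nHi <- sum(callReads(hi, amp)$passed_qc)
    expect_gte(nLo, nHi)
})

test_that("sample summary handles zero passed reads", {
    amp <- toyAmplicon(10)
    junk <- paste(rep("A", 50), collapse = "")
    res <- summarizeSample(callReads(junk, amp), sampleId = "bad")
    expect_identical(res@readsPassed, 0L)
    expect_true(is.na(res@samplePositive))
    expect_error(summarizeSample(callReads(junk, amp)[0, ]), "one read")
})
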