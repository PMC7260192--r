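#' Construct a promoter amplicon reference
#'
#' @param name amplicon identifier.
#' @param sequence unconverted genomic top-strand sequence between the
#'   primers (character or \code{DNAString}).
#' @param cpgPositions 0-based offsets of CpG cytosines; autodetected from
#'   the sequence when NULL.
#' @param excludedSites CpG positions excluded from methylation calling
#'   (numerator and denominator), e.g. sites found constitutively
#'   methylated in all samples.
#' @param primers optional forward/reverse primer annotation.
#' @return an \linkS4class{AmpliconReference}.
#' @export
ampliconReference <- function(name, sequence, cpgPositions = NULL,
                              excludedSites = integer(),
                              primers = character()) {
    seqc <- toupper(as.character(sequence))
    if (nchar(seqc) == 0L) stop("empty amplicon sequence")
    if (is.null(cpgPositions)) {
        hits <- gregexpr("CG", seqc, fixed = TRUE)[[1L]]
        cpgPositions <- if (hits[1L] == -1L) integer() else as.integer(hits - 1L)
    }
    if (length(cpgPositions) == 0L)
        stop("amplicon must contain at least one CpG site")
    new("AmpliconReference", name = name,
        sequence = Biostrings::DNAString(seqc),
        cpgPositions = as.integer(sort(cpgPositions)),
        excludedSites = as.integer(sort(excludedSites)),
        primers = primers)
}

#' Bisulfite conversion templates of an amplicon
#'
#' The fully methylated template retains CpG cytosines and converts every
#' other cytosine to thymine; the fully converted (unmethylated) template
#' converts all cytosines.
#'
#' @param amplicon an \linkS4class{AmpliconReference}.
#' @param methylated logical; which template.
#' @return character sequence.
#' @export
bisulfiteTemplate <- function(amplicon, methylated = TRUE) {
    s <- strsplit(as.character(amplicon@sequence), "")[[1L]]
    isC <- s == "C"
    if (methylated) {
        keep <- rep(FALSE, length(s))
        keep[amplicon@cpgPositions + 1L] <- TRUE
        s[isC & !keep] <- "T"
    } else {
        s[isC] <- "T"
    }
    paste(s, collapse = "")
}

.bisulfiteSubstMatrix <- function(match = 1, mismatch = -2) {
    bases <- c("A", "C", "G", "T", "N")
    m <- matrix(mismatch, 5L, 5L, dimnames = list(bases, bases))
    diag(m) <- match
    m["N", ] <- mismatch; m[, "N"] <- mismatch; m["N", "N"] <- mismatch
    # a read T opposite a reference C is a potential bisulfite conversion,
    # scored as a match (rows = read/pattern, cols = reference/subject)
    m["T", "C"] <- match
    m
}

#' Bisulfite-aware global alignment of merged amplicon reads
#'
#' Aligns each read globally to the unconverted amplicon with
#' bisulfite-aware scoring: a read T opposite a reference C scores as a
#' match (potential conversion), every other substitution is a
#' non-bisulfite mismatch. Identity is the fraction of reference positions
#' matched (T-opposite-C included). Reads shorter than 30% of the amplicon
#' are not aligned and are reported with identity 0.
#'
#' @param reads character vector or \code{DNAStringSet} of merged,
#'   primer-trimmed reads (top-strand orientation).
#' @param amplicon an \linkS4class{AmpliconReference}.
#' @param gapOpening,gapExtension affine gap penalties (positive costs).
#' @param match,mismatch substitution scores.
#' @return data.frame, one row per read: \code{read_id}, \code{aligned},
#'   \code{identity}, \code{non_bisulfite_mismatches},
#'   \code{unconverted_noncpg_c}, \code{cpg_total}, \code{cpg_methylated},
#'   \code{cpg_degenerate} (any scored CpG column neither C nor T), and
#'   \code{score}.
#' @export
bisulfiteAlign <- function(reads, amplicon, gapOpening = 10,
                           gapExtension = 4, match = 1, mismatch = -2) {
    reads <- Biostrings::DNAStringSet(reads)
    n <- length(reads)
    if (n == 0L) stop("no reads supplied")
    refc <- as.character(amplicon@sequence)
    refLen <- nchar(refc)
    cpgAll <- amplicon@cpgPositions
    cpgUsed <- setdiff(cpgAll, amplicon@excludedSites)
    cpgTotal <- length(cpgUsed)
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_len(n))

    out <- data.frame(read_id = ids, aligned = FALSE, identity = 0,
                      non_bisulfite_mismatches = NA_integer_,
                      unconverted_noncpg_c = NA_integer_,
                      cpg_total = cpgTotal, cpg_methylated = NA_integer_,
                      cpg_degenerate = NA, score = NA_real_,
                      stringsAsFactors = FALSE)
    long <- Biostrings::width(reads) >= 0.3 * refLen
    if (!any(long)) return(out)

    al <- Biostrings::pairwiseAlignment(
        reads[long], amplicon@sequence, type = "global",
        substitutionMatrix = .bisulfiteSubstMatrix(match, mismatch),
        gapOpening = gapOpening, gapExtension = gapExtension)
    # pattern projected into reference coordinates: every aligned string
    # has reference length (deletions as "-", inserted read bases dropped;
    # insertions reduce neither identity nor the mismatch count)
    alM <- do.call(rbind, strsplit(as.character(Biostrings::aligned(al)), ""))
    refChars <- strsplit(refc, "")[[1L]]
    refM <- matrix(refChars, nrow = nrow(alM), ncol = refLen, byrow = TRUE)
    isMatch <- (alM == refM & alM != "-") | (refM == "C" & alM == "T")
    nonCpgC <- which(refChars == "C" & !(seq_len(refLen) - 1L) %in% cpgAll)
    cpgCols <- cpgUsed + 1L
    cpgM <- alM[, cpgCols, drop = FALSE]

    out$aligned[long] <- TRUE
    out$identity[long] <- rowSums(isMatch) / refLen
    out$non_bisulfite_mismatches[long] <-
        as.integer(rowSums(alM != "-" & !isMatch))
    out$unconverted_noncpg_c[long] <-
        as.integer(rowSums(alM[, nonCpgC, drop = FALSE] == "C"))
    out$cpg_methylated[long] <- as.integer(rowSums(cpgM == "C"))
    out$cpg_degenerate[long] <- rowSums(cpgM != "C" & cpgM != "T") > 0L
    out$score[long] <- Biostrings::score(al)
    out
}

#' Read-level quality filter for bisulfite amplicon alignments
#'
#' Applies, in order: identity below \code{minIdentity} (reject
#' \code{low_identity}); more than \code{maxMismatch} non-bisulfite
#' mismatches (\code{excess_mismatch}); more than \code{maxUnconverted}
#' unconverted cytosines at non-CpG sites, i.e. incomplete bisulfite
#' conversion (\code{incomplete_conversion}); any scored CpG site neither C
#' nor T, or no scorable CpG sites (\code{degenerate_cpg}).
#'
#' @param aln data.frame from [bisulfiteAlign()].
#' @param minIdentity minimum conversion-aware identity (default 0.90).
#' @param maxMismatch maximum non-bisulfite mismatches (default 1).
#' @param maxUnconverted maximum unconverted non-CpG cytosines
#'   (default 0, the strictest reading; configurable).
#' @return the input with \code{passed_qc} and \code{reject_reason}
#'   columns added.
#' @export
methylationQc <- function(aln, minIdentity = 0.90, maxMismatch = 1L,
                          maxUnconverted = 0L) {
    reason <- rep("none", nrow(aln))
    reason[aln$cpg_total == 0L | (aln$aligned & aln$cpg_degenerate)] <-
        "degenerate_cpg"
    reason[aln$aligned & aln$unconverted_noncpg_c > maxUnconverted] <-
        "incomplete_conversion"
    reason[aln$aligned & aln$non_bisulfite_mismatches > maxMismatch] <-
        "excess_mismatch"
    reason[!aln$aligned | aln$identity < minIdentity] <- "low_identity"
    aln$passed_qc <- reason == "none"
    aln$reject_reason <- reason
    aln
}

#' Per-read methylation calls for one sample
#'
#' Aligns, filters and calls each merged bisulfite read: a CpG site is
#' methylated when the read base at that reference cytosine is C, and a
#' read is called methylated when strictly more than \code{callThreshold}
#' (default 90%) of its scorable CpG sites are methylated. Excluded sites
#' never enter numerator or denominator.
#'
#' @inheritParams bisulfiteAlign
#' @inheritParams methylationQc
#' @param callThreshold strict lower bound on the methylated CpG fraction.
#' @return data.frame of per-read calls: the [bisulfiteAlign()] columns
#'   plus \code{passed_qc}, \code{reject_reason} and \code{methylated}.
#' @examples
#' amp <- ampliconReference("toy", "ACGTTACGGATCGA")
#' callReads(bisulfiteTemplate(amp, methylated = TRUE), amp)
#' @export
callReads <- function(reads, amplicon, minIdentity = 0.90, maxMismatch = 1L,
                      maxUnconverted = 0L, callThreshold = 0.90,
                      gapOpening = 10, gapExtension = 4) {
    aln <- bisulfiteAlign(reads, amplicon, gapOpening = gapOpening,
                          gapExtension = gapExtension)
    aln <- methylationQc(aln, minIdentity = minIdentity,
                         maxMismatch = maxMismatch,
                         maxUnconverted = maxUnconverted)
    aln$methylated <- aln$passed_qc &
        aln$cpg_methylated / aln$cpg_total > callThreshold
    aln
}

#' Sample-level methylation summary
#'
#' @param calls per-read calls from [callReads()].
#' @param positivityThreshold methylated-read fraction at or above which
#'   the sample is methylation positive (default 0.10; the source assay
#'   reports samples as methylated or not without a printed fraction
#'   threshold, so this is a package default, not an inferred value).
#' @param minReads minimum passed reads for a determinate sample call.
#' @param sampleId sample identifier.
#' @return a \linkS4class{SampleMethylationResult}. With zero passed reads
#'   the methylated fraction is NA and the sample call undetermined.
#' @export
summarizeSample <- function(calls, positivityThreshold = 0.10,
                            minReads = 100L, sampleId = "sample") {
    if (nrow(calls) == 0L) stop("need at least one read")
    passed <- sum(calls$passed_qc)
    meth <- sum(calls$methylated)
    frac <- if (passed > 0L) meth / passed else NA_real_
    pos <- if (passed >= minReads) frac >= positivityThreshold else NA
    new("SampleMethylationResult", sampleId = sampleId,
        readsTotal = nrow(calls), readsPassed = as.integer(passed),
        methylatedReads = as.integer(meth), methylatedFraction = frac,
        samplePositive = pos, positivityThreshold = positivityThreshold)
}
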